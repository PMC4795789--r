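#' Output-stream features: NP, MP, MPT
#'
#' The segment-level filter reduces a network output stream (default 10
#' scores in \[-1, +1\]) to three features:
#'
#' * `feature_np()` — NP, the number of strictly positive scores;
#' * `feature_mp()` — MP, the sum of the positive scores divided by the
#'   stream length;
#' * `feature_mpt()` — MPT, the sum of the scores strictly above the inner
#'   threshold `tau`, divided by the stream length.
#'
#' "Positive" means strictly greater than zero throughout; MPT compares
#' strictly against `tau`.
#'
#' @param stream Numeric vector of network scores (non-empty).
#' @param tau Strictly positive inner threshold for MPT, typically from
#'   [calibrate_tau()].
#' @return A single number (NP an integer count; MP and MPT in \[0, 1\]).
#' @name stream_features
#' @examples
#' s <- c(0.5, 0.3, 0.1, -0.2, -0.4, -0.1, -0.3, -0.5, -0.2, -0.1)
#' feature_np(s)
#' feature_mp(s)
#' feature_mpt(s, tau = 0.2)
NULL

check_stream <- function(stream) {
  if (length(stream) == 0) abort("output stream must be non-empty")
  if (!is.numeric(stream)) abort("output stream must be numeric")
  invisible(stream)
}

#' @rdname stream_features
#' @export
feature_np <- function(stream) {
  check_stream(stream)
  sum(stream > 0)
}

#' @rdname stream_features
#' @export
feature_mp <- function(stream) {
  check_stream(stream)
  sum(stream[stream > 0]) / length(stream)
}

#' @rdname stream_features
#' @export
feature_mpt <- function(stream, tau) {
  check_stream(stream)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single number > 0")
  }
  sum(stream[stream > tau]) / length(stream)
}

#' Calibrate the inner MPT threshold tau
#'
#' `tau` is the mean of all strictly positive scores pooled over the
#' validation output streams.
#'
#' @param streams A list of numeric output streams (or a single stream).
#' @return The calibrated `tau`.
#' @export
#' @examples
#' calibrate_tau(list(c(0.1, -0.5), c(0.3, -0.2)))
calibrate_tau <- function(streams) {
  if (is.numeric(streams)) streams <- list(streams)
  pooled <- unlist(streams, use.names = FALSE)
  pos <- pooled[pooled > 0]
  if (length(pos) == 0) {
    abort("cannot calibrate tau: no positive values in the validation streams")
  }
  mean(pos)
}

#' Calibrate a feature bound from validation features
#'
#' When the negative-segment features and positive-segment features are
#' separated by a gap (every negative below every positive), the bound is
#' the midpoint of the gap. When the distributions overlap, the bound is the
#' threshold (over candidate feature values) that maximizes validation
#' accuracy under the rule "positive iff feature > bound", taking the lowest
#' such threshold on ties.
#'
#' @param pos_features Feature values from positive (digging) validation
#'   segments.
#' @param neg_features Feature values from negative validation segments.
#' @return The calibrated bound.
#' @export
#' @examples
#' calibrate_bounds(pos_features = c(0.3, 0.4), neg_features = c(0.05, 0.10))
calibrate_bounds <- function(pos_features, neg_features) {
  if (length(pos_features) == 0 || length(neg_features) == 0) {
    abort("both feature collections must be non-empty")
  }
  lo <- max(neg_features)
  hi <- min(pos_features)
  if (lo < hi) {
    return((lo + hi) / 2)
  }
  # Overlap: scan every pooled feature value as a candidate strict threshold.
  cand <- sort(unique(c(pos_features, neg_features)))
  acc <- vapply(cand, function(th) {
    (sum(pos_features > th) + sum(neg_features <= th)) /
      (length(pos_features) + length(neg_features))
  }, numeric(1))
  cand[which.max(acc)]  # which.max takes the first (lowest) maximizer
}

#' Filter thresholds
#'
#' Bundle of the calibrated thresholds used by the two-of-three segment
#' vote: the inner MPT threshold `tau`, the MP and MPT feature bounds, and
#' the NP count bound (default 2 — on digging segments at least a quarter of
#' the 10 scores are positive).
#'
#' @param tau Inner MPT threshold, > 0.
#' @param mp_bound,mpt_bound Feature bounds (strict).
#' @param np_bound Minimum count of positive scores (>= comparison).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(tau, mp_bound, mpt_bound, np_bound = 2L) {
  if (!is.finite(tau) || tau <= 0) abort("`tau` must be > 0")
  check_scalar_number(mp_bound, "mp_bound")
  check_scalar_number(mpt_bound, "mpt_bound")
  check_scalar_number(np_bound, "np_bound", lower = 1, integer = TRUE)
  structure(
    list(tau = tau, mp_bound = mp_bound, mpt_bound = mpt_bound,
         np_bound = as.integer(np_bound)),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf(
    "<filter_thresholds> tau=%.4f, MP>%.4f, MPT>%.4f, NP>=%d\n",
    x$tau, x$mp_bound, x$mpt_bound, x$np_bound))
  invisible(x)
}

#' Calibrate the segment filter on labelled validation streams
#'
#' Runs the full calibration procedure: `tau` as the mean of pooled positive
#' scores over all validation streams, then the MP and MPT bounds from the
#' per-class feature values via [calibrate_bounds()].
#'
#' @param streams List of output streams, one per validation segment.
#' @param labels Activity or binary labels, one per stream (digging is the
#'   positive class).
#' @param np_bound NP count bound (default 2).
#' @return A [filter_thresholds()] object.
#' @export
calibrate_filter <- function(streams, labels, np_bound = 2L) {
  if (length(streams) != length(labels)) {
    abort("`streams` and `labels` must have the same length")
  }
  binary <- as_binary_label(labels)
  if (!any(binary == "digging") || !any(binary == "non-digging")) {
    abort("calibration needs streams of both classes")
  }
  tau <- calibrate_tau(streams)
  mp <- vapply(streams, feature_mp, numeric(1))
  mpt <- vapply(streams, feature_mpt, numeric(1), tau = tau)
  pos <- binary == "digging"
  filter_thresholds(
    tau = tau,
    mp_bound = calibrate_bounds(mp[pos], mp[!pos]),
    mpt_bound = calibrate_bounds(mpt[pos], mpt[!pos]),
    np_bound = np_bound
  )
}

#' Classify one segment by the two-of-three feature vote
#'
#' Each feature votes positive when it clears its threshold — NP when at
#' least `np_bound` scores are positive, MP and MPT when strictly above
#' their bounds — and the segment is classified as digging if and only if at
#' least two of the three votes are positive.
#'
#' @param stream Output stream of the segment.
#' @param thresholds A [filter_thresholds()] object.
#' @return `"digging"` or `"non-digging"`.
#' @export
classify_segment <- function(stream, thresholds) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  votes <- segment_votes(stream, thresholds)
  if (sum(votes) >= 2L) "digging" else "non-digging"
}

# The three boolean feature votes for one stream.
segment_votes <- function(stream, thresholds) {
  c(np = feature_np(stream) >= thresholds$np_bound,
    mp = feature_mp(stream) > thresholds$mp_bound,
    mpt = feature_mpt(stream, thresholds$tau) > thresholds$mpt_bound)
}

#' Classify every scored segment of a tibble
#'
#' Tidy wrapper over [classify_segment()]: takes a segment tibble carrying a
#' `stream` list-column (from [output_streams()]) and adds the feature
#' values, the votes and the predicted binary label.
#'
#' @param segments Segment tibble with a `stream` list-column.
#' @param thresholds A [filter_thresholds()] object.
#' @return `segments` with added columns `np`, `mp`, `mpt`, `votes` and
#'   `pred`.
#' @export
classify_segments <- function(segments, thresholds) {
  if (!"stream" %in% names(segments)) {
    abort("`segments` must carry a `stream` list-column; see output_streams()")
  }
  segments %>%
    mutate(
      np = vapply(.data$stream, feature_np, numeric(1)),
      mp = vapply(.data$stream, feature_mp, numeric(1)),
      mpt = vapply(.data$stream, feature_mpt, numeric(1),
                   tau = thresholds$tau),
      votes = vapply(.data$stream, function(s) {
        sum(segment_votes(s, thresholds))
      }, numeric(1)),
      pred = vapply(.data$stream, classify_segment, character(1),
                    thresholds = thresholds)
    )
}

#' Serialize filter thresholds next to a model file
#'
#' @param thresholds A [filter_thresholds()] object.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read filter thresholds written by [write_thresholds()]
#'
#' @param path Path to the JSON thresholds file.
#' @return A [filter_thresholds()] object.
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_thresholds(obj$tau, obj$mp_bound, obj$mpt_bound, obj$np_bound)
}
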