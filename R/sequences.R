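#' Build a labelled accelerometer sequence tibble
#'
#' A sequence is the unit of data collection: one bout of a single activity
#' (digging, walking or eating) recorded by a carapace-mounted accelerometer.
#' Sequences are represented in long form, one row per sample, so that many
#' sequences can be stacked in a single tibble and manipulated with dplyr.
#'
#' @param x Integer vector of x-axis accelerometer counts (the axis the
#'   recognition system analyses).
#' @param label Activity label: one of `"digging"`, `"walking"`, `"eating"`.
#' @param id Sequence identifier (unique within a dataset).
#' @param rate_hz Sampling rate in Hz; 4 at collection, 1 after
#'   down-sampling.
#' @param y Optional integer vector of y-axis counts, same length as `x`.
#'   Ingested and round-tripped but never used by the models.
#' @return A tibble with columns `id`, `label`, `rate_hz`, `t` (0-based
#'   sample index), `x` and `y` (`NA` when absent).
#' @export
#' @examples
#' acc_sequence(c(510L, 540L, 480L), label = "digging", id = "d01")
acc_sequence <- function(x, label, id = "seq1", rate_hz = 4, y = NULL) {
  if (length(x) == 0) abort("`x` must be non-empty")
  if (any(!is.finite(x)) || any(x != round(x))) {
    abort("`x` must contain only finite integer samples")
  }
  if (!is.null(y)) {
    if (length(y) != length(x)) abort("`y` must have the same length as `x`")
    if (any(!is.finite(y)) || any(y != round(y))) {
      abort("`y` must contain only finite integer samples")
    }
  }
  if (!is.character(label) || length(label) != 1L ||
      !label %in% ACTIVITY_LEVELS) {
    abort(paste0("`label` must be one of: ",
                 paste(ACTIVITY_LEVELS, collapse = ", ")))
  }
  if (!rate_hz %in% c(4, 1)) abort("`rate_hz` must be 4 (raw) or 1 (down-sampled)")
  tibble(
    id = as.character(id),
    label = label,
    rate_hz = as.numeric(rate_hz),
    t = seq_along(x) - 1L,
    x = as.integer(x),
    y = if (is.null(y)) NA_integer_ else as.integer(y)
  )
}

# Check the long-form sequence tibble contract shared by all modules.
validate_sequences <- function(seqs, arg = "seqs") {
  needed <- c("id", "label", "rate_hz", "t", "x")
  missing <- setdiff(needed, names(seqs))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(seqs) == 0) abort(sprintf("`%s` contains no samples", arg))
  bad <- setdiff(unique(seqs$label), ACTIVITY_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("`%s` has unknown label(s): %s", arg,
                  paste(bad, collapse = ", ")))
  }
  if (!all(unique(seqs$rate_hz) %in% c(4, 1))) {
    abort(sprintf("`%s` has rate_hz outside {4, 1}", arg))
  }
  invisible(seqs)
}

#' Read accelerometer sequences from the flat text format
#'
#' The on-disk format is a self-describing flat text file: each sequence is a
#' section opened by header lines `#id=`, `#label=` and `#rate_hz=`, followed
#' by one CSV row per sample with columns `t,x` or `t,x,y`. Integer samples
#' are parsed exactly.
#'
#' @param path Path to a sequence file written by [write_sequences()].
#' @return A long-form sequence tibble (see [acc_sequence()]).
#' @seealso [write_sequences()]
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  sections <- list()
  hdr <- list()
  rows <- list()
  n_rows <- 0L
  open <- FALSE
  start_line <- NA_integer_

  flush_section <- function() {
    if (!open) return()
    for (key in c("id", "label", "rate_hz")) {
      if (is.null(hdr[[key]])) {
        abort(sprintf("section starting at line %d is missing header '#%s='",
                      start_line, key))
      }
    }
    if (n_rows == 0L) {
      abort(sprintf("section '%s' (line %d) has an empty data section",
                    hdr$id, start_line))
    }
    m <- do.call(rbind, rows[seq_len(n_rows)])
    seq_tbl <- acc_sequence(
      x = m[, 2], label = hdr$label, id = hdr$id,
      rate_hz = as.numeric(hdr$rate_hz),
      y = if (ncol(m) == 3 && !anyNA(m[, 3])) m[, 3] else NULL
    )
    sections[[length(sections) + 1L]] <<- seq_tbl
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, "#")) {
      kv <- regmatches(line, regexec("^#([A-Za-z_]+)=(.*)$", line))[[1]]
      if (length(kv) != 3) {
        abort(sprintf("line %d: malformed header line '%s'", i, line))
      }
      key <- kv[2]; value <- kv[3]
      if (key == "id") {
        flush_section()
        hdr <- list(); rows <- list(); n_rows <- 0L
        open <- TRUE; start_line <- i
      } else if (!open) {
        abort(sprintf("line %d: header '#%s=' before any '#id=' line", i, key))
      }
      hdr[[key]] <- value
    } else {
      if (!open) abort(sprintf("line %d: data row before any '#id=' header", i))
      fields <- strsplit(line, ",", fixed = TRUE)[[1]]
      if (!length(fields) %in% c(2L, 3L)) {
        abort(sprintf("line %d: expected 2 or 3 comma-separated fields, got %d",
                      i, length(fields)))
      }
      vals <- suppressWarnings(as.numeric(fields))
      if (anyNA(vals) || any(vals != round(vals))) {
        abort(sprintf("line %d: malformed integer row '%s'", i, line))
      }
      n_rows <- n_rows + 1L
      rows[[n_rows]] <- if (length(vals) == 2L) c(vals, NA) else vals
    }
  }
  flush_section()
  if (length(sections) == 0) abort(sprintf("file '%s' contains no sequences", path))
  bind_rows(sections)
}

#' Write accelerometer sequences to the flat text format
#'
#' @param seqs Long-form sequence tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sequences()]
#' @export
write_sequences <- function(seqs, path) {
  validate_sequences(seqs)
  ids <- unique(seqs$id)
  out <- character(0)
  for (sid in ids) {
    s <- seqs[seqs$id == sid, , drop = FALSE]
    has_y <- "y" %in% names(s) && !anyNA(s$y)
    out <- c(out,
             sprintf("#id=%s", sid),
             sprintf("#label=%s", s$label[[1]]),
             sprintf("#rate_hz=%s", format(s$rate_hz[[1]])),
             if (has_y) sprintf("%d,%d,%d", s$t, s$x, s$y)
             else sprintf("%d,%d", s$t, s$x))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Default part sizes for the four-way dataset split
#'
#' The protocol splits the segment dataset into four disjoint parts: patterns
#' to train the network (67 positive + 67 negative 90-step patterns),
#' patterns to select its configuration (10 + 10), segments to calibrate the
#' output filter (15 + 15), and segments for the final test (28 + 28). Sizes
#' are per class.
#'
#' @param ann_train,ann_validation Number of patterns per class.
#' @param filter_validation,test Number of segments per class.
#' @param patterns_per_segment Maximum number of 90-step patterns drawn from
#'   one 300-step source segment.
#' @return A named list of counts.
#' @export
split_counts <- function(ann_train = 67, ann_validation = 10,
                         filter_validation = 15, test = 28,
                         patterns_per_segment = 2) {
  for (nm in c("ann_train", "ann_validation", "filter_validation", "test")) {
    check_scalar_number(get(nm), nm, lower = 1, integer = TRUE)
  }
  check_scalar_number(patterns_per_segment, "patterns_per_segment",
                      lower = 1, integer = TRUE)
  list(ann_train = as.integer(ann_train),
       ann_validation = as.integer(ann_validation),
       filter_validation = as.integer(filter_validation),
       test = as.integer(test),
       patterns_per_segment = as.integer(patterns_per_segment))
}

# Offsets (0-based) of rising edges in a normalized 1 Hz segment, usable as
# start offsets of a two-wave characteristic pattern. An edge is a sign
# change low -> high of the lightly smoothed signal with a sustained run on
# both sides, which makes the detector robust to sample noise.
edge_offsets <- function(samples, window_len, min_run = 3L) {
  sm <- moving_average(samples, 3L)
  s <- sm > 0
  n <- length(s)
  cand <- integer(0)
  run <- rle(s)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  for (j in seq_along(run$lengths)[-1]) {
    if (run$values[j] && !run$values[j - 1L] &&
        run$lengths[j] >= min_run && run$lengths[j - 1L] >= min_run) {
      cand <- c(cand, starts[j] - 1L)  # 0-based
    }
  }
  cand[cand + window_len <= length(samples)]
}

# Draw up to `k` pattern offsets from one segment. Negative patterns use
# random offsets (drawn from the active RNG stream) for maximum coverage of
# the non-digging window space. Positive (digging) patterns follow
# `alignment`: "edge" anchors every pattern at a rising edge (the canonical
# two-square-wave characteristic pattern), "random" samples free phases,
# "mixed" anchors the first pattern per segment at an edge and samples the
# rest freely (phase-tolerant training around the characteristic pattern).
pattern_offsets <- function(samples, window_len, k, positive,
                            alignment = "edge") {
  L <- length(samples)
  random_offsets <- function(m) {
    sort(sample.int(L - window_len + 1L, min(m, L - window_len + 1L)) - 1L)
  }
  if (!positive) return(random_offsets(k))
  ed <- edge_offsets(samples, window_len)
  if (alignment == "random" || length(ed) == 0) return(random_offsets(k))
  keep <- ed[c(TRUE, diff(ed) >= window_len %/% 2)]  # near-disjoint edges
  if (alignment == "edge") return(head(keep, k))
  unique(c(keep[1], random_offsets(k - 1L)))[seq_len(min(k, 1L + (k - 1L)))]
}

#' Split segments into the four-part train/validation/test layout
#'
#' Partitions a segment tibble into the four disjoint parts of the protocol
#' (see [split_counts()]): network training patterns, network validation
#' patterns, filter-validation segments and test segments. Parts are disjoint
#' by source segment, class-balanced, and deterministic given `seed`.
#'
#' @param segments Segment tibble from [extract_segments()] (1 Hz, 300-step
#'   segments with a `label` column).
#' @param counts Part sizes per class, from [split_counts()].
#' @param seed Integer seed controlling the shuffle.
#' @param window_len Pattern length in time steps.
#' @param alignment Positive-pattern phase policy: `"edge"` anchors every
#'   positive pattern at a rising edge of the square wave (default), `"random"`
#'   samples free phases, `"mixed"` anchors one pattern per
#'   segment and samples the rest freely, which trains the network to
#'   recognize the characteristic pattern at any phase of the shifting
#'   window.
#' @return An object of class `dataset_split`: a list with pattern tibbles
#'   `ann_train` and `ann_validation` (columns `pattern_id`, `source_id`,
#'   `offset`, `target`, `samples`) and segment tibbles `filter_validation`
#'   and `test`.
#' @export
make_split <- function(segments, counts = split_counts(), seed = 1L,
                       window_len = 90L,
                       alignment = c("edge", "mixed", "random")) {
  alignment <- match.arg(alignment)
  if (!all(c("segment_id", "source_id", "offset", "label", "samples") %in%
           names(segments))) {
    abort("`segments` must come from extract_segments()")
  }
  pos <- segments[segments$label == "digging", , drop = FALSE]
  neg <- segments[segments$label != "digging", , drop = FALSE]
  pps <- counts$patterns_per_segment
  need_pat_seg <- function(n_pat) as.integer(ceiling(n_pat / pps))
  need_pos <- counts$test + counts$filter_validation +
    need_pat_seg(counts$ann_train) + need_pat_seg(counts$ann_validation)
  need_neg <- need_pos
  if (nrow(pos) < need_pos) {
    abort(sprintf(
      "insufficient positive (digging) segments: need %d, have %d",
      need_pos, nrow(pos)))
  }
  if (nrow(neg) < need_neg) {
    abort(sprintf(
      "insufficient negative (non-digging) segments: need %d, have %d",
      need_neg, nrow(neg)))
  }

  with_seed(seed, {
    pos <- pos[sample.int(nrow(pos)), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg)), , drop = FALSE]

    take <- function(df, n) {
      list(part = df[seq_len(n), , drop = FALSE],
           rest = df[-seq_len(n), , drop = FALSE])
    }
    p <- take(pos, counts$test); pos_test <- p$part; pos <- p$rest
    n <- take(neg, counts$test); neg_test <- n$part; neg <- n$rest
    p <- take(pos, counts$filter_validation); pos_fv <- p$part; pos <- p$rest
    n <- take(neg, counts$filter_validation); neg_fv <- n$part; neg <- n$rest

    draw_patterns <- function(df, n_pat, positive) {
      out <- vector("list", 0)
      got <- 0L
      used <- 0L
      for (i in seq_len(nrow(df))) {
        if (got >= n_pat) break
        used <- i
        smp <- df$samples[[i]]
        offs <- pattern_offsets(smp, window_len, pps, positive, alignment)
        for (o in offs) {
          if (got >= n_pat) break
          got <- got + 1L
          out[[got]] <- tibble(
            source_id = df$segment_id[[i]],
            offset = as.integer(o),
            target = if (positive) 1 else -1,
            samples = list(smp[(o + 1L):(o + window_len)])
          )
        }
      }
      if (got < n_pat) {
        abort(sprintf(
          "insufficient %s segments to extract %d patterns (got %d)",
          if (positive) "positive" else "negative", n_pat, got))
      }
      list(patterns = bind_rows(out), n_used = used)
    }

    dp <- draw_patterns(pos, counts$ann_train, TRUE)
    pos_train <- dp$patterns; pos <- pos[-seq_len(dp$n_used), , drop = FALSE]
    dn <- draw_patterns(neg, counts$ann_train, FALSE)
    neg_train <- dn$patterns; neg <- neg[-seq_len(dn$n_used), , drop = FALSE]
    dp <- draw_patterns(pos, counts$ann_validation, TRUE)
    pos_val <- dp$patterns
    dn <- draw_patterns(neg, counts$ann_validation, FALSE)
    neg_val <- dn$patterns

    as_patterns <- function(df) {
      df$pattern_id <- sprintf("p%03d", seq_len(nrow(df)))
      df[, c("pattern_id", "source_id", "offset", "target", "samples")]
    }

    structure(
      list(
        ann_train = as_patterns(bind_rows(pos_train, neg_train)),
        ann_validation = as_patterns(bind_rows(pos_val, neg_val)),
        filter_validation = bind_rows(pos_fv, neg_fv),
        test = bind_rows(pos_test, neg_test),
        counts = counts,
        seed = as.integer(seed),
        window_len = as.integer(window_len)
      ),
      class = "dataset_split"
    )
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  cat(sprintf("  ann_train:         %d patterns (%d positive)\n",
              nrow(x$ann_train), sum(x$ann_train$target > 0)))
  cat(sprintf("  ann_validation:    %d patterns (%d positive)\n",
              nrow(x$ann_validation), sum(x$ann_validation$target > 0)))
  cat(sprintf("  filter_validation: %d segments (%d digging)\n",
              nrow(x$filter_validation),
              sum(x$filter_validation$label == "digging")))
  cat(sprintf("  test:              %d segments (%d digging)\n",
              nrow(x$test), sum(x$test$label == "digging")))
  invisible(x)
}
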