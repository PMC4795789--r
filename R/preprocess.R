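#' Preprocessing configuration
#'
#' Parameters of the raw-signal preprocessing chain and the window/segment
#' geometry. Defaults are the operating point of the deployed system: a
#' 5-point moving average, 4 Hz to 1 Hz down-sampling, 90-step input
#' windows shifted by a quarter window (22 steps) over 300-step segments,
#' which yields an output stream of 10 network scores per segment.
#'
#' @param ma_points Moving-average interval in samples.
#' @param downsample_factor Keep every `downsample_factor`-th sample.
#' @param window_len Input-window (and training-pattern) length in time steps.
#' @param segment_len Segment length in time steps; the segment is the unit
#'   of final classification (5 minutes at 1 Hz).
#' @param shift Window shift in time steps (a quarter of the window,
#'   truncated to 22).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(ma_points = 5L, downsample_factor = 4L,
                              window_len = 90L, segment_len = 300L,
                              shift = 22L) {
  check_scalar_number(ma_points, "ma_points", lower = 1, integer = TRUE)
  check_scalar_number(downsample_factor, "downsample_factor", lower = 1,
                      integer = TRUE)
  check_scalar_number(window_len, "window_len", lower = 1, integer = TRUE)
  check_scalar_number(segment_len, "segment_len", lower = 1, integer = TRUE)
  check_scalar_number(shift, "shift", lower = 1, integer = TRUE)
  if (window_len > segment_len) abort("`window_len` must be <= `segment_len`")
  structure(
    list(ma_points = as.integer(ma_points),
         downsample_factor = as.integer(downsample_factor),
         window_len = as.integer(window_len),
         segment_len = as.integer(segment_len),
         shift = as.integer(shift)),
    class = "preprocess_config"
  )
}

#' Centered moving-average filter
#'
#' FIR noise filter: each output sample is the mean of the centered window of
#' up to `points` input samples. At the boundaries the window is truncated
#' symmetrically (the same number of samples on each side), so the output
#' keeps the input's length and phase — no lag is introduced into the square
#' wave that marks digging.
#'
#' @param samples Numeric vector.
#' @param points Interval length in samples (odd; an even value uses the next
#'   odd size).
#' @return Numeric vector of the same length as `samples`.
#' @export
#' @examples
#' moving_average(c(0, 0, 0, 0, 20, 0, 0, 0, 0), 5)
moving_average <- function(samples, points = 5L) {
  check_scalar_number(points, "points", lower = 1, integer = TRUE)
  n <- length(samples)
  if (n < 1) abort("`samples` must be non-empty")
  r <- points %/% 2L
  if (r == 0L) return(as.numeric(samples))
  cs <- cumsum(c(0, samples))
  idx <- seq_len(n)
  ri <- pmin(r, idx - 1L, n - idx)
  (cs[idx + ri + 1L] - cs[idx - ri]) / (2 * ri + 1)
}

#' Integer normalization by mean subtraction
#'
#' Centers the signal by subtracting the (rounded) mean of all observed
#' values, keeping the network input stream in integer form — the property
#' that lets the input buffer live in integer registers on a
#' memory-constrained device. This is deliberately not a proper
#' normalization: no scaling is applied.
#'
#' Rounding is half-away-from-zero: `output[i] = round(input[i]) -
#' round(mean(input))`.
#'
#' @param samples Numeric vector (typically the moving-average output).
#' @return Integer vector of the same length; its mean is within 1 of zero.
#' @export
#' @examples
#' normalize_integer(c(10, 20, 30))
normalize_integer <- function(samples) {
  if (length(samples) == 0) abort("`samples` must be non-empty")
  as.integer(round_half_away(samples) - round_half_away(mean(samples)))
}

#' Down-sample by sample exclusion
#'
#' Reduces the sampling rate by keeping indices 0, `factor`, `2*factor`, ...
#' of the input (simple decimation, no interpolation). Applied after the
#' moving-average filter.
#'
#' @param samples Numeric vector.
#' @param factor Positive integer decimation factor (4 for 4 Hz to 1 Hz).
#' @return Vector of length `ceiling(length(samples) / factor)`.
#' @export
downsample <- function(samples, factor = 4L) {
  check_scalar_number(factor, "factor", lower = 1, integer = TRUE)
  samples[seq(1L, length(samples), by = as.integer(factor))]
}

#' Run the full preprocessing chain on raw 4 Hz sequences
#'
#' Applies, per sequence: moving-average filtering, integer normalization
#' (mean subtraction), then down-sampling to 1 Hz. Only the x axis is
#' processed; the y axis, which carries negligible discriminative
#' information, is dropped from the output.
#'
#' @param seqs Long-form raw sequence tibble at the collection rate.
#' @param cfg A [preprocess_config()].
#' @return A sequence tibble at `rate_hz = 1` with integer `x`.
#' @export
preprocess <- function(seqs, cfg = preprocess_config()) {
  validate_sequences(seqs)
  stopifnot(inherits(cfg, "preprocess_config"))
  seqs %>%
    group_by(.data$id, .data$label) %>%
    summarise(
      x = list(downsample(
        normalize_integer(moving_average(.data$x, cfg$ma_points)),
        cfg$downsample_factor)),
      .groups = "drop"
    ) %>%
    mutate(rate_hz = 1) %>%
    tidyr::unnest_longer(col = "x") %>%
    group_by(.data$id) %>%
    mutate(t = row_number() - 1L, y = NA_integer_) %>%
    ungroup() %>%
    select("id", "label", "rate_hz", "t", "x", "y")
}

#' Cut 1 Hz sequences into non-overlapping segments
#'
#' Segments are consecutive, non-overlapping slices of exactly `segment_len`
#' time steps — the unit on which the recognition system makes a decision. A
#' trailing remainder shorter than `segment_len` is discarded, never padded.
#'
#' @param seqs Sequence tibble at 1 Hz.
#' @param segment_len Segment length in time steps.
#' @return A tibble with one row per segment: `segment_id`, `source_id`,
#'   `offset` (0-based start in the parent sequence), `label`, and a
#'   `samples` list-column of integer vectors of length `segment_len`.
#' @export
extract_segments <- function(seqs, segment_len = 300L) {
  validate_sequences(seqs)
  check_scalar_number(segment_len, "segment_len", lower = 1, integer = TRUE)
  if (!all(seqs$rate_hz == 1)) abort("`seqs` must be down-sampled to 1 Hz")
  out <- list()
  for (s in group_split(group_by(seqs, .data$id))) {
    n_full <- nrow(s) %/% segment_len
    if (n_full == 0) next
    for (k in seq_len(n_full)) {
      off <- (k - 1L) * as.integer(segment_len)
      out[[length(out) + 1L]] <- tibble(
        segment_id = sprintf("%s:%d", s$id[[1]], off),
        source_id = s$id[[1]],
        offset = off,
        label = s$label[[1]],
        samples = list(s$x[(off + 1L):(off + segment_len)])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(segment_id = character(), source_id = character(),
                  offset = integer(), label = character(), samples = list()))
  }
  bind_rows(out)
}

#' Slice a segment into shifted input windows
#'
#' Windows start at offsets `0, shift, 2*shift, ...` while they fit inside
#' the segment, giving `floor((L - window_len) / shift) + 1` windows. With
#' the default geometry (300-step segment, 90-step window, 22-step shift)
#' this is exactly 10 windows, hence a 10-value output stream per segment.
#'
#' @param samples Integer vector of segment samples (length >= `window_len`).
#' @param window_len Window length in time steps.
#' @param shift Shift between consecutive windows.
#' @return A numeric matrix, one row per window, with an `offsets` attribute
#'   holding the 0-based start offsets.
#' @export
extract_windows <- function(samples, window_len = 90L, shift = 22L) {
  check_scalar_number(window_len, "window_len", lower = 1, integer = TRUE)
  check_scalar_number(shift, "shift", lower = 1, integer = TRUE)
  L <- length(samples)
  if (L < window_len) {
    abort(sprintf("segment of length %d is shorter than the window (%d)",
                  L, window_len))
  }
  offsets <- seq(0L, L - window_len, by = as.integer(shift))
  W <- matrix(0, nrow = length(offsets), ncol = window_len)
  for (i in seq_along(offsets)) {
    W[i, ] <- samples[(offsets[i] + 1L):(offsets[i] + window_len)]
  }
  attr(W, "offsets") <- as.integer(offsets)
  W
}
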