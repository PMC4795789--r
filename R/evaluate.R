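#' Run the full recognition system on a raw sequence
#'
#' End-to-end classification: preprocess the raw 4 Hz signal, cut it into
#' 300-step segments, score each segment's shifted windows with the trained
#' network and apply the two-of-three filter vote, in order.
#'
#' @param seqs Raw 4 Hz sequence tibble.
#' @param fit A trained `idnn_fit`.
#' @param thresholds Calibrated [filter_thresholds()].
#' @param pre_cfg A [preprocess_config()].
#' @return A tibble with one row per segment: `segment_id`, `source_id`,
#'   `offset`, `truth` (binary label from the sequence label) and `pred`.
#' @export
run_ars <- function(seqs, fit, thresholds, pre_cfg = preprocess_config()) {
  clean <- preprocess(seqs, pre_cfg)
  segments <- extract_segments(clean, pre_cfg$segment_len)
  if (nrow(segments) == 0) {
    return(tibble(segment_id = character(), source_id = character(),
                  offset = integer(), truth = character(),
                  pred = character()))
  }
  scored <- output_streams(fit, segments, pre_cfg$window_len, pre_cfg$shift)
  scored <- classify_segments(scored, thresholds)
  tibble(
    segment_id = scored$segment_id,
    source_id = scored$source_id,
    offset = scored$offset,
    truth = as_binary_label(scored$label),
    pred = scored$pred
  )
}

#' Confusion matrix for binary segment classification
#'
#' Digging is the positive class.
#'
#' @param truth,pred Character vectors over `c("digging", "non-digging")`
#'   (activity labels are collapsed with [as_binary_label()]).
#' @return An object of class `conf_mat` with counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have the same length")
  }
  truth <- as_binary_label(truth)
  pred <- as_binary_label(pred)
  structure(
    list(
      tp = sum(truth == "digging" & pred == "digging"),
      fn = sum(truth == "digging" & pred == "non-digging"),
      fp = sum(truth == "non-digging" & pred == "digging"),
      tn = sum(truth == "non-digging" & pred == "non-digging")
    ),
    class = "conf_mat"
  )
}

#' @export
print.conf_mat <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(`real` = c("digging", "non-digging"),
                              `predicted` = c("digging", "non-digging")))
  print(m)
  cat(sprintf("accuracy: %.2f%%\n", 100 * accuracy(x)))
  invisible(x)
}

#' Classification accuracy of a confusion matrix
#'
#' @param cm A `conf_mat` from [confusion()].
#' @return `(tp + tn) / total`, a number in \[0, 1\].
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "conf_mat"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) abort("empty confusion matrix")
  (cm$tp + cm$tn) / total
}

#' @export
tidy.conf_mat <- function(x, ...) {
  tibble(
    truth = rep(c("digging", "digging", "non-digging", "non-digging")),
    pred = rep(c("digging", "non-digging"), 2),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' Evaluate a model variant over several weight initializations
#'
#' Runs the full protocol once per seed: train the network on the training
#' patterns, record validation-pattern accuracy, recalibrate the filter
#' thresholds on the filter-validation segments (thresholds are defined on
#' the scale of that instance's outputs, so they are per-seed), classify the
#' test segments and accumulate the confusion matrix. Reports mean and
#' standard deviation of test-segment accuracy over seeds.
#'
#' @param cfg An [idnn_config()].
#' @param control A [train_control()].
#' @param split A `dataset_split` from [make_split()] or [gen_benchmark()].
#' @param seeds Integer vector of initialization seeds (default `1:5`, the
#'   protocol's five initializations).
#' @param pre_cfg A [preprocess_config()] (window geometry for the streams).
#' @return An object of class `ars_eval` with a per-seed tibble, per-seed
#'   confusion matrices and thresholds, and summary statistics. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
evaluate_multiseed <- function(cfg, control = train_control(), split,
                               seeds = 1:5, pre_cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "idnn_config"), inherits(split, "dataset_split"))
  if (length(seeds) == 0) abort("`seeds` must be non-empty")
  rows <- vector("list", length(seeds))
  mats <- vector("list", length(seeds))
  ths <- vector("list", length(seeds))
  fits <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[[i]]
    fit <- train_idnn(split$ann_train, cfg, control, seed = s)
    train_pred <- classify_pattern(cfg, fit$weights, split$ann_train)
    val_pred <- classify_pattern(cfg, fit$weights, split$ann_validation)
    fv <- output_streams(fit, split$filter_validation,
                         pre_cfg$window_len, pre_cfg$shift)
    th <- calibrate_filter(fv$stream, fv$label)
    fv_pred <- vapply(fv$stream, classify_segment, character(1),
                      thresholds = th)
    te <- output_streams(fit, split$test, pre_cfg$window_len, pre_cfg$shift)
    te <- classify_segments(te, th)
    cm <- confusion(te$label, te$pred)
    rows[[i]] <- tibble(
      seed = s,
      train_accuracy = mean(train_pred == split$ann_train$target),
      val_accuracy = mean(val_pred == split$ann_validation$target),
      filter_val_accuracy = mean(fv_pred == as_binary_label(fv$label)),
      test_accuracy = accuracy(cm),
      tau = th$tau,
      n_epochs = fit$n_epochs
    )
    mats[[i]] <- cm
    ths[[i]] <- th
    fits[[i]] <- fit
  }
  per_seed <- bind_rows(rows)
  structure(
    list(
      config = cfg,
      control = control,
      seeds = seeds,
      per_seed = per_seed,
      matrices = mats,
      thresholds = ths,
      fits = fits,
      mean_test_accuracy = mean(per_seed$test_accuracy),
      sd_test_accuracy = stats::sd(per_seed$test_accuracy)
    ),
    class = "ars_eval"
  )
}

#' @export
print.ars_eval <- function(x, ...) {
  cat(sprintf("<ars_eval> %s over %d initialization(s)\n",
              toupper(gsub("_", " ", x$config$variant)), length(x$seeds)))
  cat(sprintf("  mean test accuracy: %.2f%% (sd %.2f)\n",
              100 * x$mean_test_accuracy,
              100 * ifelse(is.na(x$sd_test_accuracy), 0,
                           x$sd_test_accuracy)))
  cat(sprintf("  mean training-pattern accuracy: %.2f%%\n",
              100 * mean(x$per_seed$train_accuracy)))
  invisible(x)
}

#' @export
tidy.ars_eval <- function(x, ...) x$per_seed

#' @export
glance.ars_eval <- function(x, ...) {
  sd_t <- x$sd_test_accuracy
  tibble(
    variant = x$config$variant,
    n_seeds = length(x$seeds),
    mean_train_accuracy = mean(x$per_seed$train_accuracy),
    mean_val_accuracy = mean(x$per_seed$val_accuracy),
    mean_filter_val_accuracy = mean(x$per_seed$filter_val_accuracy),
    mean_test_accuracy = x$mean_test_accuracy,
    sd_test_accuracy = if (length(x$seeds) == 1) 0 else sd_t,
    footprint_bytes = memory_footprint(x$config)
  )
}

#' @export
autoplot.ars_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_seed[, c("seed", "train_accuracy", "val_accuracy",
                        "test_accuracy")],
    cols = -"seed", names_to = "set", values_to = "accuracy")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$seed),
                                  y = .data$accuracy,
                                  fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "initialization seed", y = "accuracy",
                  title = sprintf("%s accuracy per initialization",
                                  toupper(gsub("_", " ",
                                               object$config$variant)))) +
    ggplot2::theme_minimal()
}

#' Confirm digging detections by repetition
#'
#' In extended monitoring the classification is repeated after two segment
#' lengths (10 minutes): a digging detection at segment `i` is confirmed
#' only if segment `i + gap_segments` is also classified digging; otherwise
#' it is rejected as a likely false identification. Detections too close to
#' the end of the run, where the confirming segment does not exist yet, are
#' reported as pending.
#'
#' @param segment_labels Ordered character vector of per-segment predictions
#'   (binary or activity labels).
#' @param gap_segments Number of segments between detection and
#'   confirmation (default 2, i.e. 10 minutes).
#' @return A tibble with one row per digging detection: `segment` (1-based
#'   index) and `status` in `c("confirmed", "rejected", "pending")`.
#' @export
#' @examples
#' confirm_digging(c("digging", "non-digging", "digging"))
#' confirm_digging(c("digging", "non-digging", "non-digging"))
confirm_digging <- function(segment_labels, gap_segments = 2L) {
  check_scalar_number(gap_segments, "gap_segments", lower = 1, integer = TRUE)
  labels <- as_binary_label(segment_labels)
  hits <- which(labels == "digging")
  status <- vapply(hits, function(i) {
    j <- i + gap_segments
    if (j > length(labels)) return("pending")
    if (labels[[j]] == "digging") "confirmed" else "rejected"
  }, character(1))
  tibble(segment = as.integer(hits), status = status)
}
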