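#' Run the full simulate -> preprocess -> train -> calibrate -> evaluate
#' pipeline
#'
#' One call drives the whole protocol from a single configuration: generate
#' the synthetic benchmark (or load sequences from a file), build the
#' four-part split, evaluate each requested model variant over the
#' configured seeds with per-seed filter recalibration, and write the
#' artifacts (model weights, thresholds, a plain-text report and a
#' machine-readable JSON report) to the output directory.
#'
#' The configuration is a named list (or a path to a JSON file with the same
#' shape) with optional entries `sim`, `composition`, `counts`, `preprocess`
#' (argument lists for [sim_config()], [benchmark_composition()],
#' [split_counts()] and [preprocess_config()]), `train` (arguments for
#' [train_control()]), `variants` (character vector), `n_hidden` (for the
#' plain IDNN), `seeds` (integer vector), `seed` (master data seed),
#' `input` (path to a sequence file to use instead of simulation) and
#' `thresholds` (path to fixed filter thresholds; skips calibration-based
#' evaluation and is applied as-is).
#'
#' @param config Named list or path to a JSON config file.
#' @param out_dir Output directory for artifacts (created if missing).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with one `ars_eval` per variant and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("nestnet-run-"),
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config stage: no such file: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config stage: `config` must be a list or a JSON path")
  say <- function(...) if (!quiet) message(sprintf(...))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(sim_config, config$sim %||% list())
  comp <- do.call(benchmark_composition, config$composition %||% list())
  counts <- do.call(split_counts, config$counts %||% list())
  pre <- do.call(preprocess_config, config$preprocess %||% list())
  ctl_for <- function(variant) {
    if (is.null(config$train)) recommended_control(variant)
    else do.call(train_control, config$train)
  }
  variants <- config$variants %||% c("idnn", "idnn_lrf", "idnn_lrf_ws")
  seeds <- as.integer(config$seeds %||% 1:5)
  seed <- as.integer(config$seed %||% 1L)

  if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      abort(sprintf("input stage: no such file: %s", config$input))
    }
    say("input stage: reading sequences from %s", config$input)
    sequences <- read_sequences(config$input)
    clean <- preprocess(sequences, pre)
    segments <- extract_segments(clean, pre$segment_len)
    split <- make_split(segments, counts, seed = seed,
                        window_len = pre$window_len)
  } else {
    say("simulate stage: composition %d/%d/%d (dig/walk/eat), seed %d",
        comp$n_digging, comp$n_walking, comp$n_eating, seed)
    bench <- gen_benchmark(sim, comp, seed = seed, counts = counts,
                           pre_cfg = pre)
    split <- bench$split
  }

  fixed_th <- if (!is.null(config$thresholds)) {
    say("calibrate stage: skipped, using fixed thresholds from %s",
        config$thresholds)
    read_thresholds(config$thresholds)
  } else {
    NULL
  }

  evals <- list()
  report_lines <- c("nest-digging recognition pipeline report", "")
  json_report <- list(seed = seed, seeds = seeds, variants = list())
  for (v in variants) {
    cfg <- idnn_config(v, n_hidden = as.integer(config$n_hidden %||% 5L))
    say("train/evaluate stage: %s over %d seed(s)", v, length(seeds))
    ev <- evaluate_multiseed_fixed(cfg, ctl_for(v), split, seeds, pre, fixed_th)
    evals[[v]] <- ev
    g <- glance(ev)
    cm <- Reduce(function(a, b) {
      structure(list(tp = a$tp + b$tp, fn = a$fn + b$fn, fp = a$fp + b$fp,
                     tn = a$tn + b$tn), class = "conf_mat")
    }, ev$matrices)
    write_model(ev$fits[[1]], file.path(out_dir, paste0(v, "-model.json")))
    if (is.null(fixed_th)) {
      write_thresholds(ev$thresholds[[1]],
                       file.path(out_dir, paste0(v, "-thresholds.json")))
    }
    report_lines <- c(report_lines,
      sprintf("%s (footprint %d bytes)", toupper(gsub("_", " ", v)),
              g$footprint_bytes),
      sprintf("  mean test accuracy: %.2f%% (sd %.2f)",
              100 * g$mean_test_accuracy, 100 * g$sd_test_accuracy),
      sprintf("  pooled confusion (real x predicted): tp=%d fn=%d fp=%d tn=%d",
              cm$tp, cm$fn, cm$fp, cm$tn),
      "")
    json_report$variants[[v]] <- c(
      as.list(g),
      list(confusion = list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn))
    )
  }
  report_path <- file.path(out_dir, "report.txt")
  writeLines(report_lines, report_path)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json_report, json_path, digits = 10,
                       auto_unbox = TRUE)
  say("report written to %s", report_path)
  invisible(list(evals = evals, report = report_path, json = json_path,
                 out_dir = out_dir))
}

# evaluate_multiseed, but optionally with externally fixed thresholds
# (per-seed recalibration skipped).
evaluate_multiseed_fixed <- function(cfg, control, split, seeds, pre_cfg,
                                     fixed_th = NULL) {
  if (is.null(fixed_th)) {
    return(evaluate_multiseed(cfg, control, split, seeds, pre_cfg))
  }
  rows <- vector("list", length(seeds))
  mats <- vector("list", length(seeds))
  fits <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[[i]]
    fit <- train_idnn(split$ann_train, cfg, control, seed = s)
    te <- output_streams(fit, split$test, pre_cfg$window_len, pre_cfg$shift)
    te <- classify_segments(te, fixed_th)
    cm <- confusion(te$label, te$pred)
    rows[[i]] <- tibble(
      seed = s,
      train_accuracy = mean(classify_pattern(cfg, fit$weights,
                                             split$ann_train) ==
                              split$ann_train$target),
      val_accuracy = mean(classify_pattern(cfg, fit$weights,
                                           split$ann_validation) ==
                            split$ann_validation$target),
      filter_val_accuracy = NA_real_,
      test_accuracy = accuracy(cm),
      tau = fixed_th$tau,
      n_epochs = fit$n_epochs
    )
    mats[[i]] <- cm
    fits[[i]] <- fit
  }
  per_seed <- bind_rows(rows)
  structure(
    list(config = cfg, control = control, seeds = seeds,
         per_seed = per_seed, matrices = mats,
         thresholds = rep(list(fixed_th), length(seeds)), fits = fits,
         mean_test_accuracy = mean(per_seed$test_accuracy),
         sd_test_accuracy = stats::sd(per_seed$test_accuracy)),
    class = "ars_eval"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
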