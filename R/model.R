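#' Network architecture configuration
#'
#' Three small input-delay network (IDNN) variants classify each 90-step
#' input window with a tanh multilayer perceptron:
#'
#' * `"idnn"` — every hidden unit sees the full window (90 inputs + bias);
#'   the number of hidden units is a free hyperparameter in 1..10 (5 was the
#'   selected operating point).
#' * `"idnn_lrf"` — local receptive fields: the window is divided into four
#'   contiguous 22-step sub-windows, one per hidden unit, matching the two
#'   ascent and two descent phases of the two-square-wave digging pattern.
#'   Fixed at 4 hidden units of 22 inputs + bias each.
#' * `"idnn_lrf_ws"` — additionally shares weights between the two ascent
#'   sub-windows and between the two descent sub-windows, reducing the model
#'   to 2 hidden units, each applied (summed pre-activation, one bias) to its
#'   two receptive fields.
#'
#' Hidden and output units all use the hyperbolic tangent, so the network
#' score lies in (-1, +1); positive scores flag windows similar to the
#' digging pattern.
#'
#' With `window_len = 90` and `subwindow_len = 22`, the four sub-windows
#' cover samples 0..87; the last two samples of the window are unused by the
#' LRF variants (4 x 22 = 88 < 90).
#'
#' @param variant One of `"idnn"`, `"idnn_lrf"`, `"idnn_lrf_ws"`.
#' @param n_hidden Hidden units for the plain IDNN (1..10). Ignored (fixed by
#'   the architecture) for the LRF variants.
#' @param window_len Input window length.
#' @param subwindow_len Receptive-field length for the LRF variants.
#' @return A list of class `idnn_config` with elements `variant`,
#'   `window_len`, `subwindow_len`, `n_hidden` (number of hidden units),
#'   `n_distinct` (number of distinct hidden weight vectors) and `input_dim`
#'   (inputs per hidden weight vector).
#' @export
#' @examples
#' idnn_config("idnn_lrf_ws")
idnn_config <- function(variant = c("idnn", "idnn_lrf", "idnn_lrf_ws"),
                        n_hidden = 5L, window_len = 90L,
                        subwindow_len = 22L) {
  variant <- match.arg(variant)
  check_scalar_number(window_len, "window_len", lower = 1, integer = TRUE)
  check_scalar_number(subwindow_len, "subwindow_len", lower = 1,
                      integer = TRUE)
  if (variant != "idnn" && 4L * subwindow_len > window_len) {
    abort("four sub-windows must fit in the input window")
  }
  if (variant == "idnn") {
    check_scalar_number(n_hidden, "n_hidden", lower = 1, upper = 10,
                        integer = TRUE)
  }
  n_hidden <- switch(variant,
                     idnn = as.integer(n_hidden),
                     idnn_lrf = 4L,
                     idnn_lrf_ws = 2L)
  structure(
    list(
      variant = variant,
      window_len = as.integer(window_len),
      subwindow_len = as.integer(subwindow_len),
      n_hidden = n_hidden,
      n_distinct = if (variant == "idnn_lrf_ws") 2L else n_hidden,
      input_dim = if (variant == "idnn") as.integer(window_len)
                  else as.integer(subwindow_len)
    ),
    class = "idnn_config"
  )
}

#' @export
print.idnn_config <- function(x, ...) {
  cat(sprintf("<idnn_config> %s: %d hidden unit(s), %d weights per hidden unit, %d bytes\n",
              toupper(gsub("_", " ", x$variant)), x$n_hidden,
              count_weights_per_hidden_unit(x), memory_footprint(x)))
  invisible(x)
}

# Column index ranges of the four contiguous sub-windows.
subwindow_cols <- function(cfg) {
  lapply(0:3, function(k) {
    (k * cfg$subwindow_len + 1L):((k + 1L) * cfg$subwindow_len)
  })
}

#' Training configuration
#'
#' Hyperparameters of full-batch backpropagation with classical momentum and
#' L2 weight decay. Ranges are enforced to the model-selection search space:
#' learning rate in \[0.0001, 0.1\], momentum in \[0, 0.1\], weight decay in
#' \[0, 0.001\]. The loss is summed (not averaged) over training patterns.
#' Input-to-hidden weights are initialized uniformly in \[-0.00001, 0.00001\]
#' and hidden-to-output weights in \[-0.01, 0.01\].
#'
#' Training stops when the relative improvement of the training loss stays
#' below `stop_tol` for `stop_patience` consecutive epochs (the "no longer
#' significant" rule) or at `max_epochs`.
#'
#' @param learning_rate Gradient-descent step size.
#' @param momentum Heavy-ball momentum coefficient.
#' @param weight_decay L2 penalty coefficient (biases included).
#' @param max_epochs Epoch cap.
#' @param stop_tol Relative-improvement threshold.
#' @param stop_patience Consecutive below-threshold epochs before stopping.
#' @param init_hidden,init_output Half-widths of the uniform initialization
#'   ranges for the two layers.
#' @return A list of class `train_control`.
#' @export
train_control <- function(learning_rate = 1e-4, momentum = 0.05,
                          weight_decay = 1e-5, max_epochs = 5000L,
                          stop_tol = 1e-5, stop_patience = 10L,
                          init_hidden = 1e-5, init_output = 0.01) {
  check_scalar_number(learning_rate, "learning_rate", 1e-4, 0.1)
  check_scalar_number(momentum, "momentum", 0, 0.1)
  check_scalar_number(weight_decay, "weight_decay", 0, 0.001)
  check_scalar_number(max_epochs, "max_epochs", lower = 1, integer = TRUE)
  check_scalar_number(stop_tol, "stop_tol", lower = 0)
  check_scalar_number(stop_patience, "stop_patience", lower = 1,
                      integer = TRUE)
  check_scalar_number(init_hidden, "init_hidden", lower = 0)
  check_scalar_number(init_output, "init_output", lower = 0)
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
         stop_tol = stop_tol, stop_patience = as.integer(stop_patience),
         init_hidden = init_hidden, init_output = init_output),
    class = "train_control"
  )
}

#' Hyperparameters selected for each architecture variant
#'
#' The training hyperparameters chosen by validation-based model selection
#' on the synthetic benchmark, within the protocol's search ranges (learning
#' rate in \[0.0001, 0.1\], momentum in \[0, 0.1\], weight decay in
#' \[0, 0.001\]). The full-window IDNN prefers a larger step with a binding
#' weight decay; the receptive-field variants train best with a smaller
#' step.
#'
#' @param variant One of `"idnn"`, `"idnn_lrf"`, `"idnn_lrf_ws"`.
#' @return A [train_control()].
#' @export
recommended_control <- function(variant = c("idnn", "idnn_lrf",
                                            "idnn_lrf_ws")) {
  variant <- match.arg(variant)
  if (variant == "idnn") {
    train_control(learning_rate = 1e-3, weight_decay = 1e-3)
  } else {
    train_control(learning_rate = 3e-4)
  }
}

#' Initialize a weight set
#'
#' Input-to-hidden weights (including hidden biases) are drawn uniformly
#' from the narrow range `[-init_hidden, init_hidden]` (default 1e-5);
#' hidden-to-output weights and the output bias from
#' `[-init_output, init_output]` (default 0.01). Deterministic given `seed`.
#'
#' @param cfg An [idnn_config()].
#' @param control A [train_control()] (supplies the init ranges).
#' @param seed Integer seed.
#' @return A list of class `weight_set` with `W` (matrix `input_dim` x
#'   `n_distinct` of hidden input weights), `b` (hidden biases, one per
#'   distinct hidden unit), `v` (output weights, one per hidden unit) and
#'   `c` (output bias).
#' @export
init_weights <- function(cfg, control = train_control(), seed = 1L) {
  stopifnot(inherits(cfg, "idnn_config"))
  with_seed(seed, {
    structure(
      list(
        W = matrix(runif(cfg$input_dim * cfg$n_distinct,
                         -control$init_hidden, control$init_hidden),
                   nrow = cfg$input_dim, ncol = cfg$n_distinct),
        b = runif(cfg$n_distinct, -control$init_hidden, control$init_hidden),
        v = runif(cfg$n_hidden, -control$init_output, control$init_output),
        c = runif(1, -control$init_output, control$init_output)
      ),
      class = "weight_set"
    )
  })
}

# Coerce a pattern/window argument to an n x window_len matrix.
as_window_matrix <- function(x, window_len) {
  if (is.matrix(x)) {
    X <- x
  } else if (is.numeric(x)) {
    X <- matrix(x, nrow = 1)
  } else if (is.data.frame(x) && "samples" %in% names(x)) {
    X <- do.call(rbind, x$samples)
  } else if (is.list(x)) {
    X <- do.call(rbind, x)
  } else {
    abort("cannot interpret input as windows")
  }
  if (ncol(X) != window_len) {
    abort(sprintf("window length %d does not match the configured %d",
                  ncol(X), window_len))
  }
  X
}

# Hidden pre-activations, one column per hidden unit. For the weight-shared
# variant, each unit sums the pre-activations of its two receptive fields
# through the single shared vector and adds its bias once.
hidden_preact <- function(cfg, w, X) {
  switch(cfg$variant,
    idnn = sweep(X %*% w$W, 2, w$b, "+"),
    idnn_lrf = {
      cols <- subwindow_cols(cfg)
      P <- matrix(0, nrow(X), 4L)
      for (k in 1:4) P[, k] <- X[, cols[[k]], drop = FALSE] %*% w$W[, k]
      sweep(P, 2, w$b, "+")
    },
    idnn_lrf_ws = {
      cols <- subwindow_cols(cfg)
      P <- matrix(0, nrow(X), 2L)
      # unit 1 (ascent): sub-windows 1 and 3; unit 2 (descent): 2 and 4
      P[, 1] <- X[, cols[[1]], drop = FALSE] %*% w$W[, 1] +
                X[, cols[[3]], drop = FALSE] %*% w$W[, 1]
      P[, 2] <- X[, cols[[2]], drop = FALSE] %*% w$W[, 2] +
                X[, cols[[4]], drop = FALSE] %*% w$W[, 2]
      sweep(P, 2, w$b, "+")
    }
  )
}

# Forward pass with intermediates retained for backpropagation.
forward_cache <- function(cfg, w, X) {
  P <- hidden_preact(cfg, w, X)
  A <- tanh(P)
  z <- drop(A %*% w$v) + w$c
  list(A = A, o = tanh(z))
}

#' Network forward pass
#'
#' Computes the tanh network score for one or more input windows. Scores lie
#' strictly inside (-1, +1); positive scores indicate similarity to the
#' characteristic digging pattern.
#'
#' @param cfg An [idnn_config()].
#' @param w A `weight_set`.
#' @param windows A numeric vector (one window), a matrix (one window per
#'   row), a list of windows, or a pattern tibble with a `samples`
#'   list-column.
#' @return Numeric vector of scores, one per window.
#' @export
idnn_forward <- function(cfg, w, windows) {
  X <- as_window_matrix(windows, cfg$window_len)
  forward_cache(cfg, w, X)$o
}

# Sum of squares over every trainable parameter, biases included.
weight_sq_norm <- function(w) {
  sum(w$W^2) + sum(w$b^2) + sum(w$v^2) + w$c^2
}

#' Training loss
#'
#' Sum over patterns of the squared difference between the network score and
#' the +1/-1 target, plus `weight_decay` times the squared L2 norm of all
#' weights (biases included).
#'
#' @inheritParams idnn_forward
#' @param targets Numeric vector of +1/-1 targets, one per window.
#' @param weight_decay L2 penalty coefficient.
#' @return A single non-negative number.
#' @export
idnn_loss <- function(cfg, w, windows, targets, weight_decay = 0) {
  o <- idnn_forward(cfg, w, windows)
  if (length(o) != length(targets)) {
    abort("`targets` must have one entry per window")
  }
  sum((o - targets)^2) + weight_decay * weight_sq_norm(w)
}

# Analytic gradient of idnn_loss with respect to every parameter. For the
# weight-shared variant the shared vector's gradient is the sum of the
# gradients contributed by both of its receptive fields.
idnn_gradient <- function(cfg, w, X, targets, weight_decay = 0) {
  fc <- forward_cache(cfg, w, X)
  A <- fc$A; o <- fc$o
  dz <- 2 * (o - targets) * (1 - o^2)        # dL/dz at the output unit
  gv <- drop(crossprod(A, dz)) + 2 * weight_decay * w$v
  gc <- sum(dz) + 2 * weight_decay * w$c
  dP <- (dz %o% w$v) * (1 - A^2)             # dL/dP, n x n_hidden
  gb <- colSums(dP) + 2 * weight_decay * w$b
  gW <- switch(cfg$variant,
    idnn = crossprod(X, dP),
    idnn_lrf = {
      cols <- subwindow_cols(cfg)
      G <- matrix(0, cfg$input_dim, 4L)
      for (k in 1:4) {
        G[, k] <- crossprod(X[, cols[[k]], drop = FALSE], dP[, k])
      }
      G
    },
    idnn_lrf_ws = {
      cols <- subwindow_cols(cfg)
      G <- matrix(0, cfg$input_dim, 2L)
      G[, 1] <- crossprod(X[, cols[[1]], drop = FALSE], dP[, 1]) +
                crossprod(X[, cols[[3]], drop = FALSE], dP[, 1])
      G[, 2] <- crossprod(X[, cols[[2]], drop = FALSE], dP[, 2]) +
                crossprod(X[, cols[[4]], drop = FALSE], dP[, 2])
      G
    }
  )
  list(W = gW + 2 * weight_decay * w$W, b = gb, v = gv, c = gc)
}

#' Train a network by full-batch backpropagation
#'
#' Gradient descent on the summed squared-error loss with classical
#' (heavy-ball) momentum and weight decay. Weight decay is applied in the
#' classical multiplicative form, `w <- w - lr * grad + momentum_term -
#' weight_decay * w`: each epoch shrinks every weight (biases included) by
#' the decay factor, which bounds the weight magnitude at equilibrium and
#' keeps the tanh units out of hard saturation. (As a loss-penalty
#' coefficient the stated search range \[0, 0.001\] would change weights by
#' less than 1e-6 per epoch at these learning rates — it would do nothing.)
#' With only 134 training patterns the batch is the full training set. Stops
#' by the [train_control()] rule.
#'
#' @param patterns Pattern tibble (columns `samples`, `target`) or a matrix
#'   of windows together with `targets`.
#' @param cfg An [idnn_config()].
#' @param control A [train_control()].
#' @param seed Integer seed for weight initialization.
#' @param targets Targets when `patterns` is a bare matrix; ignored when
#'   `patterns` is a tibble with a `target` column.
#' @return An object of class `idnn_fit`: the configuration, trained
#'   `weights`, the per-epoch loss `log` (a tibble), and convergence
#'   bookkeeping. Supports [predict()][predict.idnn_fit()], [tidy()],
#'   [glance()] and [autoplot()].
#' @export
train_idnn <- function(patterns, cfg = idnn_config(), control = train_control(),
                       seed = 1L, targets = NULL) {
  stopifnot(inherits(cfg, "idnn_config"), inherits(control, "train_control"))
  if (is.data.frame(patterns)) {
    if (!"target" %in% names(patterns)) abort("patterns need a `target` column")
    targets <- patterns$target
  }
  X <- as_window_matrix(patterns, cfg$window_len)
  if (nrow(X) == 0) abort("empty training set")
  if (is.null(targets) || length(targets) != nrow(X)) {
    abort("`targets` must have one entry per pattern")
  }
  if (!all(targets %in% c(-1, 1))) abort("targets must be +1 or -1")

  w <- init_weights(cfg, control, seed)
  vel <- list(W = w$W * 0, b = w$b * 0, v = w$v * 0, c = 0)
  lambda <- control$weight_decay
  losses <- numeric(control$max_epochs)
  prev <- idnn_loss(cfg, w, X, targets)
  calm <- 0L
  epoch <- 0L
  converged <- FALSE
  while (epoch < control$max_epochs) {
    epoch <- epoch + 1L
    g <- idnn_gradient(cfg, w, X, targets)
    for (p in c("W", "b", "v", "c")) {
      vel[[p]] <- control$momentum * vel[[p]] - control$learning_rate * g[[p]]
      w[[p]] <- w[[p]] + vel[[p]] - lambda * w[[p]]
    }
    cur <- idnn_loss(cfg, w, X, targets)
    losses[epoch] <- cur
    rel <- (prev - cur) / max(prev, .Machine$double.eps)
    calm <- if (rel < control$stop_tol) calm + 1L else 0L
    prev <- cur
    if (calm >= control$stop_patience) {
      converged <- TRUE
      break
    }
  }
  epochs_run <- seq_len(epoch)
  structure(
    list(
      config = cfg,
      control = control,
      weights = w,
      seed = as.integer(seed),
      n_patterns = nrow(X),
      log = tibble(epoch = epochs_run, loss = losses[epochs_run]),
      n_epochs = epoch,
      final_loss = prev,
      converged = converged
    ),
    class = "idnn_fit"
  )
}

#' @export
print.idnn_fit <- function(x, ...) {
  cat(sprintf(
    "<idnn_fit> %s, %d hidden unit(s), trained on %d patterns (seed %d)\n",
    toupper(gsub("_", " ", x$config$variant)), x$config$n_hidden,
    x$n_patterns, x$seed))
  cat(sprintf("  epochs: %d%s, final loss: %.4f\n", x$n_epochs,
              if (x$converged) " (converged)" else " (epoch cap)",
              x$final_loss))
  invisible(x)
}

#' Predict from a fitted network
#'
#' @param object An `idnn_fit`.
#' @param newdata Windows in any form accepted by [idnn_forward()].
#' @param type `"score"` for the raw tanh score in (-1, +1); `"class"` for
#'   the +1/-1 sign decision (an exact 0 maps to -1, the conservative
#'   non-digging side).
#' @param ... Unused.
#' @return Numeric vector of scores or +1/-1 classes.
#' @export
predict.idnn_fit <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  o <- idnn_forward(object$config, object$weights, newdata)
  if (type == "score") o else classify_pattern(object$config, object$weights, newdata)
}

#' Sign decision for a single window
#'
#' Maps the network score to a +1 (characteristic-pattern-like) or -1 target;
#' an exact zero score resolves to -1 so ties never raise a false digging
#' flag.
#'
#' @inheritParams idnn_forward
#' @return Vector of +1/-1.
#' @export
classify_pattern <- function(cfg, w, windows) {
  o <- idnn_forward(cfg, w, windows)
  ifelse(o > 0, 1, -1)
}

#' Score the shifted windows of one segment
#'
#' Applies the network to every shifted window of a 300-step segment, in
#' order, producing the segment's output stream: 10 scores in (-1, +1) with
#' the default geometry.
#'
#' @param fit An `idnn_fit` (or a list with `config` and `weights`).
#' @param samples Integer vector of segment samples.
#' @param window_len,shift Window geometry (see [extract_windows()]).
#' @return Numeric vector of window scores.
#' @export
output_stream <- function(fit, samples, window_len = 90L, shift = 22L) {
  W <- extract_windows(samples, window_len, shift)
  idnn_forward(fit$config, fit$weights, W)
}

#' Score every segment of a segment tibble
#'
#' Tidy wrapper around [output_stream()]: adds a `stream` list-column with
#' one output stream per segment row.
#'
#' @param fit An `idnn_fit`.
#' @param segments Segment tibble from [extract_segments()].
#' @inheritParams output_stream
#' @return `segments` with an added `stream` list-column.
#' @export
output_streams <- function(fit, segments, window_len = 90L, shift = 22L) {
  segments$stream <- lapply(segments$samples, function(s) {
    output_stream(fit, s, window_len, shift)
  })
  segments
}

#' Weights stored per hidden unit
#'
#' Number of weights one hidden unit needs, including its bias: 91 for the
#' plain IDNN (full 90-step window), 23 for both local-receptive-field
#' variants (22-step sub-window).
#'
#' @param cfg An [idnn_config()].
#' @return Integer count.
#' @export
count_weights_per_hidden_unit <- function(cfg) {
  stopifnot(inherits(cfg, "idnn_config"))
  cfg$input_dim + 1L
}

#' Memory footprint of a network's weights
#'
#' Bytes needed to memorize the input weight vectors of the hidden units and
#' the output unit: `(distinct hidden vectors x (inputs + bias) + output
#' weights + output bias) x bytes_per_weight`. Weight sharing stores one
#' vector for each pair of tied receptive fields, which is what makes the
#' smallest variant fit comfortably inside a few-kilobyte device: 1844 bytes
#' for the 5-hidden-unit IDNN, 388 for the LRF variant, 196 with weight
#' sharing. The 90-value integer input buffer is not part of this count.
#'
#' @param cfg An [idnn_config()].
#' @param bytes_per_weight Bytes per stored weight (4 for single-precision
#'   float).
#' @return Integer byte count.
#' @export
#' @examples
#' memory_footprint(idnn_config("idnn", n_hidden = 5))
#' memory_footprint(idnn_config("idnn_lrf_ws"))
memory_footprint <- function(cfg, bytes_per_weight = 4L) {
  stopifnot(inherits(cfg, "idnn_config"))
  check_scalar_number(bytes_per_weight, "bytes_per_weight", lower = 1,
                      integer = TRUE)
  n_float <- cfg$n_distinct * (cfg$input_dim + 1L) + cfg$n_hidden + 1L
  as.integer(n_float * bytes_per_weight)
}

#' Select the best configuration on the validation patterns
#'
#' Trains every candidate `(config, control)` pair over `n_seeds` seeds and
#' ranks candidates by mean validation pattern accuracy (fraction of
#' validation patterns whose sign decision matches the target). Ties are
#' broken toward the smaller memory footprint, then the lower grid index —
#' the deployment-driven preference for cheaper models.
#'
#' @param grid A list of candidates, each a list with elements `config` (an
#'   [idnn_config()]) and `control` (a [train_control()]).
#' @param train_patterns,val_patterns Pattern tibbles.
#' @param n_seeds Number of weight initializations per candidate.
#' @return A list with `best` (index into `grid`), `config`, `control`, and
#'   a `report` tibble (one row per candidate: mean/sd validation accuracy,
#'   footprint).
#' @export
select_model <- function(grid, train_patterns, val_patterns, n_seeds = 5L) {
  if (length(grid) == 0) abort("`grid` must contain at least one candidate")
  check_scalar_number(n_seeds, "n_seeds", lower = 1, integer = TRUE)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cand <- grid[[i]]
    accs <- vapply(seq_len(n_seeds), function(s) {
      fit <- train_idnn(train_patterns, cand$config, cand$control, seed = s)
      pred <- classify_pattern(fit$config, fit$weights, val_patterns)
      mean(pred == val_patterns$target)
    }, numeric(1))
    rows[[i]] <- tibble(
      candidate = i,
      variant = cand$config$variant,
      n_hidden = cand$config$n_hidden,
      mean_val_accuracy = mean(accs),
      sd_val_accuracy = stats::sd(accs),
      footprint_bytes = memory_footprint(cand$config)
    )
  }
  report <- bind_rows(rows)
  ord <- order(-report$mean_val_accuracy, report$footprint_bytes,
               report$candidate)
  best <- report$candidate[ord[1]]
  list(best = best, config = grid[[best]]$config,
       control = grid[[best]]$control, report = report)
}

#' @export
tidy.idnn_fit <- function(x, ...) {
  w <- x$weights
  hidden <- tibble(
    layer = "hidden",
    unit = rep(seq_len(ncol(w$W) ), each = nrow(w$W) + 1L),
    term = rep(c(paste0("w", seq_len(nrow(w$W))), "bias"), ncol(w$W)),
    estimate = as.numeric(rbind(w$W, w$b))
  )
  output <- tibble(
    layer = "output",
    unit = 1L,
    term = c(paste0("h", seq_along(w$v)), "bias"),
    estimate = c(w$v, w$c)
  )
  bind_rows(hidden, output)
}

#' @export
glance.idnn_fit <- function(x, ...) {
  tibble(
    variant = x$config$variant,
    n_hidden = x$config$n_hidden,
    n_patterns = x$n_patterns,
    n_epochs = x$n_epochs,
    final_loss = x$final_loss,
    converged = x$converged,
    weights_per_hidden_unit = count_weights_per_hidden_unit(x$config),
    footprint_bytes = memory_footprint(x$config)
  )
}

#' @export
autoplot.idnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "epoch", y = "training loss (summed squared error + decay)",
      title = sprintf("%s training curve",
                      toupper(gsub("_", " ", object$config$variant)))
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a fitted network to flat JSON
#'
#' @param fit An `idnn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "idnn_fit"))
  obj <- list(
    config = unclass(fit$config),
    control = unclass(fit$control),
    seed = fit$seed,
    weights = list(W = as.numeric(fit$weights$W),
                   dim_W = dim(fit$weights$W),
                   b = fit$weights$b, v = fit$weights$v, c = fit$weights$c)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted network written by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return An `idnn_fit` (without the training log).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- idnn_config(obj$config$variant, n_hidden = obj$config$n_hidden,
                     window_len = obj$config$window_len,
                     subwindow_len = obj$config$subwindow_len)
  ctl <- do.call(train_control, obj$control)
  w <- structure(
    list(W = matrix(obj$weights$W, obj$weights$dim_W[1], obj$weights$dim_W[2]),
         b = obj$weights$b, v = obj$weights$v, c = obj$weights$c),
    class = "weight_set"
  )
  structure(
    list(config = cfg, control = ctl, weights = w, seed = obj$seed,
         n_patterns = NA_integer_, log = tibble(epoch = integer(),
                                                loss = numeric()),
         n_epochs = NA_integer_, final_loss = NA_real_, converged = NA),
    class = "idnn_fit"
  )
}
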