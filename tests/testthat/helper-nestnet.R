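# Shared fixtures and oracles, all built in code at test time.

# Small toy configurations whose forward pass can be checked by hand.
toy_config <- function(variant) {
  idnn_config(variant, n_hidden = 3L, window_len = 8L, subwindow_len = 2L)
}

# Structured random weights at a controllable scale (init_weights draws from
# the tiny protocol ranges, which is too small for gradient exercises).
rand_weights <- function(cfg, scale = 0.5, seed = 99L) {
  w <- init_weights(cfg, train_control(), seed = seed)
  with_seed2(seed + 1L, {
    w$W <- matrix(runif(length(w$W), -scale, scale), nrow(w$W), ncol(w$W))
    w$b <- runif(length(w$b), -scale, scale)
    w$v <- runif(length(w$v), -scale, scale)
    w$c <- runif(1, -scale, scale)
  })
  w
}

# Local seeded-RNG scope for test code.
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Independent central finite-difference gradient oracle.
fd_gradient <- function(cfg, w, X, targets, weight_decay = 0, eps = 1e-6) {
  g <- list()
  for (p in c("W", "b", "v", "c")) {
    gp <- w[[p]]
    for (j in seq_along(gp)) {
      wp <- w; wm <- w
      wp[[p]][j] <- wp[[p]][j] + eps
      wm[[p]][j] <- wm[[p]][j] - eps
      gp[j] <- (idnn_loss(cfg, wp, X, targets, weight_decay) -
                idnn_loss(cfg, wm, X, targets, weight_decay)) / (2 * eps)
    }
    g[[p]] <- gp
  }
  g
}

max_rel_dev <- function(a, b) {
  max(mapply(function(x, y) max(abs(x - y) / pmax(abs(y), 1e-8)), a, b))
}

# A small synthetic world shared by the end-to-end module tests (the
# acceptance suite builds the full-size benchmark itself). Cached per
# session.
.tiny_cache <- new.env(parent = emptyenv())
tiny_benchmark <- function() {
  if (is.null(.tiny_cache$bench)) {
    .tiny_cache$bench <- gen_benchmark(
      sim_config(),
      composition = benchmark_composition(n_digging = 13, n_walking = 5,
                                          n_eating = 2, dur_walking = 1500),
      seed = 7,
      counts = split_counts(ann_train = 12, ann_validation = 4,
                            filter_validation = 4, test = 8)
    )
  }
  .tiny_cache$bench
}

# A quick trained model + thresholds on the tiny world.
tiny_fit <- function(variant = "idnn_lrf_ws") {
  key <- paste0("fit_", variant)
  if (is.null(.tiny_cache[[key]])) {
    bench <- tiny_benchmark()
    ctl <- recommended_control(variant)
    ctl$max_epochs <- 1500L
    fit <- train_idnn(bench$split$ann_train, idnn_config(variant), ctl,
                      seed = 1)
    fv <- output_streams(fit, bench$split$filter_validation)
    th <- calibrate_filter(fv$stream, fv$label)
    .tiny_cache[[key]] <- list(fit = fit, thresholds = th)
  }
  .tiny_cache[[key]]
}
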