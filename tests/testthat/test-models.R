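test_that("architecture configurations enforce the variant structure", {
  expect_equal(idnn_config("idnn", n_hidden = 7)$n_hidden, 7L)
  expect_error(idnn_config("idnn", n_hidden = 0))
  expect_error(idnn_config("idnn", n_hidden = 11))
  lrf <- idnn_config("idnn_lrf")
  expect_equal(lrf$n_hidden, 4L)
  expect_equal(lrf$input_dim, 22L)
  ws <- idnn_config("idnn_lrf_ws")
  expect_equal(ws$n_hidden, 2L)
  expect_equal(ws$n_distinct, 2L)
  expect_error(idnn_config("idnn_lrf", subwindow_len = 30), "sub-windows")
})

test_that("weight and memory accounting matches the deployment arithmetic", {
  expect_equal(count_weights_per_hidden_unit(idnn_config("idnn")), 91L)
  expect_equal(count_weights_per_hidden_unit(idnn_config("idnn_lrf")), 23L)
  expect_equal(count_weights_per_hidden_unit(idnn_config("idnn_lrf_ws")), 23L)
  # closed form for the plain IDNN at window 90: 4 * (H*91 + H + 1) bytes
  for (H in 1:10) {
    expect_equal(memory_footprint(idnn_config("idnn", n_hidden = H)),
                 4L * (H * 91L + H + 1L))
  }
  expect_equal(memory_footprint(idnn_config("idnn_lrf")), 388L)
  expect_equal(memory_footprint(idnn_config("idnn_lrf_ws")), 196L)
  expect_equal(memory_footprint(idnn_config("idnn_lrf_ws"),
                                bytes_per_weight = 8), 392L)
})

test_that("initialization respects the two layer ranges and the seed", {
  for (v in c("idnn", "idnn_lrf", "idnn_lrf_ws")) {
    cfg <- idnn_config(v)
    w <- init_weights(cfg, train_control(), seed = 42)
    expect_true(all(abs(w$W) <= 1e-5))
    expect_true(all(abs(w$b) <= 1e-5))
    expect_true(all(abs(w$v) <= 0.01))
    expect_lte(abs(w$c), 0.01)
    expect_identical(w, init_weights(cfg, train_control(), seed = 42))
    expect_false(identical(w, init_weights(cfg, train_control(), seed = 43)))
  }
  ws <- init_weights(idnn_config("idnn_lrf_ws"), train_control(), seed = 1)
  expect_equal(dim(ws$W), c(22L, 2L))  # two distinct shared vectors
  expect_length(ws$v, 2L)
})

test_that("forward pass: tanh range, zero map, and a hand-computed toy net", {
  for (v in c("idnn", "idnn_lrf", "idnn_lrf_ws")) {
    cfg <- toy_config(v)
    w0 <- rand_weights(cfg)
    w0$W[] <- 0; w0$b[] <- 0; w0$v[] <- 0; w0$c <- 0
    expect_equal(idnn_forward(cfg, w0, rnorm(8)), 0)
    w <- rand_weights(cfg, scale = 2)
    o <- idnn_forward(cfg, w, matrix(rnorm(50 * 8, sd = 3), 50, 8))
    expect_true(all(o > -1 & o < 1))
  }

  # window_len = 4, subwindow_len = 1: LRF forward checked by hand
  cfg <- idnn_config("idnn_lrf", window_len = 4, subwindow_len = 1)
  w <- list(W = matrix(c(0.5, -1, 2, 0.25), nrow = 1),
            b = c(0.1, -0.2, 0.3, 0), v = c(1, -0.5, 0.25, 2), c = -0.3)
  x <- c(2, 1, -1, 4)
  h <- tanh(c(0.5 * 2 + 0.1, -1 * 1 - 0.2, 2 * -1 + 0.3, 0.25 * 4))
  expect_equal(idnn_forward(cfg, w, x), tanh(sum(h * w$v) - 0.3))

  # weight-shared toy net checked by hand: unit sums both its fields
  cfgw <- idnn_config("idnn_lrf_ws", window_len = 4, subwindow_len = 1)
  ww <- list(W = matrix(c(0.5, -1), nrow = 1), b = c(0.1, -0.2),
             v = c(1, 2), c = 0.05)
  # fields: unit 1 reads x[1] and x[3]; unit 2 reads x[2] and x[4]
  h1 <- tanh(0.5 * (2 + -1) + 0.1)
  h2 <- tanh(-1 * (1 + 4) - 0.2)
  expect_equal(idnn_forward(cfgw, ww, x), tanh(h1 + 2 * h2 + 0.05))
})

test_that("weight sharing makes the output exactly invariant to field swaps", {
  cfg <- idnn_config("idnn_lrf_ws")
  w <- rand_weights(cfg, scale = 0.1)
  with_seed2(21, {
    for (k in 1:10) {
      x <- as.numeric(sample(-30:30, 90, replace = TRUE))
      x_swap <- x
      x_swap[1:22] <- x[45:66];  x_swap[45:66] <- x[1:22]    # ascent pair
      x_swap[23:44] <- x[67:88]; x_swap[67:88] <- x[23:44]   # descent pair
      expect_identical(idnn_forward(cfg, w, x), idnn_forward(cfg, w, x_swap))
    }
  })
})

test_that("loss is the summed squared error plus the weight penalty", {
  cfg <- toy_config("idnn")
  w0 <- rand_weights(cfg)
  w0$W[] <- 0; w0$b[] <- 0; w0$v[] <- 0; w0$c <- 0
  X <- matrix(rnorm(8), 1, 8)
  expect_equal(idnn_loss(cfg, w0, X, 0, weight_decay = 0), 0)
  w <- rand_weights(cfg)
  expect_gt(idnn_loss(cfg, w, X, 1, weight_decay = 0.001),
            idnn_loss(cfg, w, X, 1, weight_decay = 0))
  # single pattern by hand
  o <- idnn_forward(cfg, w, X)
  sq <- sum(w$W^2) + sum(w$b^2) + sum(w$v^2) + w$c^2
  expect_equal(idnn_loss(cfg, w, X, -1, weight_decay = 0.5),
               (o + 1)^2 + 0.5 * sq)
})

test_that("backpropagation gradients match central finite differences", {
  with_seed2(31, {
    for (v in c("idnn", "idnn_lrf", "idnn_lrf_ws")) {
      cfg <- toy_config(v)
      w <- rand_weights(cfg, scale = 0.4, seed = 7)
      X <- matrix(rnorm(5 * 8), 5, 8)
      targets <- c(1, -1, 1, -1, 1)
      ga <- nestnet:::idnn_gradient(cfg, w, X, targets, 5e-4)
      gf <- fd_gradient(cfg, w, X, targets, 5e-4)
      expect_lt(max_rel_dev(ga, gf), 1e-6)
    }
  })
})

test_that("training separates a separable toy task and decay shrinks weights", {
  cfg <- toy_config("idnn")
  X <- rbind(matrix(1, 10, 8), matrix(-1, 10, 8))
  targets <- rep(c(1, -1), each = 10)
  ctl <- train_control(learning_rate = 0.01, max_epochs = 2000)
  fit <- train_idnn(X, cfg, ctl, seed = 1, targets = targets)
  expect_equal(classify_pattern(cfg, fit$weights, X), targets)
  expect_s3_class(fit$log, "tbl_df")
  expect_equal(nrow(fit$log), fit$n_epochs)

  norm_of <- function(w) sqrt(sum(w$W^2) + sum(w$b^2) + sum(w$v^2) + w$c^2)
  ctl_decay <- train_control(learning_rate = 0.01, max_epochs = 2000,
                             weight_decay = 0.001)
  fit_decay <- train_idnn(X, cfg, ctl_decay, seed = 1, targets = targets)
  expect_lt(norm_of(fit_decay$weights), norm_of(fit$weights))

  expect_error(train_idnn(X[0, , drop = FALSE], cfg, ctl,
                          targets = numeric(0)), "empty")
  expect_error(train_idnn(X, cfg, ctl, targets = rep(0.5, 20)), "targets")
})

test_that("training loss does not increase in the first epoch at a small step", {
  with_seed2(41, {
    for (v in c("idnn", "idnn_lrf", "idnn_lrf_ws")) {
      cfg <- toy_config(v)
      X <- matrix(rnorm(12 * 8, sd = 2), 12, 8)
      targets <- rep(c(1, -1), 6)
      ctl <- train_control(learning_rate = 1e-4, max_epochs = 1,
                           weight_decay = 0, momentum = 0)
      w0 <- init_weights(cfg, ctl, seed = 5)
      l0 <- idnn_loss(cfg, w0, X, targets)
      fit <- train_idnn(X, cfg, ctl, seed = 5, targets = targets)
      expect_lte(fit$log$loss[1], l0)
    }
  })
})

test_that("sign decision maps an exact zero to the non-digging side", {
  cfg <- toy_config("idnn")
  w0 <- rand_weights(cfg)
  w0$W[] <- 0; w0$b[] <- 0; w0$v[] <- 0; w0$c <- 0
  expect_equal(classify_pattern(cfg, w0, rnorm(8)), -1)
  w0$c <- 1
  expect_equal(classify_pattern(cfg, w0, rnorm(8)), 1)
  w0$c <- -1
  expect_equal(classify_pattern(cfg, w0, rnorm(8)), -1)
})

test_that("the output stream has one score per shifted window", {
  cfg <- idnn_config("idnn_lrf_ws")
  w0 <- init_weights(cfg, train_control(), seed = 1)
  w0$W[] <- 0; w0$b[] <- 0; w0$v[] <- 0; w0$c <- 0
  fit <- list(config = cfg, weights = w0)
  s <- output_stream(fit, rep(1L, 300))
  expect_length(s, 10)
  expect_true(all(s == 0))
})

test_that("model selection ranks by validation accuracy with stable ties", {
  bench <- tiny_benchmark()
  sp <- bench$split
  good <- list(config = idnn_config("idnn_lrf_ws"),
               control = { c <- recommended_control("idnn_lrf_ws"); c$max_epochs <- 800L; c })
  bad <- list(config = idnn_config("idnn_lrf_ws"),
              control = { c <- recommended_control("idnn_lrf_ws"); c$max_epochs <- 1L; c })
  res <- select_model(list(bad, good), sp$ann_train, sp$ann_validation,
                      n_seeds = 2)
  expect_equal(res$best, 2)
  expect_gt(res$report$mean_val_accuracy[2], res$report$mean_val_accuracy[1])

  res1 <- select_model(list(good), sp$ann_train, sp$ann_validation, n_seeds = 1)
  expect_equal(res1$best, 1)
  # identical candidates tie on accuracy and footprint: lowest index wins
  res_tie <- select_model(list(bad, bad), sp$ann_train, sp$ann_validation,
                          n_seeds = 1)
  expect_equal(res_tie$best, 1)
  expect_error(select_model(list(), sp$ann_train, sp$ann_validation), "grid")
})

test_that("fitted models serialize to JSON and back without loss", {
  tf <- tiny_fit("idnn_lrf_ws")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(tf$fit, path)
  back <- read_model(path)
  x <- tiny_benchmark()$split$test$samples[[1]]
  expect_equal(output_stream(back, x), output_stream(tf$fit, x))
  expect_equal(back$config$variant, "idnn_lrf_ws")
})

test_that("tidy and glance expose the weight table and fit summary", {
  tf <- tiny_fit("idnn_lrf_ws")
  td <- tidy(tf$fit)
  expect_equal(nrow(td), 2 * 23 + 3)  # two shared vectors + output unit
  expect_setequal(unique(td$layer), c("hidden", "output"))
  g <- glance(tf$fit)
  expect_equal(g$footprint_bytes, 196L)
  expect_equal(g$weights_per_hidden_unit, 23L)
  p <- autoplot(tf$fit)
  expect_s3_class(p, "ggplot")
})
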