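# Loop-based oracle for the centered moving average with symmetric boundary
# truncation: radius shrinks near the edges so the window stays centered.
ma_oracle <- function(x, points) {
  n <- length(x)
  r <- points %/% 2
  vapply(seq_len(n), function(i) {
    ri <- min(r, i - 1, n - i)
    mean(x[(i - ri):(i + ri)])
  }, numeric(1))
}

test_that("moving average is centered, truncated symmetrically, and lag-free", {
  expect_equal(moving_average(rep(5, 7), 5), rep(5, 7))
  ramp <- moving_average(1:7, 5)
  expect_equal(ramp[3:5], c(3, 4, 5))  # full interior windows on a ramp
  impulse <- c(0, 0, 0, 0, 20, 0, 0, 0, 0)
  expect_equal(moving_average(impulse, 5), ma_oracle(impulse, 5))
  # oracle agreement on random inputs and window sizes
  with_seed2(11, {
    for (k in 1:20) {
      x <- rnorm(sample(1:40, 1))
      p <- sample(c(1, 3, 5, 7, 9), 1)
      expect_equal(moving_average(x, p), ma_oracle(x, p))
    }
  })
  expect_error(moving_average(1:5, 0), "points")
})

test_that("moving average is linear", {
  with_seed2(12, {
    for (k in 1:10) {
      n <- sample(5:50, 1)
      x <- rnorm(n); y <- rnorm(n)
      a <- rnorm(1); b <- rnorm(1)
      expect_equal(moving_average(a * x + b * y, 5),
                   a * moving_average(x, 5) + b * moving_average(y, 5))
    }
  })
})

test_that("integer normalization subtracts the rounded mean, half away from zero", {
  expect_equal(normalize_integer(c(10, 20, 30)), c(-10L, 0L, 10L))
  expect_equal(normalize_integer(c(7, 7, 7)), c(0L, 0L, 0L))
  # mean 1.5 rounds away from zero to 2
  expect_equal(normalize_integer(c(1, 2)), c(-1L, 0L))
  expect_error(normalize_integer(numeric(0)), "non-empty")
  with_seed2(13, {
    for (k in 1:10) {
      out <- normalize_integer(rnorm(sample(2:100, 1), mean = runif(1, -50, 50)))
      expect_type(out, "integer")
      expect_lte(abs(mean(out)), 1)
    }
  })
})

test_that("down-sampling keeps every factor-th sample from index 0", {
  x <- 1:8
  expect_equal(downsample(x, 4), c(1, 5))
  expect_equal(downsample(x, 1), x)
  expect_length(downsample(rnorm(360), 4), 90)
  expect_error(downsample(x, 0), "factor")
  # composition: factors p then q equals factor p*q
  with_seed2(14, {
    for (k in 1:10) {
      x <- rnorm(sample(10:200, 1))
      p <- sample(1:5, 1); q <- sample(1:5, 1)
      expect_equal(downsample(downsample(x, p), q), downsample(x, p * q))
    }
  })
})

test_that("segments are non-overlapping, exact-length, remainder discarded", {
  seqs <- acc_sequence(rep(1L, 600), "walking", id = "a", rate_hz = 1)
  segs <- extract_segments(seqs, 300)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$offset, c(0L, 300L))
  expect_equal(nrow(extract_segments(
    acc_sequence(rep(1L, 299), "walking", rate_hz = 1), 300)), 0)
  segs750 <- extract_segments(
    acc_sequence(rep(1L, 750), "walking", rate_hz = 1), 300)
  expect_equal(nrow(segs750), 2)
  expect_true(all(vapply(segs750$samples, length, integer(1)) == 300L))
})

test_that("window extraction matches the count formula and the default geometry", {
  W <- extract_windows(seq_len(300), 90, 22)
  expect_equal(nrow(W), 10)  # the 10-value output stream
  expect_equal(attr(W, "offsets"), as.integer(seq(0, 198, by = 22)))
  expect_equal(nrow(extract_windows(seq_len(90), 90, 22)), 1)
  expect_error(extract_windows(seq_len(89), 90, 22), "shorter")

  # brute-force enumeration oracle over random geometries
  count_oracle <- function(L, w, s) {
    n <- 0; o <- 0
    while (o + w <= L) { n <- n + 1; o <- o + s }
    n
  }
  with_seed2(15, {
    for (k in 1:40) {
      w <- sample(1:30, 1)
      L <- w + sample(0:60, 1)
      s <- sample(1:10, 1)
      W <- extract_windows(seq_len(L), w, s)
      expect_equal(nrow(W), count_oracle(L, w, s))
      expect_equal(nrow(W), floor((L - w) / s) + 1)
    }
  })
})

test_that("the preprocessing chain maps 4 Hz raw input to integer 1 Hz output", {
  const <- acc_sequence(rep(512L, 1200), "eating", id = "c")
  out <- preprocess(const)
  expect_equal(nrow(out), 300)
  expect_true(all(out$x == 0L))
  expect_equal(unique(out$rate_hz), 1)

  # noiseless digging keeps its two-waves-per-90-s rhythm through the chain
  cfg <- sim_config(noise_sd = 0, period_jitter = 0, wave_jitter = 0,
                    amp_jitter = 0, duration_s = 450)
  dig <- preprocess(gen_digging(cfg))
  crossings <- sum(diff(sign(dig$x[dig$x != 0])) != 0)
  waves <- crossings / 2
  expect_equal(waves, 450 / 45, tolerance = 0.11)
  expect_true(all(dig$x == round(dig$x)))
})
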