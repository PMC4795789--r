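test_that("NP, MP and MPT evaluate their printed formulas", {
  s <- c(-0.3, 0.2, 0.5, -0.1)
  expect_equal(feature_np(s), 2)
  expect_equal(feature_np(c(-1, -0.2)), 0)
  expect_equal(feature_np(rep(0.1, 10)), 10)

  s10 <- c(0.5, 0.3, rep(-0.2, 8))
  expect_equal(feature_mp(s10), 0.08)
  expect_equal(feature_mp(rep(-0.5, 4)), 0)
  expect_equal(feature_mp(rep(1, 10)), 1)

  s_mpt <- c(0.5, 0.3, 0.1, rep(-0.4, 7))
  expect_equal(feature_mpt(s_mpt, tau = 0.2), 0.08)
  expect_equal(feature_mpt(c(0.1, 0.2, -1), tau = 0.5), 0)
  expect_error(feature_mpt(s10, tau = 0), "tau")
  expect_error(feature_np(numeric(0)), "non-empty")
})

test_that("feature bounds: 0 <= MPT <= MP <= 1 and MPT decreases in tau", {
  with_seed2(51, {
    for (k in 1:30) {
      s <- runif(10, -1, 1)
      tau <- runif(1, 0.01, 0.9)
      mp <- feature_mp(s)
      mpt <- feature_mpt(s, tau)
      expect_gte(mpt, 0)
      expect_lte(mpt, mp)
      expect_lte(mp, 1)
      expect_gte(mpt, feature_mpt(s, tau + 0.05))
    }
    # tau -> 0+ recovers MP
    s <- runif(10, -1, 1)
    expect_equal(feature_mpt(s, 1e-12), feature_mp(s))
  })
})

test_that("tau calibration is the mean of pooled positive validation scores", {
  expect_equal(calibrate_tau(list(c(0.1, -0.5), c(0.3, -0.2))), 0.2)
  expect_equal(calibrate_tau(list(c(-0.1, 0.4))), 0.4)
  expect_error(calibrate_tau(list(c(-0.1, -0.4))), "no positive")
})

test_that("feature-bound calibration uses the gap midpoint, else the accuracy scan", {
  expect_equal(calibrate_bounds(c(0.30, 0.45), c(0.05, 0.10)), 0.20)
  expect_equal(calibrate_bounds(1, 0), 0.5)
  expect_error(calibrate_bounds(numeric(0), 1), "non-empty")

  # brute-force oracle over a fine threshold grid for overlapping classes
  scan_oracle <- function(pos, neg) {
    grid <- sort(unique(c(pos, neg)))
    acc <- vapply(grid, function(th) {
      (sum(pos > th) + sum(neg <= th)) / (length(pos) + length(neg))
    }, numeric(1))
    grid[which.max(acc)]
  }
  with_seed2(52, {
    for (k in 1:20) {
      pos <- runif(15, 0.2, 0.8)
      neg <- runif(15, 0, 0.5)
      th <- calibrate_bounds(pos, neg)
      expect_equal(th, scan_oracle(pos, neg))
      # returned threshold attains the maximum achievable accuracy
      acc_at <- function(t) (sum(pos > t) + sum(neg <= t)) / 30
      expect_equal(acc_at(th), max(vapply(sort(c(pos, neg)), acc_at, numeric(1))))
    }
  })
})

test_that("the two-of-three vote is exactly the stated truth table", {
  # engineer each of the 8 vote combinations; note MPT <= MP always, so the
  # bounds are chosen per case to realize every combination
  cases <- list(
    #            stream                       mp_b  mpt_b np_b  votes  label
    list(c(0.9, 0.8, 0.7, rep(-1, 7)),        0.1,  0.1,  2L,   3, "digging"),
    list(c(0.9, 0.8, 0.7, rep(-1, 7)),        0.9,  0.1,  2L,   2, "digging"),
    list(c(0.9, 0.8, 0.7, rep(-1, 7)),        0.1,  0.9,  2L,   2, "digging"),
    list(c(0.9, rep(-1, 9)),                  0.01, 0.01, 2L,   2, "digging"),
    list(c(0.9, 0.8, 0.7, rep(-1, 7)),        0.9,  0.9,  2L,   1, "non-digging"),
    list(c(0.9, rep(-1, 9)),                  0.9,  0.01, 2L,   1, "non-digging"),
    list(c(0.9, rep(-1, 9)),                  0.01, 0.9,  2L,   1, "non-digging"),
    list(rep(-0.5, 10),                       0.01, 0.01, 2L,   0, "non-digging")
  )
  for (cs in cases) {
    th <- filter_thresholds(tau = 0.5, mp_bound = cs[[2]], mpt_bound = cs[[3]],
                            np_bound = cs[[4]])
    votes <- sum(nestnet:::segment_votes(cs[[1]], th))
    expect_equal(votes, cs[[5]])
    expect_equal(classify_segment(cs[[1]], th), cs[[6]])
  }
})

test_that("raising any single score never flips digging to non-digging", {
  with_seed2(53, {
    for (k in 1:40) {
      s <- runif(10, -1, 1)
      th <- filter_thresholds(tau = runif(1, 0.05, 0.5),
                              mp_bound = runif(1, 0, 0.4),
                              mpt_bound = runif(1, 0, 0.3))
      before <- classify_segment(s, th)
      i <- sample(10, 1)
      s2 <- s
      s2[i] <- min(1, s[i] + runif(1, 0, 1))
      after <- classify_segment(s2, th)
      if (before == "digging") expect_equal(after, "digging")
    }
  })
})

test_that("calibration on gapped validation streams separates them perfectly", {
  # digging streams: strong positives; non-digging: at most weak positives
  with_seed2(54, {
    dig <- replicate(6, c(runif(5, 0.5, 0.9), runif(5, -1, 0)),
                     simplify = FALSE)
    non <- replicate(6, c(runif(1, 0, 0.1), runif(9, -1, 0)),
                     simplify = FALSE)
    streams <- c(dig, non)
    labels <- rep(c("digging", "walking"), each = 6)
    th <- calibrate_filter(streams, labels)
    expect_s3_class(th, "filter_thresholds")
    pred <- vapply(streams, classify_segment, character(1), thresholds = th)
    expect_equal(pred, rep(c("digging", "non-digging"), each = 6))
    # tau equals the pooled positive mean
    pooled <- unlist(streams)
    expect_equal(th$tau, mean(pooled[pooled > 0]))
  })
  expect_error(calibrate_filter(list(c(0.1)), "digging"), "both classes")
})

test_that("thresholds serialize and read back", {
  th <- filter_thresholds(0.2, 0.15, 0.1, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(th, path)
  expect_equal(read_thresholds(path), th)
})
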