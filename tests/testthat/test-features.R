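test_that("AR band power localizes a sinusoid and scales quadratically", {
  spec <- ar_spec()
  t <- (0:599) / 1200
  set.seed(2)
  y <- sin(2 * pi * 85 * t) + 0.05 * rnorm(600)
  bp <- ar_band_power(y, 1200, spec)
  expect_length(bp, 20L)
  expect_identical(which.max(bp), 9L) # [80, 90) Hz
  expect_true(all(bp >= 0))
  # quadratic scaling: doubling the signal quadruples every band power
  expect_equal(ar_band_power(2 * y, 1200, spec), 4 * bp,
               tolerance = 1e-9)
  expect_error(ar_band_power(rep(1, 600), 1200, spec), "degenerate")
  expect_error(ar_band_power(y[1:100], 1200, spec), "exactly")
})

test_that("AR spectrum of white noise is near-flat and tracks variance", {
  spec <- ar_spec(f_max = 600, bin_width = 10)
  set.seed(4)
  means <- rowMeans(vapply(1:50, function(i) {
    ar_band_power(rnorm(600), 1200, spec)
  }, numeric(60)))
  expect_lt(max(means) / min(means), 2)
  # Parseval-style: total band power over the full range ~ unit variance
  expect_gt(sum(means), 0.5)
  expect_lt(sum(means), 2)
})

test_that("the Burg recursion matches the reference implementation", {
  set.seed(7)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.25)), 400))
  ref <- stats::ar.burg(x, aic = FALSE, order.max = 12)
  mine <- .burg_fit(x - mean(x), 12L)
  expect_equal(as.numeric(mine$ar), as.numeric(ref$ar), tolerance = 1e-10)
  expect_equal(mine$var_pred, ref$var.pred, tolerance = 1e-10)
})

test_that("sliding features warm up for exactly one window of frames", {
  spec <- ar_spec() # 0.5 s window = 600 samples = 15 frames of 40
  buf <- feature_buffer(2L, 600L)
  cfg <- sim_config(n_channels = 2L, depth = 0, seed = 1)
  st <- sim_channel_states(cfg)
  outs <- lapply(0:19, function(k) {
    sliding_features(buf, simulate_block(cfg, cursor_drive(0, FALSE),
                                         40L, st), spec)
  })
  warm <- vapply(outs, inherits, logical(1), "feature_warmup")
  expect_identical(sum(warm), 14L) # frames 0..13 flagged, full at frame 14
  expect_s3_class(outs[[15L]], "feature_matrix")
  expect_identical(outs[[15L]]$index, 14L)
  expect_identical(outs[[20L]]$index, 19L)
})

test_that("features are per-channel: permuting channels permutes rows", {
  spec <- ar_spec()
  set.seed(9)
  X <- matrix(rnorm(3 * 600), 3)
  blk <- function(m) signal_block(m, 1200, 0L)
  b1 <- feature_buffer(3L, 600L)
  b2 <- feature_buffer(3L, 600L)
  f1 <- sliding_features(b1, blk(X), spec)
  f2 <- sliding_features(b2, blk(X[c(3, 1, 2), ]), spec)
  expect_equal(f2$power, f1$power[c(3, 1, 2), ])
  # identical consecutive windows give identical features
  b3 <- feature_buffer(3L, 600L)
  g1 <- sliding_features(b3, blk(X), spec)
  g2 <- sliding_features(b3, blk(X), spec) # buffer now holds X again
  expect_equal(g1$power, g2$power)
})

test_that("baseline statistics stream correctly (Welford)", {
  st <- baseline_stats(1L, 1L)
  fm <- function(v) feature_matrix(matrix(v, 1, 1), c(0, 10), 0.5, 0L)
  st <- update_baseline(st, fm(1))
  st <- update_baseline(st, fm(3))
  expect_equal(st$mean[1, 1], 2)
  expect_equal(baseline_sd(st)[1, 1], sqrt(2)) # sample sd of {1, 3}
  # identical frames give zero spread
  st2 <- baseline_stats(2L, 2L)
  fm2 <- feature_matrix(matrix(1:4, 2, 2) * 1.0, c(0, 10, 20), 0.5, 0L)
  st2 <- update_baseline(update_baseline(st2, fm2), fm2)
  expect_true(all(baseline_sd(st2) == 0))
  expect_error(update_baseline(st, fm2), "shape mismatch")
})

test_that("pseudo-Z normalization is exact, invertible, and guarded", {
  st <- baseline_stats(1L, 2L)
  fm <- function(a, b) feature_matrix(matrix(c(a, b), 1, 2),
                                      c(0, 10, 20), 0.5, 0L)
  st <- update_baseline(st, fm(1, 10))
  st <- update_baseline(st, fm(3, 30))
  z <- normalize_features(fm(2, 20), st) # f = mean -> 0
  expect_equal(as.numeric(z$power), c(0, 0))
  z1 <- normalize_features(fm(2 + sqrt(2), 20), st) # f = mean + sd -> 1
  expect_equal(z1$power[1, 1], 1)
  # round trip
  raw <- fm(2.7, 12.3)
  back <- denormalize_features(normalize_features(raw, st), st)
  expect_equal(back$power, raw$power, tolerance = 1e-9)
  # a zero-sd feature is named in the error
  st0 <- baseline_stats(1L, 2L)
  st0 <- update_baseline(st0, fm(1, 5))
  st0 <- update_baseline(st0, fm(2, 5))
  expect_error(normalize_features(fm(1, 1), st0), "channel 1, band 2")
})
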