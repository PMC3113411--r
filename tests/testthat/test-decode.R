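make_buf <- function(Y, K) {
  buf <- training_buffer()
  for (i in seq_len(nrow(Y))) buffer_frame(buf, Y[i, ], K[i, ])
  buf
}

uniform_dirs <- function(n_per = 5L, n_dir = 8L) {
  ang <- rep(2 * pi * (0:(n_dir - 1L)) / n_dir, each = n_per)
  cbind(cos(ang), sin(ang))
}

test_that("noiseless tuning is recovered exactly by OLS", {
  K <- uniform_dirs()
  Y <- cbind(1 + 2 * K[, 1L], 0.5 - K[, 2L])
  m <- fit_tuning(make_buf(Y, K))
  expect_equal(m$b0, c(1, 0.5))
  expect_equal(m$bx, c(2, 0))
  expect_equal(m$by, c(0, -1))
  expect_equal(m$r2, c(1, 1))
  expect_equal(m$pd[1L, ], c(1, 0))
  expect_equal(m$pd[2L, ], c(0, -1))
})

test_that("tuning fit enforces its preconditions", {
  K <- uniform_dirs(6L, 2L) # collinear: only two opposite targets
  Y <- matrix(rnorm(nrow(K)), ncol = 1)
  expect_error(fit_tuning(make_buf(Y, K)), "collinear")
  expect_error(fit_tuning(make_buf(Y[1:4, , drop = FALSE],
                                   K[1:4, , drop = FALSE])), "at least 10")
  constK <- matrix(0.5, 12, 2) / sqrt(2)
  expect_error(fit_tuning(make_buf(matrix(rnorm(12)), constK)),
               "constant")
})

test_that("untuned features have low R-squared", {
  set.seed(31)
  K <- uniform_dirs(63L, 8L) # ~500 frames
  Y <- matrix(rnorm(nrow(K) * 100), nrow(K))
  m <- fit_tuning(make_buf(Y, K))
  expect_gt(mean(m$r2 < 0.05), 0.9)
})

test_that("shuffle null is reproducible and separates a tuned feature", {
  set.seed(5)
  K <- uniform_dirs(10L, 8L)
  Y <- cbind(1 + 2 * K[, 1L], matrix(rnorm(80 * 5), 80))
  buf <- make_buf(Y, K)
  a <- shuffle_null(buf, 200L, seed = 9)
  b <- shuffle_null(buf, 200L, seed = 9)
  expect_identical(a, b)
  expect_error(shuffle_null(buf, 0L), "n_iter")
  m <- fit_tuning(buf)
  expect_gt(m$r2[1L], a$p95) # perfectly tuned feature far above the null
  expect_true(a$p80 <= a$p90 && a$p90 <= a$p95)
})

test_that("feature selection thresholds behave at the extremes", {
  K <- uniform_dirs()
  Y <- cbind(1 + K[, 1L], rnorm(nrow(K)))
  m <- fit_tuning(make_buf(Y, K))
  all_in <- select_features(m, 0)
  expect_identical(all_in$selected, 1:2)
  none <- select_features(m, 1 + 1e-9)
  expect_length(none$selected, 0)
  expect_true(attr(none, "empty_selection"))
})

test_that("population vector sums activity excess along preferred directions", {
  m <- structure(list(b0 = c(0.5, 1), bx = c(1, 0), by = c(0, 1),
                      r2 = c(1, 1), pd = rbind(c(1, 0), c(0, 1)),
                      selected = 1L, n_frames = 10L),
                 class = "tuning_model")
  p1 <- population_vector(m, c(1.5, 0), gain = 1, index = 2L)
  expect_equal(p1$velocity, c(1, 0)) # one feature, excess 1, PD (1,0)
  m$selected <- 1:2
  p2 <- population_vector(m, c(1.5, 2), gain = 1)
  expect_equal(p2$velocity, c(1, 1)) # vector sum of two unit excesses
  p0 <- population_vector(m, c(0.5, 1), gain = 3)
  expect_equal(p0$velocity, c(0, 0)) # zero excess -> zero output
  expect_error(population_vector(m, c(1, 2, 3)), "length")
  m$selected <- integer(0)
  expect_error(population_vector(m, c(1, 2)), "no features")
})

test_that("push-pull control is the gain-scaled channel difference", {
  p <- push_pull_params(a = 1, b = 0)
  expect_equal(push_pull(2, 2, p)$velocity, 0)
  expect_equal(push_pull(2, 0.5, p)$velocity, 1.5)
  p2 <- push_pull_params(a = 2, b = 1)
  expect_equal(push_pull(1, 0, p2)$velocity, 1)
  expect_error(push_pull_params(a = 0, b = 1), "positive")
})

test_that("push-pull calibration standardizes the baseline", {
  p <- calibrate_push_pull(c(0, 2))
  expect_equal(p$a, 1 / sqrt(2))
  expect_equal(p$b, sqrt(2) / 2)
  out <- vapply(c(0, 2), function(s) push_pull(s, 0, p)$velocity,
                numeric(1))
  expect_equal(out, c(-1, 1) / sqrt(2))
  expect_equal(mean(out), 0)
  expect_equal(var(out), 1)
  # already-standardized input: identity-ish calibration
  set.seed(8)
  z <- rnorm(2000)
  z <- (z - mean(z)) / sd(z)
  pz <- calibrate_push_pull(z)
  expect_equal(pz$a, 1, tolerance = 1e-9)
  expect_equal(pz$b, 0, tolerance = 1e-9)
  expect_error(calibrate_push_pull(rep(1, 10)), "degenerate")
})

test_that("linear decoder handles shapes and matches the population vector", {
  expect_equal(linear_decoder(matrix(2, 1, 1), 0, 3)$velocity, 6)
  expect_equal(linear_decoder(matrix(0, 2, 3), c(1, -1),
                              c(5, 5, 5))$velocity, c(1, -1))
  expect_error(linear_decoder(matrix(1, 2, 2), c(0, 0), c(1, 2, 3)),
               "shape")
  # algebraic equivalence with the population vector
  set.seed(12)
  K <- uniform_dirs(6L, 8L)
  Y <- matrix(rnorm(48 * 10), 48) +
    outer(K[, 1L], rnorm(10)) + outer(K[, 2L], rnorm(10))
  m <- select_features(fit_tuning(make_buf(Y, K)), 0.1)
  w <- population_vector_weights(m, gain = 1.7)
  for (i in 1:20) {
    d <- rnorm(10)
    expect_equal(linear_decoder(w$W, w$w0, d)$velocity,
                 population_vector(m, d, gain = 1.7)$velocity,
                 tolerance = 1e-10)
  }
})
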