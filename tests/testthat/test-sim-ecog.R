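test_that("pink noise is reproducible, streaming-continuous, and validated", {
  expect_error(pink_noise(1, 1200, 1), ">= 2")
  expect_identical(pink_noise(500, 1200, 3), pink_noise(500, 1200, 3))
  # streaming contract: two 40-sample frames == one 80-sample call
  s1 <- pink_state(1200, 9); s2 <- pink_state(1200, 9)
  two <- c(pink_noise_block(s1, 40), pink_noise_block(s1, 40))
  one <- pink_noise_block(s2, 80)
  expect_identical(two, one)
})

test_that("pink noise PSD falls off as 1/f (log-log slope -1 +/- 0.2)", {
  x <- pink_noise(60 * 1200, 1200, seed = 2)
  w <- welch_psd(x, 1200)
  sel <- w$freq >= 2 & w$freq <= 300
  slope <- unname(coef(lm(log10(w$psd[sel]) ~ log10(w$freq[sel])))[2])
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
})

test_that("preferred directions are uniform over the circle", {
  expect_equal(assign_preferred_directions(4),
               c(0, pi / 2, pi, 3 * pi / 2))
  pd32 <- assign_preferred_directions(32)
  expect_length(pd32, 32)
  expect_equal(diff(pd32), rep(2 * pi / 32, 31))
  expect_equal(assign_preferred_directions(1), 0)
  expect_error(assign_preferred_directions(0), ">= 1")
})

test_that("with depth 0 or inactive drive the output is exactly S1", {
  cfg0 <- sim_config(n_channels = 3L, depth = 0, seed = 5)
  cfgd <- sim_config(n_channels = 3L, depth = 0.7, seed = 5)
  st0 <- sim_channel_states(cfg0)
  stb <- sim_channel_states(cfgd)
  a <- simulate_block(cfg0, cursor_drive(1.1, active = TRUE), 120, st0)
  b <- simulate_block(cfgd, cursor_drive(0, active = FALSE), 120, stb)
  expect_identical(a$data, b$data) # baseline == d = 0 == pure S1
})

test_that("modulation is linear in depth with identical generator states", {
  mk <- function(d) {
    cfg <- sim_config(n_channels = 2L, depth = d, seed = 11)
    st <- sim_channel_states(cfg)
    simulate_block(cfg, cursor_drive(0.4), 240, st)$data
  }
  s1 <- mk(0)
  full <- mk(1)
  half <- mk(0.5)
  expect_equal(half, s1 + 0.5 * (full - s1), tolerance = 1e-12)
})

test_that("a channel orthogonal to the drive stays unmodulated", {
  # PD of channel 2 of 4 is pi/2; drive at 0 gives cos(pi/2) = 0
  cfg <- sim_config(n_channels = 4L, depth = 0.8, seed = 3)
  st1 <- sim_channel_states(cfg)
  st2 <- sim_channel_states(sim_config(n_channels = 4L, depth = 0,
                                       seed = 3))
  a <- simulate_block(cfg, cursor_drive(0), 200, st1)
  b <- simulate_block(sim_config(n_channels = 4L, depth = 0, seed = 3),
                      cursor_drive(0), 200, st2)
  expect_equal(a$data[2L, ], b$data[2L, ], tolerance = 1e-9)
  expect_gt(max(abs(a$data[1L, ] - b$data[1L, ])), 0)
})

test_that("band power increases with depth when driven along the PD", {
  secs <- 20
  powers <- vapply(c(0.1, 0.3, 0.5), function(d) {
    cfg <- sim_config(n_channels = 1L, depth = d,
                      preferred_directions = 0, seed = 21)
    st <- sim_channel_states(cfg)
    x <- simulate_block(cfg, cursor_drive(0), secs * 1200, st)$data[1L, ]
    welch_band_power(welch_psd(x, 1200), c(70, 120))
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("the power increase is confined to the modulated band", {
  mk <- function(d) {
    cfg <- sim_config(n_channels = 1L, depth = d,
                      preferred_directions = 0, seed = 33)
    st <- sim_channel_states(cfg)
    simulate_block(cfg, cursor_drive(0), 50 * 600, st)$data[1L, ]
  }
  x0 <- mk(0)
  x1 <- mk(0.5) # same seed: identical S1, so differences are pure S2
  w0 <- welch_psd(x0, 1200); w1 <- welch_psd(x1, 1200)
  inb <- welch_band_power(w1, c(70, 120)) / welch_band_power(w0, c(70, 120))
  out_lo <- welch_band_power(w1, c(2, 60)) / welch_band_power(w0, c(2, 60))
  out_hi <- welch_band_power(w1, c(130, 300)) /
    welch_band_power(w0, c(130, 300))
  expect_gt(inb, 1.5) # (1 + d)^2 = 2.25 at the PD
  expect_lt(abs(out_lo - 1), 0.02)
  expect_lt(abs(out_hi - 1), 0.02)
})
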