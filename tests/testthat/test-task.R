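test_that("a trial with no control input fails exactly at the timeout", {
  cfg <- task_config(trial_timeout = 10, iti = 2)
  st <- new_trial(cfg, 1L)
  dt <- 1 / 30
  n <- 0L
  while (st$phase == "active") {
    st <- step_task(st, control_signal(c(0, 0), 0L), dt, cfg)
    n <- n + 1L
  }
  expect_identical(st$outcome, "failure")
  expect_equal(n * dt, 10, tolerance = dt)
})

test_that("control pointed at the target succeeds before the timeout", {
  cfg <- task_config()
  st <- new_trial(cfg, 3L)
  dt <- 1 / 30
  n <- 0L
  while (st$phase == "active" && n < 1000L) {
    dir <- st$target_pos - st$cursor_pos
    v <- 0.5 * dir / sqrt(sum(dir^2))
    st <- step_task(st, control_signal(v, 0L), dt, cfg)
    n <- n + 1L
  }
  expect_identical(st$outcome, "success")
  expect_lt(n * dt, cfg$trial_timeout)
})

test_that("control input is ignored during the inter-trial interval", {
  cfg <- task_config(iti = 2)
  st <- new_trial(cfg, 1L)
  st$phase <- "iti"; st$elapsed <- 0; st$outcome <- "failure"
  dt <- 1 / 30
  k <- 0L
  while (st$phase == "iti") {
    st <- step_task(st, control_signal(c(5, 5), 0L), dt, cfg)
    k <- k + 1L
  }
  expect_identical(st$phase, "done")
  expect_equal(st$cursor_pos, c(0, 0)) # frozen at center
  expect_equal(k * dt, 2, tolerance = dt)
})

test_that("1-D control moves the vertical axis only, positive up", {
  cfg <- task_config(n_targets = 2L, dims = 1L)
  expect_equal(target_angle(cfg, 1L), pi / 2)
  expect_equal(target_angle(cfg, 2L), 3 * pi / 2)
  st <- new_trial(cfg, 1L)
  st <- step_task(st, control_signal(0.3, 0L), 1, cfg)
  expect_equal(st$cursor_pos, c(0, 0.3))
})

test_that("target schedules are balanced per block and seed-reproducible", {
  cfg <- task_config(n_targets = 2L)
  sched <- schedule_targets(cfg, seed = 5)
  draws <- vapply(1:10, function(i) next_target(sched), integer(1))
  expect_identical(as.integer(table(draws)), c(5L, 5L))
  # every consecutive pair of draws is one balanced block
  expect_true(all(vapply(seq(1, 9, 2),
                         function(i) setequal(draws[i:(i + 1)], 1:2),
                         logical(1))))
  sched2 <- schedule_targets(cfg, seed = 5)
  expect_identical(draws, vapply(1:10, function(i) next_target(sched2),
                                 integer(1)))
  cfg8 <- task_config(n_targets = 8L)
  s8 <- schedule_targets(cfg8, seed = 1)
  expect_setequal(vapply(1:8, function(i) next_target(s8), integer(1)),
                  1:8)
})

test_that("session summaries account for every trial", {
  cfg <- task_config()
  mk <- function(outcome, k) {
    t <- new_trial(cfg, k); t$outcome <- outcome; t$phase <- "done"; t
  }
  trials <- c(lapply(1:7, function(k) mk("success", ((k - 1) %% 8) + 1)),
              list(mk("failure", 8L)))
  s <- session_summary(trials)
  expect_identical(s$n_trials, 8L)
  expect_identical(s$n_success, 7L)
  expect_equal(s$success_rate, 0.875)
  all_fail <- session_summary(lapply(1:4, function(k) mk("failure", k)))
  expect_equal(all_fail$success_rate, 0)
  expect_error(session_summary(list()), "no trials")
  expect_error(session_summary(list(new_trial(cfg, 1L))), "pending")
})

test_that("trial accounting holds over a randomized closed run", {
  cfg <- task_config(trial_timeout = 2, iti = 0.5)
  sched <- schedule_targets(cfg, seed = 3)
  rng <- rng_stream(77)
  trials <- list()
  st <- new_trial(cfg, next_target(sched))
  dt <- 1 / 30
  for (k in 1:1200) {
    v <- with_rng(rng, stats::rnorm(2, mean = c(0.2, 0.2), sd = 0.6))
    prev_phase <- st$phase
    st <- step_task(st, control_signal(v, 0L), dt, cfg)
    if (prev_phase == "active" && st$phase != "active")
      trials[[length(trials) + 1L]] <- st
    if (st$phase == "done") st <- new_trial(cfg, next_target(sched))
  }
  s <- session_summary(trials)
  outcomes <- vapply(trials, function(t) t$outcome, character(1))
  expect_identical(s$n_success + sum(outcomes == "failure"), s$n_trials)
  expect_gt(s$n_trials, 5L)
})
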