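#' Center-out cursor task
#'
#' A cursor starts at the screen center; one of `n_targets` peripheral
#' targets is presented. The control signal is integrated as a velocity;
#' the trial succeeds when the cursor overlaps the target, and fails if the
#' 10 s trial timeout elapses first. Every trial is followed by a 2 s
#' inter-trial interval in which cursor and target are hidden and control
#' input is ignored. Coordinates: screen origin at center, workspace
#' clamped to the unit square, angles counter-clockwise from screen right;
#' for one-dimensional control only the vertical axis moves and positive
#' control is up.
#'
#' @name task-center-out
NULL

#' Task configuration
#'
#' @param n_targets number of targets (default 8 for 2-D; use 2 for the
#'   1-D vertical task).
#' @param dims control dimensionality, 1 or 2.
#' @param target_radius,cursor_radius,target_distance screen units
#'   (workspace is `[-1, 1]^2`).
#' @param trial_timeout maximum trial length in seconds (default 10).
#' @param iti inter-trial interval in seconds (default 2).
#' @param hold_time seconds the cursor must stay on target (default 0:
#'   hit-to-succeed).
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_targets = 8L, dims = 2L, target_radius = 0.1,
                        cursor_radius = 0.1, target_distance = 0.8,
                        trial_timeout = 10, iti = 2, hold_time = 0) {
  stopifnot(n_targets >= 1, dims %in% 1:2, trial_timeout > 0, iti >= 0,
            target_distance > 0, hold_time >= 0)
  structure(list(n_targets = as.integer(n_targets), dims = as.integer(dims),
                 target_radius = target_radius,
                 cursor_radius = cursor_radius,
                 target_distance = target_distance,
                 trial_timeout = trial_timeout, iti = iti,
                 hold_time = hold_time),
            class = "task_config")
}

#' Angle of target `k`
#'
#' 2-D targets are spaced uniformly from screen right; the 1-D vertical
#' task places its targets straight up and straight down.
#'
#' @param cfg a [task_config()].
#' @param k target index in `1..n_targets`.
#' @return angle in radians.
#' @export
target_angle <- function(cfg, k) {
  stopifnot(k >= 1, k <= cfg$n_targets)
  if (cfg$dims == 1L) {
    c(pi / 2, 3 * pi / 2)[((k - 1L) %% 2L) + 1L]
  } else {
    2 * pi * (k - 1L) / cfg$n_targets
  }
}

target_position <- function(cfg, k) {
  a <- target_angle(cfg, k)
  cfg$target_distance * c(cos(a), sin(a))
}

#' Begin a new trial
#'
#' @param cfg a [task_config()].
#' @param target_index index of the presented target.
#' @return an object of class `trial_state`, phase `active`, cursor at
#'   center.
#' @export
new_trial <- function(cfg, target_index) {
  structure(list(phase = "active", target_index = as.integer(target_index),
                 target_pos = target_position(cfg, target_index),
                 cursor_pos = c(0, 0), elapsed = 0, hold = 0,
                 outcome = "pending"),
            class = "trial_state")
}

#' Advance the task state machine by one frame
#'
#' During `active`, the control velocity is integrated
#' (`cursor <- cursor + v * dt`; a 1-D control moves only the vertical
#' axis, positive up), the cursor is clamped to the workspace, a hit
#' (center distance at most `target_radius + cursor_radius`, sustained for
#' `hold_time`) succeeds and a timeout fails. During `iti` control input is
#' ignored and the cursor stays frozen at center; the phase ends after
#' `cfg$iti` seconds.
#'
#' @param state a [new_trial()] state (phase `active`, `iti`, or `done`).
#' @param control a [control_signal()] or `NULL`.
#' @param dt frame period in seconds (> 0).
#' @param cfg a [task_config()].
#' @return the updated `trial_state`; when a trial just ended its phase is
#'   `iti` and `outcome` is final. After the interval the phase is `done`
#'   (caller starts the next trial).
#' @export
step_task <- function(state, control, dt, cfg) {
  stopifnot(inherits(state, "trial_state"), dt > 0,
            inherits(cfg, "task_config"))
  if (state$phase == "iti") {
    state$elapsed <- state$elapsed + dt
    if (state$elapsed >= cfg$iti - 1e-12) state$phase <- "done"
    return(state)
  }
  if (state$phase == "done") return(state)
  v <- if (is.null(control)) c(0, 0) else control$velocity
  if (length(v) == 1L) v <- c(0, v) # 1-D control moves the vertical axis
  state$cursor_pos <- pmin(1, pmax(-1, state$cursor_pos + v[1:2] * dt))
  state$elapsed <- state$elapsed + dt
  hit <- sqrt(sum((state$cursor_pos - state$target_pos)^2)) <=
    cfg$target_radius + cfg$cursor_radius
  if (hit) {
    state$hold <- state$hold + dt
    if (state$hold >= cfg$hold_time) {
      state$outcome <- "success"
      state$phase <- "iti"
      state$elapsed <- 0
      return(state)
    }
  } else {
    state$hold <- 0
  }
  if (state$elapsed >= cfg$trial_timeout - 1e-12) {
    state$outcome <- "failure"
    state$phase <- "iti"
    state$elapsed <- 0
  }
  state
}

#' Pseudo-random balanced target schedule
#'
#' Targets are drawn in balanced blocks: within each block every target
#' appears exactly once, in an order shuffled per block.
#'
#' @param cfg a [task_config()].
#' @param seed integer seed.
#' @return an environment; call [next_target()] on it.
#' @export
schedule_targets <- function(cfg, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$rng <- rng_stream(seed)
  e$block <- integer(0)
  class(e) <- "target_schedule"
  e
}

#' Draw the next target from a schedule
#'
#' @param sched a [schedule_targets()] generator.
#' @return a target index in `1..n_targets`.
#' @export
next_target <- function(sched) {
  stopifnot(inherits(sched, "target_schedule"))
  if (length(sched$block) == 0L)
    sched$block <- with_rng(sched$rng, sample.int(sched$cfg$n_targets))
  k <- sched$block[[1L]]
  sched$block <- sched$block[-1L]
  k
}

#' Summarize a list of finished trials
#'
#' @param trials list of `trial_state` objects, all with final outcomes.
#' @return `list(n_trials, n_success, success_rate, per_target)` where
#'   `per_target` is a success-rate vector indexed by target.
#' @export
session_summary <- function(trials) {
  if (length(trials) == 0L) stop("no trials to summarize")
  ok <- vapply(trials, function(t) {
    if (t$outcome == "pending") stop("trial still pending")
    t$outcome == "success"
  }, logical(1))
  tgt <- vapply(trials, function(t) t$target_index, integer(1))
  per <- tapply(ok, tgt, mean)
  list(n_trials = length(trials), n_success = sum(ok),
       success_rate = mean(ok), per_target = per)
}
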