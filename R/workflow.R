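#' Scripted end-to-end brain-control session
#'
#' Orchestrates the standard four-step workflow on the simulator, as live
#' parameter transitions within one continuously running system (no
#' engine restarts): (1) baseline collection for pseudo-Z statistics,
#' (2) training-data collection with the simulator driven toward the
#' scheduled target, (3) decoder fitting with shuffle-null feature
#' selection, (4) closed-loop center-out control — with optional
#' mid-session refits running off the growing training buffer.
#'
#' @name workflow
NULL

#' Session plan
#'
#' @param baseline_s seconds of baseline data (default 180).
#' @param training_trials number of scripted training trials (default 24:
#'   three balanced blocks of eight targets).
#' @param control_trials number of closed-loop trials (default 40).
#' @param retrain_points trial counts at which to refit mid-control.
#' @return an object of class `session_plan`.
#' @export
session_plan <- function(baseline_s = 180, training_trials = 24L,
                         control_trials = 40L,
                         retrain_points = integer(0)) {
  stopifnot(baseline_s > 0, training_trials >= 0, control_trials >= 0)
  structure(list(baseline_s = baseline_s,
                 training_trials = as.integer(training_trials),
                 control_trials = as.integer(control_trials),
                 retrain_points = as.integer(retrain_points)),
            class = "session_plan")
}

#' Run a full scripted session
#'
#' @param plan a [session_plan()].
#' @param sim a [sim_config()] (its `seed` drives all simulator noise).
#' @param task a [task_config()].
#' @param features an [ar_spec()].
#' @param seed master seed for scheduling and the shuffle null.
#' @param run_path run-file path (`NULL` disables recording).
#' @param n_shuffle shuffle-null iterations at fit time.
#' @param training_trial_s seconds of modulated data per training trial.
#' @param keep_features retain every raw feature frame in the decoder
#'   state (memory-hungry; used by normalization diagnostics).
#' @param max_extra_frames safety cap beyond the nominal frame budget.
#' @return `list(run_path, summary, model, null, system)` where `summary`
#'   is the [session_summary()] of the control trials (or `NULL` when
#'   `control_trials == 0`).
#' @export
run_session <- function(plan, sim = sim_config(), task = task_config(),
                        features = ar_spec(), seed = 1L, run_path = NULL,
                        n_shuffle = 1000L, training_trial_s = 3,
                        keep_features = FALSE,
                        max_extra_frames = 20000L) {
  stopifnot(inherits(plan, "session_plan"))
  frame_samples <- round(sim$sample_rate / 30)
  frame_period <- frame_samples / sim$sample_rate
  acq <- sim_acquisition_engine(sim, frame_samples)
  sp <- pv_decoder_engine(features, n_shuffle = n_shuffle,
                          shuffle_seed = derive_seed(seed, "shuffle"))
  app <- center_out_engine(task,
                           schedule_seed = derive_seed(seed, "targets"),
                           training_trial_s = training_trial_s,
                           frame_period = frame_period)
  sys <- launch(acq, sp, app, meta = run_metadata("sim"),
                run_path = run_path, frame_period = frame_period,
                clock = "sim")
  # (1) baseline: drive inactive, statistics accumulate
  if (keep_features)
    post_update(sys, "signal_processing", "keep_features", TRUE)
  post_update(sys, "signal_processing", "mode", "baseline")
  run_frames(sys, round(plan$baseline_s / frame_period))
  stats <- sys$engines$signal_processing$state$stats
  if (is.null(stats) || stats$n_frames < 2L ||
      any(baseline_sd(stats) == 0))
    stop("degenerate baseline: a feature has zero spread")
  # (2) training-data collection: simulator driven toward the target
  if (plan$training_trials > 0L) {
    post_update(sys, "signal_processing", "mode", "training")
    post_update(sys, "application", "mode", "training")
    app_state <- sys$engines$application$state
    budget <- plan$training_trials *
      ceiling((training_trial_s + task$iti) / frame_period) + 10L
    while (length(app_state$trials) < plan$training_trials &&
           budget > 0L) {
      step_system(sys)
      budget <- budget - 1L
    }
    # (3) decoder fit + shuffle-null selection, between frames: one more
    # frame lets the trigger apply at the next main sequence
    post_update(sys, "signal_processing", "train_now", 1L)
    step_system(sys)
  }
  # (4) closed-loop control
  summary <- NULL
  if (plan$control_trials > 0L) {
    post_update(sys, "signal_processing", "mode", "control")
    post_update(sys, "application", "mode", "control")
    app_state <- sys$engines$application$state
    done_at_entry <- length(app_state$trials)
    retrain_pending <- plan$retrain_points
    retrain_count <- 1L
    budget <- plan$control_trials *
      ceiling((task$trial_timeout + task$iti) / frame_period) +
      max_extra_frames
    while (length(app_state$trials) - done_at_entry <
           plan$control_trials && budget > 0L) {
      ntr <- length(app_state$trials) - done_at_entry
      if (length(retrain_pending) > 0L && ntr >= retrain_pending[[1L]]) {
        retrain_count <- retrain_count + 1L
        post_update(sys, "signal_processing", "train_now", retrain_count)
        retrain_pending <- retrain_pending[-1L]
      }
      step_system(sys)
      budget <- budget - 1L
    }
    trials <- app_state$trials[
      (done_at_entry + 1L):length(app_state$trials)]
    summary <- session_summary(trials)
  }
  sp_state <- sys$engines$signal_processing$state
  path <- shutdown(sys)
  list(run_path = path, summary = summary, model = sp_state$model,
       null = sp_state$null, system = sys)
}

#' Mean early-trial cursor heading error
#'
#' For each control trial in a run file, takes the cursor displacement
#' over the first `window_s` seconds of the trial and measures the
#' circular error between its direction and the target direction.
#'
#' @param run a [read_run()] record or run-file path.
#' @param window_s early window length (default 1 s).
#' @param frame_period seconds per frame.
#' @return mean absolute heading error in degrees across trials.
#' @export
heading_error <- function(run, window_s = 1, frame_period = 1 / 30) {
  if (is.character(run)) run <- read_run(run)
  cx <- run_sampled_matrix(run, "center_out", "cursor_x")
  cy <- run_sampled_matrix(run, "center_out", "cursor_y")
  tx <- run_sampled_matrix(run, "center_out", "target_x")
  ty <- run_sampled_matrix(run, "center_out", "target_y")
  ph <- run$engines$center_out$sampled$phase$values
  tn <- run_sampled_matrix(run, "center_out", "trial_number")
  active <- vapply(ph, identical, logical(1), "active")
  errs <- c()
  nwin <- round(window_s / frame_period)
  for (tr in unique(tn[active])) {
    rows <- which(active & tn == tr)
    if (length(rows) < 2L) next
    rows <- rows[seq_len(min(nwin, length(rows)))]
    disp <- c(cx[rows[length(rows)]] - cx[rows[1L]],
              cy[rows[length(rows)]] - cy[rows[1L]])
    if (sqrt(sum(disp^2)) < 1e-9) next
    tgt <- atan2(ty[rows[1L]], tx[rows[1L]])
    errs <- c(errs, angle_error(atan2(disp[2L], disp[1L]), tgt))
  }
  mean(errs) * 180 / pi
}
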