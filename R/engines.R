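#' Concrete engines: simulator acquisition, feature/decoder signal
#' processing, and the center-out application
#'
#' These factories produce the [engine_spec()]s used by the scripted
#' session workflow. They communicate through bundle items:
#'
#' * acquisition -> signal processing: `signal` (channels x samples),
#'   `sample_rate`, plus the task fields passed through from the previous
#'   frame's feedback (`m_x`, `m_y`, `training_active`, `task_phase`).
#' * signal processing -> application: `control` (velocity vector),
#'   `decoder_ready`, `n_selected`.
#' * application -> acquisition (feedback): `drive_angle`,
#'   `drive_active`, `m_x`, `m_y`, `training_active`, `task_phase`.
#'
#' @name engines
NULL

#' Synthetic-ECoG acquisition engine
#'
#' Emits one frame of directionally modulated synthetic ECoG per ring
#' cycle, driven by the feedback bundle's `drive_angle`/`drive_active`
#' fields (inactive during baseline). The task fields of the feedback are
#' passed through downstream so the decoder can buffer training
#' kinematics.
#'
#' @param cfg a [sim_config()].
#' @param frame_samples samples per frame (default
#'   `round(sample_rate / 30)`, i.e. a 33.3 ms frame).
#' @return an [engine_spec()] of kind `acquisition`.
#' @export
sim_acquisition_engine <- function(cfg,
                                   frame_samples =
                                     round(cfg$sample_rate / 30)) {
  force(cfg); force(frame_samples)
  engine_spec(
    "acquisition", "sim_ecog",
    params = list(depth = cfg$depth),
    init = function(state, params) {
      state$cfg <- cfg
      state$channels <- sim_channel_states(cfg)
    },
    process = function(input, params, state, index) {
      if (!identical(params$depth, state$cfg$depth)) {
        state$cfg$depth <- params$depth # live modulation-depth control
      }
      drive <- cursor_drive(
        angle = if (is.null(input$drive_angle)) 0 else input$drive_angle,
        active = isTRUE(input$drive_active))
      blk <- simulate_block(state$cfg, drive, frame_samples,
                            state$channels)
      list(out = list(
        signal = blk$data, sample_rate = blk$sample_rate,
        m_x = if (is.null(input$m_x)) 0 else input$m_x,
        m_y = if (is.null(input$m_y)) 0 else input$m_y,
        training_active = isTRUE(input$training_active),
        task_phase = if (is.null(input$task_phase)) "idle"
                     else input$task_phase))
    })
}

#' UDP acquisition engine
#'
#' Reads frames from a [udp_reader()] instead of the simulator; task
#' feedback fields are passed through unchanged.
#'
#' @param reader a [udp_reader()].
#' @param timeout_ms per-frame receive timeout.
#' @return an [engine_spec()] of kind `acquisition`.
#' @export
udp_acquisition_engine <- function(reader, timeout_ms = 1000) {
  force(reader)
  engine_spec(
    "acquisition", "read_udp_binary",
    process = function(input, params, state, index) {
      blk <- udp_read_block(reader, timeout_ms)
      if (is.null(blk)) stop("no datagram within timeout")
      list(out = list(signal = blk$data, sample_rate = blk$sample_rate))
    })
}

# shared by the decoder engine: one normalized feature frame (or NULL
# while warming up / no baseline)
decoder_features <- function(state, input, index, spec) {
  blk <- signal_block(input$signal, input$sample_rate, index)
  if (is.null(state$buffer))
    state$buffer <- feature_buffer(nrow(blk$data),
                                   round(spec$window_s * blk$sample_rate))
  fm <- sliding_features(state$buffer, blk, spec)
  if (inherits(fm, "feature_warmup")) return(NULL)
  fm
}

#' Population-vector signal-processing engine
#'
#' Maintains the AR band-power feature pipeline and pseudo-Z baseline,
#' buffers training data, fits the tuning model with shuffle-null feature
#' selection on request, and decodes a 2-D population-vector control
#' signal. Modes (live parameter `mode`): `idle`, `baseline`, `training`,
#' `control`. The parameter `train_now` (set to any new value) triggers a
#' (re)fit between frames: the new model is published atomically — frames
#' before the trigger decode with the old model, frames from the trigger
#' on with the new one.
#'
#' @param spec an [ar_spec()].
#' @param n_shuffle shuffle-null iterations at fit time.
#' @param shuffle_seed seed for the null.
#' @param cruise_speed desired mean cursor speed (screen units/s) used to
#'   calibrate the output gain from the training data.
#' @return an [engine_spec()] of kind `signal_processing`.
#' @export
pv_decoder_engine <- function(spec = ar_spec(), n_shuffle = 1000L,
                              shuffle_seed = 1L, cruise_speed = 0.4) {
  force(spec)
  engine_spec(
    "signal_processing", "population_vector",
    params = list(mode = "idle", r2_threshold = -1, gain = 1,
                  train_now = 0L, keep_features = FALSE),
    saved_variables = c("control", "n_selected", "weights"),
    init = function(state, params) {
      state$stats <- NULL
      state$tbuf <- training_buffer()
      state$model <- NULL
      state$null <- NULL
      state$feature_log <- list()
      state$trained_at <- 0L # matches the initial train_now parameter
    },
    process = function(input, params, state, index) {
      fm <- decoder_features(state, input, index, spec)
      control <- c(0, 0)
      n_sel <- 0L
      refit_weights <- NULL
      if (!is.null(fm)) {
        if (isTRUE(params$keep_features))
          state$feature_log[[length(state$feature_log) + 1L]] <- fm$power
        if (identical(params$mode, "baseline")) {
          if (is.null(state$stats))
            state$stats <- baseline_stats(nrow(fm$power), ncol(fm$power))
          state$stats <- update_baseline(state$stats, fm)
        } else if (!is.null(state$stats) && state$stats$n_frames >= 2L) {
          z <- normalize_features(fm, state$stats)
          act <- as.numeric(z$power)
          if (isTRUE(input$training_active))
            buffer_frame(state$tbuf, act, c(input$m_x, input$m_y))
          if (!identical(params$train_now, state$trained_at) &&
              length(state$tbuf) >= 10L) {
            # atomic republish between frames: this frame already
            # decodes with the new model
            state$model <- fit_tuning(state$tbuf)
            state$null <- shuffle_null(state$tbuf, n_shuffle, shuffle_seed)
            thr <- if (params$r2_threshold >= 0) params$r2_threshold
                   else state$null$p95
            state$model <- select_features(state$model, thr)
            state$trained_at <- params$train_now
            refit_weights <- c(state$model$b0, state$model$bx,
                               state$model$by)
            # gain calibration: mean decoded speed over the training set
            m <- training_matrices(state$tbuf)
            sel <- state$model$selected
            if (length(sel) > 0L) {
              ex <- sweep(m$Y[, sel, drop = FALSE], 2,
                          state$model$b0[sel])
              P <- ex %*% state$model$pd[sel, , drop = FALSE]
              spd <- mean(sqrt(rowSums(P^2)))
              state$gain_auto <- if (spd > 0) cruise_speed / spd else 1
            }
          }
          if (identical(params$mode, "control") &&
              !is.null(state$model) &&
              length(state$model$selected) > 0L) {
            g <- params$gain * (if (is.null(state$gain_auto)) 1
                                else state$gain_auto)
            cs <- population_vector(state$model, act, g, index)
            control <- cs$velocity
          }
        }
      }
      if (!is.null(state$model)) n_sel <- length(state$model$selected)
      save <- list(control = control, n_selected = n_sel)
      if (!is.null(refit_weights)) save$weights <- refit_weights
      list(out = list(control = control, decoder_ready = n_sel > 0L,
                      n_selected = n_sel),
           save = save)
    })
}

#' Center-out application engine
#'
#' Runs the task state machine from the decoded control signal and feeds
#' target information back to the acquisition engine (which forwards it
#' to the decoder for training). Modes (live parameter `mode`): `idle`
#' (baseline; cursor hidden, drive inactive), `training` (scripted
#' presentation: the drive angle points at the scheduled target, the
#' task-kinematics regressor is the target unit vector), `control`
#' (closed loop: the cursor moves under the control signal and the drive
#' angle points from the cursor toward the target — the scripted stand-in
#' for a subject's corrective intent).
#'
#' @param cfg a [task_config()].
#' @param schedule_seed seed for the balanced target schedule.
#' @param training_trial_s seconds of modulated data per training trial.
#' @param frame_period seconds per frame (the application engine sees no
#'   raw signal, so the frame period is configured, not inferred).
#' @return an [engine_spec()] of kind `application`.
#' @export
center_out_engine <- function(cfg, schedule_seed = 1L,
                              training_trial_s = 3,
                              frame_period = 1 / 30) {
  force(cfg)
  engine_spec(
    "application", "center_out",
    params = list(mode = "idle", gain = 1),
    saved_variables = c("cursor_x", "cursor_y", "target_x", "target_y",
                        "target_index", "phase", "outcome",
                        "trial_number"),
    init = function(state, params) {
      state$sched <- schedule_targets(cfg, schedule_seed)
      state$trial <- NULL
      state$trials <- list()
      state$traj <- list() # live cursor log, for replay comparisons
      state$mode_seen <- "idle"
      state$train_elapsed <- 0
    },
    process = function(input, params, state, index) {
      dt <- frame_period
      if (!identical(params$mode, state$mode_seen)) {
        # mode transition: reset the per-mode clock and current trial
        state$mode_seen <- params$mode
        state$trial <- NULL
        state$train_elapsed <- 0
      }
      fb <- list(drive_angle = 0, drive_active = FALSE, m_x = 0, m_y = 0,
                 training_active = FALSE, task_phase = params$mode)
      save <- list(cursor_x = 0, cursor_y = 0, target_x = 0, target_y = 0,
                   target_index = 0L, phase = "idle", outcome = "none",
                   trial_number = length(state$trials))
      if (identical(params$mode, "training")) {
        if (is.null(state$trial)) {
          k <- next_target(state$sched)
          state$trial <- new_trial(cfg, k)
          state$train_elapsed <- 0
        }
        state$train_elapsed <- state$train_elapsed + dt
        ang <- target_angle(cfg, state$trial$target_index)
        in_active <- state$train_elapsed <= training_trial_s
        if (in_active) {
          fb$drive_angle <- ang
          fb$drive_active <- TRUE
          fb$m_x <- cos(ang); fb$m_y <- sin(ang)
          fb$training_active <- TRUE
          save$phase <- "training_active"
        } else if (state$train_elapsed >= training_trial_s + cfg$iti) {
          state$trial$outcome <- "success" # scripted presentation
          state$trials[[length(state$trials) + 1L]] <- state$trial
          state$trial <- NULL
          save$phase <- "training_iti"
        } else {
          save$phase <- "training_iti"
        }
        if (!is.null(state$trial)) {
          save$target_x <- state$trial$target_pos[1L]
          save$target_y <- state$trial$target_pos[2L]
          save$target_index <- state$trial$target_index
        }
      } else if (identical(params$mode, "control")) {
        if (is.null(state$trial))
          state$trial <- new_trial(cfg, next_target(state$sched))
        ctl <- if (is.null(input$control)) NULL
               else control_signal(params$gain * input$control, index)
        st <- step_task(state$trial, ctl, dt, cfg)
        if (st$phase != "active" && state$trial$phase == "active") {
          # trial just finished
          state$trials[[length(state$trials) + 1L]] <- st
        }
        if (st$phase == "done")
          st <- new_trial(cfg, next_target(state$sched))
        state$trial <- st
        active <- st$phase == "active"
        if (active) {
          to_target <- st$target_pos - st$cursor_pos
          fb$drive_angle <- atan2(to_target[2L], to_target[1L])
          fb$drive_active <- TRUE
          ang <- target_angle(cfg, st$target_index)
          fb$m_x <- cos(ang); fb$m_y <- sin(ang)
          fb$training_active <- TRUE # allows parallel retraining
        }
        state$traj[[length(state$traj) + 1L]] <-
          c(index, st$cursor_pos)
        save$cursor_x <- st$cursor_pos[1L]
        save$cursor_y <- st$cursor_pos[2L]
        save$target_x <- st$target_pos[1L]
        save$target_y <- st$target_pos[2L]
        save$target_index <- st$target_index
        save$phase <- st$phase
        save$outcome <- st$outcome
        save$trial_number <- length(state$trials) +
          as.integer(st$phase == "active")
      }
      list(out = fb, save = save)
    })
}
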