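#' Engine runtime: lifecycle, deterministic scheduling, and hot-swap
#'
#' The system is a closed ring of three engines — acquisition, signal
#' processing, application — driven frame by frame by a single
#' deterministic scheduler (the acquisition engine owns the clock). Each
#' frame, every engine executes exactly this main sequence:
#' receive the upstream bundle, apply pending parameter updates, run its
#' processing hook, send the downstream bundle, enqueue a visualization
#' snapshot, enqueue a save record. Visualization and saving are bounded,
#' non-blocking queues drained outside the main sequence, so a stalled
#' consumer can never slow the ring. Cyclical dataflow is enforced
#' structurally: the application engine's output for frame `k` is the
#' acquisition engine's input for frame `k + 1`, and frame `k + 1` cannot
#' begin before it arrives.
#'
#' Clock modes: `"sim"` advances a virtual clock by exactly one frame
#' period per frame (deterministic; used for tests and benches), `"wall"`
#' sleeps to the frame boundary.
#'
#' @name engine-runtime
NULL

ENGINE_KINDS <- c("acquisition", "signal_processing", "application")

#' Declare an engine
#'
#' @param kind one of `"acquisition"`, `"signal_processing"`,
#'   `"application"`.
#' @param name engine name (used in run files).
#' @param process frame hook
#'   `function(input, params, state, index)` receiving the upstream
#'   bundle's items (named list), the current parameter list, the
#'   engine's private state environment, and the packet index; returns
#'   `list(out =, viz =, save =)` of named lists (`viz`/`save` optional;
#'   `save` defaults to `out`).
#' @param params named list of initial parameter values.
#' @param saved_variables names (within the save list) to record.
#' @param init optional `function(state, params)` run once at launch.
#' @return an object of class `engine_spec`.
#' @export
engine_spec <- function(kind, name, process, params = list(),
                        saved_variables = character(0), init = NULL) {
  kind <- match.arg(kind, ENGINE_KINDS)
  stopifnot(is.function(process), is.character(name), nzchar(name))
  structure(list(kind = kind, name = name, process = process,
                 params = params, saved_variables = saved_variables,
                 init = init),
            class = "engine_spec")
}

#' A pass-through template engine
#'
#' Forwards its input unchanged; used to keep the ring's dataflow running
#' (and as the starting point for new engines).
#'
#' @param kind engine kind.
#' @param name engine name.
#' @return an [engine_spec()].
#' @export
template_engine <- function(kind, name = paste0(kind, "_template")) {
  engine_spec(kind, name,
              process = function(input, params, state, index) {
                list(out = input)
              })
}

new_engine <- function(spec) {
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$params <- spec$params
  e$state <- new.env(parent = emptyenv())
  e$pending <- list()
  e$viz <- list()
  e$viz_dropped <- 0L
  e$faulted <- FALSE
  if (!is.null(spec$init)) spec$init(e$state, e$params)
  e
}

#' Launch a three-engine system
#'
#' Starts the engines, forms the ring, connects the recorder, and writes
#' the metadata header.
#'
#' @param acquisition,signal_processing,application [engine_spec()]s of
#'   the matching kinds (one of each; anything else refuses to start).
#' @param meta a [run_metadata()].
#' @param run_path run-file path, or `NULL` to run without recording.
#' @param frame_period seconds per frame (default 1/30, i.e. 33.3 ms).
#' @param clock `"sim"` (virtual, deterministic) or `"wall"`.
#' @param transport `"local"` (in-process handoff) or `"tcp"` (loopback
#'   ring links carrying the encoded bundles).
#' @param viz_capacity visualization queue depth per engine (drop-oldest).
#' @return an object of class `bmi_system`.
#' @export
launch <- function(acquisition, signal_processing, application,
                   meta = run_metadata("sim"), run_path = NULL,
                   frame_period = 1 / 30, clock = c("sim", "wall"),
                   transport = c("local", "tcp"), viz_capacity = 8L) {
  specs <- list(acquisition, signal_processing, application)
  kinds <- vapply(specs, function(s) s$kind, character(1))
  if (!identical(sort(kinds), sort(ENGINE_KINDS)))
    stop("need exactly one engine of each kind; got: ",
         paste(kinds, collapse = ", "))
  clock <- match.arg(clock)
  transport <- match.arg(transport)
  sys <- new.env(parent = emptyenv())
  sys$engines <- stats::setNames(lapply(specs, new_engine), kinds)
  sys$meta <- meta
  sys$frame_period <- frame_period
  sys$clock <- clock
  sys$viz_capacity <- as.integer(viz_capacity)
  sys$next_index <- 0L
  sys$feedback <- NULL
  sys$suspended <- FALSE
  sys$run_path <- run_path
  sys$run_counter <- 0L
  sys$log <- character(0)
  sys$processing_times <- list()
  sys$refresh_times <- list()
  sys$overruns <- 0L
  sys$t_start <- Sys.time()
  sys$ring <- if (transport == "tcp") establish_ring(ring_topology())
              else NULL
  sys$recorder <- NULL
  if (!is.null(run_path)) sys_open_run(sys)
  class(sys) <- "bmi_system"
  sys
}

sys_run_file <- function(sys) {
  if (sys$run_counter == 0L) sys$run_path
  else sub("(\\.[A-Za-z0-9]+)?$",
           sprintf("_run%d\\1", sys$run_counter + 1L), sys$run_path)
}

sys_open_run <- function(sys) {
  engs <- vapply(sys$engines, function(e) e$spec$name, character(1))
  sys$recorder <- recorder_open(sys_run_file(sys), sys$meta, engs)
  # log every engine's initial parameter values as index-0 controls
  for (eng in sys$engines) {
    for (nm in names(eng$params)) {
      record_control(sys$recorder, eng$spec$name,
                     parameter_update(nm, eng$params[[nm]], applied_at = 0L))
    }
  }
  invisible(sys)
}

#' Queue a parameter update for an engine
#'
#' The new value is applied atomically at the beginning of the engine's
#' next main sequence, stamped with that frame's packet index, and
#' forwarded to the recorder as a control change.
#'
#' @param sys a [launch()]ed system.
#' @param kind engine kind.
#' @param name parameter name.
#' @param value new value.
#' @export
post_update <- function(sys, kind, name, value) {
  stopifnot(inherits(sys, "bmi_system"))
  eng <- sys$engines[[match.arg(kind, ENGINE_KINDS)]]
  eng$pending[[length(eng$pending) + 1L]] <- parameter_update(name, value)
  invisible(sys)
}

#' Apply an engine's pending parameter updates
#'
#' All pending updates are applied in arrival order before the frame's
#' processing (last writer wins); each is stamped `applied_at =
#' current_index` and every one — including superseded ones — is logged.
#' Updates naming an unknown parameter are logged and skipped.
#'
#' @param eng internal engine handle.
#' @param current_index packet index of the frame about to be processed.
#' @param sys owning system (for recorder and log access).
#' @return list of applied [parameter_update()]s.
#' @keywords internal
apply_parameter_updates <- function(eng, current_index, sys) {
  if (length(eng$pending) == 0L) return(list())
  applied <- list()
  for (u in eng$pending) {
    if (!u$name %in% names(eng$params)) {
      sys$log <- c(sys$log, sprintf(
        "frame %d: engine %s: unknown parameter '%s' skipped",
        current_index, eng$spec$name, u$name))
      next
    }
    eng$params[[u$name]] <- u$value
    stamped <- parameter_update(u$name, u$value,
                                applied_at = current_index)
    applied[[length(applied) + 1L]] <- stamped
    if (!is.null(sys$recorder))
      record_control(sys$recorder, eng$spec$name, stamped)
  }
  eng$pending <- list()
  applied
}

viz_enqueue <- function(sys, eng, bundle) {
  if (length(eng$viz) >= sys$viz_capacity) {
    eng$viz <- eng$viz[-1L] # drop oldest; never back-pressure the ring
    eng$viz_dropped <- eng$viz_dropped + 1L
  }
  eng$viz[[length(eng$viz) + 1L]] <- bundle
  invisible(NULL)
}

#' Drain an engine's visualization queue
#'
#' @param sys a [launch()]ed system.
#' @param kind engine kind.
#' @return list of queued visualization bundles (oldest first).
#' @export
viz_drain <- function(sys, kind) {
  eng <- sys$engines[[match.arg(kind, ENGINE_KINDS)]]
  out <- eng$viz
  eng$viz <- list()
  out
}

#' Advance the system by one frame
#'
#' Executes the full ring for one packet index in the fixed engine order,
#' enforcing the cyclical-dataflow contract.
#'
#' @param sys a [launch()]ed system.
#' @return the application engine's output bundle for the frame,
#'   invisibly.
#' @export
step_system <- function(sys) {
  stopifnot(inherits(sys, "bmi_system"))
  if (sys$suspended) stop("system is suspended; resume() first")
  idx <- sys$next_index
  if (idx > 0L && is.null(sys$feedback))
    stop("cyclical dataflow violated: no feedback for frame ", idx - 1L)
  t0 <- proc.time()[["elapsed"]]
  input <- if (is.null(sys$feedback)) make_bundle(list(), idx)
           else sys$feedback
  hops <- c(acquisition = "as", signal_processing = "sp",
            application = "pa")
  for (kind in ENGINE_KINDS) {
    eng <- sys$engines[[kind]]
    apply_parameter_updates(eng, idx, sys)
    res <- tryCatch(
      eng$spec$process(input$items, eng$params, eng$state, idx),
      error = function(e) {
        eng$faulted <- TRUE
        sys$log <- c(sys$log, sprintf("frame %d: engine %s faulted: %s",
                                      idx, eng$spec$name,
                                      conditionMessage(e)))
        stop("engine ", eng$spec$name, " faulted at frame ", idx, ": ",
             conditionMessage(e), call. = FALSE)
      })
    out <- make_bundle(if (is.null(res$out)) list() else res$out, idx)
    if (!is.null(sys$ring)) {
      ring_send(sys$ring, hops[[kind]], out)
      out <- ring_recv(sys$ring, hops[[kind]])
    }
    if (!is.null(res$viz))
      viz_enqueue(sys, eng, make_bundle(res$viz, idx))
    save_items <- if (!is.null(res$save)) res$save else res$out
    keep <- intersect(eng$spec$saved_variables, names(save_items))
    if (!is.null(sys$recorder) && length(keep) > 0L)
      record_sampled(sys$recorder, eng$spec$name,
                     make_bundle(save_items[keep], idx))
    input <- out
  }
  sys$feedback <- input # application output, delivered before frame idx+1
  elapsed <- proc.time()[["elapsed"]] - t0
  sys$processing_times[[idx + 1L]] <- elapsed
  if (elapsed > sys$frame_period) sys$overruns <- sys$overruns + 1L
  # virtual display-update stamp: frame count in sim clock (multiplied by
  # the period on report, so gap-free runs give exactly equal intervals)
  sys$refresh_times[[idx + 1L]] <-
    if (sys$clock == "sim") as.numeric(idx + 1L)
    else as.numeric(Sys.time())
  if (sys$clock == "wall") {
    target <- sys$t_start + (idx + 1L) * sys$frame_period
    now <- Sys.time()
    if (now < target)
      Sys.sleep(as.numeric(target - now, units = "secs"))
  }
  sys$next_index <- idx + 1L
  invisible(input)
}

#' Run a number of frames
#'
#' @param sys a [launch()]ed system.
#' @param n frame count.
#' @export
run_frames <- function(sys, n) {
  for (i in seq_len(n)) step_system(sys)
  if (!is.null(sys$recorder)) recorder_flush(sys$recorder)
  invisible(sys)
}

#' Suspend the system
#'
#' Closes the current run file (all references released); engine
#' in-memory state — decoder weights, baseline statistics, filter states —
#' is preserved. Idempotent.
#'
#' @param sys a [launch()]ed system.
#' @export
suspend <- function(sys) {
  stopifnot(inherits(sys, "bmi_system"))
  if (sys$suspended) return(invisible(sys)) # double-suspend is a no-op
  if (!is.null(sys$recorder)) {
    recorder_close(sys$recorder)
    sys$recorder <- NULL
  }
  for (eng in sys$engines) eng$viz <- list() # in-flight viz discarded
  sys$suspended <- TRUE
  invisible(sys)
}

#' Resume a suspended system
#'
#' Opens a fresh run file (packet indices restart at 0 — a run file is
#' always gap-free from 0) while every engine keeps its in-memory state.
#'
#' @param sys a suspended system.
#' @export
resume <- function(sys) {
  stopifnot(inherits(sys, "bmi_system"))
  if (!sys$suspended) return(invisible(sys))
  sys$suspended <- FALSE
  sys$next_index <- 0L
  sys$feedback <- NULL
  sys$t_start <- Sys.time()
  if (!is.null(sys$run_path)) {
    sys$run_counter <- sys$run_counter + 1L
    sys_open_run(sys)
  }
  invisible(sys)
}

#' Replace one engine with another of the same kind
#'
#' The remaining engines keep their state ("hot swap"). The system must
#' be suspended or between frames.
#'
#' @param sys a [launch()]ed system.
#' @param spec an [engine_spec()] of the kind to replace.
#' @export
swap_engine <- function(sys, spec) {
  stopifnot(inherits(sys, "bmi_system"), inherits(spec, "engine_spec"))
  sys$engines[[spec$kind]] <- new_engine(spec)
  if (!is.null(sys$ring)) {
    # the hops touching the swapped engine re-form
    hop_in <- c(acquisition = "pa", signal_processing = "as",
                application = "sp")[[spec$kind]]
    hop_out <- c(acquisition = "as", signal_processing = "sp",
                 application = "pa")[[spec$kind]]
    ring_repair(sys$ring, hop_in)
    ring_repair(sys$ring, hop_out)
  }
  invisible(sys)
}

#' Shut the system down
#'
#' @param sys a [launch()]ed system.
#' @return the last run-file path, or `NULL`.
#' @export
shutdown <- function(sys) {
  stopifnot(inherits(sys, "bmi_system"))
  path <- NULL
  if (!is.null(sys$recorder)) path <- recorder_close(sys$recorder)
  if (!is.null(sys$ring)) ring_close(sys$ring)
  sys$recorder <- NULL
  sys$ring <- NULL
  invisible(path)
}
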