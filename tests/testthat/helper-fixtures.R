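# Shared fixture builders. Everything is generated in code at test time.

tiny_bundle <- function(index = 0L) {
  make_bundle(list(x = 3.0, v = c(1, 2, 3), m = matrix(1:6, 2, 3),
                   s = "hello", f = c(TRUE, FALSE)), index)
}

# A small system of counting engines: acquisition emits its frame index,
# the application saves what it received, so index bookkeeping is
# observable end to end.
counting_system <- function(run_path = NULL, clock = "sim",
                            transport = "local") {
  acq <- engine_spec("acquisition", "counter",
                     process = function(input, params, state, index) {
                       # append-by-index: amortized growth, no GC churn
                       state$emitted[length(state$emitted) + 1L] <- index
                       list(out = list(frame = index))
                     },
                     init = function(state, params)
                       state$emitted <- integer(0))
  sp <- template_engine("signal_processing")
  app <- engine_spec("application", "sink",
                     params = list(note = "initial"),
                     saved_variables = c("frame_seen", "note_value"),
                     init = function(state, params)
                       state$seen <- integer(0),
                     process = function(input, params, state, index) {
                       state$seen[length(state$seen) + 1L] <- input$frame
                       list(out = list(ack = index),
                            save = list(frame_seen = input$frame,
                                        note_value = params$note))
                     })
  launch(acq, sp, app, meta = run_metadata("test"), run_path = run_path,
         clock = clock, transport = transport)
}

# A short scripted session at reduced scale, deterministic given `seed`.
mini_session <- function(seed, run_path, control_trials = 4L,
                         depth = 0.5) {
  run_session(session_plan(baseline_s = 15, training_trials = 8L,
                           control_trials = control_trials),
              sim = sim_config(n_channels = 8L, depth = depth,
                               seed = derive_seed(seed, "sim")),
              task = task_config(n_targets = 8L),
              seed = seed, run_path = run_path, n_shuffle = 50L)
}

# Record bytes of a run file with the header stripped: what must be
# byte-identical across reruns with the same seeds.
run_stream_bytes <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  s <- decode_stream(bytes)
  keep <- Filter(function(b) !identical(b$items$.kind, "header"),
                 s$bundles)
  do.call(c, c(list(raw(0)), lapply(keep, encode_bundle)))
}
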