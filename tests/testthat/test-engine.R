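test_that("identity engines pass 100 frames through in order", {
  sys <- counting_system()
  run_frames(sys, 100L)
  expect_identical(sys$engines$acquisition$state$emitted, 0:99)
  expect_identical(sys$engines$application$state$seen, 0:99)
  expect_identical(sys$next_index, 100L)
  # every frame's application output fed back before the next frame
  expect_identical(sys$feedback$index, 99L)
})

test_that("a launch refuses mismatched engine kinds", {
  expect_error(launch(template_engine("acquisition"),
                      template_engine("acquisition"),
                      template_engine("application")),
               "one engine of each kind")
})

test_that("parameter updates apply at the start of the next main sequence", {
  path <- tempfile(fileext = ".run")
  sys <- counting_system(run_path = path)
  run_frames(sys, 5L) # frames 0..4 see "initial"
  post_update(sys, "application", "note", "changed")
  run_frames(sys, 5L) # frames 5..9 see "changed"
  shutdown(sys)
  run <- read_run(path)
  notes <- unlist(run$engines$sink$sampled$note_value$values)
  expect_identical(notes, c(rep("initial", 5), rep("changed", 5)))
  ctl <- run$engines$sink$controls
  note_changes <- Filter(function(c) c$name == "note", ctl)
  expect_length(note_changes, 2L) # initial value at 0 plus one change
  expect_identical(note_changes[[2L]]$index, 5L)
  expect_identical(note_changes[[2L]]$value, "changed")
})

test_that("two updates in one gap: last writer wins, both are logged", {
  path <- tempfile(fileext = ".run")
  sys <- counting_system(run_path = path)
  run_frames(sys, 3L)
  post_update(sys, "application", "note", "first")
  post_update(sys, "application", "note", "second")
  run_frames(sys, 1L)
  expect_identical(sys$engines$application$params$note, "second")
  shutdown(sys)
  ctl <- Filter(function(c) c$name == "note",
                read_run(path)$engines$sink$controls)
  expect_length(ctl, 3L) # initial + both updates
  expect_identical(vapply(ctl[2:3], function(c) c$index, integer(1)),
                   c(3L, 3L))
  # unknown parameter names are logged and skipped
  post_update(sys, "application", "nonexistent", 1)
  run_frames(sys, 1L)
  expect_match(sys$log[length(sys$log)], "unknown parameter")
})

test_that("the visualization queue drops oldest beyond capacity", {
  acq <- engine_spec("acquisition", "v",
                     process = function(input, params, state, index)
                       list(out = list(), viz = list(k = index)))
  sys <- launch(acq, template_engine("signal_processing"),
                template_engine("application"), viz_capacity = 8L)
  run_frames(sys, 20L) # stalled consumer: nothing drained
  q <- viz_drain(sys, "acquisition")
  expect_length(q, 8L)
  expect_identical(vapply(q, function(b) b$items$k, integer(1)), 12:19)
  expect_identical(sys$engines$acquisition$viz_dropped, 12L)
  expect_identical(sys$next_index, 20L) # ring never back-pressured
})

test_that("suspend closes the run file; resume opens a new one with state kept", {
  path <- tempfile(fileext = ".run")
  sys <- counting_system(run_path = path)
  run_frames(sys, 10L)
  suspend(sys)
  expect_error(step_system(sys), "suspended")
  suspend(sys) # double-suspend is an idempotent no-op
  emitted_before <- sys$engines$acquisition$state$emitted
  resume(sys)
  run_frames(sys, 5L)
  second <- shutdown(sys)
  expect_false(identical(path, second)) # a fresh file per run
  expect_identical(read_run(path)$engines$sink$sampled$frame_seen$indices,
                   0:9)
  expect_identical(
    read_run(second)$engines$sink$sampled$frame_seen$indices, 0:4)
  # engine in-memory state survived the suspend/resume cycle
  expect_identical(sys$engines$acquisition$state$emitted[1:10],
                   emitted_before)
})

test_that("swapping one engine preserves the state of the others", {
  sys <- counting_system()
  run_frames(sys, 10L)
  before <- sys$engines$acquisition$state$emitted
  swap_engine(sys, engine_spec("application", "sink2",
                               process = function(input, params, state,
                                                  index)
                                 list(out = list(ack = index))))
  run_frames(sys, 5L)
  expect_identical(sys$engines$acquisition$state$emitted[1:10], before)
  expect_identical(sys$engines$application$spec$name, "sink2")
  expect_identical(sys$next_index, 15L)
})

test_that("a faulting hook surfaces the engine name and frame", {
  bad <- engine_spec("signal_processing", "boom",
                     process = function(input, params, state, index) {
                       if (index == 3L) stop("numerical blowup")
                       list(out = input)
                     })
  sys <- launch(template_engine("acquisition"), bad,
                template_engine("application"))
  expect_error(run_frames(sys, 10L), "boom faulted at frame 3")
  expect_true(sys$engines$signal_processing$faulted)
  expect_match(sys$log[length(sys$log)], "numerical blowup")
})

test_that("local and TCP-loopback transports produce identical streams", {
  p1 <- tempfile(fileext = ".run"); p2 <- tempfile(fileext = ".run")
  s1 <- counting_system(run_path = p1, transport = "local")
  run_frames(s1, 30L); shutdown(s1)
  s2 <- counting_system(run_path = p2, transport = "tcp")
  run_frames(s2, 30L); shutdown(s2)
  expect_identical(run_stream_bytes(p1), run_stream_bytes(p2))
})
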