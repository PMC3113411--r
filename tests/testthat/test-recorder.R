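open_rec <- function(path = tempfile(fileext = ".run")) {
  recorder_open(path, run_metadata("subj1", 2L, "tester"),
                engine_names = c("a", "b"))
}

test_that("sampled streams are keyed by packet index, 0..n-1", {
  rec <- open_rec()
  for (k in 0:99)
    record_sampled(rec, "app",
                   make_bundle(list(cursor_pos = c(k * 0.01, -k * 0.01)),
                               k))
  path <- recorder_close(rec)
  run <- read_run(path)
  expect_identical(run$header$subject_id, "subj1")
  expect_identical(run$header$session_number, 2L)
  v <- run$engines$app$sampled$cursor_pos
  expect_identical(v$indices, 0:99)
  m <- run_sampled_matrix(run, "app", "cursor_pos")
  expect_equal(dim(m), c(100L, 2L))
  expect_equal(m[51L, ], c(0.5, -0.5))
})

test_that("variable-size arrays store per-packet shapes", {
  rec <- open_rec()
  record_sampled(rec, "a", make_bundle(list(w = c(1, 2, 3)), 0L))
  record_sampled(rec, "a", make_bundle(list(w = c(1, 2, 3, 4, 5)), 1L))
  run <- read_run(recorder_close(rec))
  v <- run$engines$a$sampled$w
  expect_length(v$values[[1L]], 3L)
  expect_length(v$values[[2L]], 5L)
})

test_that("out-of-order arrivals are index-sorted on read", {
  rec <- open_rec()
  for (k in c(3L, 0L, 2L, 1L))
    record_sampled(rec, "a", make_bundle(list(x = k * 1.0), k))
  run <- read_run(recorder_close(rec))
  expect_identical(run$engines$a$sampled$x$indices, 0:3)
  expect_identical(unlist(run$engines$a$sampled$x$values), c(0, 1, 2, 3))
})

test_that("controls are change-logged with the initial value at index 0", {
  rec <- open_rec()
  record_control(rec, "a", parameter_update("n_targets", 8L, 0L))
  record_control(rec, "a", parameter_update("n_targets", 4L, 10L))
  record_control(rec, "a", parameter_update("n_targets", 2L, 50L))
  run <- read_run(recorder_close(rec))
  expect_length(run$engines$a$controls, 3L)
  expect_identical(control_value_at(run, "a", "n_targets", 9L), 8L)
  expect_identical(control_value_at(run, "a", "n_targets", 10L), 4L)
  expect_identical(control_value_at(run, "a", "n_targets", 49L), 4L)
  expect_identical(control_value_at(run, "a", "n_targets", 200L), 2L)
  rec2 <- open_rec()
  expect_error(record_control(rec2, "a", parameter_update("x", 1)),
               "not been applied")
  recorder_close(rec2)
})

test_that("an empty run is a valid file with a header only", {
  rec <- open_rec()
  run <- read_run(recorder_close(rec))
  expect_identical(run$n_records, 0L)
  expect_length(replay_run(run), 0L)
})

test_that("a truncated (crashed) file reads up to the last whole record", {
  rec <- open_rec()
  for (k in 0:9)
    record_sampled(rec, "a", make_bundle(list(x = k * 1.0), k))
  path <- recorder_close(rec)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  trunc_path <- tempfile(fileext = ".run")
  writeBin(bytes[seq_len(length(bytes) - 7L)], trunc_path) # cut mid-record
  run <- read_run(trunc_path)
  expect_identical(run$engines$a$sampled$x$indices, 0:8)
})

test_that("the FIFO drops with a counter beyond capacity", {
  rec <- recorder_open(tempfile(fileext = ".run"), run_metadata("s"),
                       queue_capacity = 4L, flush_every = 1000L)
  rec$open <- FALSE # simulate a closed file: nothing can drain
  for (k in 0:9)
    record_sampled(rec, "a", make_bundle(list(x = 1), k))
  expect_identical(length(rec$queue), 4L)
  expect_identical(rec$dropped, 6L)
  close(rec$con)
})

test_that("replay merges sampled values with piecewise-constant controls", {
  rec <- open_rec()
  record_control(rec, "a", parameter_update("gain", 1, 0L))
  for (k in 0:5)
    record_sampled(rec, "a", make_bundle(list(x = k * 1.0), k))
  record_control(rec, "a", parameter_update("gain", 7, 3L))
  frames <- replay_run(read_run(recorder_close(rec)))
  expect_length(frames, 6L)
  gains <- vapply(frames, function(f) f$controls$a$gain, numeric(1))
  expect_equal(gains, c(1, 1, 1, 7, 7, 7)) # change visible from index 3 on
  expect_equal(vapply(frames, function(f) f$sampled$a$x, numeric(1)),
               0:5)
})

test_that("MAT export round-trips through an independent reader", {
  rec <- open_rec()
  for (k in 0:4)
    record_sampled(rec, "eng one",
                   make_bundle(list(pos = c(k, 2 * k)), k))
  record_sampled(rec, "eng one", make_bundle(list(var_arr = c(1, 2)), 5L))
  record_sampled(rec, "eng one",
                 make_bundle(list(var_arr = c(3, 4, 5)), 6L))
  record_control(rec, "eng one", parameter_update("mode", "idle", 0L))
  record_control(rec, "eng one", parameter_update("mode", "run", 3L))
  run <- read_run(recorder_close(rec))
  mat <- tempfile(fileext = ".mat")
  export_mat(run, mat)
  script <- sprintf("
import scipy.io, sys, numpy as np
m = scipy.io.loadmat(%s, simplify_cells=True)
s = m['eng_one_sampled']
assert list(s['pos']['packet_index']) == [0, 1, 2, 3, 4]
assert np.allclose(s['pos']['value'][2], [2, 4])
va = s['var_arr']['value']
assert list(va[0]) == [1, 2] and list(va[1]) == [3, 4, 5]
c = m['eng_one_controls']['mode']
assert list(c['packet_index']) == [0, 3]
assert list(c['value']) == ['idle', 'run']
assert m['header']['subject_id'] == 'subj1'
print('MATOK')
", deparse(mat))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  expect_true(any(grepl("MATOK", out)),
              info = paste(out, collapse = "\n"))
})

test_that("the MAT writer's containers are read back faithfully", {
  path <- tempfile(fileext = ".mat")
  write_mat5(list(a = matrix(1:6 * 1.0, 2, 3), txt = "héllo",
                  cells = list(c(1, 2), "x"),
                  st = list(f1 = 3.5, f2 = c(1, 2, 3))), path)
  script <- sprintf("
import scipy.io, numpy as np
m = scipy.io.loadmat(%s, simplify_cells=True)
assert np.allclose(m['a'], np.arange(1, 7).reshape(3, 2).T)
assert m['txt'] == 'héllo'
assert np.allclose(m['cells'][0], [1, 2]) and m['cells'][1] == 'x'
assert m['st']['f1'] == 3.5 and np.allclose(m['st']['f2'], [1, 2, 3])
print('MATOK')
", deparse(path))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  expect_true(any(grepl("MATOK", out)),
              info = paste(out, collapse = "\n"))
})
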