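#' Run recording, replay, and export
#'
#' The recorder receives save bundles from all engines, buffers them FIFO,
#' and streams them to a per-run file. A run file is a plain concatenation
#' of framed codec messages (see the wire-codec layout): the first record
#' is a header; every subsequent record is either a *sampled* record (all
#' saved per-frame values of one engine, keyed by packet index) or a
#' *control* record (one parameter change, keyed by the index at which it
#' took effect). Reserved item names beginning with `.` carry the record
#' kind, engine, and control name. Because records are self-contained, a
#' truncated file (crash) is readable up to the last flushed record.
#'
#' @name recorder
NULL

#' Run metadata for the file header
#'
#' @param subject_id non-empty subject identifier.
#' @param session_number integer session counter.
#' @param investigators free text.
#' @param date ISO date string (defaults to today).
#' @return an object of class `run_metadata`.
#' @export
run_metadata <- function(subject_id, session_number = 1L,
                         investigators = "", date = NULL) {
  stopifnot(is.character(subject_id), nzchar(subject_id))
  structure(list(subject_id = subject_id,
                 session_number = as.integer(session_number),
                 investigators = investigators,
                 date = if (is.null(date)) format(Sys.Date()) else date),
            class = "run_metadata")
}

#' Open a run file for writing
#'
#' @param path output file path.
#' @param meta a [run_metadata()].
#' @param engine_names character vector of engine names.
#' @param config_snapshot named list of scalar configuration values to
#'   embed in the header.
#' @param queue_capacity FIFO capacity in bundles (overflow is dropped and
#'   counted, never silent).
#' @param flush_every drain the FIFO to disk after this many records.
#' @return an object of class `run_recorder`.
#' @export
recorder_open <- function(path, meta, engine_names = character(0),
                          config_snapshot = list(),
                          queue_capacity = 1024L, flush_every = 64L) {
  stopifnot(inherits(meta, "run_metadata"))
  e <- new.env(parent = emptyenv())
  e$path <- path
  e$con <- file(path, "wb")
  e$queue <- list()
  e$capacity <- as.integer(queue_capacity)
  e$flush_every <- as.integer(flush_every)
  e$dropped <- 0L
  e$last_flush <- Sys.time()
  e$open <- TRUE
  hdr <- list(.kind = "header", subject_id = meta$subject_id,
              session_number = meta$session_number,
              investigators = meta$investigators, date = meta$date,
              engines = as.character(engine_names))
  for (nm in names(config_snapshot))
    hdr[[paste0("cfg.", nm)]] <- config_snapshot[[nm]]
  writeBin(encode_bundle(make_bundle(hdr, 0L)), e$con)
  class(e) <- "run_recorder"
  e
}

rec_enqueue <- function(rec, bundle) {
  if (length(rec$queue) >= rec$capacity) {
    rec$dropped <- rec$dropped + 1L
    return(invisible(FALSE))
  }
  rec$queue[[length(rec$queue) + 1L]] <- encode_bundle(bundle)
  if (rec$open && (length(rec$queue) >= rec$flush_every ||
                   as.numeric(Sys.time() - rec$last_flush, units = "secs")
                   > 1))
    recorder_flush(rec)
  invisible(TRUE)
}

#' Drain the recorder FIFO to disk
#' @param rec a [recorder_open()] handle.
#' @export
recorder_flush <- function(rec) {
  stopifnot(inherits(rec, "run_recorder"))
  if (!rec$open || length(rec$queue) == 0L) return(invisible(rec))
  writeBin(do.call(c, rec$queue), rec$con)
  rec$queue <- list()
  rec$last_flush <- Sys.time()
  invisible(rec)
}

#' Record one frame of sampled variables from an engine
#'
#' @param rec a [recorder_open()] handle.
#' @param engine engine name.
#' @param bundle a variable bundle of the values to save; its packet index
#'   keys the record. Array values may change size between frames — each
#'   record stores its own shapes.
#' @return `TRUE` if enqueued, `FALSE` if dropped (FIFO full or file
#'   closed beyond capacity).
#' @export
record_sampled <- function(rec, engine, bundle) {
  stopifnot(inherits(rec, "run_recorder"),
            inherits(bundle, "variable_bundle"))
  items <- c(list(.kind = "sampled", .engine = engine), bundle$items)
  rec_enqueue(rec, make_bundle(items, bundle$index))
}

#' Record one parameter change from an engine
#'
#' Controls are change-logged: one record per applied update, keyed by the
#' index at which the new value took effect.
#'
#' @param rec a [recorder_open()] handle.
#' @param engine engine name.
#' @param update an applied [parameter_update()] (`applied_at` set).
#' @export
record_control <- function(rec, engine, update) {
  stopifnot(inherits(rec, "run_recorder"),
            inherits(update, "parameter_update"))
  if (is.na(update$applied_at)) stop("update has not been applied")
  items <- list(.kind = "control", .engine = engine, .name = update$name,
                value = update$value)
  rec_enqueue(rec, make_bundle(items, update$applied_at))
}

#' Finalize a run file
#'
#' Drains the FIFO and closes the file; the recorder refuses further
#' writes (a later [recorder_open()] starts a new run).
#'
#' @param rec a [recorder_open()] handle.
#' @return the run-file path, invisibly.
#' @export
recorder_close <- function(rec) {
  stopifnot(inherits(rec, "run_recorder"))
  if (rec$open) {
    recorder_flush(rec)
    close(rec$con)
    rec$open <- FALSE
  }
  invisible(rec$path)
}

#' Read a run file
#'
#' @param path a run file written by this recorder.
#' @return an object of class `run_record`: `header` (named list),
#'   `engines` — per engine a list with `sampled` (per variable:
#'   `indices` and `values`, index-sorted) and `controls` (a list of
#'   `(name, index, value)` in file order) — and `n_records`. A trailing
#'   partial record (crash) is ignored.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("run file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  s <- decode_stream(bytes)
  if (length(s$bundles) == 0L) stop("not a run file (no records): ", path)
  hdr <- s$bundles[[1L]]
  if (!identical(hdr$items$.kind, "header"))
    stop("not a run file (missing header): ", path)
  recs <- s$bundles[-1L]
  kinds <- vapply(recs, function(b) as.character(b$items$.kind),
                  character(1))
  engs <- vapply(recs, function(b) as.character(b$items$.engine),
                 character(1))
  idxs <- vapply(recs, function(b) b$index, integer(1))
  engines <- list()
  for (eng in unique(engs)) {
    sampled <- list()
    s_rows <- which(kinds == "sampled" & engs == eng)
    if (length(s_rows) > 0L) {
      vars <- unique(unlist(lapply(recs[s_rows],
                                   function(b) names(b$items))))
      vars <- setdiff(vars, c(".kind", ".engine"))
      for (nm in vars) {
        has <- s_rows[vapply(recs[s_rows],
                             function(b) nm %in% names(b$items),
                             logical(1))]
        # index-sort on read: records may arrive out of order
        o <- order(idxs[has])
        has <- has[o]
        sampled[[nm]] <- list(
          indices = idxs[has],
          values = lapply(recs[has], function(b) b$items[[nm]]))
      }
    }
    c_rows <- which(kinds == "control" & engs == eng)
    controls <- lapply(c_rows, function(i)
      list(name = recs[[i]]$items$.name, index = idxs[[i]],
           value = recs[[i]]$items$value))
    engines[[eng]] <- list(sampled = sampled, controls = controls)
  }
  structure(list(header = hdr$items[setdiff(names(hdr$items), ".kind")],
                 engines = engines, n_records = length(s$bundles) - 1L),
            class = "run_record")
}

#' Sampled variable as an index-by-value matrix
#'
#' Convenience accessor for fixed-size numeric variables.
#'
#' @param run a [read_run()] record.
#' @param engine,name engine and variable names.
#' @return matrix with one row per record; row names are packet indices.
#' @export
run_sampled_matrix <- function(run, engine, name) {
  v <- run$engines[[engine]]$sampled[[name]]
  if (is.null(v)) stop("no sampled variable '", name, "' for engine '",
                       engine, "'")
  m <- do.call(rbind, lapply(v$values, as.numeric))
  rownames(m) <- v$indices
  m
}

#' Value of a control at a given packet index
#'
#' Controls are piecewise-constant: the value in effect at `index` is the
#' last change at or before it.
#'
#' @param run a [read_run()] record.
#' @param engine,name engine and parameter names.
#' @param index packet index.
#' @return the control value, or `NULL` if not yet set at that index.
#' @export
control_value_at <- function(run, engine, name, index) {
  ctl <- run$engines[[engine]]$controls
  best <- NULL; best_idx <- -1L
  for (c in ctl) {
    if (identical(c$name, name) && c$index <= index && c$index >= best_idx) {
      best <- c$value; best_idx <- c$index
    }
  }
  best
}

#' Frame-by-frame replay of a run file
#'
#' Yields, per packet index, the merged sampled variables of every engine
#' and the control values in effect (piecewise-constant from the change
#' log).
#'
#' @param run a [read_run()] record or a run-file path.
#' @return a list with one element per frame:
#'   `list(index =, sampled = list(engine -> list(var -> value)),
#'   controls = list(engine -> list(name -> value)))`. Missing indices in
#'   a sampled stream produce a gap warning.
#' @export
replay_run <- function(run) {
  if (is.character(run)) run <- read_run(run)
  stopifnot(inherits(run, "run_record"))
  all_idx <- sort(unique(unlist(lapply(run$engines, function(e)
    lapply(e$sampled, function(v) v$indices)))))
  if (length(all_idx) == 0L) return(list())
  if (!identical(as.integer(all_idx),
                 seq.int(min(all_idx), max(all_idx))))
    warning("gap in packet indices during replay")
  frames <- vector("list", length(all_idx))
  ctl_state <- lapply(run$engines, function(e) list())
  ctl_sorted <- lapply(run$engines, function(e) {
    idx <- vapply(e$controls, function(c) c$index, integer(1))
    e$controls[order(idx)]
  })
  ctl_pos <- lapply(run$engines, function(e) 1L)
  # frame -> record-row lookup per sampled variable, computed once
  pos_map <- lapply(run$engines, function(e)
    lapply(e$sampled, function(v) match(all_idx, v$indices)))
  for (fi in seq_along(all_idx)) {
    ix <- all_idx[[fi]]
    sampled <- list()
    for (eng in names(run$engines)) {
      # advance control log up to ix
      cl <- ctl_sorted[[eng]]
      while (ctl_pos[[eng]] <= length(cl) &&
             cl[[ctl_pos[[eng]]]]$index <= ix) {
        ch <- cl[[ctl_pos[[eng]]]]
        ctl_state[[eng]][[ch$name]] <- ch$value
        ctl_pos[[eng]] <- ctl_pos[[eng]] + 1L
      }
      vars <- list()
      for (nm in names(run$engines[[eng]]$sampled)) {
        hit <- pos_map[[eng]][[nm]][[fi]]
        if (!is.na(hit))
          vars[[nm]] <- run$engines[[eng]]$sampled[[nm]]$values[[hit]]
      }
      if (length(vars) > 0L) sampled[[eng]] <- vars
    }
    frames[[fi]] <- list(index = ix, sampled = sampled,
                         controls = ctl_state)
  }
  frames
}

#' Export a run file to MATLAB MAT (v5) format
#'
#' Produces one struct per engine and record group:
#' `<engine>_sampled` holds, per variable, a `value` array (a cell array
#' when element sizes vary between frames) and its `packet_index` vector;
#' `<engine>_controls` holds per change-logged parameter the
#' `(packet_index, value)` pairs. A `header` struct carries the run
#' metadata.
#'
#' @param run a [read_run()] record or run-file path.
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
export_mat <- function(run, path) {
  if (is.character(run)) run <- read_run(run)
  stopifnot(inherits(run, "run_record"))
  sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  out <- list(header = run$header)
  for (eng in names(run$engines)) {
    smp <- list()
    for (nm in names(run$engines[[eng]]$sampled)) {
      v <- run$engines[[eng]]$sampled[[nm]]
      lens <- vapply(v$values, length, integer(1))
      value <- if (length(unique(lens)) == 1L && !is.character(v$values[[1L]]))
        do.call(rbind, lapply(v$values, as.numeric))
      else
        v$values # variable-size arrays -> cell array
      smp[[sanitize(nm)]] <- list(value = value,
                                  packet_index = as.numeric(v$indices))
    }
    ctl <- list()
    for (c in run$engines[[eng]]$controls) {
      nm <- sanitize(c$name)
      if (is.null(ctl[[nm]]))
        ctl[[nm]] <- list(packet_index = numeric(0), value = list())
      ctl[[nm]]$packet_index <- c(ctl[[nm]]$packet_index, c$index)
      ctl[[nm]]$value[[length(ctl[[nm]]$value) + 1L]] <- c$value
    }
    out[[paste0(sanitize(eng), "_sampled")]] <- smp
    out[[paste0(sanitize(eng), "_controls")]] <- ctl
  }
  write_mat5(out, path)
  invisible(path)
}
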