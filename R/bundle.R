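#' Core domain types: packet-indexed frames and variable bundles
#'
#' Everything that circulates in the processing ring is stamped with a
#' *packet index*: the count of acquisition frames since the start of the
#' run. Records saved to disk, parameter updates, and inter-engine messages
#' all carry exactly one index, which is what makes offline reconstruction
#' of the full system state possible.
#'
#' @name model-core
NULL

assert_packet_index <- function(index) {
  if (length(index) != 1L || is.na(index) || index < 0 ||
      index != trunc(index) || index >= 2^31)
    stop("packet index must be a single non-negative integer < 2^31")
  as.integer(index)
}

#' Create a variable bundle
#'
#' A variable bundle is an ordered collection of named values — the unit of
#' inter-engine traffic, visualization snapshots, and save records. Values
#' may be numeric, integer, or logical arrays of any rank, or character
#' vectors. Names must be unique; order is preserved and significant for
#' equality.
#'
#' @param pairs named list of values (possibly empty).
#' @param index packet index to attach.
#' @return an object of class `variable_bundle`.
#' @examples
#' b <- make_bundle(list(gain = 1.5, pd = c(0, pi)), index = 7)
#' b$items$gain
#' @export
make_bundle <- function(pairs = list(), index = 0L) {
  index <- assert_packet_index(index)
  if (length(pairs) > 0) {
    nms <- names(pairs)
    if (is.null(nms) || any(!nzchar(nms)))
      stop("all bundle items must be named")
    dup <- nms[duplicated(nms)]
    if (length(dup) > 0)
      stop("duplicate bundle item name: '", dup[[1L]], "'")
    for (nm in nms) check_bundle_value(pairs[[nm]], nm)
  } else {
    pairs <- stats::setNames(list(), character(0))
  }
  structure(list(items = pairs, index = index), class = "variable_bundle")
}

check_bundle_value <- function(v, nm) {
  if (is.double(v) || is.integer(v) || is.logical(v) || is.character(v)) {
    if (is.numeric(v) && any(!is.finite(v)) && !is.character(v))
      return(invisible(TRUE)) # non-finite numerics allowed (e.g. NA markers)
    return(invisible(TRUE))
  }
  stop("unsupported value kind for bundle item '", nm, "': ", class(v)[[1L]])
}

#' @export
print.variable_bundle <- function(x, ...) {
  cat(sprintf("<variable_bundle> index %d, %d item(s)\n",
              x$index, length(x$items)))
  for (nm in names(x$items)) {
    v <- x$items[[nm]]
    d <- if (is.null(dim(v))) length(v) else paste(dim(v), collapse = "x")
    cat(sprintf("  %s: %s [%s]\n", nm, typeof(v), d))
  }
  invisible(x)
}

#' Structural bundle equality
#'
#' Same names, same order, same shapes, numerically identical values.
#'
#' @param a,b variable bundles.
#' @param check_index also compare packet indices (default TRUE).
#' @return logical scalar.
#' @export
bundle_identical <- function(a, b, check_index = TRUE) {
  stopifnot(inherits(a, "variable_bundle"), inherits(b, "variable_bundle"))
  if (check_index && a$index != b$index) return(FALSE)
  if (!identical(names(a$items), names(b$items))) return(FALSE)
  for (nm in names(a$items)) {
    va <- a$items[[nm]]; vb <- b$items[[nm]]
    if (!identical(dim(va), dim(vb))) return(FALSE)
    if (is.character(va) != is.character(vb)) return(FALSE)
    if (is.character(va)) {
      if (!identical(va, vb)) return(FALSE)
    } else {
      if (length(va) != length(vb)) return(FALSE)
      if (!isTRUE(all(as.numeric(va) == as.numeric(vb)))) return(FALSE)
    }
  }
  TRUE
}

#' One frame of raw multichannel time-domain data
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param index packet index of the frame.
#' @return an object of class `signal_block`.
#' @export
signal_block <- function(data, sample_rate, index) {
  if (!is.matrix(data) || !is.numeric(data) || nrow(data) < 1)
    stop("data must be a numeric matrix with at least one channel row")
  if (any(!is.finite(data))) stop("signal block contains non-finite values")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(data = data, sample_rate = as.numeric(sample_rate),
                 index = assert_packet_index(index)),
            class = "signal_block")
}

#' Channels-by-bands power features for one frame
#'
#' @param power numeric matrix channels x bands (raw powers are
#'   non-negative; pseudo-Z normalized values may be any real).
#' @param band_edges strictly increasing band edges in Hz
#'   (length `ncol(power) + 1`).
#' @param window_s analysis window length in seconds.
#' @param index packet index.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(power, band_edges, window_s, index) {
  if (!is.matrix(power) || !is.numeric(power))
    stop("power must be a numeric matrix")
  if (length(band_edges) != ncol(power) + 1L)
    stop("band_edges must have length ncol(power) + 1")
  if (any(diff(band_edges) <= 0))
    stop("band_edges must be strictly increasing")
  structure(list(power = power, band_edges = as.numeric(band_edges),
                 window_s = as.numeric(window_s),
                 index = assert_packet_index(index)),
            class = "feature_matrix")
}

#' A decoded velocity command for one frame
#'
#' @param velocity numeric vector of length 1, 2 or 3, screen units per
#'   second.
#' @param index packet index.
#' @return an object of class `control_signal`.
#' @export
control_signal <- function(velocity, index) {
  if (!is.numeric(velocity) || !length(velocity) %in% 1:3 ||
      any(!is.finite(velocity)))
    stop("velocity must be a finite numeric vector of length 1, 2 or 3")
  structure(list(velocity = as.numeric(velocity),
                 index = assert_packet_index(index)),
            class = "control_signal")
}

#' A pending or applied engine-parameter change
#'
#' Parameter updates are applied atomically at the start of an engine's
#' main sequence; `applied_at` is the index of the first frame whose
#' processing saw the new value.
#'
#' @param name parameter name.
#' @param value new value (any bundle-compatible value).
#' @param applied_at packet index at which the update took effect, or `NA`
#'   while still pending.
#' @return an object of class `parameter_update`.
#' @export
parameter_update <- function(name, value, applied_at = NA) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_bundle_value(value, name)
  structure(list(name = name, value = value,
                 applied_at = if (is.na(applied_at)) NA_integer_
                              else assert_packet_index(applied_at)),
            class = "parameter_update")
}
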