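#' Minimal MATLAB MAT (v5) writer
#'
#' Covers the subset the run-file export needs: double arrays, character
#' strings, cell arrays, and (nested) structs. Numeric data are written as
#' miDOUBLE, strings as UTF-16 char arrays, R lists as 1x1 structs when
#' named and as cell arrays when unnamed. Little-endian only.
#'
#' @name mat5
NULL

mat_pad8 <- function(bytes) {
  rem <- length(bytes) %% 8L
  if (rem == 0L) bytes else c(bytes, raw(8L - rem))
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_sub <- function(type, data_raw) {
  c(mat_tag(type, length(data_raw)), mat_pad8(data_raw))
}

mat_flags <- function(class_id) {
  mat_sub(6L, c(writeBin(as.integer(class_id), raw(), size = 4,
                         endian = "little"),
                writeBin(0L, raw(), size = 4, endian = "little")))
}

mat_dims <- function(dims) {
  mat_sub(5L, writeBin(as.integer(dims), raw(), size = 4,
                       endian = "little"))
}

mat_name <- function(name) {
  mat_sub(1L, if (nzchar(name)) charToRaw(name) else raw(0))
}

mat_matrix_element <- function(body) {
  c(mat_tag(14L, length(body)), body)
}

mat_element <- function(value, name) {
  if (is.null(value)) value <- numeric(0)
  if (is.logical(value) || is.integer(value)) value <- as.numeric(value)
  if (is.numeric(value)) {
    dims <- if (is.matrix(value)) dim(value)
            else c(1L, length(value))
    if (length(value) == 0L) dims <- c(0L, 0L)
    body <- c(mat_flags(6L), mat_dims(dims), mat_name(name),
              mat_sub(9L, writeBin(as.numeric(value), raw(), size = 8,
                                   endian = "little")))
    return(mat_matrix_element(body))
  }
  if (is.character(value)) {
    if (length(value) != 1L) {
      # vector of strings -> cell array of char
      return(mat_element(as.list(value), name))
    }
    codes <- utf8ToInt(enc2utf8(value))
    body <- c(mat_flags(4L), mat_dims(c(1L, length(codes))),
              mat_name(name),
              mat_sub(16L, charToRaw(enc2utf8(value)))) # miUTF8 payload
    return(mat_matrix_element(body))
  }
  if (is.list(value)) {
    nms <- names(value)
    if (!is.null(nms) && all(nzchar(nms))) {
      # 1x1 struct
      fn_len <- 32L
      fnames <- raw(0)
      for (nm in nms) {
        b <- charToRaw(substr(nm, 1L, fn_len - 1L))
        fnames <- c(fnames, b, raw(fn_len - length(b)))
      }
      fields <- raw(0)
      for (nm in nms) fields <- c(fields, mat_element(value[[nm]], ""))
      body <- c(mat_flags(2L), mat_dims(c(1L, 1L)), mat_name(name),
                mat_sub(5L, writeBin(fn_len, raw(), size = 4,
                                     endian = "little")),
                mat_sub(1L, fnames), fields)
      return(mat_matrix_element(body))
    }
    # cell array 1 x n
    cells <- raw(0)
    for (v in value) cells <- c(cells, mat_element(v, ""))
    body <- c(mat_flags(1L), mat_dims(c(1L, length(value))),
              mat_name(name), cells)
    return(mat_matrix_element(body))
  }
  stop("cannot export value of class ", class(value)[[1L]])
}

#' Write a named list of variables to a MAT v5 file
#'
#' @param vars named list; see the supported kinds in the format note
#'   above.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by neuroring on %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 124L - length(hdr)))
  writeBin(hdr, con)
  writeBin(c(as.raw(0x00), as.raw(0x01)), con) # version 0x0100, LE
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) writeBin(mat_element(vars[[nm]], nm), con)
  invisible(path)
}
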