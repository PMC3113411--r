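#' Wire codec for variable bundles
#'
#' Binary, little-endian, self-describing, length-prefixed. Layout
#' (all integers little-endian):
#'
#' ```
#' message := version:uint8 (0x01) | payload_len:uint32 | payload
#' payload := index:int32 | n_items:int32 | item*
#' item    := name_len:uint16 | name (UTF-8) | type:uint8 | rank:uint8
#'            | dims:int32 x rank | data
#' type 1 = double  (8-byte IEEE)     type 2 = int32
#' type 3 = logical (1 byte each)     type 4 = character
#' ```
#'
#' Rank 0 encodes a dimensionless scalar; a plain vector has rank 1; an
#' array's `dim` attribute gives higher ranks. Character data is stored as
#' per-element `uint32` length + UTF-8 bytes. Because each message is
#' length-prefixed, consecutive messages frame cleanly on a byte stream and
#' a decoder fed a partial message can report exactly how many more bytes
#' it needs.
#'
#' @name wire-codec
NULL

NR_PROTOCOL_VERSION <- 1L

w_int <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                    endian = "little")
w_dbl <- function(x) writeBin(as.numeric(x), raw(), size = 8,
                              endian = "little")

encode_value <- function(v) {
  dims <- dim(v)
  rank <- if (!is.null(dims)) length(dims)
          else if (length(v) == 1L) 0L else 1L
  dims <- if (rank == 0L) integer(0)
          else if (is.null(dims)) length(v) else dims
  if (is.double(v)) {
    type <- 1L; data <- w_dbl(v)
  } else if (is.integer(v)) {
    type <- 2L; data <- w_int(v, 4)
  } else if (is.logical(v)) {
    type <- 3L; data <- as.raw(as.integer(v))
  } else if (is.character(v)) {
    type <- 4L
    parts <- lapply(v, function(s) {
      b <- charToRaw(enc2utf8(s))
      c(w_int(length(b), 4), b)
    })
    data <- do.call(c, c(list(raw(0)), parts))
  } else {
    stop("unsupported value kind: ", class(v)[[1L]])
  }
  c(writeBin(type, raw(), size = 1), writeBin(rank, raw(), size = 1),
    w_int(dims, 4), data)
}

#' Encode a variable bundle to its wire form
#'
#' @param b a [make_bundle()] object.
#' @return a raw vector holding exactly one framed message.
#' @seealso [decode_bundle()]
#' @export
encode_bundle <- function(b) {
  stopifnot(inherits(b, "variable_bundle"))
  parts <- list(w_int(b$index, 4), w_int(length(b$items), 4))
  for (nm in names(b$items)) {
    v <- b$items[[nm]]
    if (!(is.double(v) || is.integer(v) || is.logical(v) || is.character(v)))
      stop("unsupported value kind in item '", nm, "'")
    nb <- charToRaw(enc2utf8(nm))
    parts[[length(parts) + 1L]] <- c(w_int(length(nb), 2), nb,
                                     encode_value(v))
  }
  payload <- do.call(c, parts)
  c(writeBin(NR_PROTOCOL_VERSION, raw(), size = 1),
    w_int(length(payload), 4), payload)
}

r_int <- function(bytes, pos, size, n = 1L) {
  readBin(bytes[pos:(pos + size * n - 1L)], "integer", n = n, size = size,
          endian = "little")
}

#' Decode one framed message from a byte sequence
#'
#' On complete input returns the decoded bundle plus the number of bytes
#' consumed, so concatenated messages can be decoded in sequence. On
#' partial input returns a `needs_more` outcome stating how many further
#' bytes are required, rather than failing.
#'
#' @param bytes raw vector holding a message boundary at `from`.
#' @param from byte position (1-based) at which the message starts.
#' @return either `list(bundle=, consumed=)` or an object of class
#'   `needs_more` with element `bytes_needed`.
#' @export
decode_bundle <- function(bytes, from = 1L) {
  stopifnot(is.raw(bytes))
  avail <- length(bytes) - from + 1L
  if (avail < 5L)
    return(structure(list(bytes_needed = 5L - avail),
                     class = "needs_more"))
  version <- as.integer(bytes[[from]])
  if (version != NR_PROTOCOL_VERSION)
    stop("framing error at byte offset 0: unknown protocol version ",
         version)
  plen <- r_int(bytes, from + 1L, 4)
  if (plen < 8L) stop("framing error at byte offset 1: bad payload length")
  total <- 5L + plen
  if (avail < total)
    return(structure(list(bytes_needed = total - avail),
                     class = "needs_more"))
  pos <- from + 5L
  index <- r_int(bytes, pos, 4); pos <- pos + 4L
  n_items <- r_int(bytes, pos, 4); pos <- pos + 4L
  if (n_items < 0L) stop("framing error at byte offset ", pos - 5L)
  items <- vector("list", n_items)
  nms <- character(n_items)
  for (i in seq_len(n_items)) {
    nlen <- r_int(bytes, pos, 2); pos <- pos + 2L
    nms[[i]] <- rawToChar(bytes[pos:(pos + nlen - 1L)]); pos <- pos + nlen
    type <- as.integer(bytes[[pos]]); pos <- pos + 1L
    rank <- as.integer(bytes[[pos]]); pos <- pos + 1L
    dims <- if (rank > 0L) r_int(bytes, pos, 4, rank) else integer(0)
    pos <- pos + 4L * rank
    nelem <- if (rank == 0L) 1L else as.integer(prod(dims))
    if (nelem == 0L) {
      v <- switch(as.character(type), "1" = numeric(0), "2" = integer(0),
                  "3" = logical(0), "4" = character(0),
                  stop("framing error: unknown type tag ", type))
      if (rank > 1L) dim(v) <- dims
      items[[i]] <- v
      next
    }
    v <- switch(as.character(type),
      "1" = { out <- readBin(bytes[pos:(pos + 8L * nelem - 1L)], "double",
                             n = nelem, size = 8, endian = "little")
              pos <- pos + 8L * nelem; out },
      "2" = { out <- r_int(bytes, pos, 4, nelem)
              pos <- pos + 4L * nelem; out },
      "3" = { out <- as.logical(as.integer(bytes[pos:(pos + nelem - 1L)]))
              pos <- pos + nelem; out },
      "4" = { out <- character(nelem)
              for (k in seq_len(nelem)) {
                slen <- r_int(bytes, pos, 4); pos <- pos + 4L
                out[[k]] <- if (slen > 0L) {
                  s <- rawToChar(bytes[pos:(pos + slen - 1L)])
                  Encoding(s) <- "UTF-8"; s
                } else ""
                pos <- pos + slen
              }
              out },
      stop("framing error at byte offset ", pos - 3L, ": unknown type tag ",
           type))
    if (rank > 1L) dim(v) <- dims
    items[[i]] <- v
  }
  if (pos - from != total)
    stop("framing error: payload length mismatch (", pos - from, " vs ",
         total, ")")
  names(items) <- nms
  list(bundle = make_bundle(items, index), consumed = total)
}

#' Decode every complete message in a byte stream
#'
#' @param bytes raw vector possibly holding several concatenated messages
#'   and a trailing partial one.
#' @return `list(bundles = list of variable_bundle, remainder = raw)`.
#' @export
decode_stream <- function(bytes) {
  out <- list()
  pos <- 1L
  while (pos <= length(bytes)) {
    r <- decode_bundle(bytes, from = pos)
    if (inherits(r, "needs_more")) break
    out[[length(out) + 1L]] <- r$bundle
    pos <- pos + r$consumed
  }
  list(bundles = out,
       remainder = if (pos > length(bytes)) raw(0)
                   else bytes[pos:length(bytes)])
}

#' Merge a received bundle into a local one, matching by name
#'
#' Received items overwrite same-named local items; received names with no
#' local counterpart are retained in the result and reported as unmatched.
#'
#' @param local,received variable bundles.
#' @return `list(bundle=, unmatched = character vector of names)`.
#' @export
merge_bundle <- function(local, received) {
  stopifnot(inherits(local, "variable_bundle"),
            inherits(received, "variable_bundle"))
  items <- local$items
  unmatched <- setdiff(names(received$items), names(items))
  for (nm in names(received$items)) items[[nm]] <- received$items[[nm]]
  list(bundle = make_bundle(items, received$index), unmatched = unmatched)
}
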