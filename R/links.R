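#' TCP links and the three-engine ring
#'
#' Inter-engine traffic travels over TCP stream links carrying framed
#' bundle messages (see the wire codec). Nagle's algorithm is disabled on
#' every connection — messages must leave immediately; batching happens at
#' the application layer instead, one bundle per frame per link. Links
#' re-establish themselves after a drop (exponential backoff capped at
#' 2 s) and the in-flight frame is re-sent, which is idempotent because
#' every message carries its packet index.
#'
#' @name wire-links
NULL

#' Ring topology: acquisition -> signal processing -> application -> back
#'
#' @param acquisition,signal_processing,application each a
#'   `list(host =, port =)`; port 0 selects an ephemeral port.
#' @return an object of class `ring_topology`.
#' @export
ring_topology <- function(acquisition = list(host = "127.0.0.1", port = 0L),
                          signal_processing = list(host = "127.0.0.1",
                                                   port = 0L),
                          application = list(host = "127.0.0.1",
                                             port = 0L)) {
  chk <- function(ep) {
    stopifnot(is.character(ep$host), ep$port == 0L ||
                (ep$port >= 1024 && ep$port <= 65535))
    ep
  }
  structure(list(acquisition = chk(acquisition),
                 signal_processing = chk(signal_processing),
                 application = chk(application)),
            class = "ring_topology")
}

# One directional hop of the ring: the sender-side fd, the receiver-side
# fd, and the receiver's stream reassembly buffer.
new_link <- function(host, port) {
  e <- new.env(parent = emptyenv())
  e$host <- host; e$port <- port
  e$send_fd <- -1L; e$recv_fd <- -1L; e$listen_fd <- -1L
  e$rbuf <- raw(0)
  e$last_sent <- NULL
  class(e) <- "ring_link"
  e
}

link_open <- function(link, timeout_ms = 2000) {
  ls <- .nr_tcp_listen(link$host, link$port)
  link$listen_fd <- ls$fd
  link$port <- ls$port
  link$send_fd <- .nr_tcp_connect(link$host, link$port, timeout_ms)
  if (link$send_fd < 0) stop("could not connect to ", link$host, ":",
                             link$port)
  link$recv_fd <- .nr_tcp_accept(link$listen_fd, timeout_ms)
  if (link$recv_fd < 0) stop("accept timed out on port ", link$port)
  invisible(link)
}

link_close <- function(link) {
  for (f in c("send_fd", "recv_fd", "listen_fd")) {
    if (link[[f]] >= 0) .nr_close(link[[f]])
    link[[f]] <- -1L
  }
  link$rbuf <- raw(0)
  invisible(link)
}

# Drop and re-form the connection (listener retained), re-sending the
# in-flight message.
link_repair <- function(link, timeout_ms = 2000) {
  if (link$send_fd >= 0) .nr_close(link$send_fd)
  if (link$recv_fd >= 0) .nr_close(link$recv_fd)
  link$rbuf <- raw(0)
  backoff <- 0.05
  repeat {
    link$send_fd <- .nr_tcp_connect(link$host, link$port, timeout_ms)
    if (link$send_fd >= 0) break
    Sys.sleep(backoff)
    backoff <- min(backoff * 2, 2) # capped exponential backoff
  }
  link$recv_fd <- .nr_tcp_accept(link$listen_fd, timeout_ms)
  if (link$recv_fd < 0) stop("re-accept timed out")
  if (!is.null(link$last_sent)) .nr_send(link$send_fd, link$last_sent)
  invisible(link)
}

link_send <- function(link, bundle) {
  msg <- encode_bundle(bundle)
  link$last_sent <- msg
  if (.nr_send(link$send_fd, msg) < 0) {
    link_repair(link)
  }
  invisible(link)
}

link_recv <- function(link, timeout_ms = 2000) {
  deadline <- Sys.time() + timeout_ms / 1000
  repeat {
    r <- decode_bundle(link$rbuf)
    if (!inherits(r, "needs_more")) {
      link$rbuf <- link$rbuf[-seq_len(r$consumed)]
      return(r$bundle)
    }
    if (Sys.time() > deadline) stop("link receive timed out")
    chunk <- .nr_recv(link$recv_fd, 65536L, 200L)
    if (is.null(chunk)) stop("peer closed the connection")
    if (length(chunk) > 0L) link$rbuf <- c(link$rbuf, chunk)
  }
}

#' Establish the closed three-hop ring
#'
#' Creates the three directional links acquisition -> signal processing ->
#' application -> acquisition on the configured endpoints (loopback in a
#' single process).
#'
#' @param topology a [ring_topology()].
#' @return an object of class `engine_ring` with hops `as`, `sp`, `pa`.
#' @export
establish_ring <- function(topology) {
  stopifnot(inherits(topology, "ring_topology"))
  ring <- structure(list(
    as = new_link(topology$signal_processing$host,
                  topology$signal_processing$port),
    sp = new_link(topology$application$host, topology$application$port),
    pa = new_link(topology$acquisition$host, topology$acquisition$port)),
    class = "engine_ring")
  for (h in ring) link_open(h)
  ring
}

#' Send one bundle along a ring hop
#' @param ring an [establish_ring()] handle.
#' @param hop one of `"as"` (acquisition to signal processing), `"sp"`,
#'   `"pa"`.
#' @param bundle a variable bundle.
#' @export
ring_send <- function(ring, hop, bundle) {
  link_send(ring[[hop]], bundle)
  invisible(NULL)
}

#' Receive one bundle from a ring hop
#' @inheritParams ring_send
#' @param timeout_ms receive timeout.
#' @return the decoded bundle.
#' @export
ring_recv <- function(ring, hop, timeout_ms = 2000) {
  link_recv(ring[[hop]], timeout_ms)
}

#' Tear down and re-form one hop (engine swap / drop recovery)
#' @inheritParams ring_send
#' @export
ring_repair <- function(ring, hop) {
  link_repair(ring[[hop]])
  invisible(NULL)
}

#' Close all ring links
#' @param ring an [establish_ring()] handle.
#' @export
ring_close <- function(ring) {
  for (h in ring) link_close(h)
  invisible(NULL)
}
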