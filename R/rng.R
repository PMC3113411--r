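#' Independent, resumable random-number streams
#'
#' Each stochastic component of the system (simulator channels, target
#' scheduler, shuffle null, ...) owns its own stream so that runs are
#' reproducible regardless of what else draws from R's global generator.
#'
#' @param seed integer seed.
#' @return an object of class `rng_stream` (an environment holding the
#'   generator state).
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's generator state
#'
#' Swaps the stream's state into the global generator, evaluates, and
#' swaps back, saving the advanced state into the stream.
#'
#' @param stream an [rng_stream()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_rng <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Derive a child seed from a base seed and a component label
#'
#' Deterministic, label-dependent, and kept below 2^31.
#'
#' @param seed base integer seed.
#' @param label component name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
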