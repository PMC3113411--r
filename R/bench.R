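#' Timing benches: processing time, display refresh, and latency
#'
#' Reproduces the three classic real-time BMI timing measurements against
#' any configured system. In simulated-clock mode the measurements are
#' deterministic given seeds; wall-clock numbers depend on the host and
#' are reported but make no portable claims.
#'
#' @name bench-timing
NULL

timing_report <- function(kind, values) {
  structure(list(kind = kind, values = values,
                 summary = c(mean = mean(values), sd = stats::sd(values),
                             n = length(values))),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("<timing_report:%s> n=%d mean=%.4f ms sd=%.4f ms\n",
              x$kind, as.integer(x$summary[["n"]]),
              1000 * x$summary[["mean"]], 1000 * x$summary[["sd"]]))
  invisible(x)
}

#' Per-frame processing time
#'
#' Runs the system for `n_frames` and records, per frame, the time
#' between the arrival of a block and the completion of all ring
#' processing for it. Frames whose processing exceeds the frame period
#' are counted as overruns.
#'
#' @param sys a [launch()]ed system.
#' @param n_frames frames to measure (default 5000).
#' @return a `timing_report` with an `overruns` attribute.
#' @export
measure_processing <- function(sys, n_frames = 5000L) {
  stopifnot(inherits(sys, "bmi_system"))
  start <- length(sys$processing_times)
  over0 <- sys$overruns
  run_frames(sys, n_frames)
  vals <- unlist(sys$processing_times[(start + 1L):(start + n_frames)])
  rep <- timing_report("processing", vals)
  attr(rep, "overruns") <- sys$overruns - over0
  rep
}

#' Display refresh intervals
#'
#' Measures the time between consecutive display updates of the
#' application engine. In simulated clock every interval equals exactly
#' one frame period.
#'
#' @inheritParams measure_processing
#' @return a `timing_report` of the inter-update intervals.
#' @export
measure_refresh <- function(sys, n_frames = 5000L) {
  stopifnot(inherits(sys, "bmi_system"))
  start <- length(sys$refresh_times)
  run_frames(sys, n_frames)
  times <- unlist(sys$refresh_times[(start + 1L):(start + n_frames)])
  if (start > 0L) times <- c(unlist(sys$refresh_times[start]), times)
  iv <- diff(times)
  if (sys$clock == "sim") iv <- iv * sys$frame_period
  timing_report("refresh", iv)
}

#' Input-to-output latency with a sinusoidal probe
#'
#' One input channel carries a 10 Hz zero-offset sine; a response flag
#' flips at the display update of the frame in which a zero crossing
#' (either edge) is detected. Latency is the elapsed time from the true
#' crossing to the flag flip. The frame covering `[kT, (k+1)T)` arrives
#' at `(k+1)T` and its processing completes `processing_delay` seconds
#' later, so with crossing phases uniform over the frame the expected
#' mean latency is `T/2 + processing_delay` and the standard deviation is
#' `T/sqrt(12)`.
#'
#' Against an ideal simulated clock a probe at exactly 10 Hz would lock
#' to only two crossing phases (50 ms is 1.5 frames), so the probe
#' oscillator re-draws its phase every cycle (seeded); this realizes the
#' uniform-phase condition that independent hardware clocks produce
#' naturally.
#'
#' @param n_events number of zero crossings to collect (default 5000).
#' @param frame_period seconds per frame (default 1/30).
#' @param freq probe frequency in Hz (default 10).
#' @param processing_delay injected per-frame processing time in seconds.
#' @param seed seed for the phase dither.
#' @return a `timing_report` of per-event latencies.
#' @export
measure_latency <- function(n_events = 5000L, frame_period = 1 / 30,
                            freq = 10, processing_delay = 0, seed = 1L) {
  stopifnot(n_events >= 1, frame_period > 0, freq > 0)
  rng <- rng_stream(seed)
  latencies <- numeric(n_events)
  n_found <- 0L
  half <- 1 / (2 * freq) # seconds between successive zero crossings
  t_next <- with_rng(rng, stats::runif(1, 0, half))
  k <- 0L
  while (n_found < n_events) {
    t0 <- k * frame_period
    t1 <- t0 + frame_period
    # crossings falling inside this frame
    while (t_next < t1 && n_found < n_events) {
      if (t_next >= t0) {
        flip_time <- t1 + processing_delay # detected at display update
        n_found <- n_found + 1L
        latencies[n_found] <- flip_time - t_next
      }
      # next crossing: half a period later, phase re-drawn each cycle
      jitter <- with_rng(rng, stats::runif(1, -0.45, 0.45)) * half
      t_next <- t_next + half + jitter
    }
    k <- k + 1L
  }
  timing_report("latency", latencies)
}
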