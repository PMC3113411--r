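#' Directionally tuned synthetic ECoG
#'
#' The simulator emits multichannel pink-noise signals whose high-gamma
#' (70-120 Hz) amplitude is modulated by the cosine of the angle between a
#' drive direction and each channel's preferred direction:
#'
#' \deqn{S = S_1 + d\,\cos(\theta - \mathrm{PD}_i)\, S_2}
#'
#' where \eqn{S_1} is a 1/f ("pink") noise series, \eqn{S_2} is its
#' band-pass-filtered high-gamma component, and \eqn{d \in [0,1]} is the
#' modulation depth. Deriving \eqn{S_2} from \eqn{S_1} (rather than from an
#' independent noise source) makes the in-band amplitude gain
#' \eqn{1 + d\cos(\theta-\mathrm{PD}_i)}, so band power is monotone in
#' \eqn{\cos} and the preferred direction is identifiable by linear
#' regression — the property the decoder-training stage depends on. With
#' \eqn{d = 0}, or when the drive is inactive (baseline), the output is
#' exactly \eqn{S_1}.
#'
#' @name sim-ecog
NULL

# --- pink noise -------------------------------------------------------------

#' Design a streaming 1/f ("pinking") filter
#'
#' Cascade of first-order pole-zero shelving sections with corner
#' frequencies log-spaced over `[f_lo, f_hi]`, bilinear-transformed with
#' prewarping. Driven by white Gaussian noise the cascade output has a
#' power spectral density proportional to 1/f over the design band.
#'
#' @param sample_rate Hz.
#' @param f_lo,f_hi design band edges in Hz (defaults 1 Hz to a quarter of
#'   the sample rate).
#' @param n_sections number of pole-zero pairs.
#' @return list of sections, each `list(b =, a =)`, plus the cascade's
#'   white-noise RMS gain in attribute `rms_gain`.
#' @keywords internal
design_pink_filter <- function(sample_rate, f_lo = 1,
                               f_hi = sample_rate / 4, n_sections = 6) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_hi < sample_rate / 2)
  r <- (f_hi / f_lo)^(1 / n_sections)
  g <- sqrt(r) # per-section zero/pole frequency ratio -> -10 dB/decade power
  sections <- vector("list", n_sections)
  prewarp <- function(f) 2 * sample_rate * tan(pi * f / sample_rate)
  for (i in seq_len(n_sections)) {
    centre <- f_lo * r^(i - 0.5)
    fp <- centre / sqrt(g)
    fz <- centre * sqrt(g)
    wp <- prewarp(fp); wz <- prewarp(fz)
    kz <- 2 * sample_rate / wz
    kp <- 2 * sample_rate / wp
    b <- c(1 + kz, 1 - kz) / (1 + kp)
    a <- c(1, (1 - kp) / (1 + kp))
    sections[[i]] <- list(b = b, a = a)
  }
  # white-noise RMS gain via impulse response energy
  h <- c(1, numeric(8191))
  for (s in sections) h <- .iir_filter(s$b, s$a, h, numeric(1))$y
  attr(sections, "rms_gain") <- sqrt(sum(h^2))
  sections
}

#' Create a streaming pink-noise generator state
#'
#' @param sample_rate Hz.
#' @param seed integer seed for the white-noise source.
#' @return an environment carrying the RNG stream and filter states;
#'   successive [pink_noise_block()] calls are continuous (identical to one
#'   long call).
#' @export
pink_state <- function(sample_rate, seed) {
  e <- new.env(parent = emptyenv())
  e$sample_rate <- sample_rate
  e$sections <- design_pink_filter(sample_rate)
  e$rms_gain <- attr(e$sections, "rms_gain")
  e$z <- lapply(e$sections, function(s) numeric(1))
  e$rng <- rng_stream(seed)
  class(e) <- "pink_state"
  e
}

#' Generate the next block from a pink-noise stream
#'
#' @param state a [pink_state()].
#' @param n_samples number of samples (>= 1).
#' @return numeric vector of length `n_samples`, unit long-run RMS.
#' @export
pink_noise_block <- function(state, n_samples) {
  stopifnot(inherits(state, "pink_state"), n_samples >= 1)
  x <- with_rng(state$rng, stats::rnorm(n_samples))
  for (i in seq_along(state$sections)) {
    s <- state$sections[[i]]
    r <- .iir_filter(s$b, s$a, x, state$z[[i]])
    x <- r$y
    state$z[[i]] <- r$zf
  }
  x / state$rms_gain
}

#' One-shot pink-noise series
#'
#' Stationary series whose power spectral density falls off as 1/f over
#' roughly `[1, sample_rate/4]` Hz.
#'
#' @param n_samples series length (>= 2).
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return numeric vector.
#' @examples
#' x <- pink_noise(1200, 1200, seed = 1)
#' @export
pink_noise <- function(n_samples, sample_rate, seed) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  pink_noise_block(pink_state(sample_rate, seed), n_samples)
}

# --- simulator --------------------------------------------------------------

#' Simulator configuration
#'
#' @param n_channels number of simulated channels (default 32).
#' @param sample_rate Hz (default 1200).
#' @param mod_band modulated band in Hz (default `c(70, 120)`, the
#'   high-gamma band).
#' @param depth modulation depth `d` in `[0, 1]` (default 0.3).
#' @param preferred_directions radians, counter-clockwise from screen
#'   right; default uniformly spaced over the circle.
#' @param amplitude_scale output RMS in microvolts (default 50).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 32L, sample_rate = 1200,
                       mod_band = c(70, 120), depth = 0.3,
                       preferred_directions =
                         assign_preferred_directions(n_channels),
                       amplitude_scale = 50, seed = 1L) {
  stopifnot(depth >= 0, depth <= 1,
            mod_band[1] > 0, mod_band[2] < sample_rate / 2,
            mod_band[1] < mod_band[2],
            length(preferred_directions) == n_channels)
  structure(list(n_channels = as.integer(n_channels),
                 sample_rate = sample_rate, mod_band = mod_band,
                 depth = depth, preferred_directions = preferred_directions,
                 amplitude_scale = amplitude_scale, seed = as.integer(seed)),
            class = "sim_config")
}

#' Uniformly distributed preferred directions
#'
#' @param n number of channels (>= 1).
#' @return radians `2*pi*k/n`, `k = 0..n-1`.
#' @examples
#' assign_preferred_directions(4) # 0, pi/2, pi, 3*pi/2
#' @export
assign_preferred_directions <- function(n) {
  if (n < 1) stop("n must be >= 1")
  2 * pi * (seq_len(n) - 1) / n
}

#' Drive direction for the simulator
#'
#' @param angle radians from screen center toward the cursor/target.
#' @param active when `FALSE` (baseline) the modulation term is omitted.
#' @return an object of class `cursor_drive`.
#' @export
cursor_drive <- function(angle = 0, active = TRUE) {
  if (active && !is.finite(angle)) stop("drive angle must be finite")
  structure(list(angle = angle, active = isTRUE(active)),
            class = "cursor_drive")
}

#' Initialize per-channel simulator states
#'
#' The high-gamma component \eqn{S_2} is extracted with a linear-phase
#' windowed-sinc FIR band-pass whose group delay `D` is compensated by
#' delaying \eqn{S_1} by the same `D` samples, so the modulation is
#' zero-phase: in-band, the two series add coherently and the amplitude
#' gain is exactly \eqn{1 + d\cos(\theta-\mathrm{PD})}. (A causal IIR
#' band-pass would rotate \eqn{S_2}'s phase against \eqn{S_1} and destroy
#' most of the modulation.) The whole output is therefore delayed by `D`
#' samples relative to the noise source — irrelevant for a simulator.
#'
#' @param cfg a [sim_config()].
#' @return an environment with per-channel pink-noise streams, FIR states,
#'   delay lines, and the frame counter.
#' @export
sim_channel_states <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  nch <- cfg$n_channels
  e$rng <- lapply(seq_len(nch), function(i)
    rng_stream(derive_seed(cfg$seed, paste0("sim_ch", i))))
  sections <- design_pink_filter(cfg$sample_rate)
  e$pink_gain <- attr(sections, "rms_gain")
  e$pink_b <- do.call(rbind, lapply(sections, function(s) s$b))
  e$pink_a <- do.call(rbind, lapply(sections, function(s) s$a))
  e$pink_z <- matrix(0, nch, length(sections))
  ntaps <- 241L # ~16 Hz transition width at 1200 Hz; group delay 0.1 s
  e$fir <- as.numeric(signal::fir1(ntaps - 1L,
                                   cfg$mod_band / (cfg$sample_rate / 2),
                                   type = "pass"))
  e$delay <- (ntaps - 1L) %/% 2L
  e$fir_z <- matrix(0, nch, ntaps - 1L)
  e$delay_buf <- matrix(0, nch, e$delay)
  e$next_index <- 0L
  class(e) <- "sim_channel_states"
  e
}

#' Generate one frame of directionally modulated synthetic ECoG
#'
#' @param cfg a [sim_config()].
#' @param drive a [cursor_drive()].
#' @param n_samples samples in the frame.
#' @param states a [sim_channel_states()] (mutated: filter states and the
#'   frame counter advance).
#' @return a [signal_block()] in microvolts.
#' @export
simulate_block <- function(cfg, drive, n_samples, states) {
  stopifnot(inherits(cfg, "sim_config"), inherits(drive, "cursor_drive"),
            inherits(states, "sim_channel_states"))
  nch <- cfg$n_channels
  white <- matrix(0, nch, n_samples)
  for (i in seq_len(nch))
    white[i, ] <- with_rng(states$rng[[i]], stats::rnorm(n_samples))
  gains <- if (drive$active && cfg$depth > 0)
    cfg$depth * cos(drive$angle - cfg$preferred_directions)
  else numeric(nch)
  out <- .sim_frame(white, states$pink_b, states$pink_a, states$pink_z,
                    states$pink_gain, states$fir, states$fir_z,
                    states$delay_buf, gains, cfg$amplitude_scale)
  blk <- signal_block(out, cfg$sample_rate, states$next_index)
  states$next_index <- states$next_index + 1L
  blk
}

# --- raw binary UDP reader --------------------------------------------------

#' Encode one frame in the raw binary UDP dialect
#'
#' Datagram layout, little-endian: `uint32` frame counter, `uint16` channel
#' count, `uint16` samples per channel, then channel-major IEEE float32
#' samples (all samples of channel 1, then channel 2, ...).
#'
#' @param counter frame counter (sender-side).
#' @param data channels x samples numeric matrix.
#' @return raw vector.
#' @export
udp_encode_frame <- function(counter, data) {
  stopifnot(is.matrix(data))
  c(writeBin(as.integer(counter), raw(), size = 4, endian = "little"),
    writeBin(nrow(data), raw(), size = 2, endian = "little"),
    writeBin(ncol(data), raw(), size = 2, endian = "little"),
    writeBin(as.numeric(t(data)), raw(), size = 4, endian = "little"))
}

#' Open a raw binary UDP acquisition source
#'
#' @param port UDP port to bind (0 selects an ephemeral port).
#' @param n_channels,frame_samples expected frame geometry; datagrams that
#'   disagree are dropped and counted.
#' @param sample_rate Hz, attached to emitted blocks.
#' @param host bind address (default loopback).
#' @return an object of class `udp_reader` with elements `port` (actual
#'   bound port) and counters `dropped`, `gaps`.
#' @export
udp_reader <- function(port, n_channels, sample_rate, frame_samples,
                       host = "127.0.0.1") {
  b <- .nr_udp_bind(host, as.integer(port))
  e <- new.env(parent = emptyenv())
  e$fd <- b$fd; e$port <- b$port
  e$n_channels <- as.integer(n_channels)
  e$frame_samples <- as.integer(frame_samples)
  e$sample_rate <- sample_rate
  e$next_index <- 0L
  e$last_counter <- NA_integer_
  e$dropped <- 0L; e$gaps <- 0L
  class(e) <- "udp_reader"
  e
}

#' Read the next frame from a UDP source
#'
#' @param reader a [udp_reader()].
#' @param timeout_ms how long to wait for a datagram.
#' @return a [signal_block()] (index assigned by arrival order), or `NULL`
#'   on timeout. Malformed datagrams are dropped with a counter increment;
#'   counter gaps are logged in `reader$gaps`.
#' @export
udp_read_block <- function(reader, timeout_ms = 100) {
  stopifnot(inherits(reader, "udp_reader"))
  expect_len <- 8L + 4L * reader$n_channels * reader$frame_samples
  repeat {
    dg <- .nr_udp_recv(reader$fd, max(expect_len, 65536L), timeout_ms)
    if (length(dg) == 0L) return(NULL)
    if (length(dg) < 8L) { reader$dropped <- reader$dropped + 1L; next }
    counter <- readBin(dg[1:4], "integer", size = 4, endian = "little")
    nch <- readBin(dg[5:6], "integer", size = 2, endian = "little",
                   signed = FALSE)
    nsmp <- readBin(dg[7:8], "integer", size = 2, endian = "little",
                    signed = FALSE)
    if (nch != reader$n_channels || nsmp != reader$frame_samples ||
        length(dg) != 8L + 4L * nch * nsmp) {
      reader$dropped <- reader$dropped + 1L
      next
    }
    vals <- readBin(dg[-(1:8)], "double", n = nch * nsmp, size = 4,
                    endian = "little")
    if (!is.na(reader$last_counter) && counter != reader$last_counter + 1L)
      reader$gaps <- reader$gaps + 1L
    reader$last_counter <- counter
    blk <- signal_block(matrix(vals, nch, nsmp, byrow = TRUE),
                        reader$sample_rate, reader$next_index)
    reader$next_index <- reader$next_index + 1L
    return(blk)
  }
}

#' Close a UDP source
#' @param reader a [udp_reader()].
#' @export
udp_close <- function(reader) {
  if (!is.null(reader$fd)) .nr_close(reader$fd)
  reader$fd <- NULL
  invisible(NULL)
}
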