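#' Autoregressive band-power features and pseudo-Z normalization
#'
#' Each frame, the trailing 0.5 s window of every channel is fitted with a
#' 15th-order autoregressive model (Burg recursion); the model spectrum is
#' integrated over 10 Hz bins to give band powers. Band powers are then
#' standardized to pseudo-Z scores,
#' \deqn{f_{\mathrm{norm},i,j} = (f_{i,j} - \bar f_{i,j}) / \sigma_{i,j},}
#' with the per-feature mean and standard deviation estimated from a
#' no-task baseline period.
#'
#' @name spectral-features
NULL

#' Autoregressive spectral-estimation settings
#'
#' @param order AR model order (default 15).
#' @param bin_width frequency bin width in Hz (default 10); must divide
#'   the upper frequency limit.
#' @param window_s analysis window length in seconds (default 0.5).
#' @param f_max upper frequency limit in Hz (default 200; all decoded
#'   features live at or below 120 Hz).
#' @param grid_per_bin trapezoid sub-intervals per bin when integrating
#'   the AR spectrum (default 16).
#' @return an object of class `ar_spec`.
#' @export
ar_spec <- function(order = 15L, bin_width = 10, window_s = 0.5,
                    f_max = 200, grid_per_bin = 16L) {
  stopifnot(order >= 1, bin_width > 0, window_s > 0, f_max > bin_width)
  if (abs(f_max / bin_width - round(f_max / bin_width)) > 1e-9)
    stop("bin_width must divide f_max")
  structure(list(order = as.integer(order), bin_width = bin_width,
                 window_s = window_s, f_max = f_max,
                 band_edges = seq(0, f_max, by = bin_width),
                 grid_per_bin = as.integer(grid_per_bin)),
            class = "ar_spec")
}

#' Band powers of one window via AR spectral estimation
#'
#' Fits a Burg AR model to the (demeaned) window, evaluates the model's
#' one-sided power spectral density on a fine grid, and integrates it over
#' each bin.
#'
#' @param window numeric vector of length `window_s * sample_rate`.
#' @param sample_rate Hz.
#' @param spec an [ar_spec()].
#' @return numeric vector of non-negative band powers, one per bin.
#' @export
ar_band_power <- function(window, sample_rate, spec) {
  stopifnot(inherits(spec, "ar_spec"))
  expect_n <- round(spec$window_s * sample_rate)
  if (length(window) != expect_n)
    stop("window must hold exactly ", expect_n, " samples")
  if (expect_n < 2L * spec$order)
    stop("window too short for AR order ", spec$order)
  .burg_band_power(matrix(window, 1L), spec$order, sample_rate,
                   spec$band_edges, spec$grid_per_bin)[1L, ]
}

#' Rolling multichannel sample history
#'
#' @param n_channels channel count.
#' @param window_samples samples to retain per channel.
#' @return an environment holding the history buffer.
#' @export
feature_buffer <- function(n_channels, window_samples) {
  e <- new.env(parent = emptyenv())
  e$n_channels <- as.integer(n_channels)
  e$window_samples <- as.integer(window_samples)
  e$buf <- matrix(0, n_channels, 0)
  class(e) <- "feature_buffer"
  e
}

#' Per-frame sliding-window features
#'
#' Appends the new block to the history and computes band powers on the
#' trailing window ending at the newest sample (the window advances by one
#' frame per call). Until a full window has accumulated, a flagged warm-up
#' outcome is returned instead of features.
#'
#' @param buf a [feature_buffer()].
#' @param block a [signal_block()].
#' @param spec an [ar_spec()].
#' @return a [feature_matrix()] with the block's index, or an object of
#'   class `feature_warmup` while history is insufficient.
#' @export
sliding_features <- function(buf, block, spec) {
  stopifnot(inherits(buf, "feature_buffer"), inherits(block, "signal_block"),
            inherits(spec, "ar_spec"))
  if (nrow(block$data) != buf$n_channels)
    stop("channel count mismatch")
  keep <- buf$window_samples
  buf$buf <- cbind(buf$buf, block$data)
  if (ncol(buf$buf) > keep)
    buf$buf <- buf$buf[, (ncol(buf$buf) - keep + 1L):ncol(buf$buf),
                       drop = FALSE]
  if (ncol(buf$buf) < keep)
    return(structure(list(index = block$index,
                          have = ncol(buf$buf), need = keep),
                     class = "feature_warmup"))
  pw <- .burg_band_power(buf$buf, spec$order, block$sample_rate,
                         spec$band_edges, spec$grid_per_bin)
  feature_matrix(pw, spec$band_edges, spec$window_s, block$index)
}

#' Streaming baseline statistics (Welford)
#'
#' @param n_channels,n_bands feature-matrix shape.
#' @return an object of class `baseline_stats` with per-feature running
#'   mean, squared-deviation accumulator, and frame count.
#' @export
baseline_stats <- function(n_channels, n_bands) {
  structure(list(mean = matrix(0, n_channels, n_bands),
                 m2 = matrix(0, n_channels, n_bands),
                 n_frames = 0L),
            class = "baseline_stats")
}

#' Fold one feature frame into the baseline statistics
#'
#' Numerically stable streaming update of per-feature mean and standard
#' deviation.
#'
#' @param stats a [baseline_stats()].
#' @param fm a [feature_matrix()] of matching shape.
#' @return the updated `baseline_stats`.
#' @export
update_baseline <- function(stats, fm) {
  stopifnot(inherits(stats, "baseline_stats"),
            inherits(fm, "feature_matrix"))
  if (!all(dim(stats$mean) == dim(fm$power)))
    stop("feature shape mismatch: stats ",
         paste(dim(stats$mean), collapse = "x"), " vs frame ",
         paste(dim(fm$power), collapse = "x"))
  n <- stats$n_frames + 1L
  delta <- fm$power - stats$mean
  stats$mean <- stats$mean + delta / n
  stats$m2 <- stats$m2 + delta * (fm$power - stats$mean)
  stats$n_frames <- n
  stats
}

#' Per-feature baseline standard deviation (sample, n-1 denominator)
#'
#' @param stats a [baseline_stats()] with at least two frames.
#' @return matrix of standard deviations.
#' @export
baseline_sd <- function(stats) {
  stopifnot(inherits(stats, "baseline_stats"))
  if (stats$n_frames < 2L) stop("need at least 2 baseline frames")
  sqrt(stats$m2 / (stats$n_frames - 1L))
}

#' Pseudo-Z normalization of a feature frame
#'
#' @param fm a [feature_matrix()] of raw band powers.
#' @param stats a [baseline_stats()] estimated from the baseline period
#'   (>= 2 frames; every feature must have positive spread).
#' @return a [feature_matrix()] of pseudo-Z scores.
#' @export
normalize_features <- function(fm, stats) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(stats, "baseline_stats"))
  if (stats$n_frames < 2L) stop("need at least 2 baseline frames")
  sdv <- baseline_sd(stats)
  if (any(sdv == 0)) {
    ij <- which(sdv == 0, arr.ind = TRUE)[1L, ]
    stop("degenerate feature: zero baseline sd at channel ", ij[1L],
         ", band ", ij[2L])
  }
  feature_matrix((fm$power - stats$mean) / sdv, fm$band_edges, fm$window_s,
                 fm$index)
}

#' Invert a pseudo-Z normalization
#'
#' @param fm normalized [feature_matrix()].
#' @param stats the [baseline_stats()] used to normalize.
#' @return a [feature_matrix()] of raw band powers.
#' @export
denormalize_features <- function(fm, stats) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(stats, "baseline_stats"))
  feature_matrix(fm$power * baseline_sd(stats) + stats$mean,
                 fm$band_edges, fm$window_s, fm$index)
}

#' Welch power spectral density (mean of windowed periodograms)
#'
#' Nonparametric reference spectrum used by the simulator fidelity checks
#' (the AR estimator is parametric and can redistribute power between
#' bands).
#'
#' @param x numeric series.
#' @param sample_rate Hz.
#' @param nseg segment length (power of two recommended).
#' @return `list(freq =, psd =)`, one-sided.
#' @export
welch_psd <- function(x, sample_rate, nseg = 4096L) {
  stopifnot(length(x) >= nseg)
  hop <- nseg %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1L)) / (nseg - 1L))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc[seq_len(nseg %/% 2L)] / (length(starts) * sum(win^2) *
                                        sample_rate) * 2
  list(freq = (0:(nseg %/% 2L - 1L)) * sample_rate / nseg, psd = psd)
}

#' Integrate a Welch spectrum over a band
#'
#' @param w result of [welch_psd()].
#' @param band `c(lo, hi)` in Hz.
#' @return band power.
#' @export
welch_band_power <- function(w, band) {
  sel <- w$freq >= band[1] & w$freq < band[2]
  sum(w$psd[sel]) * (w$freq[2] - w$freq[1])
}
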