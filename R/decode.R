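#' Tuning models and decoders
#'
#' Directional tuning of each feature is modeled by multiple linear
#' regression of its pseudo-Z activity on the desired movement direction,
#' \deqn{f_i = b_{0,i} + b_{x,i} m_x + b_{y,i} m_y,}
#' with preferred direction \eqn{C_i = (b_{x,i}, b_{y,i}) / \lVert\cdot\rVert}
#' and fit quality measured by the plain coefficient of determination.
#' Features are selected by comparing each \eqn{R^2_i} against percentiles
#' of a pooled null distribution obtained by refitting after shuffling the
#' target labels. The population-vector decoder then outputs
#' \deqn{P = \sum_{i \in \mathrm{selected}} (d_i - b_{0,i})\, C_i.}
#'
#' @name decode
NULL

#' Training buffer of feature frames and kinematics
#'
#' Accumulates pseudo-Z feature vectors alongside the desired-movement
#' regressor (the unit vector toward the current target).
#'
#' @return an environment of class `training_buffer`.
#' @export
training_buffer <- function() {
  e <- new.env(parent = emptyenv())
  e$features <- list()
  e$kinematics <- list()
  class(e) <- "training_buffer"
  e
}

#' Append one frame to a training buffer
#'
#' @param buf a [training_buffer()].
#' @param features numeric vector of feature activities for the frame.
#' @param kinematics length-2 numeric `(m_x, m_y)` with norm at most 1.
#' @return the buffer, invisibly.
#' @export
buffer_frame <- function(buf, features, kinematics) {
  stopifnot(inherits(buf, "training_buffer"), length(kinematics) == 2L)
  if (sqrt(sum(kinematics^2)) > 1 + 1e-9)
    stop("kinematics rows must have norm <= 1")
  buf$features[[length(buf$features) + 1L]] <- as.numeric(features)
  buf$kinematics[[length(buf$kinematics) + 1L]] <- as.numeric(kinematics)
  invisible(buf)
}

#' @export
length.training_buffer <- function(x) length(x$features)

training_matrices <- function(buf) {
  list(Y = do.call(rbind, buf$features),
       K = do.call(rbind, buf$kinematics))
}

ols_r2 <- function(X, Y) {
  # per-column OLS of Y on X; returns coefficients and plain R^2
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("rank-deficient design: training directions are collinear")
  B <- qr.coef(qrx, Y)
  res <- Y - X %*% B
  sse <- colSums(res^2)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(sst > 0, pmax(0, 1 - sse / sst), 0)
  list(B = B, r2 = as.numeric(r2))
}

#' Fit per-feature directional tuning
#'
#' Ordinary least squares of every feature on `(1, m_x, m_y)`.
#'
#' @param buf a [training_buffer()] with at least 10 frames and
#'   non-constant kinematics.
#' @return an object of class `tuning_model` with coefficients `b0`, `bx`,
#'   `by`, fit quality `r2`, unit preferred directions `pd` (features x 2;
#'   `NA` rows where both slopes are zero), and empty selection.
#' @export
fit_tuning <- function(buf) {
  stopifnot(inherits(buf, "training_buffer"))
  if (length(buf) < 10L) stop("need at least 10 training frames")
  m <- training_matrices(buf)
  if (all(apply(m$K, 2, function(c) length(unique(c)) == 1L)))
    stop("kinematics are constant; cannot fit tuning")
  X <- cbind(1, m$K)
  fit <- ols_r2(X, m$Y)
  bx <- fit$B[2L, ]; by <- fit$B[3L, ]
  nrm <- sqrt(bx^2 + by^2)
  pd <- cbind(ifelse(nrm > 0, bx / nrm, NA_real_),
              ifelse(nrm > 0, by / nrm, NA_real_))
  structure(list(b0 = fit$B[1L, ], bx = bx, by = by, r2 = fit$r2,
                 pd = pd, null_percentiles = NULL, threshold = NULL,
                 selected = integer(0), n_frames = length(buf)),
            class = "tuning_model")
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf(
    "<tuning_model> %d features, %d frames, %d selected%s\n",
    length(x$r2), x$n_frames, length(x$selected),
    if (!is.null(x$threshold))
      sprintf(", threshold %.4f", x$threshold) else ""))
  invisible(x)
}

#' Target-shuffle null distribution of tuning R-squared
#'
#' Each iteration permutes whole kinematics rows (breaking the pairing of
#' features with targets while preserving the marginal target
#' distribution), refits every feature, and pools the resulting R-squared
#' values across features and iterations.
#'
#' @param buf a [training_buffer()].
#' @param n_iter number of shuffle iterations (default 1000).
#' @param seed integer seed.
#' @return `list(mean=, p80=, p90=, p95=)` of the pooled null.
#' @export
shuffle_null <- function(buf, n_iter = 1000L, seed = 1L,
                         chunk_size = 200L) {
  stopifnot(inherits(buf, "training_buffer"))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  m <- training_matrices(buf)
  Y <- m$Y; K <- m$K
  n <- nrow(Y); nf <- ncol(Y)
  rng <- rng_stream(seed)
  # Permuting rows of the design leaves X'X unchanged, so each refit needs
  # only X'Y. All permutations of a chunk are batched into one product.
  cs_y <- colSums(Y)
  sst <- colSums(Y^2) - cs_y^2 / n
  s1 <- colSums(K)
  xtx <- rbind(c(n, s1), cbind(s1, crossprod(K)))
  pooled <- vector("list", ceiling(n_iter / chunk_size))
  done <- 0L; ci <- 0L
  while (done < n_iter) {
    nc <- min(chunk_size, n_iter - done)
    KP <- matrix(0, n, 2L * nc)
    for (i in seq_len(nc)) {
      perm <- with_rng(rng, sample.int(n))
      KP[, 2L * i - 1L] <- K[perm, 1L]
      KP[, 2L * i] <- K[perm, 2L]
    }
    A <- crossprod(KP, Y) # (2 nc) x nf
    r2c <- matrix(0, nc, nf)
    for (i in seq_len(nc)) {
      xty <- rbind(cs_y, A[2L * i - 1L, ], A[2L * i, ])
      B <- solve(xtx, xty)
      ssr <- colSums(B * xty) - cs_y^2 / n
      r2c[i, ] <- pmin(1, pmax(0, ifelse(sst > 0, ssr / sst, 0)))
    }
    ci <- ci + 1L
    pooled[[ci]] <- as.numeric(r2c)
    done <- done + nc
  }
  pooled <- unlist(pooled, use.names = FALSE)
  list(mean = mean(pooled),
       p80 = as.numeric(stats::quantile(pooled, 0.80)),
       p90 = as.numeric(stats::quantile(pooled, 0.90)),
       p95 = as.numeric(stats::quantile(pooled, 0.95)))
}

#' Select features by an R-squared threshold
#'
#' The threshold is a live parameter: it may be changed mid-run and the
#' selection recomputed without refitting.
#'
#' @param model a fitted [fit_tuning()] model.
#' @param threshold scalar R-squared cut.
#' @return the model with `threshold` and `selected` set; an empty
#'   selection is allowed but flagged via attribute `empty_selection`.
#' @export
select_features <- function(model, threshold) {
  stopifnot(inherits(model, "tuning_model"), is.numeric(threshold),
            length(threshold) == 1L)
  model$threshold <- threshold
  model$selected <- which(model$r2 >= threshold)
  attr(model, "empty_selection") <- length(model$selected) == 0L
  model
}

#' Population-vector control signal
#'
#' \eqn{P = \sum_{i\in\mathrm{selected}} (d_i - b_{0,i}) C_i}, scaled by a
#' live gain.
#'
#' @param model a [select_features()]-ed tuning model with a non-empty
#'   selection.
#' @param activity numeric vector of instantaneous feature activities
#'   (full feature vector, same length as `model$r2`).
#' @param gain output gain in screen units per second per activity unit.
#' @param index packet index for the emitted control.
#' @return a 2-D [control_signal()].
#' @export
population_vector <- function(model, activity, gain = 1, index = 0L) {
  stopifnot(inherits(model, "tuning_model"))
  if (length(model$selected) == 0L) stop("no features selected")
  if (length(activity) != length(model$r2))
    stop("activity length ", length(activity),
         " does not match feature count ", length(model$r2))
  sel <- model$selected
  excess <- activity[sel] - model$b0[sel]
  P <- c(sum(excess * model$pd[sel, 1L]), sum(excess * model$pd[sel, 2L]))
  control_signal(gain * P, index)
}

#' Push-pull decoder parameters
#'
#' @param a gain (> 0).
#' @param b offset.
#' @param ch_pos,ch_neg identifiers of the two control channels.
#' @param band control band in Hz (default `c(70, 110)`).
#' @return an object of class `push_pull_params`.
#' @export
push_pull_params <- function(a, b, ch_pos = 1L, ch_neg = 2L,
                             band = c(70, 110)) {
  if (a <= 0) stop("gain a must be positive")
  structure(list(a = a, b = b, ch_pos = ch_pos, ch_neg = ch_neg,
                 band = band),
            class = "push_pull_params")
}

#' One-dimensional push-pull control signal
#'
#' \eqn{c_y = a (s_1 - s_2) - b}; positive values move the cursor up.
#'
#' @param s1,s2 band powers of the two control channels.
#' @param p a [push_pull_params()].
#' @param index packet index.
#' @return a 1-D [control_signal()].
#' @export
push_pull <- function(s1, s2, p, index = 0L) {
  stopifnot(inherits(p, "push_pull_params"), is.finite(s1), is.finite(s2))
  control_signal(p$a * (s1 - s2) - p$b, index)
}

#' Calibrate push-pull gain and offset from baseline samples
#'
#' Chooses `a` and `b` so the calibrated control over the baseline has
#' zero mean and unit variance: `a = 1/sd(s1 - s2)`, `b = a * mean(s1 - s2)`
#' (sample standard deviation).
#'
#' @param diff_samples baseline series of `s1 - s2`.
#' @param ... passed to [push_pull_params()].
#' @return a [push_pull_params()].
#' @export
calibrate_push_pull <- function(diff_samples, ...) {
  if (length(diff_samples) < 2L) stop("need at least 2 baseline samples")
  s <- stats::sd(diff_samples)
  if (s == 0) stop("degenerate baseline: zero variance of s1 - s2")
  a <- 1 / s
  push_pull_params(a = a, b = a * mean(diff_samples), ...)
}

#' Generic linear decoder
#'
#' @param W weight matrix (outputs x features).
#' @param w0 intercept vector (length = outputs).
#' @param activity feature vector.
#' @param index packet index.
#' @return a [control_signal()] `v = W d + w0`.
#' @export
linear_decoder <- function(W, w0, activity, index = 0L) {
  if (!is.matrix(W)) W <- matrix(W, nrow = length(w0))
  if (ncol(W) != length(activity) || nrow(W) != length(w0))
    stop("shape mismatch: W is ", nrow(W), "x", ncol(W), ", activity ",
         length(activity), ", w0 ", length(w0))
  control_signal(as.numeric(W %*% activity + w0), index)
}

#' Express a population-vector decoder as a linear decoder
#'
#' @param model a selected tuning model.
#' @param gain output gain.
#' @return `list(W =, w0 =)` such that
#'   `linear_decoder(W, w0, d)` equals `population_vector(model, d, gain)`.
#' @export
population_vector_weights <- function(model, gain = 1) {
  stopifnot(inherits(model, "tuning_model"))
  sel <- model$selected
  nf <- length(model$r2)
  W <- matrix(0, 2L, nf)
  W[1L, sel] <- gain * model$pd[sel, 1L]
  W[2L, sel] <- gain * model$pd[sel, 2L]
  w0 <- -gain * c(sum(model$b0[sel] * model$pd[sel, 1L]),
                  sum(model$b0[sel] * model$pd[sel, 2L]))
  list(W = W, w0 = w0)
}

#' Circular absolute error between two angles
#'
#' @param a,b angles in radians.
#' @return absolute difference wrapped to `[0, pi]`.
#' @export
angle_error <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
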