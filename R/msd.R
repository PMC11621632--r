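# Mean square displacement over nonoverlapping lags, and power-law fits of
# the diffusion constant D and scaling exponent alpha.

#' Mean square displacement over nonoverlapping lags
#'
#' For each lag of `dt` frames, averages the squared Euclidean displacement
#' between the nonoverlapping sample pairs `(j-1)*dt + 1` and `j*dt + 1`,
#' `j = 1 ... floor((N-1)/dt)`. Overlapping pairs are strongly correlated
#' and would bias the scaling exponent upward when few traces are available,
#' so only nonoverlapping pairs enter. Lags run from 1 to `floor(N/4)`
#' frames; longer lags have too few pairs to be reliable.
#'
#' @param trace an [eye_trace()] or n x 2 position matrix (arcmin).
#' @param frame_rate sampling rate in Hz, taken from the trace when given.
#' @return an object of class `msd_curve`: data frame with columns
#'   `lag_frames`, `lag_s`, `msd` (arcmin^2), `n_pairs`.
#' @seealso [fit_diffusion()] to fit `(D, alpha)` from the curve.
#' @examples
#' tr <- generate_drift_trace(D = 5, n_frames = 90, seed = 1)
#' head(msd_curve(tr))
#' @export
msd_curve <- function(trace, frame_rate = frame_rate_of(trace)) {
  pos <- as_positions(trace)
  n <- nrow(pos)
  if (n < 8L) {
    stop("trace too short: need at least 8 frames for 2 MSD lags",
         call. = FALSE)
  }
  max_lag <- n %/% 4L
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  x <- pos[, 1L]
  y <- pos[, 2L]
  for (dt in lags) {
    j <- seq_len((n - 1L) %/% dt)
    i1 <- (j - 1L) * dt + 1L
    i2 <- j * dt + 1L
    sq <- (x[i2] - x[i1])^2 + (y[i2] - y[i1])^2
    msd[dt] <- mean(sq)
    n_pairs[dt] <- length(sq)
  }
  out <- data.frame(lag_frames = lags, lag_s = lags / frame_rate,
                    msd = msd, n_pairs = n_pairs)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
as.data.frame.msd_curve <- function(x, ...) {
  out <- x
  class(out) <- "data.frame"
  attr(out, "frame_rate") <- NULL
  out
}

#' Fit diffusion constant and scaling exponent from an MSD curve
#'
#' Fits the anomalous-diffusion power law `MSD = 2 * d * D * dt^alpha` by
#' ordinary least squares of `log10(MSD)` on `log10(dt)` with the lag in
#' seconds: the slope is `alpha` and the intercept is
#' `log10(2 * d * D)`, so `D = 10^intercept / (2 * d)` carries units of
#' arcmin^2/s. `alpha = 1` is Brownian motion, `alpha > 1` persistent
#' (superdiffusive) and `alpha < 1` antipersistent (subdiffusive) motion;
#' a constant-velocity trajectory has `alpha = 2` exactly. Zero-MSD lags are
#' excluded (their log is undefined); fewer than two usable lags is an
#' error.
#'
#' @param curve an [msd_curve()] (or data frame with `lag_s`, `msd`,
#'   `n_pairs`).
#' @param d spatial dimension of the motion (2 for gaze traces).
#' @param source label for the motion source: `"EM"` (eye), `"WM"` (world),
#'   `"RM"` (retinal), or `"PM"` (perceptual match).
#' @param speed optional mean speed (arcmin/s) to carry in the result.
#' @return an object of class `motion_stats`: list with `D` (arcmin^2/s),
#'   `alpha`, `speed`, `source`, `fit_r2`, `n_lags`.
#' @examples
#' curve <- msd_curve(generate_drift_trace(D = 5, n_frames = 90, seed = 1))
#' fit_diffusion(curve)
#' @export
fit_diffusion <- function(curve, d = 2, source = "EM", speed = NA_real_) {
  stopifnot(is.data.frame(curve), all(c("lag_s", "msd") %in% names(curve)))
  use <- is.finite(curve$msd) & curve$msd > 0
  if (sum(use) < 2L) {
    stop("fewer than 2 lags with positive MSD: cannot fit a power law",
         call. = FALSE)
  }
  lx <- log10(curve$lag_s[use])
  ly <- log10(curve$msd[use])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2L])
  D <- 10^unname(fit$coefficients[1L]) / (2 * d)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  motion_stats(D = D, alpha = alpha, speed = speed, source = source,
               fit_r2 = r2, n_lags = sum(use))
}

motion_stats <- function(D, alpha, speed = NA_real_, source = "EM",
                         fit_r2 = NA_real_, n_lags = NA_integer_) {
  source <- match.arg(source, c("EM", "WM", "RM", "PM"))
  if (!is.na(D) && D < 0) stop("`D` must be nonnegative", call. = FALSE)
  structure(
    list(D = D, alpha = alpha, speed = speed, source = source,
         fit_r2 = fit_r2, n_lags = n_lags),
    class = "motion_stats"
  )
}

#' @export
print.motion_stats <- function(x, ...) {
  cat(sprintf("<motion_stats %s: D = %.4g arcmin^2/s, alpha = %.3f, speed = %.4g arcmin/s (R^2 = %.4f, %s lags)>\n",
              x$source, x$D, x$alpha, x$speed, x$fit_r2,
              format(x$n_lags)))
  invisible(x)
}

#' @export
as.data.frame.motion_stats <- function(x, ...) {
  data.frame(source = x$source, D = x$D, alpha = x$alpha, speed = x$speed,
             fit_r2 = x$fit_r2, n_lags = x$n_lags)
}

#' Mean drift speed
#'
#' Average frame-to-frame Euclidean displacement of the eye per unit time.
#'
#' @param trace an [eye_trace()] or n x 2 position matrix.
#' @param frame_rate sampling rate in Hz, taken from the trace when given.
#' @return mean speed, arcmin/s.
#' @export
mean_speed <- function(trace, frame_rate = frame_rate_of(trace)) {
  pos <- as_positions(trace)
  st <- pos[-1L, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  mean(sqrt(rowSums(st^2))) * frame_rate
}

#' Pooled motion statistics over several presentations
#'
#' Combines the valid presentations of one trial into a single `(D, alpha)`
#' estimate. The default pools the MSD curves: curves are computed per
#' trajectory, averaged at each common lag with weights proportional to the
#' number of nonoverlapping pairs, and the averaged curve is fitted once.
#' Lags are limited by the shortest trajectory. `method = "per_trace"` fits
#' each trajectory separately and averages the fitted parameters instead, as
#' a sensitivity check; pooling the curves first is less noisy because the
#' high-lag points of a single short trace average very few pairs.
#'
#' @param traces list of [eye_trace()] objects or n x 2 position matrices,
#'   all sharing one frame rate.
#' @param frame_rate sampling rate in Hz (taken from the first trace if it
#'   carries one).
#' @param d spatial dimension (2).
#' @param source motion-source label for the result.
#' @param method `"pooled_msd"` (default) or `"per_trace"`.
#' @return a `motion_stats` object; `speed` is the mean of the per-trace
#'   mean speeds.
#' @export
pooled_stats <- function(traces, frame_rate = NULL, d = 2, source = "EM",
                         method = c("pooled_msd", "per_trace")) {
  method <- match.arg(method)
  if (length(traces) == 0L) {
    stop("no valid traces to pool", call. = FALSE)
  }
  if (is.null(frame_rate)) frame_rate <- frame_rate_of(traces[[1L]])
  speed <- mean(vapply(traces, mean_speed, numeric(1L),
                       frame_rate = frame_rate))
  if (method == "per_trace") {
    fits <- lapply(traces, function(tr) {
      fit_diffusion(msd_curve(tr, frame_rate), d = d, source = source)
    })
    return(motion_stats(
      D = mean(vapply(fits, `[[`, numeric(1L), "D")),
      alpha = mean(vapply(fits, `[[`, numeric(1L), "alpha")),
      speed = speed, source = source,
      fit_r2 = mean(vapply(fits, `[[`, numeric(1L), "fit_r2")),
      n_lags = min(vapply(fits, `[[`, integer(1L), "n_lags"))
    ))
  }
  curves <- lapply(traces, msd_curve, frame_rate = frame_rate)
  max_lag <- min(vapply(curves, nrow, integer(1L)))
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (dt in seq_len(max_lag)) {
    w <- vapply(curves, function(cu) cu$n_pairs[dt], numeric(1L))
    v <- vapply(curves, function(cu) cu$msd[dt], numeric(1L))
    msd[dt] <- sum(w * v) / sum(w)
    n_pairs[dt] <- as.integer(sum(w))
  }
  pooled <- data.frame(lag_frames = seq_len(max_lag),
                       lag_s = seq_len(max_lag) / frame_rate,
                       msd = msd, n_pairs = n_pairs)
  class(pooled) <- c("msd_curve", "data.frame")
  attr(pooled, "frame_rate") <- frame_rate
  fit_diffusion(pooled, d = d, source = source, speed = speed)
}
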