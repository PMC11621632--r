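# Synthetic drift, microsaccades, delivery jitter, and the random-walk
# stimulus library.

#' Generate a synthetic fixational drift trace
#'
#' Simulates two-dimensional drift as independent fractional Brownian motion
#' per axis, with the diffusion constant anchored at the one-frame lag: the
#' expected mean square displacement at a one-frame lag is
#' `2 * d * D * (1/frame_rate)^alpha` with dimension `d = 2`, so an MSD
#' power-law fit over lags recovers `(D, alpha)` in expectation at every lag,
#' not just the first. For `alpha = 1` this reduces to an ordinary Brownian
#' walk with per-axis step SD `sqrt(D / (frame_rate / 2))` (at 60 Hz,
#' `sqrt(D / 30)`); `alpha > 1` gives persistent (superdiffusive) drift and
#' `alpha < 1` antipersistent (subdiffusive) drift.
#'
#' @param D diffusion constant target, arcmin^2/s (>= 0).
#' @param alpha MSD scaling-exponent target, in (0, 2); fixational drift is
#'   typically in 0.8--1.6.
#' @param n_frames trace length in frames (>= 8, so that at least two
#'   nonoverlapping-MSD lags exist for fitting).
#' @param frame_rate sampling rate, Hz.
#' @param seed optional integer; fixed seeds reproduce traces exactly without
#'   disturbing the session RNG stream.
#' @param trace_id label for the returned trace.
#' @return an [eye_trace()] starting at the origin.
#' @examples
#' tr <- generate_drift_trace(D = 5, alpha = 1.2, n_frames = 90, seed = 1)
#' fit_diffusion(msd_curve(tr))
#' @export
generate_drift_trace <- function(D, alpha = 1, n_frames = 90, frame_rate = 60,
                                 seed = NULL, trace_id = "sim") {
  stopifnot_scalar(D, "D")
  stopifnot_scalar(alpha, "alpha")
  if (D < 0) stop("`D` must be nonnegative", call. = FALSE)
  if (alpha <= 0 || alpha >= 2) {
    stop("`alpha` must lie strictly inside (0, 2)", call. = FALSE)
  }
  if (n_frames < 8L) {
    stop("`n_frames` must be at least 8 (two fitting lags)", call. = FALSE)
  }
  n_inc <- n_frames - 1L
  if (D == 0) {
    pos <- matrix(0, n_frames, 2L)
  } else {
    # Per-axis one-frame increment SD from the MSD-at-lag-1 calibration:
    # 2 * sigma^2 = 2 * d * D * dt^alpha with d = 2.
    sigma <- sqrt(2 * D * (1 / frame_rate)^alpha)
    H <- alpha / 2
    inc <- with_seed(seed, {
      cbind(fgn_sample(n_inc, H), fgn_sample(n_inc, H)) * sigma
    })
    pos <- rbind(c(0, 0), apply(inc, 2L, cumsum))
  }
  eye_trace(pos, frame_rate = frame_rate, trace_id = trace_id)
}

#' Analytic diffusion constant of a Brownian step length
#'
#' Closed-form diffusion constant of a random walk whose per-frame x and y
#' steps are drawn independently from a normal distribution with SD
#' `step_sd`: the one-frame MSD is `2 * step_sd^2`, so
#' `D = MSD / (2 * d * dt) = step_sd^2 * frame_rate / 2` with `d = 2` and
#' `dt = 1/frame_rate`. A step length of 1.6 arcmin at 60 Hz corresponds to
#' 76.8 arcmin^2/s.
#'
#' @param step_sd per-axis step SD, arcmin/frame (>= 0); vectorised.
#' @param frame_rate sampling rate, Hz.
#' @return diffusion constant(s), arcmin^2/s.
#' @export
analytic_diffusion_constant <- function(step_sd, frame_rate = 60) {
  if (any(step_sd < 0)) stop("`step_sd` must be nonnegative", call. = FALSE)
  step_sd^2 * frame_rate / 2
}

#' Generate the Brownian random-walk stimulus library
#'
#' Builds the pregenerated matching-stimulus library: for each per-frame step
#' length on a grid, `n_generate` Brownian displacement paths are drawn and
#' the `n_keep` paths whose fitted diffusion constants lie closest to the
#' step length's analytic diffusion constant are retained (ties broken by
#' candidate index). Because step directions are isotropic, the scaling
#' exponent of the retained paths is approximately 1 by construction. The
#' defaults reproduce the study library: 32 step lengths from 0.05 to 1.6
#' arcmin in 0.05 steps, 100 candidates per step length, 10 kept.
#'
#' @param step_min,step_max,step_inc step-length grid, arcmin/frame.
#' @param n_generate candidate paths per step length.
#' @param n_keep retained paths per step length (<= `n_generate`).
#' @param duration_frames path length in frames (90 frames = 1,500 ms at
#'   60 Hz; use 45 for the 750-ms condition).
#' @param frame_rate sampling rate, Hz.
#' @param seed optional integer seed; identical seeds reproduce the library
#'   bit for bit.
#' @return an object of class `walk_library`: list with `step_lengths`,
#'   `analytic_D`, `duration_frames`, `frame_rate`, `seed`, and `paths` (one
#'   element per step length, each a list of retained paths carrying
#'   `candidate`, `positions`, `fitted_D`, `fitted_alpha`).
#' @export
generate_walk_library <- function(step_min = 0.05, step_max = 1.6,
                                  step_inc = 0.05, n_generate = 100L,
                                  n_keep = 10L, duration_frames = 90L,
                                  frame_rate = 60, seed = NULL) {
  steps <- seq(step_min, step_max, by = step_inc)
  if (length(steps) == 0L) stop("step grid is empty", call. = FALSE)
  if (n_keep > n_generate) {
    stop("`n_keep` cannot exceed `n_generate`", call. = FALSE)
  }
  if (duration_frames < 8L) {
    stop("`duration_frames` must be at least 8", call. = FALSE)
  }
  analytic <- analytic_diffusion_constant(steps, frame_rate)
  paths <- with_seed(seed, {
    lapply(seq_along(steps), function(i) {
      sd_i <- steps[i]
      cands <- lapply(seq_len(n_generate), function(j) {
        inc <- matrix(stats::rnorm(2L * (duration_frames - 1L), sd = sd_i),
                      ncol = 2L)
        pos <- rbind(c(0, 0), apply(inc, 2L, cumsum))
        colnames(pos) <- c("x", "y")
        fit <- fit_diffusion(msd_curve(pos, frame_rate = frame_rate))
        list(candidate = j, positions = pos,
             fitted_D = fit$D, fitted_alpha = fit$alpha)
      })
      dev <- vapply(cands, function(p) abs(p$fitted_D - analytic[i]),
                    numeric(1L))
      cands[order(dev)[seq_len(n_keep)]] # order() is stable: ties by index
    })
  })
  structure(
    list(step_lengths = steps, analytic_D = analytic,
         duration_frames = as.integer(duration_frames),
         frame_rate = frame_rate, n_keep = as.integer(n_keep),
         n_generate = as.integer(n_generate), seed = seed, paths = paths),
    class = "walk_library"
  )
}

#' @export
print.walk_library <- function(x, ...) {
  cat(sprintf(
    "<walk_library: %d step lengths (%.2f..%.2f arcmin), %d/%d paths kept, %d frames @ %g Hz>\n",
    length(x$step_lengths), min(x$step_lengths), max(x$step_lengths),
    x$n_keep, x$n_generate, x$duration_frames, x$frame_rate))
  invisible(x)
}

#' Snap a diffusion constant to the nearest library level
#'
#' @param D diffusion constant, arcmin^2/s.
#' @param library a [generate_walk_library()] object.
#' @return the analytic diffusion constant of the closest step-length level.
#' @export
snap_to_library <- function(D, library) {
  stopifnot(inherits(library, "walk_library"))
  library$analytic_D[which.min(abs(library$analytic_D - D))]
}

#' Inject ballistic microsaccades into a drift trace
#'
#' Adds linear, ballistic displacement segments at Poisson-distributed onset
#' times: each event displaces the eye by `amplitude_arcmin` in a uniformly
#' random direction, spread evenly over `duration_frames` frames, and the
#' eye remains at the post-saccadic position afterwards. The defaults
#' (10 arcmin over 2 frames, i.e. a peak speed of 300 arcmin/s at 60 Hz) sit
#' far above drift speeds, as real microsaccades do relative to drift.
#' Events are placed without overlap and away from the trace ends; ground
#' truth is attached as attribute `"saccade_events"` (a data frame of
#' `onset_frame`, `offset_frame` displacement intervals).
#'
#' @param trace an [eye_trace()].
#' @param rate_hz mean event rate, events/s (0 returns the trace unchanged).
#' @param amplitude_arcmin saccade amplitude, arcmin.
#' @param duration_frames frames over which the displacement is spread.
#' @param seed optional integer seed.
#' @return an [eye_trace()] with attribute `"saccade_events"`.
#' @export
inject_microsaccades <- function(trace, rate_hz = 0.5, amplitude_arcmin = 10,
                                 duration_frames = 2L, seed = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  if (rate_hz < 0 || amplitude_arcmin < 0) {
    stop("`rate_hz` and `amplitude_arcmin` must be nonnegative", call. = FALSE)
  }
  n <- n_frames(trace)
  events <- data.frame(onset_frame = integer(0), offset_frame = integer(0))
  if (rate_hz == 0 || n <= duration_frames + 2L) {
    attr(trace, "saccade_events") <- events
    return(trace)
  }
  dur_s <- (n - 1) / trace$frame_rate
  pos <- trace$positions
  with_seed(seed, {
    k <- stats::rpois(1L, rate_hz * dur_s)
    if (k > 0L) {
      # candidate onset steps (displacement indices), kept off the ends
      cand <- sample(seq(2L, n - duration_frames - 1L))
      chosen <- integer(0)
      for (s in cand) {
        if (length(chosen) == k) break
        if (!any(abs(chosen - s) <= duration_frames)) chosen <- c(chosen, s)
      }
      chosen <- sort(chosen)
      for (s in chosen) {
        theta <- stats::runif(1L, 0, 2 * pi)
        step <- amplitude_arcmin / duration_frames *
          c(cos(theta), sin(theta))
        for (j in seq_len(duration_frames)) {
          rows <- seq(s + j, n) # shift all later frames: eye stays displaced
          pos[rows, 1L] <- pos[rows, 1L] + step[1L]
          pos[rows, 2L] <- pos[rows, 2L] + step[2L]
        }
      }
      if (length(chosen) > 0L) {
        events <- data.frame(onset_frame = chosen,
                             offset_frame = chosen + as.integer(duration_frames))
      }
    }
  })
  out <- eye_trace(pos, frame_rate = trace$frame_rate,
                   valid_mask = trace$valid_mask, trace_id = trace$trace_id)
  attr(out, "saccade_events") <- events
  out
}

#' Simulate imperfect stimulus delivery
#'
#' Models per-frame stimulus-delivery error: the delivered stimulus position
#' is the targeted position plus i.i.d. Gaussian error of SD `jitter_sd` per
#' axis. The targeted positions are the world trajectory of a
#' [trajectory_set][apply_gain()] (or any n x 2 matrix).
#'
#' @param trajectory a `trajectory_set` or n x 2 matrix of targeted
#'   positions (arcmin).
#' @param jitter_sd per-axis delivery error SD, arcmin (>= 0).
#' @param seed optional integer seed.
#' @param presentation_mask optional logical vector of frames with stimulus
#'   presentation; defaults to all `TRUE`.
#' @return an object of class `delivery_record`: list with `targeted`,
#'   `delivered`, `presentation_mask`.
#' @seealso [delivery_quality()] for the QC screen applied to the record.
#' @export
inject_delivery_jitter <- function(trajectory, jitter_sd, seed = NULL,
                                   presentation_mask = NULL) {
  targeted <- if (inherits(trajectory, "trajectory_set")) {
    trajectory$world
  } else {
    as_positions(trajectory)
  }
  stopifnot_scalar(jitter_sd, "jitter_sd")
  if (jitter_sd < 0) stop("`jitter_sd` must be nonnegative", call. = FALSE)
  n <- nrow(targeted)
  if (is.null(presentation_mask)) presentation_mask <- rep(TRUE, n)
  err <- with_seed(seed, matrix(stats::rnorm(2L * n, sd = jitter_sd),
                                ncol = 2L))
  structure(
    list(targeted = targeted, delivered = targeted + err,
         presentation_mask = as.logical(presentation_mask)),
    class = "delivery_record"
  )
}
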