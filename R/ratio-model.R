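# MSD-matching model observer: predicts the perceived-to-world
# diffusion-constant ratio as a function of the world-motion scaling
# exponent.

#' Model-observer parameters
#'
#' The model observer equates the mean square displacement of a Brownian
#' comparison stimulus (scaling exponent fixed at 1) with that of the
#' retina-contingent stimulus at a single matching interval. The study's
#' least-squares fit selected an interval of 2 frames at 60 Hz.
#'
#' @param delta_t_match matching interval, frames (>= 1).
#' @param frame_rate sampling rate, Hz.
#' @param alpha_pm scaling exponent of the comparison stimulus; 1 unless
#'   explicitly overridden.
#' @return list of class `match_model_params`.
#' @export
match_model_params <- function(delta_t_match = 2L, frame_rate = 60,
                               alpha_pm = 1) {
  if (delta_t_match < 1) stop("`delta_t_match` must be >= 1", call. = FALSE)
  structure(
    list(delta_t_match = delta_t_match, frame_rate = frame_rate,
         alpha_pm = alpha_pm),
    class = "match_model_params"
  )
}

#' Predicted perceived-to-world diffusion ratio
#'
#' Equating `MSD_PM(dt) = 2 d D_PM dt` (Brownian comparison) with
#' `MSD_WM(dt) = 2 d D_WM dt^alpha_WM` at the matching interval
#' `dt = delta_t_match / frame_rate` seconds gives
#' `D_PM / D_WM = (frame_rate / delta_t_match)^(1 - alpha_WM)`; with the
#' defaults, `30^(1 - alpha_WM)`. Brownian world motion (`alpha_WM = 1`) is
#' matched veridically (ratio 1); persistent motion (`alpha_WM > 1`) covers
#' more ground at short intervals than its diffusion constant alone implies
#' and is matched by a ratio below 1 (exponential decay in `alpha_WM`);
#' antipersistent motion is matched by a ratio above 1.
#'
#' @param alpha_wm scaling exponent(s) of the world motion; vectorised.
#' @param params a [match_model_params()].
#' @return predicted `D_PM / D_WM` (dimensionless).
#' @examples
#' predict_ratio(c(0.9, 1, 1.8))
#' @export
predict_ratio <- function(alpha_wm, params = match_model_params()) {
  if (any(!is.finite(alpha_wm))) {
    stop("`alpha_wm` must be finite", call. = FALSE)
  }
  (params$frame_rate / params$delta_t_match)^(1 - alpha_wm)
}

#' Matched diffusion constant of the model observer
#'
#' The Brownian diffusion constant whose MSD equals the world-motion MSD at
#' the matching interval: `D_PM = D_WM * predict_ratio(alpha_WM)`.
#'
#' @param D_wm world-motion diffusion constant, arcmin^2/s (>= 0).
#' @param alpha_wm world-motion scaling exponent.
#' @param params a [match_model_params()].
#' @return matched diffusion constant `D_PM`, arcmin^2/s.
#' @export
match_D <- function(D_wm, alpha_wm, params = match_model_params()) {
  if (any(D_wm < 0)) stop("`D_wm` must be nonnegative", call. = FALSE)
  D_wm * predict_ratio(alpha_wm, params)
}

#' Recover the matching interval from observed ratios
#'
#' Grid search over candidate integer matching intervals, minimising the sum
#' of squared residuals between observed `D_PM / D_WM` ratios and the model
#' prediction at the matched `alpha_WM` values; ties are broken toward the
#' smaller interval. Observations with `alpha_WM` identically 1 carry no
#' information (every interval predicts ratio 1), so an all-Brownian input
#' is flagged as degenerate rather than returning an arbitrary interval.
#'
#' @param ratios observed `D_PM / D_WM` values.
#' @param alphas matched `alpha_WM` values, same length.
#' @param frame_rate Hz.
#' @param candidates integer intervals to try, frames; defaults to
#'   `1:(frame_rate %/% 4)`.
#' @return list with `delta_t_match` (frames; `NA` when degenerate),
#'   `degenerate`, and `sse` (named vector of residual sums over the grid).
#' @export
fit_match_interval <- function(ratios, alphas, frame_rate = 60,
                               candidates = NULL) {
  if (length(ratios) != length(alphas) || length(ratios) < 2L) {
    stop("need >= 2 aligned (ratio, alpha) observations", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- seq_len(frame_rate %/% 4)
  candidates <- sort(unique(as.integer(candidates))) # ties -> smaller dt
  if (all(abs(alphas - 1) < sqrt(.Machine$double.eps))) {
    warning("all alpha_WM equal 1: matching interval is unidentifiable",
            call. = FALSE)
    return(list(delta_t_match = NA_integer_, degenerate = TRUE,
                sse = stats::setNames(rep(NA_real_, length(candidates)),
                                      candidates)))
  }
  sse <- vapply(candidates, function(dt) {
    pred <- predict_ratio(alphas, match_model_params(dt, frame_rate))
    sum((ratios - pred)^2)
  }, numeric(1L))
  names(sse) <- candidates
  best <- candidates[which.min(sse)] # which.min: first minimum = smallest dt
  list(delta_t_match = best, degenerate = FALSE, sse = sse)
}

#' Model-curve table
#'
#' Evaluates the predicted ratio over a grid of world-motion scaling
#' exponents, in the layout used to overlay the model on observed ratios.
#'
#' @param alpha_grid exponent grid (default 0.9 to 1.8 in 0.01 steps, the
#'   range spanned by measured world motion).
#' @param params a [match_model_params()].
#' @return data frame with `alpha_wm`, `predicted_ratio`.
#' @export
model_curve <- function(alpha_grid = seq(0.9, 1.8, by = 0.01),
                        params = match_model_params()) {
  data.frame(alpha_wm = alpha_grid,
             predicted_ratio = predict_ratio(alpha_grid, params))
}
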