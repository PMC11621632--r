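# Independent oracles, kept deliberately naive so they share no code with
# the implementation they check.

# Brute-force nonoverlapping-pair MSD: walk pairs explicitly for each lag.
brute_msd <- function(pos, frame_rate = 60) {
  n <- nrow(pos)
  max_lag <- floor(n / 4)
  out <- data.frame(lag_frames = integer(0), lag_s = numeric(0),
                    msd = numeric(0), n_pairs = integer(0))
  for (dt in seq_len(max_lag)) {
    sq <- c()
    start <- 1
    while (start + dt <= n) {
      dx <- pos[start + dt, 1] - pos[start, 1]
      dy <- pos[start + dt, 2] - pos[start, 2]
      sq <- c(sq, dx^2 + dy^2)
      start <- start + dt # next nonoverlapping pair
    }
    out <- rbind(out, data.frame(lag_frames = dt, lag_s = dt / frame_rate,
                                 msd = mean(sq), n_pairs = length(sq)))
  }
  out
}

# Numerically equate a Brownian MSD with an anomalous-diffusion MSD at one
# interval: find D_pm with 2*d*D_pm*dt = 2*d*D_wm*dt^alpha by root finding.
msd_equate_oracle <- function(D_wm, alpha_wm, dt_s, d = 2) {
  f <- function(D_pm) 2 * d * D_pm * dt_s - 2 * d * D_wm * dt_s^alpha_wm
  upper <- max(1, 10 * D_wm * max(dt_s^(alpha_wm - 1), 1e6))
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

# Random short test trace (Brownian, unit steps).
random_trace <- function(n, frame_rate = 60) {
  pos <- cbind(cumsum(c(0, rnorm(n - 1))), cumsum(c(0, rnorm(n - 1))))
  eye_trace(pos, frame_rate = frame_rate)
}
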