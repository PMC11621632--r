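# Exact fractional Gaussian noise (fGn) synthesis.
#
# Drift is modelled as fractional Brownian motion per axis: increments are
# stationary Gaussian noise with Hurst exponent H, so the per-axis MSD over a
# lag of k frames is exactly sigma^2 * k^(2H) for one-frame increment SD
# sigma. The primary sampler is Davies-Harte circulant embedding (exact and
# O(n log n)); if the circulant eigenvalues are not all nonnegative the
# sampler falls back to an exact Cholesky factorisation of the n x n
# covariance. Eigenvalues / factors are memoised per (n, H).

# Autocovariance of unit-variance fGn at integer lags k >= 0.
fgn_autocov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

.fgn_cache <- new.env(parent = emptyenv())

fgn_circulant_eigenvalues <- function(n, H) {
  key <- sprintf("ev_%d_%.12g", n, H)
  ev <- .fgn_cache[[key]]
  if (is.null(ev)) {
    g <- fgn_autocov(0:n, H)
    circ <- c(g, rev(g[seq(2L, length.out = n - 1L)])) # length 2n
    ev <- Re(stats::fft(circ))
    .fgn_cache[[key]] <- ev
  }
  ev
}

fgn_chol_factor <- function(n, H) {
  key <- sprintf("chol_%d_%.12g", n, H)
  U <- .fgn_cache[[key]]
  if (is.null(U)) {
    C <- stats::toeplitz(fgn_autocov(0:(n - 1L), H))
    U <- chol(C)
    .fgn_cache[[key]] <- U
  }
  U
}

# One unit-variance fGn sample path of length n, Hurst H in (0, 1].
# Uses the session RNG stream; seed handling belongs to callers.
fgn_sample <- function(n, H) {
  if (H <= 0 || H > 1) {
    stop("Hurst exponent must lie in (0, 1]", call. = FALSE)
  }
  if (n == 1L) {
    return(stats::rnorm(1L))
  }
  ev <- fgn_circulant_eigenvalues(n, H)
  if (min(ev) < -1e-8 * max(abs(ev))) {
    # Embedding not nonnegative definite at this (n, H): exact fallback.
    U <- fgn_chol_factor(n, H)
    return(as.vector(crossprod(U, stats::rnorm(n))))
  }
  ev <- pmax(ev, 0)
  m <- 2L * n
  w <- complex(length.out = m)
  w[1L] <- sqrt(ev[1L] / m) * stats::rnorm(1L)
  w[n + 1L] <- sqrt(ev[n + 1L] / m) * stats::rnorm(1L)
  k <- seq(2L, n)
  zr <- stats::rnorm(n - 1L)
  zi <- stats::rnorm(n - 1L)
  w[k] <- sqrt(ev[k] / (2 * m)) * complex(real = zr, imaginary = zi)
  w[m + 2L - k] <- Conj(w[k])
  Re(stats::fft(w))[seq_len(n)]
}
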