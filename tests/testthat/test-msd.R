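# Nonoverlapping-lag MSD curves and power-law diffusion fits.

test_that("toy trace reproduces the hand-enumerated MSD values", {
  pos <- cbind(c(0, 1, 3, 2, 4, 5, 7, 6), 0)
  cu <- msd_curve(pos, frame_rate = 60)
  expect_equal(cu$lag_frames, c(1, 2)) # floor(8/4) lags
  expect_equal(cu$msd, c(16 / 7, 19 / 3))
  expect_equal(cu$n_pairs, c(7L, 3L))
  expect_equal(cu$lag_s, c(1, 2) / 60)
})

test_that("degenerate traces give the expected curves", {
  const <- matrix(1.5, nrow = 16, ncol = 2)
  expect_true(all(msd_curve(const, 60)$msd == 0))

  v <- 0.25 # arcmin/frame, pure persistence
  lin <- cbind(v * (0:39), 0)
  cu <- msd_curve(lin, 60)
  expect_equal(cu$msd, (v * cu$lag_frames)^2)
})

test_that("short traces are rejected", {
  expect_error(msd_curve(matrix(rnorm(14), ncol = 2), 60), "8 frames")
})

test_that("msd_curve agrees with the brute-force pair enumerator", {
  set.seed(1203)
  for (i in 1:50) {
    n <- sample(8:64, 1)
    tr <- random_trace(n)
    expect_equal(as.data.frame(msd_curve(tr)), brute_msd(tr$positions),
                 tolerance = 1e-14)
  }
})

test_that("fit_diffusion inverts an exact power law to machine precision", {
  lags <- 1:12
  for (case in list(c(D = 5, alpha = 1), c(D = 0.3, alpha = 1.6),
                    c(D = 40, alpha = 0.8))) {
    curve <- data.frame(lag_s = lags / 60,
                        msd = 4 * case["D"] * (lags / 60)^case["alpha"],
                        n_pairs = rep(10L, 12))
    fit <- fit_diffusion(curve)
    expect_equal(fit$D, unname(case["D"]), tolerance = 1e-12)
    expect_equal(fit$alpha, unname(case["alpha"]), tolerance = 1e-12)
    expect_equal(fit$fit_r2, 1)
  }
})

test_that("a constant-velocity trajectory fits alpha = 2", {
  lin <- cbind(0.5 * (0:59), -0.2 * (0:59))
  fit <- fit_diffusion(msd_curve(lin, 60))
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
})

test_that("zero-MSD lags are excluded and all-zero curves fail", {
  curve <- data.frame(lag_s = (1:4) / 60,
                      msd = c(0, 1, 2, 4), n_pairs = c(8L, 4L, 2L, 2L))
  expect_equal(fit_diffusion(curve)$n_lags, 3L)
  allzero <- data.frame(lag_s = (1:4) / 60, msd = rep(0, 4),
                        n_pairs = rep(2L, 4))
  expect_error(fit_diffusion(allzero), "fewer than 2")
})

test_that("scaling a trace by c scales MSD and D by c^2, alpha unchanged", {
  tr <- generate_drift_trace(D = 5, alpha = 1.2, n_frames = 64, seed = 5)
  for (c_ in c(0.5, 3)) {
    scaled <- eye_trace(c_ * tr$positions)
    expect_equal(msd_curve(scaled)$msd, c_^2 * msd_curve(tr)$msd)
    fa <- fit_diffusion(msd_curve(tr))
    fb <- fit_diffusion(msd_curve(scaled))
    expect_equal(fb$D, c_^2 * fa$D, tolerance = 1e-12)
    expect_equal(fb$alpha, fa$alpha, tolerance = 1e-12)
  }
})

test_that("simulated Brownian traces recover their parameters on average", {
  fits <- vapply(1:300, function(i) {
    tr <- generate_drift_trace(D = 5, alpha = 1, n_frames = 90, seed = 5000 + i)
    fit <- fit_diffusion(msd_curve(tr))
    c(fit$D, fit$alpha)
  }, numeric(2))
  expect_equal(mean(fits[2, ]), 1, tolerance = 0.05)
  expect_equal(mean(fits[1, ]), 5, tolerance = 0.10)
})

test_that("mean_speed behaves as a speed should", {
  expect_equal(mean_speed(matrix(0, 10, 2), 60), 0)
  steps1 <- cbind(0:9, 0) # 1 arcmin per frame
  expect_equal(mean_speed(steps1, 60), 60)
  tr <- random_trace(30)
  expect_equal(mean_speed(eye_trace(3 * tr$positions)), 3 * mean_speed(tr))
})

test_that("pooling one trace equals fitting it directly", {
  tr <- generate_drift_trace(D = 4, alpha = 1.1, n_frames = 45, seed = 77)
  single <- fit_diffusion(msd_curve(tr))
  pooled <- pooled_stats(list(tr))
  expect_equal(pooled$D, single$D)
  expect_equal(pooled$alpha, single$alpha)
})

test_that("pooling k copies of a trace is idempotent", {
  tr <- generate_drift_trace(D = 4, alpha = 0.9, n_frames = 45, seed = 78)
  one <- pooled_stats(list(tr))
  four <- pooled_stats(rep(list(tr), 4))
  expect_equal(four$D, one$D)
  expect_equal(four$alpha, one$alpha)
})

test_that("pooled lags are limited by the shortest trace", {
  a <- generate_drift_trace(D = 4, alpha = 1, n_frames = 90, seed = 79)
  b <- generate_drift_trace(D = 4, alpha = 1, n_frames = 48, seed = 80)
  st <- pooled_stats(list(a, b))
  expect_equal(st$n_lags, 12L) # floor(48/4)
})

test_that("pooled-MSD estimates beat per-trace averages in alpha RMSE", {
  # 60 replicate trials of 6 presentations each, both aggregation rules
  errs <- vapply(1:60, function(r) {
    trs <- lapply(1:6, function(p) {
      generate_drift_trace(D = 5, alpha = 1.2, n_frames = 45,
                           seed = 9000 + 10 * r + p)
    })
    c(pooled_stats(trs)$alpha, pooled_stats(trs, method = "per_trace")$alpha)
  }, numeric(2))
  rmse <- sqrt(rowMeans((errs - 1.2)^2))
  expect_lt(rmse[1], rmse[2])
})

test_that("pooling empty input fails loudly", {
  expect_error(pooled_stats(list()), "no valid traces")
})
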