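test_that("DQE(0) follows the gain statistics and is scale invariant", {
  expect_equal(dqe_zero(1, 1), 0.5)
  expect_equal(dqe_zero(1, 0), 1)
  expect_equal(dqe_zero(2, 4), 0.5)
  for (c_scale in c(0.5, 3, 10)) {
    expect_equal(dqe_zero(1.3 * c_scale, 0.7 * c_scale^2), dqe_zero(1.3, 0.7))
  }
  expect_error(dqe_zero(0, 1), "positive")
  expect_error(dqe_zero(1, -1), "non-negative")
})

test_that("zero-frequency noise power is (g^2 + var) * dose", {
  expect_equal(nps_zero(2.33, detector_model(1, 1)), 4.66)
  expect_equal(nps_zero(0, detector_model()), 0)
  # equals Gamma = d / DQE(0) for unit gain
  m <- detector_model(1, 1.5)
  expect_equal(nps_zero(3, m), 3 / m$dqe0)
  expect_error(nps_zero(-1, m), "non-negative")
})

test_that("NPS surface is normalised, positive, and alias-boosted at the corner", {
  flat <- detector_model(mtf_coef = numeric(0), n_aliases = 0)
  expect_true(all(unclass(evaluate_nps(16, flat)) == 1))
  m <- detector_model()
  surf <- unclass(evaluate_nps(8, m))
  expect_equal(surf[1, 1], 1)
  expect_true(all(surf > 0))
  # brute-force alias sum on the 8x8 grid: folding boosts the corner
  # (4 equidistant replicas) more than the edge midpoint (2 replicas)
  b <- function(r) exp(-r^2 / 0.35^2)
  base <- function(fx, fy) b(sqrt(fx^2 + fy^2))
  fold <- function(fx, fy) {
    s <- 0
    for (kx in -1:1) for (ky in -1:1) s <- s + b(sqrt((fx - kx)^2 + (fy - ky)^2))
    s
  }
  corner_boost <- fold(0.5, 0.5) / base(0.5, 0.5)
  edge_boost <- fold(0.5, 0) / base(0.5, 0)
  expect_gt(corner_boost, edge_boost)
  # the evaluated surface shows the same ordering of boosts
  g <- icemotion:::freq_grid(8)
  b_only <- icemotion:::radial_transfer(g$r, m$mtf_coef)
  boost <- unclass(evaluate_nps(8, m)) / (b_only / b_only[1, 1])
  i_corner <- which(abs(g$fx - 0.5) < 1e-9 & abs(g$fy - 0.5) < 1e-9)
  i_edge <- which(abs(g$fx - 0.5) < 1e-9 & abs(g$fy) < 1e-9)
  expect_gt(boost[i_corner], boost[i_edge])
})

test_that("simulated response preserves the mean and the noise-power plateau", {
  d <- 2.33
  out <- simulate_response(matrix(d, 256, 256), detector_model(), seed = 11)
  se_mean <- sqrt(2 * d) / 256 # var per pixel = d/DQE = 2d
  expect_lt(abs(mean(out) - d), 3 * se_mean)
  # whitened spectrum flat at d/DQE(0) = 4.66
  w <- noise_whiten(power_spectrum(out), evaluate_nps(256, detector_model()))
  bs <- background_stats(w)
  expect_lt(abs(bs$gamma - 4.66) / 4.66, 0.05)
  # determinism under a fixed seed
  out2 <- simulate_response(matrix(d, 64, 64), detector_model(), seed = 42)
  out3 <- simulate_response(matrix(d, 64, 64), detector_model(), seed = 42)
  expect_identical(out2, out3)
  expect_error(simulate_response(matrix(-1, 4, 4)), "non-negative")
})

test_that("whitening with the generating model flattens both dose settings", {
  # 8 frames of 128^2: the purely statistical per-bin scatter of the radial
  # profile is ~4% RMS, so systematic whitening error would push past 8%
  for (d in c(0.85, 2.33)) {
    cfg <- sim_config(n_pixels = 128, n_frames = 8, dose_per_frame = d,
                      seed = 300 + round(100 * d))
    mov <- noise_movie(cfg)
    w <- lapply(mov$frames,
                function(f) noise_whiten(power_spectrum(f), fx_nps_128()))
    bs <- background_stats(w)
    expect_lt(abs(bs$gamma - d / 0.5) / (d / 0.5), 0.05)
    rc <- radial_average(block_sum_nwps(mov, 1, fx_nps_128()))
    good <- rc$count >= 100
    wt <- rc$count[good]
    flat_dev <- sqrt(sum(wt * (rc$value[good] / (8 * bs$gamma) - 1)^2) / sum(wt))
    expect_lt(flat_dev, 0.08)
  }
})

test_that("NPS model fit recovers the generating transfer and flags contamination", {
  mov <- fx_noise_movie()
  mean_spec <- power_spectrum(mov$frames[[1]])
  acc <- Reduce(`+`, lapply(mov$frames, function(f) power_spectrum(f)$values))
  mean_spec$values <- acc / length(mov$frames)
  fit <- fit_nps_model(mean_spec, n_aliases = 1, n_basis = 3)
  expect_true(fit$converged)
  expect_false(fit$contaminated)
  # recovered B(r) within 3% RMS of the generating curve over [0, Nyquist]
  r <- seq(0, 0.5, length.out = 51)
  b_true <- icemotion:::radial_transfer(r, detector_model()$mtf_coef)
  b_fit <- icemotion:::radial_transfer(r, fit$model$mtf_coef)
  expect_lt(sqrt(mean((b_fit - b_true)^2)), 0.03)
  # whitening held-out noise frames with the fit is flat to a few percent
  # beyond the ~4% statistical scatter of an 8-frame radial profile
  held <- noise_movie(sim_config(n_pixels = 128, n_frames = 8, seed = 505))
  w <- block_sum_nwps(held, 1, evaluate_nps(128, fit$model))
  rc <- radial_average(w)
  good <- rc$count >= 100
  wt <- rc$count[good]
  mu <- sum(wt * rc$value[good]) / sum(wt)
  expect_lt(sqrt(sum(wt * (rc$value[good] / mu - 1)^2) / sum(wt)), 0.08)
  # strong Thon-ring input is flagged
  ice <- fx_ice_movie()
  acc2 <- Reduce(`+`, lapply(ice$frames, function(f) power_spectrum(f)$values))
  spec2 <- power_spectrum(ice$frames[[1]])
  spec2$values <- acc2 / length(ice$frames)
  expect_warning(fit_nps_model(spec2), "specimen")
})
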