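test_that("ice generation is reproducible with short-range order at the set spacing", {
  cfg <- sim_config(n_pixels = 128, n_frames = 1, seed = 7)
  ice <- make_ice(cfg)
  expect_gt(nrow(ice$positions), 1000)
  expect_true(all(ice$positions[, 3] >= 0 & ice$positions[, 3] <= 1250))
  set.seed(99)
  peak <- pair_correlation_peak(ice$positions)
  expect_lt(abs(peak - 3.7) / 3.7, 0.1)
  # determinism and emptiness
  ice2 <- make_ice(cfg)
  expect_identical(ice$positions, ice2$positions)
  empty <- make_ice(sim_config(n_pixels = 32, n_frames = 1, density = 0))
  expect_equal(nrow(empty$positions), 0)
  expect_error(make_ice(sim_config(n_pixels = 32, n_frames = 1,
                                   density = 0.05, spacing = 3.7)),
               "infeasible")
})

test_that("rendered frames show rings at the configured CTF zeros", {
  cfg <- sim_config(n_pixels = 128, n_frames = 1, thickness = NULL, seed = 2)
  ice <- make_ice(cfg)
  fr <- render_frame(ice, cfg)
  expect_true(all(fr >= 0))
  # no scatterers -> uniform exposure
  none <- make_ice(sim_config(n_pixels = 32, n_frames = 1, density = 0))
  expect_equal(render_frame(none, sim_config(n_pixels = 32, n_frames = 1)),
               matrix(2.33, 32, 32))
  rc <- radial_average(power_spectrum(fr - mean(fr), 1.04))
  lam <- electron_wavelength(300)
  zeros <- sqrt((1:5) / (lam * 7070))
  zeros <- zeros[zeros < 0.9 * max(rc$u)]
  for (k in seq_along(zeros)) {
    iz <- which.min(abs(rc$u - zeros[k]))
    lobe_lo <- if (k == 1) 3 else which.min(abs(rc$u - zeros[k - 1]))
    lobe <- max(rc$value[lobe_lo:iz])
    dip <- min(rc$value[max(1, iz - 2):min(nrow(rc), iz + 2)])
    expect_lt(dip, 0.5 * lobe)
  }
  # doubling the contrast quadruples the structure power (at a contrast
  # low enough that the non-negativity clamp stays inactive)
  cfg1 <- cfg; cfg1$contrast <- 0.2
  cfg2 <- cfg; cfg2$contrast <- 0.4
  fr1 <- render_frame(ice, cfg1)
  fr2 <- render_frame(ice, cfg2)
  expect_gt(min(fr1), 0)
  p1 <- sum(power_spectrum(fr1 - mean(fr1))$values)
  p2 <- sum(power_spectrum(fr2 - mean(fr2))$values)
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
})

test_that("simulators conserve the expected counts and are seed-reproducible", {
  cfg <- sim_config(n_pixels = 64, n_frames = 3, seed = 12)
  for (gen in list(simulate_movie_spectral, simulate_movie_particle,
                   noise_movie)) {
    mov <- gen(cfg)
    tot <- vapply(mov$frames, sum, numeric(1))
    se <- sqrt(2 * 2.33 * 64^2) # var per pixel d/DQE
    expect_true(all(abs(tot - 2.33 * 64^2) < 4 * se))
    mov2 <- gen(cfg)
    expect_identical(mov$frames, mov2$frames)
  }
})

test_that("spectral simulator realizes the configured inter-frame correlation", {
  # substeps = 1: plain AR(1) whose lag-k structure covariance is
  # proportional to exp(-alpha_u d k); measured via the mean cross products
  # of the Fourier coefficients in the ring band.  A high dose with a
  # noiseless-gain, flat-MTF detector keeps the shot-noise floor small.
  det <- detector_model(gain_var = 0, mtf_coef = numeric(0))
  s2 <- 0.015
  d <- 50
  lag_covs <- function(seed, s2) {
    cfg <- sim_config(n_pixels = 128, n_frames = 30, dose_per_frame = d,
                      sigma0_sq = s2, substeps = 1, detector = det,
                      seed = seed)
    mov <- simulate_movie_spectral(cfg)
    u <- icemotion:::freq_grid(128)$r / 1.04
    band <- which(abs(u - 1 / 3.7) < 0.015 & icemotion:::halfplane_mask(128))
    ff <- sapply(mov$frames, function(f) stats::fft(f)[band])
    vapply(1:3, function(k) {
      i <- seq_len(ncol(ff) - k)
      mean(Re(Conj(ff[, i, drop = FALSE]) * ff[, i + k, drop = FALSE]))
    }, numeric(1)) # shot noise drops out for k >= 1
  }
  covs <- rowMeans(sapply(1:3, lag_covs, s2 = s2))
  beta <- alpha_u(s2, 1 / 3.7) * dose_to_fluence(d, 1.04)
  slope <- stats::coef(stats::lm(log(covs) ~ seq_along(covs)))[2]
  expect_equal(unname(slope), -beta, tolerance = 0.15)
  # sigma0_sq = 0: structure identical in every frame (correlation stays put)
  covs0 <- rowMeans(sapply(4:5, lag_covs, s2 = 0))
  expect_equal(covs0[3] / covs0[1], 1, tolerance = 0.1)
})

test_that("particle and spectral simulators agree with the discrete covariance model", {
  # frozen-frame regime for both (substeps = 1), 128^2, M = 16, >= 10 seeds
  d_fl <- dose_to_fluence(2.33, 1.04)
  m_vals <- c(1, 2, 4, 8, 16)
  t_disc <- vapply(m_vals, function(m)
    spectrum_discrete(1 / 3.7, m, d_fl, 0.38) / d_fl^2, numeric(1))
  pred <- (16 / m_vals) * t_disc
  run_one <- function(gen, seed, substeps) {
    cfg <- sim_config(n_pixels = 128, n_frames = 16, sigma0_sq = 0.38,
                      substeps = substeps, seed = seed)
    block_series(gen(cfg), fx_nps_128(), 1 / 3.7, 0.5)$value
  }
  res_p <- sapply(1:10, function(s) run_one(simulate_movie_particle, 600 + s, 1))
  res_s <- sapply(1:10, function(s) run_one(simulate_movie_spectral, 700 + s, 1))
  for (res in list(res_p, res_s)) {
    mn <- rowMeans(res)
    se <- apply(res, 1, sd) / sqrt(ncol(res))
    sc <- sum(mn * pred / se^2) / sum(pred^2 / se^2)
    expect_true(all(abs(mn - sc * pred) < 5 * se))
  }
  # and the two simulators agree with each other on the normalized curve
  mp <- rowMeans(res_p) / mean(rowMeans(res_p))
  ms <- rowMeans(res_s) / mean(rowMeans(res_s))
  se_pair <- sqrt(apply(res_p, 1, var) / 10) / mean(rowMeans(res_p)) +
    sqrt(apply(res_s, 1, var) / 10) / mean(rowMeans(res_s))
  expect_true(all(abs(mp - ms) < 5 * se_pair))
})

test_that("motion regimes reorder ring visibility between sum-spectrum and spectrum-sum", {
  snr_both <- function(s2, seed) {
    cfg <- sim_config(n_pixels = 128, n_frames = 16, sigma0_sq = s2,
                      seed = seed)
    ser <- block_series(simulate_movie_spectral(cfg), fx_nps_128(),
                        1 / 3.7, 0.5, m_values = c(1, 16))
    ser$value / ser$error
  }
  rigid <- snr_both(0, 451)      # solid-like: spectrum of the sum wins
  expect_gt(rigid[2], rigid[1])
  fluid <- snr_both(0.38, 452)   # ice-like: sum of spectra wins
  expect_gt(fluid[1], fluid[2])
  uncorr <- snr_both(20, 453)    # uncorrelated frames: sum of spectra wins
  expect_gt(uncorr[1], uncorr[2])
})
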