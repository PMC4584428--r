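test_that("power spectrum follows the |DFT|^2 / N_tot convention", {
  n <- 32
  # constant image: all power at DC, S(0) = N_tot c^2
  s <- power_spectrum(matrix(3, n, n))
  expect_equal(s$values[1, 1], n^2 * 9)
  expect_equal(max(abs(s$values[-1])), 0, tolerance = 1e-16)
  # cosine at a grid frequency: two symmetric peaks of N_tot a^2 / 4
  a <- 2; k <- 5
  img <- matrix(a * cos(2 * pi * k * (0:(n - 1)) / n), n, n)
  s2 <- power_spectrum(img)
  expect_equal(s2$values[k + 1, 1], n^2 * a^2 / 4, tolerance = 1e-8)
  expect_equal(s2$values[n - k + 1, 1], n^2 * a^2 / 4, tolerance = 1e-8)
  expect_equal(sum(s2$values) - s2$values[k + 1, 1] - s2$values[n - k + 1, 1],
               0, tolerance = 1e-6)
  # Parseval
  set.seed(1)
  img3 <- matrix(rnorm(n * n), n, n)
  expect_equal(sum(power_spectrum(img3)$values), sum(img3^2), tolerance = 1e-10)
  expect_error(power_spectrum(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("power spectrum is invariant to cyclic translation", {
  set.seed(7)
  n <- 64
  img <- matrix(rnorm(n * n), n, n)
  s0 <- power_spectrum(img)$values
  sh <- img[c(11:n, 1:10), c(40:n, 1:39)]
  s1 <- power_spectrum(sh)$values
  expect_lt(max(abs(s1 - s0)) / max(s0), 1e-9)
})

test_that("noise whitening divides pointwise and validates the grid", {
  set.seed(2)
  img <- matrix(rnorm(16 * 16), 16, 16)
  s <- power_spectrum(img)
  expect_equal(noise_whiten(s, matrix(1, 16, 16))$values, s$values)
  expect_error(noise_whiten(s, matrix(1, 8, 8)), "grid")
  expect_error(noise_whiten(s, matrix(0, 16, 16)), "positive")
})

test_that("block-summed whitened spectra have the predicted m-independent mean", {
  mov <- fx_noise_movie() # M = 8, d = 2.33
  nps <- fx_nps_128()
  gamma_M <- predicted_background(8, 2.33, 0.5)
  mask <- icemotion:::halfplane_mask(128)
  for (m in c(1, 2, 8)) {
    w <- block_sum_nwps(mov, m, nps)
    expect_identical(unname(w$frames_summed), c(8, m))
    expect_lt(abs(mean(w$values[mask]) - gamma_M) / gamma_M, 0.03)
  }
  # m = M is exactly the whitened spectrum of the full frame sum
  full <- Reduce(`+`, mov$frames)
  w_direct <- noise_whiten(power_spectrum(full, mov$pixel_size), nps)
  expect_equal(block_sum_nwps(mov, 8, nps)$values, w_direct$values)
  # m = 1 is exactly the sum of per-frame whitened spectra
  acc <- Reduce(`+`, lapply(mov$frames, function(f) {
    noise_whiten(power_spectrum(f, mov$pixel_size), nps)$values
  }))
  expect_equal(block_sum_nwps(mov, 1, nps)$values, acc)
  expect_error(block_sum_nwps(mov, 3, nps), "divide")
})

test_that("background and noise predictions reproduce the printed levels", {
  expect_equal(predicted_background(120, 2.33, 0.5), 559.2)
  expect_equal(round(predicted_background(120, 2.33, 0.5), -1), 560)
  expect_equal(predicted_noise(120, 2.33, 0.5, 1), 51.05, tolerance = 1e-3)
  expect_equal(predicted_background(1, 2.33, 0.5), 4.66)
  expect_equal(predicted_background(240, 2.33, 0.5),
               2 * predicted_background(120, 2.33, 0.5))
  expect_equal(predicted_noise(120, 2.33, 0.5, 120),
               predicted_background(120, 2.33, 0.5))
  expect_equal(predicted_noise(120, 2.33, 0.5, 4) /
                 predicted_noise(120, 2.33, 0.5, 1), 2)
  expect_error(predicted_noise(120, 2.33, 0.5, 7), "divide")
})

test_that("radial averaging bins correctly and tracks the noise model", {
  s <- power_spectrum(matrix(0, 64, 64))
  s$values[] <- 5
  rc <- radial_average(s, noise_level = 10)
  expect_true(all(abs(rc$value - 5) < 1e-12))
  expect_true(all(diff(rc$u) > 0))
  # bin centres stay within half a bin of Nyquist (cycles/pixel at size 1)
  expect_true(all(rc$u <= 0.5 + 0.5 / 64 + 1e-9))
  # per-bin noise falls with radius as counts grow
  expect_lt(rc$noise[nrow(rc) - 2], rc$noise[1])
  expect_equal(rc$noise, 10 / sqrt(rc$count / 2))
  # a radially symmetric ring peaks in the right bin
  g <- icemotion:::freq_grid(64)
  s$values <- exp(-((g$r - 0.3) * 64)^2)
  rc2 <- radial_average(s)
  expect_equal(rc2$u[which.max(rc2$value)], 0.3, tolerance = 0.02)
})

test_that("whitened background values behave as an exponential distribution", {
  cfg <- sim_config(n_pixels = 256, n_frames = 4, seed = 77)
  mov <- noise_movie(cfg)
  nps <- fx_nps_256()
  specs <- lapply(mov$frames, function(f) noise_whiten(power_spectrum(f), nps))
  bs <- background_stats(specs) # > 1e5 pooled independent values
  expect_gt(bs$n, 1e5)
  expect_lt(abs(bs$gamma - 4.66) / 4.66, 0.05)
  expect_gt(bs$sd_over_mean, 0.97)
  expect_lt(bs$sd_over_mean, 1.03)
  expect_true(bs$exponential_ok)
  # a constant surface has SD 0 and fails the distribution check
  flat <- specs[[1]]
  flat$values[] <- 3
  bsf <- background_stats(flat)
  expect_equal(bsf$sd, 0)
  expect_false(bsf$exponential_ok)
  expect_error(background_stats(flat, exclude_u = c(0, 10)), "no frequencies")
})

test_that("anchor shift aligns curves at high frequency and flags large shifts", {
  mov <- fx_noise_movie()
  nps <- fx_nps_128()
  gamma_M <- predicted_background(8, 2.33, 0.5)
  curves <- lapply(c(1, 2, 8), function(m) {
    radial_average(block_sum_nwps(mov, m, nps),
                   noise_level = predicted_noise(8, 2.33, 0.5, m))
  })
  names(curves) <- c("1", "2", "8")
  # identical curves need zero shift
  same <- list(`1` = curves[["1"]], `2` = curves[["1"]])
  res0 <- anchor_shift(same, background = gamma_M)
  expect_equal(unname(res0$shifts), c(0, 0))
  # a constructed +5% offset on one curve is recovered as a -5% shift
  off <- curves[["8"]]
  off$value <- curves[["1"]]$value + 0.05 * gamma_M
  res <- anchor_shift(list(`1` = curves[["1"]], `8` = off),
                      background = gamma_M)
  expect_equal(unname(res$shifts[["8"]]), -0.05 * gamma_M, tolerance = 1e-6)
  expect_true(res$max_shift_frac <= 0.0501)
  # > 5% of background triggers the warning
  off$value <- curves[["1"]]$value + 0.12 * gamma_M
  expect_warning(anchor_shift(list(`1` = curves[["1"]], `8` = off),
                              background = gamma_M), "5%")
  expect_error(anchor_shift(list(`2` = curves[["2"]])), "m = 1")
})

test_that("ring signal extraction subtracts background with propagated error", {
  mov <- fx_noise_movie()
  rc <- radial_average(block_sum_nwps(mov, 1, fx_nps_128()),
                       noise_level = predicted_noise(8, 2.33, 0.5, 1))
  gamma_M <- predicted_background(8, 2.33, 0.5)
  # flat noise-only curve: zero within error
  sig <- ring_signal_at(rc, 1 / (3.7 * 1.04), gamma_M)
  expect_lt(abs(sig$value), 4 * sig$error)
  # constructed bump of height h on a known background
  rc2 <- rc
  i <- which.min(abs(rc2$u - 0.25))
  rc2$value[] <- gamma_M
  rc2$value[i] <- gamma_M + 7
  sig2 <- ring_signal_at(rc2, rc2$u[i], gamma_M)
  expect_equal(sig2$value, 7)
  # annulus background estimate
  sig3 <- ring_signal_at(rc2, rc2$u[i], background = c(0.3, 0.4))
  expect_equal(sig3$value, 7, tolerance = 1e-6)
  expect_gt(sig3$error, sig2$error) # band uncertainty propagated
  expect_error(ring_signal_at(rc2, rc2$u[i], background = c(0.2, 0.3)),
               "overlaps")
  expect_error(ring_signal_at(rc2, 10, gamma_M), "range")
})

test_that("modulation measure is half peak-to-peak over the mean excess", {
  mov <- fx_noise_movie()
  rc <- radial_average(block_sum_nwps(mov, 1, fx_nps_128()))
  rc$value <- rep(100, nrow(rc)) # pure background
  expect_equal(measure_modulation(rc, c(0.1, 0.3), background = 100), 0)
  # background + signal c + oscillation amplitude a -> a / c
  sel <- rc$u >= 0.1 & rc$u <= 0.3
  rc$value[sel] <- 100 + 20 + 5 * sin(seq(0, 6 * pi, length.out = sum(sel)))
  expect_equal(measure_modulation(rc, c(0.1, 0.3), background = 100),
               5 / 20, tolerance = 0.05)
  expect_error(measure_modulation(rc, c(0.1, 0.101)), "few bins")
})

test_that("simulated ice shows ring modulation of the same order as the sinc damping", {
  mov <- fx_ice_movie()
  w <- block_sum_nwps(mov, mov$n_frames, fx_nps_128())
  rc <- radial_average(w)
  gamma_M <- predicted_background(mov$n_frames, 2.33, 0.5)
  # measured over about one ring oscillation at the band centre, where the
  # band envelope is nearly flat; |sin(xi)/xi| at 1250 A is ~0.105, the
  # same order as the observed single-digit-percent ring modulation
  modu <- measure_modulation(rc, c(0.255, 0.285), background = gamma_M)
  expect_gt(modu, 0.02)
  expect_lt(modu, 0.35)
})

test_that("block series carries doses, errors and metadata for the fit", {
  ser <- fx_ice_series()
  expect_s3_class(ser, "block_series")
  expect_equal(ser$m, c(1, 2, 4, 8, 16))
  expect_equal(ser$dose, ser$m * dose_to_fluence(2.33, 1.04))
  expect_true(all(ser$error > 0))
  expect_equal(attr(ser, "u_target"), 1 / 3.7)
  expect_equal(attr(ser, "M"), 16)
  # signal grows with m (saturating)
  expect_gt(ser$value[5], ser$value[1])
})
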