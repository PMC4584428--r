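# Estimation of the per-electron mean-squared displacement from block-sum
# curves, the optimal exposure per image, and Brownian-blur extrapolation to
# embedded particles.

#' Fit the motion parameter to a block series
#'
#' Weighted nonlinear least squares of
#' `scale * g(2 pi^2 sigma0_sq u^2 * m * d)` against the measured
#' background-subtracted ring signal as a function of the block size m, with
#' weights 1/error^2.  sigma0_sq is parameterised in log space (positivity);
#' the optimiser is Levenberg-Marquardt seeded from a coarse log-grid scan,
#' so the result is deterministic given the inputs.
#'
#' @param series A [block_series()] (>= 3 block sizes with errors), or any
#'   data frame with columns `m`, `value`, `error` plus attributes
#'   `fluence_per_frame` and `u_target` (or supply `d` and `u_target`).
#' @param u_target Ring frequency, 1/Angstrom; default from the series.
#' @param d Fluence per frame, e-/A^2; default from the series.
#' @return An object of class `motion_fit` with elements `sigma0_sq`,
#'   `scale`, `covariance` (2x2, on (sigma0_sq, scale)), `residual_norm`
#'   (weighted RSS), `n_points`, `fitted`, `identifiable`, `converged`.
#' @export
fit_sigma0 <- function(series, u_target = attr(series, "u_target"),
                       d = attr(series, "fluence_per_frame")) {
  stopifnot(all(c("m", "value", "error") %in% names(series)))
  if (is.null(u_target) || is.null(d)) {
    stop("`u_target` and `d` are required (not found on the series)",
         call. = FALSE)
  }
  m <- series$m
  y <- series$value
  err <- series$error
  if (length(m) < 3) stop("need at least 3 block sizes", call. = FALSE)
  if (any(err <= 0)) stop("errors must be positive", call. = FALSE)
  w <- 1 / err^2

  if (max(abs(y) / err) < 3) {
    warning("no significant ring signal: sigma0_sq is unidentifiable",
            call. = FALSE)
    return(structure(list(sigma0_sq = NA_real_, scale = NA_real_,
                          covariance = matrix(NA_real_, 2, 2),
                          residual_norm = NA_real_, n_points = length(m),
                          fitted = rep(NA_real_, length(m)),
                          identifiable = FALSE, converged = FALSE),
                     class = "motion_fit"))
  }

  # profile out the linear scale on a log grid over sigma0_sq
  grid <- 10^seq(-3, 1, length.out = 60)
  ssr_of <- function(s2) {
    gv <- g_of_z(alpha_u(s2, u_target) * m * d)
    sc <- sum(w * y * gv) / sum(w * gv^2)
    sum(w * (y - sc * gv)^2)
  }
  ssr <- vapply(grid, ssr_of, numeric(1))
  s2_0 <- grid[which.min(ssr)]
  gv0 <- g_of_z(alpha_u(s2_0, u_target) * m * d)
  sc_0 <- sum(w * y * gv0) / sum(w * gv0^2)

  resid_fn <- function(p) {
    s2 <- exp(p[1]); sc <- exp(p[2])
    (y - sc * g_of_z(alpha_u(s2, u_target) * m * d)) / err
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(s2_0), log(max(sc_0, 1e-12))), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  s2_hat <- exp(fit$par[1])
  sc_hat <- exp(fit$par[2])
  z <- alpha_u(s2_hat, u_target) * m * d
  fitted <- sc_hat * g_of_z(z)

  # identifiability: the curve must actually bend over the measured m range
  identifiable <- (max(g_of_z(z)) - min(g_of_z(z))) / max(g_of_z(z)) > 1e-3 &&
    s2_hat > 1.5 * min(grid) && s2_hat < max(grid) / 1.5
  if (!identifiable) {
    warning("block curve is nearly flat over the m range: sigma0_sq poorly identified",
            call. = FALSE)
  }

  # covariance: (J' J)^-1 on log parameters, delta method back to natural
  jac <- fit$hessian # nls.lm returns J'J approximation in $hessian
  cov_log <- tryCatch(solve(jac), error = function(e) matrix(NA_real_, 2, 2))
  scale_vec <- c(s2_hat, sc_hat)
  cov_nat <- cov_log * outer(scale_vec, scale_vec)
  dimnames(cov_nat) <- list(c("sigma0_sq", "scale"), c("sigma0_sq", "scale"))

  structure(list(sigma0_sq = s2_hat, scale = sc_hat, covariance = cov_nat,
                 residual_norm = sum(fit$fvec^2), n_points = length(m),
                 fitted = fitted, identifiable = identifiable,
                 converged = fit$info %in% 1:4),
            class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  cat(sprintf(
    "<motion_fit> sigma0_sq = %.4g A^2/(e-/A^2) (SE %.2g), scale = %.4g, wRSS = %.3g over %d points%s\n",
    x$sigma0_sq, sqrt(x$covariance[1, 1]), x$scale, x$residual_norm,
    x$n_points, if (x$identifiable) "" else " [UNIDENTIFIABLE]"))
  invisible(x)
}

#' Parameter-recovery experiment on synthetic movies
#'
#' Generates `n_seeds` independent spectral-model movies with a known
#' motion parameter, runs the full noise-whitened block-sum pipeline and the
#' saturation-curve fit on each, and collects the recovered values together
#' with the block fluence at which the measured ring signal-to-noise peaks.
#'
#' @param n_seeds Number of independent movies.
#' @param sigma0_sq Generative per-axis MSD per unit fluence.
#' @param n_pixels,n_frames,dose_per_frame Movie geometry (defaults: the
#'   package's study conditions, 256^2 pixels, 120 frames, 2.33 e-/pixel).
#' @param u_target Ring frequency for the block series, 1/Angstrom.
#' @param seed Base seed; movie i uses `seed * 1000 + i`.
#' @param m_values Block sizes (default all divisors of `n_frames`).
#' @return A data frame with one row per seed: `seed`, `sigma0_sq_hat`,
#'   `peak_dose` (e-/A^2 of the SNR-maximising block size).
#' @export
recover_sigma0_experiment <- function(n_seeds = 10, sigma0_sq = 0.38,
                                      n_pixels = 256, n_frames = 120,
                                      dose_per_frame = 2.33,
                                      u_target = 1 / 3.7, seed = 1,
                                      m_values = NULL) {
  det <- detector_model()
  nps <- evaluate_nps(n_pixels, det)
  out <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(n_pixels = n_pixels, n_frames = n_frames,
                      dose_per_frame = dose_per_frame,
                      sigma0_sq = sigma0_sq, detector = det,
                      seed = seed * 1000 + i)
    movie <- simulate_movie_spectral(cfg)
    ser <- block_series(movie, nps, u_target, det$dqe0, m_values = m_values)
    fit <- fit_sigma0(ser)
    snr <- ser$value / ser$error
    data.frame(seed = cfg$seed, sigma0_sq_hat = fit$sigma0_sq,
               peak_dose = ser$dose[which.max(snr)])
  })
  do.call(rbind, out)
}

#' Optimal dimensionless block fluence for ring visibility
#'
#' The ring signal grows as g(z) while the noise of the block-summed spectrum
#' grows as \eqn{\sqrt z}, so the signal-to-noise ratio is proportional to
#' \eqn{g(z)/\sqrt z}.  Its stationary point solves the transcendental
#' equation \eqn{1.5 - 0.5 z = e^{-z}(z + 1.5)}, located by bracketing
#' bisection to 1e-10.
#'
#' @return The optimum z*, about 2.149.
#' @export
snr_optimum_z <- function() {
  f <- function(z) 1.5 - 0.5 * z - exp(-z) * (z + 1.5)
  lo <- 0.1; hi <- 10
  stopifnot(f(lo) * f(hi) < 0)
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Optimal fluence per image for observing Thon rings
#'
#' \eqn{d_{opt} = z^* / (2\pi^2\sigma_0^2 u^2)} with z* from
#' [snr_optimum_z()]: the block fluence at which the ring signal-to-noise at
#' frequency `u` is maximal.
#'
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence (> 0).
#' @param u Spatial frequency, 1/Angstrom (> 0).
#' @return Optimal fluence per image, e-/A^2.
#' @examples
#' optimal_dose(0.37, 1 / 3.7) # about 4.0 e-/A^2
#' @export
optimal_dose <- function(sigma0_sq, u) {
  if (any(sigma0_sq <= 0) || any(u <= 0)) {
    stop("`sigma0_sq` and `u` must be positive", call. = FALSE)
  }
  snr_optimum_z() / (2 * pi^2 * sigma0_sq * u^2)
}

#' Total (3D) mean-squared displacement rate
#'
#' The motion model is isotropic with per-axis rate sigma0_sq, so the total
#' mean squared displacement per unit fluence is 3 sigma0_sq.
#'
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence (>= 0).
#' @return MSD rate in A^2 per e-/A^2.
#' @export
msd_3d_rate <- function(sigma0_sq) {
  if (any(sigma0_sq < 0)) stop("`sigma0_sq` must be non-negative", call. = FALSE)
  3 * sigma0_sq
}

#' RMS displacement after a given fluence
#'
#' @param fluence Total fluence, e-/A^2 (>= 0).
#' @param msd_rate Total MSD per unit fluence (from [msd_3d_rate()]).
#' @return RMS displacement in Angstrom, \eqn{\sqrt{fluence \times rate}}.
#' @export
rms_displacement <- function(fluence, msd_rate) {
  if (any(fluence < 0) || any(msd_rate < 0)) {
    stop("arguments must be non-negative", call. = FALSE)
  }
  sqrt(fluence * msd_rate)
}

#' Pseudo-Brownian RMS displacement of an embedded particle
#'
#' A macromolecule embedded in the moving water diffuses with a smaller
#' diffusion coefficient; by the Stokes-Einstein scaling the coefficient
#' varies as \eqn{MW^{-1/3}}, so the particle RMS displacement is the water
#' RMS divided by \eqn{\sqrt{D_{water}/D_{particle}}}.  Supply
#' `diffusion_ratio` directly to override the molecular-weight rule (hydration
#' and shape make the true ratio larger than the bare \eqn{(MW/18)^{1/3}}).
#'
#' @param water_rms RMS displacement of water molecules, Angstrom (>= 0).
#' @param molecular_weight Particle mass in Dalton (> 0).
#' @param diffusion_ratio Optional \eqn{D_{water}/D_{particle}} override.
#' @return Particle RMS displacement in Angstrom.
#' @examples
#' particle_rms(5.2, 100e3, diffusion_ratio = 30) # about 1 A
#' @export
particle_rms <- function(water_rms, molecular_weight = NULL,
                         diffusion_ratio = NULL) {
  if (any(water_rms < 0)) stop("`water_rms` must be non-negative", call. = FALSE)
  if (is.null(diffusion_ratio)) {
    if (is.null(molecular_weight) || any(molecular_weight <= 0)) {
      stop("supply `molecular_weight` (> 0) or `diffusion_ratio`", call. = FALSE)
    }
    diffusion_ratio <- (molecular_weight / 18)^(1 / 3)
  }
  water_rms / sqrt(diffusion_ratio)
}

#' B-factor equivalent of random particle blurring
#'
#' Gaussian blurring by an isotropic RMS displacement is expressed in the
#' Debye-Waller convention \eqn{B = 8\pi^2\langle u_x^2\rangle} with the
#' per-axis positional variance \eqn{\langle u_x^2\rangle = rms^2/3}.
#' Conventions for B differ by a factor of 3 depending on whether the total
#' or per-axis variance is used; this package always uses the per-axis form.
#'
#' @param rms Total (3D) RMS displacement of the particle, Angstrom (>= 0).
#' @return B-factor in A^2.
#' @export
blur_bfactor <- function(rms) {
  if (any(rms < 0)) stop("`rms` must be non-negative", call. = FALSE)
  8 * pi^2 * rms^2 / 3
}
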