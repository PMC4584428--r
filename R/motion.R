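# Gaussian-Markov model of beam-induced molecular motion: transition density,
# inter-frame spectral correlation, and closed-form power-spectrum
# predictions for dose-fractionated exposures.
#
# The single physical parameter is sigma0_sq, the mean squared displacement
# of a molecule along one axis caused by one incident electron per unit area
# (A^2 per e-/A^2).  At spatial frequency u the Fourier components of the
# specimen decorrelate at rate alpha_u = 2 pi^2 sigma0_sq u^2 per unit
# fluence.

#' Spectral decorrelation rate
#'
#' \eqn{\alpha_u = 2\pi^2\sigma_0^2 u^2}, the rate (per unit fluence,
#' e-/A^2) at which the specimen's Fourier component at frequency `u` loses
#' correlation under Gaussian random displacements of its molecules.
#'
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence,
#'   A^2/(e-/A^2) (>= 0).
#' @param u Spatial frequency, 1/Angstrom.
#' @return Decorrelation rate in (e-/A^2)^-1.
#' @export
alpha_u <- function(sigma0_sq, u) {
  stopifnot(sigma0_sq >= 0)
  2 * pi^2 * sigma0_sq * u^2
}

#' Random molecular displacement under irradiation
#'
#' Adds independent Gaussian increments with per-axis variance
#' `fluence * sigma0_sq` to a set of 3D positions.  Successive calls give
#' independent increments (the Markov property), so two steps of fluence D/2
#' compose to one step of fluence D in distribution.
#'
#' @param positions Numeric matrix with 3 columns (x, y, z in Angstrom).
#' @param fluence Incident electrons per unit area, e-/A^2 (>= 0).
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence.
#' @return Displaced positions, same shape.
#' @export
displace <- function(positions, fluence, sigma0_sq) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (fluence < 0) stop("`fluence` must be non-negative", call. = FALSE)
  if (fluence == 0 || sigma0_sq == 0) return(positions)
  positions + matrix(stats::rnorm(length(positions),
                                  sd = sqrt(fluence * sigma0_sq)),
                     nrow(positions), 3)
}

#' Correlation between the Fourier components of two frames
#'
#' \eqn{\exp(-\alpha_u |i-j| d)}: the |i-j|d electrons per unit area incident
#' between frames i and j randomly displace the molecules and decorrelate the
#' structure.
#'
#' @param u Spatial frequency, 1/Angstrom.
#' @param i,j Frame indices (>= 1).
#' @param d Fluence per frame, e-/A^2 (> 0).
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence.
#' @return Correlation in (0, 1].
#' @export
frame_correlation <- function(u, i, j, d, sigma0_sq) {
  stopifnot(all(i >= 1), all(j >= 1), d > 0)
  exp(-alpha_u(sigma0_sq, u) * abs(i - j) * d)
}

# sum_{i,j=1..M} exp(-a |i-j|) evaluated stably.
# Closed form: 2 r/(1-r)^2 * ((1-r) M + e^{-aM} - 1) + M with r = e^{-a};
# for small a*M the inner difference suffers cancellation and is replaced by
# its exact power series sum_{n>=2} (-a)^n (M^n - M)/n!.
double_sum_exp <- function(a, M) {
  if (a == 0) return(M^2)
  r <- exp(-a)
  one <- -expm1(-a) # 1 - r without cancellation
  if (a * M < 0.5) {
    term <- 1
    acc <- 0
    for (n in 2:60) {
      term_n <- (-a)^n * (M^n - M) / factorial(n)
      acc <- acc + term_n
      if (abs(term_n) < abs(acc) * 1e-17 + 1e-300) break
    }
    inner <- acc
  } else {
    inner <- one * M + expm1(-a * M)
  }
  2 * r / one^2 * inner + M
}

#' Expected power spectrum of a dose-fractionated sum (discrete frames)
#'
#' Closed form for the expected power spectrum of the sum of M frames whose
#' Fourier components decorrelate by \eqn{\exp(-\alpha_u d)} between
#' consecutive frames (molecules frozen within a frame):
#' \deqn{S(u) = d^2 F_0^2 \left[\frac{2e^{-\alpha_u d}}{(1-e^{-\alpha_u d})^2}
#'   \{(1-e^{-\alpha_u d})M + e^{-\alpha_u M d} - 1\} + M\right].}
#' Limits: \eqn{M^2 d^2 F_0^2} for no motion and \eqn{M d^2 F_0^2} for
#' uncorrelated frames.  Near \eqn{\alpha_u d = 0} a series expansion avoids
#' catastrophic cancellation.
#'
#' @param u Spatial frequency, 1/Angstrom.
#' @param M Number of frames (>= 1).
#' @param d Fluence per frame, e-/A^2 (> 0).
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence.
#' @param f0_sq Per-frame structure power \eqn{F_0(u)^2} (arbitrary units).
#' @return Expected power spectrum value.
#' @export
spectrum_discrete <- function(u, M, d, sigma0_sq, f0_sq = 1) {
  stopifnot(M >= 1, M == round(M), d > 0)
  a <- alpha_u(sigma0_sq, u) * d
  d^2 * f0_sq * double_sum_exp(a, M)
}

#' Expected power spectrum under continuous motion
#'
#' The \eqn{M \to \infty} limit of [spectrum_discrete()] at fixed total
#' fluence D: \eqn{S(u) = 2 F_0^2 [\alpha_u D + e^{-\alpha_u D} - 1] /
#' \alpha_u^2}, going to \eqn{D^2 F_0^2} for small \eqn{\alpha_u} and
#' \eqn{2 D F_0^2/\alpha_u} for large.
#'
#' @param u Spatial frequency, 1/Angstrom.
#' @param D_total Total fluence, e-/A^2 (>= 0).
#' @param sigma0_sq Per-axis mean squared displacement per unit fluence.
#' @param f0_sq Structure power \eqn{F_0(u)^2}.
#' @return Expected power spectrum value.
#' @export
spectrum_continuous <- function(u, D_total, sigma0_sq, f0_sq = 1) {
  stopifnot(D_total >= 0)
  z <- alpha_u(sigma0_sq, u) * D_total
  f0_sq * D_total^2 * saturation_factor(z)
}

# 2 (z + exp(-z) - 1) / z^2, stable at small z (-> 1).
saturation_factor <- function(z) {
  out <- numeric(length(z))
  small <- z < 1e-4
  zs <- z[small]
  out[small] <- 1 - zs / 3 + zs^2 / 12 - zs^3 / 60
  zl <- z[!small]
  out[!small] <- 2 * (zl + exp(-zl) - 1) / zl^2
  out
}

#' Saturation function of the block-summed ring signal
#'
#' \eqn{g(z) = (z + e^{-z} - 1)/z} with \eqn{z = \alpha_u m d}: monotonically
#' increasing, approximately z/2 for small z, plateauing towards 1 for large
#' z.  It is the shape in which the block-summed ring signal grows with block
#' fluence.
#'
#' @param z Dimensionless fluence times decorrelation rate (>= 0).
#' @return g(z) in [0, 1).
#' @examples
#' g_of_z(2.149)
#' @export
g_of_z <- function(z) {
  if (any(z < 0)) stop("`z` must be non-negative", call. = FALSE)
  out <- numeric(length(z))
  small <- z < 1e-4
  zs <- z[small]
  out[small] <- zs / 2 - zs^2 / 6 + zs^3 / 24
  zl <- z[!small]
  out[!small] <- (zl + exp(-zl) - 1) / zl
  out
}

#' Model for the block-summed ring signal versus block size
#'
#' \eqn{W_{M,m}(u) \propto g(\alpha_u m d)}: `scale` absorbs the total
#' fluence, electron-optical terms, specimen thickness and scattering
#' strength.  Monotone non-decreasing in m; linear in m for small
#' \eqn{\alpha_u m d} and plateauing at `scale` for large.
#'
#' @param m Frames per block (>= 1).
#' @param d Fluence per frame, e-/A^2 (> 0).
#' @param alpha Decorrelation rate \eqn{\alpha_u}, per e-/A^2 (>= 0).
#' @param scale Plateau amplitude.
#' @return Expected background-subtracted ring signal.
#' @export
block_curve_model <- function(m, d, alpha, scale = 1) {
  stopifnot(all(m >= 1), d > 0, alpha >= 0)
  scale * g_of_z(alpha * m * d)
}
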