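#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `voltage`
#' kilovolts, with the relativistic correction. At 300 kV this is 0.0197 A.
#'
#' @param voltage Accelerating voltage in kV (> 0).
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(300)
#' @export
electron_wavelength <- function(voltage) {
  stopifnot(is.numeric(voltage))
  if (any(!is.finite(voltage)) || any(voltage <= 0)) {
    stop("`voltage` must be a positive number of kilovolts", call. = FALSE)
  }
  v <- voltage * 1000 # volts
  12.2643 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Electron-optical model for contrast transfer
#'
#' Bundles the microscope parameters that determine the phase-contrast
#' transfer function: voltage (the wavelength is derived from it), defocus
#' (positive = underfocus), twofold astigmatism, spherical aberration and the
#' amplitude-contrast fraction.
#'
#' Sign convention (used everywhere in this package): the contrast is
#' \eqn{-[\sqrt{1-A^2}\sin\gamma + A\cos\gamma]} with
#' \eqn{\gamma = \pi\lambda\Delta f(\theta) u^2 - (\pi/2) C_s \lambda^3 u^4},
#' so with underfocus positive the Thon-ring maxima appear as bright rings in
#' power spectra.
#'
#' @param voltage Accelerating voltage, kV.
#' @param defocus Defocus in Angstrom, positive for underfocus.
#' @param astig_amplitude Astigmatism half-difference in Angstrom (>= 0).
#' @param astig_angle Azimuth of the astigmatism axis, radians.
#' @param cs Spherical aberration in mm (default 0).
#' @param amplitude_contrast Amplitude-contrast fraction in [0, 1).
#' @return An object of class `optics_model`.
#' @examples
#' optics_model(voltage = 300, defocus = 7070)
#' @export
optics_model <- function(voltage = 300, defocus = 7070, astig_amplitude = 0,
                         astig_angle = 0, cs = 0, amplitude_contrast = 0) {
  stopifnot(astig_amplitude >= 0, cs >= 0,
            amplitude_contrast >= 0, amplitude_contrast < 1)
  obj <- list(
    voltage = voltage,
    wavelength = electron_wavelength(voltage),
    defocus = defocus,
    astig_amplitude = astig_amplitude,
    astig_angle = astig_angle,
    cs = cs,
    amplitude_contrast = amplitude_contrast
  )
  class(obj) <- "optics_model"
  obj
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(
    "<optics_model> %g kV (lambda %.5f A), defocus %g A, astig %g A @ %.3f rad, Cs %g mm, A %g\n",
    x$voltage, x$wavelength, x$defocus, x$astig_amplitude, x$astig_angle,
    x$cs, x$amplitude_contrast))
  invisible(x)
}

#' Phase-contrast transfer function
#'
#' @param u Spatial frequency in 1/Angstrom (>= 0); vectorised.
#' @param theta Azimuth in radians (recycled against `u`).
#' @param optics An [optics_model()].
#' @return Contrast values in [-1, 1].
#' @export
ctf <- function(u, theta = 0, optics = optics_model()) {
  stopifnot(inherits(optics, "optics_model"))
  if (any(u < 0)) stop("`u` must be non-negative", call. = FALSE)
  lam <- optics$wavelength
  df_theta <- optics$defocus +
    optics$astig_amplitude * cos(2 * (theta - optics$astig_angle))
  cs_A <- optics$cs * 1e7 # mm -> Angstrom
  gamma <- pi * lam * df_theta * u^2 - (pi / 2) * cs_A * lam^3 * u^4
  a <- optics$amplitude_contrast
  -(sqrt(1 - a^2) * sin(gamma) + a * cos(gamma))
}

#' Defocus-spread (thickness) damping envelope
#'
#' A sample of thickness `t` spans a range of defocus; averaging the Thon-ring
#' oscillation over that range damps its modulation by
#' \eqn{\sin(\xi)/\xi} with \eqn{\xi = \pi\lambda u^2 t}.  The envelope is 1
#' at u = 0 and changes sign past its first node at \eqn{\xi = \pi}.
#'
#' @param u Spatial frequency, 1/Angstrom (>= 0); vectorised.
#' @param thickness Sample thickness in Angstrom (> 0).
#' @param wavelength Electron wavelength in Angstrom.
#' @return Dimensionless damping factor in [-1, 1].
#' @examples
#' thickness_envelope(1 / 3.7, 1250, electron_wavelength(300))
#' @export
thickness_envelope <- function(u, thickness, wavelength) {
  stopifnot(thickness > 0, wavelength > 0)
  if (any(u < 0)) stop("`u` must be non-negative", call. = FALSE)
  xi <- pi * wavelength * u^2 * thickness
  out <- rep(1, length(xi))
  nz <- xi != 0
  out[nz] <- sin(xi[nz]) / xi[nz]
  out
}

#' Thickness placing the first envelope node at a given frequency
#'
#' Inverts the sinc envelope: the first node (\eqn{\xi = \pi}) falls at
#' frequency `u` when the thickness is \eqn{1/(\lambda u^2)}.  The absence of
#' a node in measured ring modulation out to `u` therefore bounds the
#' thickness from above by this value.
#'
#' @param u Spatial frequency, 1/Angstrom (> 0).
#' @param wavelength Electron wavelength, Angstrom.
#' @return Thickness in Angstrom.
#' @export
first_node_thickness <- function(u, wavelength) {
  stopifnot(wavelength > 0)
  if (any(u <= 0)) stop("`u` must be positive", call. = FALSE)
  1 / (wavelength * u^2)
}

#' Frequency of the first envelope node for a given thickness
#'
#' @param thickness Sample thickness, Angstrom (> 0).
#' @param wavelength Electron wavelength, Angstrom.
#' @return Spatial frequency in 1/Angstrom, \eqn{u = 1/\sqrt{\lambda t}}.
#' @export
node_frequency <- function(thickness, wavelength) {
  stopifnot(wavelength > 0)
  if (any(thickness <= 0)) stop("`thickness` must be positive", call. = FALSE)
  1 / sqrt(wavelength * thickness)
}

#' Ice thickness from the burn-through exposure
#'
#' Radiolysis removes roughly 100 A of ice thickness per 170 e-/A^2 of
#' 300 keV exposure; counting how many successive images are needed to burn
#' through a film therefore estimates its initial thickness.
#'
#' @param n_images Number of images required to burn through (> 0).
#' @param fluence_per_image Fluence per image, e-/A^2 (> 0).
#' @return Estimated thickness in Angstrom.
#' @examples
#' thickness_from_burnthrough(10, 17) # 170 e-/A^2 total -> 100 A
#' @export
thickness_from_burnthrough <- function(n_images, fluence_per_image) {
  if (any(n_images <= 0) || any(fluence_per_image <= 0)) {
    stop("`n_images` and `fluence_per_image` must be positive", call. = FALSE)
  }
  n_images * fluence_per_image * (100 / 170)
}
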