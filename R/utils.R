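# Shared frequency-grid helpers.  All internal grids are in cycles/pixel
# (DFT layout, DC at [1,1]); conversion to 1/Angstrom happens once, at the
# radial-curve boundary.

# Signed DFT frequencies in cycles/pixel for n samples; for even n the
# Nyquist frequency +1/2 is included once.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

# Matrices of frequency components and radius (cycles/pixel) for an n x n grid.
freq_grid <- function(n) {
  f <- fft_freq(n)
  fx <- matrix(f, n, n)       # varies down rows
  fy <- matrix(f, n, n, byrow = TRUE)
  list(fx = fx, fy = fy, r = sqrt(fx^2 + fy^2))
}

# Linear index of the complex-conjugate partner of every coefficient of an
# n x n DFT (partner of frequency index k is (n - k) mod n on each axis).
conj_partner_index <- function(n) {
  k <- 0:(n - 1)
  ck <- (n - k) %% n
  outer(ck + 1, ck * n, "+") # (ci, cj) -> ci + cj*n, 1-based rows
}

# Logical mask selecting one member of each conjugate pair (DC excluded),
# so that the selected whitened power values are mutually independent.
halfplane_mask <- function(n) {
  lin <- matrix(seq_len(n * n), n, n)
  partner <- conj_partner_index(n)
  mask <- lin <= partner # keeps self-conjugate points (DC, Nyquist rows) once
  mask[1, 1] <- FALSE    # drop DC
  mask
}

# All positive divisors of M, ascending.
divisors <- function(m) {
  stopifnot(length(m) == 1, m >= 1, m == round(m))
  d <- seq_len(m)
  d[m %% d == 0]
}

#' Convert a per-pixel dose to a fluence
#'
#' Doses are recorded per detector pixel (e-/pixel) but the motion model works
#' in electrons per unit specimen area (e-/A^2).  This is the single place
#' where the conversion by the pixel area happens.
#'
#' @param dose_per_pixel Dose in electrons per pixel.
#' @param pixel_size Pixel size in Angstrom.
#' @return Fluence in e-/A^2.
#' @export
dose_to_fluence <- function(dose_per_pixel, pixel_size) {
  stopifnot(pixel_size > 0)
  dose_per_pixel / pixel_size^2
}
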