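# Power spectra, noise whitening, block-summed spectra, circular averaging,
# background statistics and ring-signal extraction.

#' Dose-fractionated movie stack
#'
#' @param frames List of equally sized square numeric matrices, values in
#'   electrons/pixel.
#' @param pixel_size Pixel size in Angstrom.
#' @param dose_per_frame Mean incident electrons per pixel per frame.
#' @param voltage Accelerating voltage, kV.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, dose_per_frame, voltage = 300) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, is.matrix, TRUE)),
            pixel_size > 0, dose_per_frame > 0)
  d1 <- dim(frames[[1]])
  if (d1[1] != d1[2]) stop("frames must be square", call. = FALSE)
  if (!all(vapply(frames, function(f) all(dim(f) == d1), TRUE))) {
    stop("all frames must have the same dimensions", call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 dose_per_frame = dose_per_frame,
                 n_frames = length(frames), voltage = voltage),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("<movie_stack> %d frames of %dx%d px, %.3g A/px, %.3g e-/px/frame, %g kV\n",
              x$n_frames, nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size, x$dose_per_frame, x$voltage))
  invisible(x)
}

#' Power spectrum of an image
#'
#' \eqn{S(u) = |f(u)|^2 / N_{tot}} with `f` the unnormalised DFT and
#' \eqn{N_{tot}} the number of pixels.  With this convention the sum of S
#' over all frequencies equals the sum of squared pixel values (Parseval),
#' and the expected off-DC level of pure shot noise equals its per-pixel
#' variance.  The DC term is stored but excluded from all downstream
#' statistics.
#'
#' @param image Square numeric matrix (finite values).
#' @param pixel_size Pixel size in Angstrom (used only to label frequencies).
#' @return An object of class `spectrum2d` with fields `values` (DFT layout,
#'   DC at [1,1]), `n_tot`, `pixel_size`, `kind` ("raw").
#' @export
power_spectrum <- function(image, pixel_size = 1) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  if (nrow(image) != ncol(image)) stop("image must be square", call. = FALSE)
  n_tot <- length(image)
  s <- Mod(stats::fft(image))^2 / n_tot
  structure(list(values = s, n_tot = n_tot, pixel_size = pixel_size,
                 kind = "raw", frames_summed = c(M = 1, m = 1)),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d:%s> %dx%d, pixel %.3g A, frames (M=%d, m=%d)\n",
              x$kind, nrow(x$values), ncol(x$values), x$pixel_size,
              x$frames_summed["M"], x$frames_summed["m"]))
  invisible(x)
}

#' Noise-whiten a power spectrum
#'
#' Pointwise division of a power spectrum by the normalised detector NPS,
#' \eqn{W(u) = S(u)/N(u)}.  For specimen-free data the whitened spectrum has
#' a flat radial profile with mean d/DQE(0).
#'
#' @param spec A `spectrum2d`.
#' @param nps An `nps_surface` (or plain matrix) from [evaluate_nps()],
#'   matching the spectrum's grid, all values > 0.
#' @return A `spectrum2d` with `kind = "whitened"`.
#' @export
noise_whiten <- function(spec, nps) {
  stopifnot(inherits(spec, "spectrum2d"))
  nps <- unclass(nps)
  if (!all(dim(nps) == dim(spec$values))) {
    stop("NPS grid does not match the spectrum grid", call. = FALSE)
  }
  if (any(nps <= 0)) stop("NPS must be positive everywhere", call. = FALSE)
  spec$values <- spec$values / nps
  spec$kind <- "whitened"
  spec
}

#' Block-summed noise-whitened power spectrum
#'
#' Partitions the M frames of a movie into M/m consecutive blocks of m
#' frames, sums the frames within each block, computes each block image's
#' noise-whitened power spectrum, and returns the sum of the M/m whitened
#' spectra, \eqn{W_{M,m}(u)}.  For uncorrelated noise its expected value,
#' \eqn{D_{tot}/DQE(0)} per pixel dose, is independent of m, while the noise
#' grows as \eqn{\sqrt m} (see [predicted_background()], [predicted_noise()]).
#'
#' @param movie A [movie_stack()].
#' @param m Frames per block; must divide the number of frames.
#' @param nps NPS surface for whitening (matrix matching the frame grid).
#' @return A `spectrum2d` with `kind = "whitened"` and `frames_summed`
#'   recording (M, m).
#' @export
block_sum_nwps <- function(movie, m, nps) {
  stopifnot(inherits(movie, "movie_stack"))
  M <- movie$n_frames
  if (m < 1 || m != round(m) || M %% m != 0) {
    stop(sprintf("`m` = %s does not divide M = %d (valid: %s)", m, M,
                 paste(divisors(M), collapse = ", ")), call. = FALSE)
  }
  nps <- unclass(nps)
  acc <- NULL
  for (b in seq_len(M %/% m)) {
    block <- Reduce(`+`, movie$frames[((b - 1) * m + 1):(b * m)])
    w <- noise_whiten(power_spectrum(block, movie$pixel_size), nps)
    acc <- if (is.null(acc)) w$values else acc + w$values
  }
  structure(list(values = acc, n_tot = length(acc),
                 pixel_size = movie$pixel_size, kind = "whitened",
                 frames_summed = c(M = M, m = m)),
            class = "spectrum2d")
}

#' Expected background of a block-summed whitened spectrum
#'
#' \eqn{\Gamma_M = M d / DQE(0)}, independent of the block size m.
#'
#' @param M Number of frames.
#' @param d Dose per frame, e-/pixel.
#' @param dqe0 Zero-frequency DQE.
#' @return Expected background level per Fourier pixel.
#' @examples
#' predicted_background(120, 2.33, 0.5) # about 560
#' @export
predicted_background <- function(M, d, dqe0) {
  stopifnot(M > 0, d > 0, dqe0 > 0)
  M * d / dqe0
}

#' Expected noise of a block-summed whitened spectrum
#'
#' Per Fourier pixel the noise of \eqn{W_{M,m}} is
#' \eqn{(Md/DQE(0))\sqrt{m/M}}: each whitened spectrum contributes noise
#' equal to its own mean (exponential values), and the M/m independent
#' spectra add in quadrature.  In a circular average over a bin containing
#' `count` Fourier pixels (of which count/2 are independent because of the
#' Hermitian symmetry of real images) divide by \eqn{\sqrt{count/2}}.
#'
#' @inheritParams predicted_background
#' @param m Frames per block; must divide `M`.
#' @return Noise level per Fourier pixel.
#' @export
predicted_noise <- function(M, d, dqe0, m) {
  if (M %% m != 0) {
    stop(sprintf("`m` = %s does not divide M = %d", m, M), call. = FALSE)
  }
  predicted_background(M, d, dqe0) * sqrt(m / M)
}

#' Circularly averaged radial curve of a 2D spectrum
#'
#' Bins Fourier pixels by radius with equal-width half-open bins `[lo, hi)`
#' of `bin_width` Fourier pixels (default one), excludes the DC term and
#' radii beyond Nyquist, and averages the values in each bin.  Frequencies
#' are converted to 1/Angstrom here, and nowhere else.
#'
#' @param spec A `spectrum2d`.
#' @param bin_width Bin width in Fourier pixels.
#' @param noise_level Optional per-Fourier-pixel noise level (for example
#'   from [predicted_noise()]); the per-bin noise column is this divided by
#'   the square root of the number of independent values in the bin
#'   (count/2).
#' @return A data frame of class `radial_curve` with columns `u` (bin-centre
#'   frequency, 1/Angstrom), `value`, `count`, `noise`, and attributes
#'   `pixel_size`, `n`, `frames_summed`.
#' @export
radial_average <- function(spec, bin_width = 1, noise_level = NULL) {
  stopifnot(inherits(spec, "spectrum2d"))
  n <- nrow(spec$values)
  g <- freq_grid(n)
  rpix <- g$r * n
  bin <- floor(rpix / bin_width) + 1L
  keep <- rpix <= n / 2
  keep[1, 1] <- FALSE
  bin_keep <- bin[keep]
  vals <- spec$values[keep]
  mean_v <- tapply(vals, bin_keep, mean)
  count <- tapply(vals, bin_keep, length)
  idx <- as.integer(names(mean_v))
  u_pix <- (idx - 0.5) * bin_width          # bin centres, Fourier pixels
  u <- u_pix / (n * spec$pixel_size)        # 1/Angstrom
  noise <- if (is.null(noise_level)) rep(NA_real_, length(idx)) else
    noise_level / sqrt(pmax(count, 1) / 2)
  out <- data.frame(u = u, value = as.numeric(mean_v),
                    count = as.integer(count), noise = as.numeric(noise))
  out <- out[order(out$u), ]
  rownames(out) <- NULL
  attr(out, "pixel_size") <- spec$pixel_size
  attr(out, "n") <- n
  attr(out, "frames_summed") <- spec$frames_summed
  class(out) <- c("radial_curve", "data.frame")
  out
}

#' Background statistics of a whitened spectrum
#'
#' For specimen-free data the whitened power values follow an exponential
#' distribution whose mean and standard deviation are both
#' \eqn{\Gamma = d/DQE(0)}.  The mean is estimated over one member of each
#' conjugate pair of Fourier coefficients (so the values are independent),
#' excluding the DC term and an optional frequency band containing specimen
#' rings.  The exponential check reports the SD/mean ratio (1 for an
#' exponential) and the Kolmogorov-Smirnov distance to an exponential with
#' the estimated mean.
#'
#' Note the exponential law holds for a *single* whitened spectrum; a
#' block-summed \eqn{W_{M,m}} is a sum of M/m of them and has SD/mean
#' \eqn{\sqrt{m/M}}.  To check the distribution over a whole movie, pass a
#' list of per-frame whitened spectra and their values are pooled.
#'
#' @param spec A whitened `spectrum2d`, or a list of them (values pooled).
#' @param exclude_u Optional `c(lo, hi)` frequency band (1/Angstrom) to
#'   exclude, e.g. the ring region.
#' @return A list of class `background_stats`: `gamma`, `sd`, `sd_over_mean`,
#'   `ks_stat`, `exponential_ok`, `n`.
#' @export
background_stats <- function(spec, exclude_u = NULL) {
  specs <- if (inherits(spec, "spectrum2d")) list(spec) else spec
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "spectrum2d")))
  if (any(vapply(specs, `[[`, "", "kind") != "whitened")) {
    warning("background statistics expect whitened spectra", call. = FALSE)
  }
  n <- nrow(specs[[1]]$values)
  mask <- halfplane_mask(n)
  if (!is.null(exclude_u)) {
    u <- freq_grid(n)$r / specs[[1]]$pixel_size
    mask <- mask & !(u >= exclude_u[1] & u <= exclude_u[2])
  }
  vals <- unlist(lapply(specs, function(s) s$values[mask]))
  if (length(vals) < 2) {
    stop("no frequencies left after exclusion", call. = FALSE)
  }
  gamma <- mean(vals)
  s <- stats::sd(vals)
  if (s == 0) {
    ks <- 1
  } else {
    ecdf_sorted <- sort(vals)
    p <- stats::pexp(ecdf_sorted, rate = 1 / gamma)
    i <- seq_along(p)
    ks <- max(pmax(i / length(p) - p, p - (i - 1) / length(p)))
  }
  sd_over_mean <- s / gamma
  structure(list(gamma = gamma, sd = s, sd_over_mean = sd_over_mean,
                 ks_stat = ks,
                 exponential_ok = (abs(sd_over_mean - 1) < 0.05 && ks < 0.01),
                 n = length(vals)),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf("<background_stats> Gamma = %.4g (SD %.4g, SD/mean %.3f), KS = %.4g over %d values; exponential %s\n",
              x$gamma, x$sd, x$sd_over_mean, x$ks_stat, x$n,
              if (x$exponential_ok) "ok" else "NOT ok"))
  invisible(x)
}

#' Anchor block-summed curves to the m = 1 curve at high frequency
#'
#' Residual correlations between frames (detector artifacts, gain-map
#' imperfections) shift the background of \eqn{W_{M,m}} with m.  Beyond the
#' specimen signal the curves should agree, so a constant per curve is added
#' to make each curve's mean over the top `band_frac` of frequency bins equal
#' to that of the m = 1 curve.  A single Nyquist bin of a square grid holds
#' only a handful of Fourier pixels, so a band is used rather than the last
#' bin alone.
#'
#' @param curves Named list of `radial_curve`s, names the m values; must
#'   include "1".
#' @param band_frac Fraction of the top frequency bins used as the anchor
#'   band (default 0.1).
#' @param background Reference background level used to express the maximum
#'   shift as a fraction; defaults to the anchor-band mean of the m = 1
#'   curve.
#' @return A list with `curves` (shifted), `shifts`, `max_shift_frac` and
#'   `ok` (TRUE when the largest shift is at most 5% of the background).
#' @export
anchor_shift <- function(curves, band_frac = 0.1, background = NULL) {
  if (!"1" %in% names(curves)) {
    stop("the m = 1 curve is required as the anchor reference", call. = FALSE)
  }
  ref <- curves[["1"]]
  nb <- nrow(ref)
  band <- seq.int(max(1, ceiling((1 - band_frac) * nb)), nb)
  band_mean <- function(cv) sum(cv$value[band] * cv$count[band]) / sum(cv$count[band])
  ref_mean <- band_mean(ref)
  if (is.null(background)) background <- ref_mean
  shifts <- vapply(curves, function(cv) {
    if (nrow(cv) != nb) stop("curves must share binning", call. = FALSE)
    ref_mean - band_mean(cv)
  }, numeric(1))
  shifted <- Map(function(cv, s) { cv$value <- cv$value + s; cv }, curves, shifts)
  max_frac <- max(abs(shifts)) / background
  if (max_frac > 0.05) {
    warning(sprintf("maximum anchor shift is %.1f%% of background (> 5%%)",
                    100 * max_frac), call. = FALSE)
  }
  list(curves = shifted, shifts = shifts, max_shift_frac = max_frac,
       ok = max_frac <= 0.05)
}

#' Background-subtracted ring signal at a target frequency
#'
#' Value of the radial curve in the bin containing `u_target`, minus a
#' background level.  The background is either a number (for example
#' [predicted_background()]) or a ring-free band `c(lo, hi)` in 1/Angstrom
#' whose count-weighted mean is used (its standard error is then propagated
#' into the reported error).
#'
#' @param curve A `radial_curve` with a `noise` column.
#' @param u_target Target frequency, 1/Angstrom, within the curve range.
#' @param background A single number, or `c(lo, hi)` band.
#' @return A list with `value`, `error`, `u_bin`, `background`.
#' @export
ring_signal_at <- function(curve, u_target, background) {
  stopifnot(inherits(curve, "radial_curve"))
  if (u_target < min(curve$u) || u_target > max(curve$u)) {
    stop("`u_target` outside the curve range", call. = FALSE)
  }
  i <- which.min(abs(curve$u - u_target))
  if (length(background) == 2) {
    in_band <- curve$u >= background[1] & curve$u <= background[2]
    if (in_band[i]) {
      stop("background band overlaps the target bin", call. = FALSE)
    }
    if (!any(in_band)) stop("empty background band", call. = FALSE)
    w <- curve$count[in_band]
    bg <- sum(curve$value[in_band] * w) / sum(w)
    bg_err2 <- sum((w * curve$noise[in_band])^2) / sum(w)^2
  } else {
    bg <- background
    bg_err2 <- 0
  }
  err <- sqrt(curve$noise[i]^2 + bg_err2)
  list(value = curve$value[i] - bg, error = err, u_bin = curve$u[i],
       background = bg)
}

#' Thon-ring modulation depth of a radial curve
#'
#' One half the peak-to-peak value of the curve within `u_range`, divided by
#' the mean of the curve above the background level; this is the fractional
#' visibility of the ring oscillation riding on the specimen signal.
#'
#' @param curve A `radial_curve`.
#' @param u_range `c(lo, hi)` frequency range (1/Angstrom) spanning at least
#'   one full ring oscillation.
#' @param background Background level underneath the signal (default 0).
#' @return Dimensionless modulation fraction.
#' @export
measure_modulation <- function(curve, u_range, background = 0) {
  stopifnot(inherits(curve, "radial_curve"), length(u_range) == 2)
  sel <- curve$u >= u_range[1] & curve$u <= u_range[2]
  if (sum(sel) < 3) stop("`u_range` selects too few bins", call. = FALSE)
  v <- curve$value[sel]
  excess <- mean(v) - background
  if (excess <= 0) return(0)
  (max(v) - min(v)) / 2 / excess
}

#' Block series: ring signal versus frames per block
#'
#' Runs the full block-sum analysis of a movie: for each block size m it
#' computes \eqn{W_{M,m}}, circularly averages it, optionally anchors the
#' curves to the m = 1 curve at high frequency, and extracts the
#' background-subtracted ring signal at `u_target` with its predicted error.
#' The background defaults to the prediction \eqn{Md/DQE(0)}; pass
#' `background_band` to estimate it from a ring-free annulus instead.
#'
#' @param movie A [movie_stack()].
#' @param nps NPS surface used for whitening.
#' @param u_target Ring frequency of interest, 1/Angstrom.
#' @param dqe0 Detector DQE(0) used for the background/noise predictions.
#' @param m_values Block sizes (divisors of the frame count); default all
#'   divisors.
#' @param background_band Optional `c(lo, hi)` ring-free band (1/Angstrom).
#' @param apply_anchor Apply [anchor_shift()] before extraction (default
#'   FALSE: the simulators contain no inter-frame detector correlation).
#' @return A data frame of class `block_series` with columns `m`, `dose`
#'   (block fluence, e-/A^2), `value`, `error`, and attributes `M`,
#'   `dose_per_frame`, `fluence_per_frame`, `u_target`, `dqe0`,
#'   `pixel_size`, `curves`.
#' @export
block_series <- function(movie, nps, u_target, dqe0,
                         m_values = NULL, background_band = NULL,
                         apply_anchor = FALSE) {
  stopifnot(inherits(movie, "movie_stack"))
  M <- movie$n_frames
  if (is.null(m_values)) m_values <- divisors(M)
  if (any(M %% m_values != 0)) {
    stop(sprintf("all m values must divide M = %d (valid: %s)", M,
                 paste(divisors(M), collapse = ", ")), call. = FALSE)
  }
  m_values <- sort(unique(m_values))
  d <- movie$dose_per_frame
  gamma_M <- predicted_background(M, d, dqe0)
  curves <- lapply(m_values, function(m) {
    radial_average(block_sum_nwps(movie, m, nps),
                   noise_level = predicted_noise(M, d, dqe0, m))
  })
  names(curves) <- as.character(m_values)
  if (apply_anchor) curves <- anchor_shift(curves, background = gamma_M)$curves
  bg <- if (is.null(background_band)) gamma_M else background_band
  sig <- lapply(curves, ring_signal_at, u_target = u_target, background = bg)
  d_fl <- dose_to_fluence(d, movie$pixel_size)
  out <- data.frame(
    m = m_values,
    dose = m_values * d_fl,
    value = vapply(sig, `[[`, numeric(1), "value"),
    error = vapply(sig, `[[`, numeric(1), "error")
  )
  rownames(out) <- NULL
  attr(out, "M") <- M
  attr(out, "dose_per_frame") <- d
  attr(out, "fluence_per_frame") <- d_fl
  attr(out, "u_target") <- u_target
  attr(out, "dqe0") <- dqe0
  attr(out, "pixel_size") <- movie$pixel_size
  attr(out, "curves") <- curves
  class(out) <- c("block_series", "data.frame")
  out
}
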