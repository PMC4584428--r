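# Pipeline commands tying the stages together: simulate -> analyze -> fit,
# with yaml configuration, MRCS movies and delimited-text curve tables.
# These functions are the package's command surface; exec/icemotion is a
# thin Rscript dispatcher over them.

run_config_keys <- list(
  simulate = c("type", "n_pixels", "pixel_size", "n_frames", "dose_per_frame",
               "sigma0_sq", "defocus", "voltage", "thickness", "f0_peak",
               "ring_center", "ring_width", "substeps", "density", "spacing",
               "contrast", "dqe0", "seed", "out"),
  analyze = c("movie", "pixel_size", "dose_per_frame", "dqe0", "m_values",
              "u_target", "apply_anchor", "out_dir"),
  fit = c("series", "u_target", "fluence", "molecular_weights", "out")
)

#' Read and validate a pipeline configuration file
#'
#' Yaml file with one top-level block per command (`simulate`, `analyze`,
#' `fit`).  Unknown keys are rejected with the offending names.
#'
#' @param path Path to a yaml file.
#' @return Named list of validated blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  bad_blocks <- setdiff(names(cfg), names(run_config_keys))
  if (length(bad_blocks)) {
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "),
         call. = FALSE)
  }
  for (blk in names(cfg)) {
    bad <- setdiff(names(cfg[[blk]]), run_config_keys[[blk]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in `%s`: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  cfg
}

sim_config_from_list <- function(opts) {
  defaults <- list(n_pixels = 256, pixel_size = 1.04, n_frames = 120,
                   dose_per_frame = 2.33, sigma0_sq = 0.38, defocus = 7070,
                   voltage = 300, thickness = 1250, f0_peak = 1.2,
                   ring_center = 1 / 3.7, ring_width = 0.04, substeps = 16,
                   density = 2e-4, spacing = 3.7, contrast = 1.8,
                   dqe0 = 0.5, seed = 1)
  opts <- utils::modifyList(defaults, opts[intersect(names(opts), names(defaults))])
  gain_var <- 1 / opts$dqe0 - 1
  sim_config(n_pixels = opts$n_pixels, pixel_size = opts$pixel_size,
             n_frames = opts$n_frames, dose_per_frame = opts$dose_per_frame,
             sigma0_sq = opts$sigma0_sq,
             optics = optics_model(voltage = opts$voltage,
                                   defocus = opts$defocus),
             detector = detector_model(gain_mean = 1, gain_var = gain_var),
             thickness = opts$thickness, f0_peak = opts$f0_peak,
             ring_center = opts$ring_center, ring_width = opts$ring_width,
             substeps = opts$substeps, density = opts$density,
             spacing = opts$spacing, contrast = opts$contrast,
             seed = opts$seed)
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Simulate a movie and write it to disk
#'
#' Runs one of the simulators and writes the movie as an MRCS stack plus a
#' yaml metadata sidecar (`<out>.yaml`) echoing the full configuration
#' including the seed, so every artifact is regenerable.
#'
#' @param config A [sim_config()], or a named list of overrides (see
#'   [read_run_config()]), or a path to a yaml config file with a
#'   `simulate` block.
#' @param out Output MRCS path.
#' @param type One of "spectral", "particle", "noise".
#' @return Invisibly, a list with `movie`, `path`, `meta_path`.
#' @export
run_simulate <- function(config = list(), out = "movie.mrcs",
                         type = c("spectral", "particle", "noise")) {
  if (is.character(config)) config <- read_run_config(config)$simulate
  if (!is.null(config$type)) type <- config$type
  type <- match.arg(type)
  if (is.character(config$out)) out <- config$out
  cfg <- if (inherits(config, "sim_config")) config else
    sim_config_from_list(config)
  log_msg("simulate (%s): %d frames of %d^2 px, d = %g e-/px, seed %s",
          type, cfg$n_frames, cfg$n_pixels, cfg$dose_per_frame,
          format(cfg$seed))
  movie <- switch(type,
                  spectral = simulate_movie_spectral(cfg),
                  particle = simulate_movie_particle(cfg),
                  noise = noise_movie(cfg))
  write_mrc(movie$frames, out, pixel_size = cfg$pixel_size)
  meta <- list(type = type, seed = cfg$seed, n_pixels = cfg$n_pixels,
               pixel_size = cfg$pixel_size, n_frames = cfg$n_frames,
               dose_per_frame = cfg$dose_per_frame,
               sigma0_sq = cfg$sigma0_sq,
               voltage = cfg$optics$voltage, defocus = cfg$optics$defocus,
               dqe0 = cfg$detector$dqe0,
               thickness = if (is.null(cfg$thickness)) 0 else cfg$thickness)
  meta_path <- paste0(out, ".yaml")
  yaml::write_yaml(meta, meta_path)
  log_msg("wrote %s (+ %s)", out, meta_path)
  invisible(list(movie = movie, path = out, meta_path = meta_path))
}

read_movie <- function(path, pixel_size = NULL, dose_per_frame = NULL,
                       voltage = NULL) {
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  mrc <- read_mrc(path)
  px <- pixel_size %||% meta$pixel_size %||% mrc$pixel_size
  d <- dose_per_frame %||% meta$dose_per_frame %||%
    stop("dose_per_frame not in sidecar; supply it", call. = FALSE)
  kv <- voltage %||% meta$voltage %||% 300
  movie_stack(mrc$frames, px, d, kv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze a movie: whitened spectra, radial curves and block series
#'
#' Computes the noise-whitened power spectrum of the frame sum, the sum of
#' the per-frame whitened spectra, circularly averaged \eqn{W_{M,m}} curves
#' for the requested block sizes, background statistics and the
#' background-subtracted block series at the target frequency.  Products
#' are written as MRC images (2D spectra) and tab-separated tables.
#'
#' @param movie A [movie_stack()] or path to an MRCS file (metadata read
#'   from the `.yaml` sidecar when present).
#' @param detector A [detector_model()] used for whitening and the
#'   background predictions.
#' @param m_values Block sizes (default all divisors of M).
#' @param u_target Ring frequency of interest, 1/Angstrom.
#' @param out_dir Output directory, or NULL to skip writing.
#' @param apply_anchor Apply the high-frequency anchor shift.
#' @param dose_per_frame,pixel_size Overrides when reading from a file.
#' @return Invisibly, a list with `series`, `curves`, `background`,
#'   `nwps_sum`, `sum_nwps`.
#' @export
run_analyze <- function(movie, detector = detector_model(), m_values = NULL,
                        u_target = 1 / 3.7, out_dir = NULL,
                        apply_anchor = FALSE, dose_per_frame = NULL,
                        pixel_size = NULL) {
  if (is.character(movie)) {
    movie <- read_movie(movie, pixel_size, dose_per_frame)
  }
  M <- movie$n_frames
  if (is.null(m_values)) m_values <- divisors(M)
  nps <- evaluate_nps(nrow(movie$frames[[1]]), detector)
  log_msg("analyze: M = %d, m = {%s}, u_target = %.4g 1/A", M,
          paste(m_values, collapse = ","), u_target)
  nwps_sum <- block_sum_nwps(movie, M, nps)   # NWPS of the full sum
  frame_nwps <- lapply(movie$frames, function(f) {
    noise_whiten(power_spectrum(f, movie$pixel_size), nps)
  })
  sum_nwps <- frame_nwps[[1]]
  sum_nwps$values <- Reduce(`+`, lapply(frame_nwps, `[[`, "values"))
  sum_nwps$frames_summed <- c(M = M, m = 1)
  # per-frame values pooled: exponential with mean d/DQE(0) off the ring
  bg <- background_stats(frame_nwps, exclude_u = u_target * c(0.85, 1.15))
  series <- block_series(movie, nps, u_target, detector$dqe0,
                         m_values = m_values, apply_anchor = apply_anchor)
  curves <- attr(series, "curves")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mrc(nwps_sum$values, file.path(out_dir, "nwps_of_sum.mrc"),
              movie$pixel_size)
    write_mrc(sum_nwps$values, file.path(out_dir, "sum_of_nwps.mrc"),
              movie$pixel_size)
    tab <- do.call(rbind, Map(function(cv, m) {
      cbind(m = as.numeric(m), as.data.frame(cv))
    }, curves, names(curves)))
    utils::write.table(tab, file.path(out_dir, "radial_curves.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_block_series(series, file.path(out_dir, "block_series.tsv"))
    yaml::write_yaml(list(gamma = bg$gamma, sd = bg$sd,
                          sd_over_mean = bg$sd_over_mean,
                          ks_stat = bg$ks_stat,
                          exponential_ok = bg$exponential_ok),
                     file.path(out_dir, "background.yaml"))
    log_msg("wrote analysis products to %s", out_dir)
  }
  invisible(list(series = series, curves = curves, background = bg,
                 nwps_sum = nwps_sum, sum_nwps = sum_nwps))
}

#' Write / read a block series table
#'
#' Tab-separated columns `m`, `dose`, `value`, `error` preceded by `#`
#' header lines carrying the series metadata.
#'
#' @param series A [block_series()].
#' @param path Output path.
#' @return `path` (write) / a `block_series` (read), invisibly for write.
#' @export
write_block_series <- function(series, path) {
  stopifnot(inherits(series, "block_series"))
  hdr <- sprintf("# %s=%.10g",
                 c("M", "dose_per_frame", "fluence_per_frame", "u_target",
                   "dqe0", "pixel_size"),
                 c(attr(series, "M"), attr(series, "dose_per_frame"),
                   attr(series, "fluence_per_frame"), attr(series, "u_target"),
                   attr(series, "dqe0"), attr(series, "pixel_size")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("m", "dose", "value", "error"), collapse = "\t"), con)
  utils::write.table(as.data.frame(series)[c("m", "dose", "value", "error")],
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_block_series
#' @export
read_block_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (i in hdr) {
    kv <- strsplit(sub("^#\\s*", "", lines[i]), "=")[[1]]
    if (length(kv) != 2 || is.na(suppressWarnings(as.numeric(kv[2])))) {
      stop(sprintf("malformed header at line %d of %s: '%s'", i, path,
                   lines[i]), call. = FALSE)
    }
    meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  first_data <- length(hdr) + 2L
  rows <- strsplit(body[-1], "\t")
  bad <- which(vapply(rows, length, 1L) != 4 |
                 vapply(rows, function(r) any(is.na(suppressWarnings(as.numeric(r)))), TRUE))
  if (length(bad)) {
    stop(sprintf("malformed table row at line %d of %s", bad[1] + first_data - 1L,
                 path), call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, lapply(rows, as.numeric)))
  names(df) <- c("m", "dose", "value", "error")
  for (k in names(meta)) attr(df, sub("^#", "", k)) <- meta[[k]]
  class(df) <- c("block_series", "data.frame")
  df
}

#' Fit the motion model and report derived quantities
#'
#' Runs [fit_sigma0()] on a block series and reports the per-axis and total
#' MSD rates, the optimal fluence per image at the target frequency, and
#' Brownian-blur extrapolations (RMS displacement and B-factor) for the
#' requested molecular weights at the given total fluence.
#'
#' @param series A [block_series()] or path to a table written by
#'   [write_block_series()].
#' @param u_target Ring frequency, 1/Angstrom (default from the series).
#' @param fluence Total exposure used for the blur extrapolation, e-/A^2.
#' @param molecular_weights Particle masses (Da) for the extrapolation.
#' @param out Optional path prefix: writes `<out>.txt` (human-readable
#'   report) and `<out>.yaml` (machine-readable).
#' @return Invisibly, a list with `fit` and `report` (named list of derived
#'   numbers).
#' @export
run_fit <- function(series, u_target = NULL, fluence = 25,
                    molecular_weights = c(25e3, 100e3, 2.5e6), out = NULL) {
  if (is.character(series)) series <- read_block_series(series)
  if (is.null(u_target)) u_target <- attr(series, "u_target")
  fit <- fit_sigma0(series, u_target = u_target)
  if (!fit$identifiable) {
    log_msg("fit unidentifiable; no derived quantities reported")
    return(invisible(list(fit = fit, report = NULL)))
  }
  msd <- msd_3d_rate(fit$sigma0_sq)
  dopt <- optimal_dose(fit$sigma0_sq, u_target)
  wrms <- rms_displacement(fluence, msd)
  blur <- lapply(molecular_weights, function(mw) {
    pr <- particle_rms(wrms, mw)
    list(molecular_weight = mw, rms = pr, bfactor = blur_bfactor(pr))
  })
  report <- list(sigma0_sq = fit$sigma0_sq,
                 sigma0_sq_se = sqrt(fit$covariance[1, 1]),
                 msd_3d_rate = msd, u_target = u_target,
                 optimal_dose = dopt, fluence = fluence,
                 water_rms = wrms, particles = blur)
  log_msg("fit: sigma0_sq = %.4g, d_opt(%.3g 1/A) = %.3g e-/A^2",
          fit$sigma0_sq, u_target, dopt)
  if (!is.null(out)) {
    txt <- c(
      "Beam-induced motion fit",
      sprintf("  sigma0_sq      : %.4g +/- %.2g A^2/(e-/A^2) per axis",
              fit$sigma0_sq, report$sigma0_sq_se),
      sprintf("  3D MSD rate    : %.4g A^2 per e-/A^2", msd),
      sprintf("  optimal dose   : %.3g e-/A^2 per image at u = %.4g 1/A",
              dopt, u_target),
      sprintf("  water RMS      : %.3g A after %.3g e-/A^2", wrms, fluence),
      "  particle blur  :",
      vapply(blur, function(b) {
        sprintf("    %8.3g Da : RMS %.3g A, B-factor %.3g A^2",
                b$molecular_weight, b$rms, b$bfactor)
      }, character(1)),
      sprintf("  weighted RSS   : %.4g over %d points", fit$residual_norm,
              fit$n_points))
    writeLines(txt, paste0(out, ".txt"))
    yaml::write_yaml(report, paste0(out, ".yaml"))
    log_msg("wrote %s.txt and %s.yaml", out, out)
  }
  invisible(list(fit = fit, report = report))
}
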