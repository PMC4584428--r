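# Shared fixtures, computed lazily and memoised for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 128^2, 8-frame specimen-free movie with the default detector
fx_noise_movie <- function() fixture("noise_movie_128", function() {
  noise_movie(sim_config(n_pixels = 128, n_frames = 8, seed = 101))
})

fx_nps_128 <- function() fixture("nps_128", function() {
  evaluate_nps(128, detector_model())
})

fx_nps_256 <- function() fixture("nps_256", function() {
  evaluate_nps(256, detector_model())
})

# default-geometry spectral-simulator ice movie at reduced size
fx_ice_movie <- function() fixture("ice_movie_128", function() {
  simulate_movie_spectral(sim_config(n_pixels = 128, n_frames = 16,
                                     sigma0_sq = 0.38, seed = 202))
})

fx_ice_series <- function() fixture("ice_series_128", function() {
  block_series(fx_ice_movie(), fx_nps_128(), 1 / 3.7, 0.5)
})
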