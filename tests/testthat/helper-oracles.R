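# Independent oracles used to freeze or cross-check expected values.

# O(M^2) covariance double sum behind the closed-form discrete spectrum
brute_spectrum_discrete <- function(u, M, d, sigma0_sq, f0_sq = 1) {
  a <- 2 * pi^2 * sigma0_sq * u^2 * d
  idx <- seq_len(M)
  d^2 * f0_sq * sum(exp(-a * abs(outer(idx, idx, "-"))))
}

# Monte-Carlo estimate of the expected |sum_i f_i|^2 for Gaussian frame
# components with the model covariance, via Cholesky sampling
mc_spectrum_discrete <- function(u, M, d, sigma0_sq, n_rep, seed) {
  set.seed(seed)
  a <- 2 * pi^2 * sigma0_sq * u^2 * d
  cov <- exp(-a * abs(outer(seq_len(M), seq_len(M), "-")))
  L <- chol(cov)
  z_re <- matrix(stats::rnorm(n_rep * M, sd = sqrt(0.5)), n_rep, M) %*% L
  z_im <- matrix(stats::rnorm(n_rep * M, sd = sqrt(0.5)), n_rep, M) %*% L
  vals <- rowSums(z_re)^2 + rowSums(z_im)^2
  list(mean = d^2 * mean(vals), se = d^2 * stats::sd(vals) / sqrt(n_rep))
}

# radially binned pair-distance density (r^2-corrected) of a point set
pair_correlation_peak <- function(positions, r_max = 8, bin = 0.2) {
  n <- nrow(positions)
  take <- if (n > 1200) sample.int(n, 1200) else seq_len(n)
  dd <- unlist(lapply(take, function(k) {
    d2 <- sqrt(rowSums((positions -
                          matrix(positions[k, ], n, 3, byrow = TRUE))^2))
    d2[d2 > 0.1 & d2 < r_max]
  }))
  h <- hist(dd, breaks = seq(0, r_max, bin), plot = FALSE)
  h$mids[which.max(h$counts / h$mids^2)]
}
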