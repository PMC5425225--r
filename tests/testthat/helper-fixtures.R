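# small fixtures built in code, shared across test files

# raster with synchronized population bursts (strong temporal correlation)
burst_raster <- function(n_neurons = 20, n_bins = 400, n_bursts = 8,
                         burst_len = 5, p_in = 0.8, p_out = 0.01,
                         bin_width = 0.25, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_neurons * n_bins, 1, p_out), n_neurons, n_bins)
    starts <- sort(sample.int(n_bins - burst_len, n_bursts))
    for (s in starts) {
      idx <- s:(s + burst_len - 1)
      m[, idx] <- matrix(rbinom(n_neurons * burst_len, 1, p_in),
                         n_neurons, burst_len)
    }
    spike_raster(m, bin_width)
  })
}

critical_config <- function(seed, n_bins = 20000, n_neurons = 100) {
  network_config(n_neurons = n_neurons, branching_parameter = 1,
                 drive_rate = 0.001, connectivity_degree = 10,
                 n_bins = n_bins, seed = seed)
}

# dense 1-D grid-search MLE, the independent oracle for mle_exponent
grid_mle <- function(samples, s_min, s_max, step = 1e-4) {
  x <- samples[samples >= s_min & samples <= s_max]
  taus <- seq(1.01, 5, by = step)
  s <- seq.int(s_min, s_max)
  log_s <- log(s)
  suff <- sum(log(x))
  # log Z on the grid, vectorized over support
  logz <- vapply(taus, function(tt) log(sum(exp(-tt * log_s))), numeric(1))
  ll <- -taus * suff - length(x) * logz
  taus[which.max(ll)]
}

# sizes shaped like shuffled-control avalanches: offset geometric
offset_geometric <- function(n, offset = 4, prob = 0.35, seed = 1) {
  withr::with_seed(seed, offset + stats::rgeom(n, prob))
}
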