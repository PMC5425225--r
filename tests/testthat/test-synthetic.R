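test_that("without drive or transmission, activity dies after the first bin", {
  cfg <- network_config(n_neurons = 30, branching_parameter = 0,
                        drive_rate = 0, connectivity_degree = 5,
                        n_bins = 50, seed = 4)
  r <- simulate_branching_network(cfg, initial_active = c(1, 5, 9))
  expect_equal(sum(r$values[, 1]), 3)
  expect_equal(sum(r$values[, -1]), 0)
})

test_that("with no recurrence the active fraction matches the drive rate", {
  q <- 0.07
  cfg <- network_config(n_neurons = 60, branching_parameter = 0,
                        drive_rate = q, connectivity_degree = 5,
                        n_bins = 4000, seed = 11)
  r <- simulate_branching_network(cfg)
  se <- sqrt(q * (1 - q) / length(r$values))
  expect_lt(abs(mean(r$values) - q), 3 * se)
})

test_that("empirical branching ratio matches sigma", {
  # seed one neuron, count descendants one generation later
  desc <- vapply(seq_len(1500), function(s) {
    cfg <- network_config(n_neurons = 100, branching_parameter = 0.5,
                          drive_rate = 0, connectivity_degree = 10,
                          n_bins = 2, seed = s)
    sum(simulate_branching_network(cfg, initial_active = 1)$values[, 2])
  }, numeric(1))
  expect_lt(abs(mean(desc) - 0.5), 0.05)
})

test_that("an invalid per-edge probability is rejected", {
  expect_error(
    network_config(n_neurons = 20, branching_parameter = 6,
                   connectivity_degree = 5),
    "not a valid probability")
})

test_that("simulation is a pure function of the config including seed", {
  cfg <- critical_config(seed = 21, n_bins = 500, n_neurons = 40)
  r1 <- simulate_branching_network(cfg)
  r2 <- simulate_branching_network(cfg)
  expect_identical(r1$values, r2$values)
  r3 <- simulate_branching_network(critical_config(seed = 22, n_bins = 500,
                                                   n_neurons = 40))
  expect_false(identical(r1$values, r3$values))
})

test_that("mean avalanche size increases with the branching parameter", {
  mean_size <- vapply(c(0.7, 1.0, 1.3), function(sg) {
    mean(vapply(1:10, function(s) {
      cfg <- network_config(n_neurons = 50, branching_parameter = sg,
                            drive_rate = 0.002, connectivity_degree = 10,
                            n_bins = 5000, seed = s)
      av <- extract_avalanches(network_activity(simulate_branching_network(cfg)))
      if (nrow(av)) mean(av$size) else 0
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_size) > 0))
})

test_that("calcium forward model reproduces the closed-form transient", {
  m <- matrix(0L, 1, 40)
  m[1, 10] <- 1L
  r <- spike_raster(m, bin_width = 0.25)
  ca <- spikes_to_calcium(r, frame_rate = 4, decay_constant = 0.8,
                          amplitude = 0.3, noise_sd = 0)
  f0 <- 10  # frame of the spike (1 bin per frame at 4 Hz / 0.25 s)
  later <- f0:40
  expected <- 0.3 * exp(-(later - f0) / (4 * 0.8))
  expect_equal(ca$values[later, 1], expected, tolerance = 1e-12)
  expect_true(all(ca$values[1:(f0 - 1), 1] == 0))
})

test_that("a silent raster renders to a flat zero-baseline trace", {
  r <- spike_raster(matrix(0L, 3, 30), bin_width = 0.25)
  ca <- spikes_to_calcium(r, frame_rate = 4, noise_sd = 0)
  expect_true(all(ca$values == 0))
})

test_that("defaults carry the standard imaging parameters", {
  expect_equal(eval(formals(spikes_to_calcium)$decay_constant), 0.8)
  expect_equal(eval(formals(infer_spike_probability)$decay_constant), 0.8)
  expect_equal(eval(formals(compute_dff)$window), 10)
  expect_equal(eval(formals(compute_dff)$lower_fraction), 0.5)
  expect_equal(eval(formals(threshold_spikes)$k_sd), 3)
  expect_equal(eval(formals(network_activity)$bin_width), 0.25)
})

test_that("shuffling preserves per-neuron counts and removes synchrony", {
  r <- burst_raster(seed = 3)
  sh <- shuffle_spike_times(r, seed = 8)
  expect_identical(rowSums(sh$values), rowSums(r$values))
  # variance of network activity can only drop, checked by recomputation
  v_before <- var(colSums(r$values))
  v_after <- var(colSums(sh$values))
  expect_lte(v_after, v_before)
  # all-zero raster maps to itself
  z <- spike_raster(matrix(0L, 4, 50), 0.25)
  expect_identical(shuffle_spike_times(z, seed = 1)$values, z$values)
  # reproducible under seed
  expect_identical(shuffle_spike_times(r, seed = 8)$values, sh$values)
})

test_that("condition drive time courses have the advertised statistics", {
  n <- 4000
  d_on <- condition_drive("ongoing", n, base_rate = 0.002)
  d_gr <- condition_drive("grating", n, base_rate = 0.002)
  d_mv <- condition_drive("movie", n, base_rate = 0.002, seed = 5)
  expect_true(all(d_on == 0.002))
  expect_equal(mean(d_gr), 0.002, tolerance = 0.01)
  expect_equal(mean(d_mv), 0.002, tolerance = 1e-9)
  expect_gt(var(d_mv), var(d_on))
  expect_true(all(d_gr >= 0 & d_gr <= 1))
})

test_that("TSV and JSON writers round-trip", {
  r <- burst_raster(n_neurons = 5, n_bins = 60, seed = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(r, p)
  r2 <- read_matrix_tsv(p, as = "raster")
  expect_equal(r2$values, r$values, ignore_attr = TRUE)
  expect_equal(r2$bin_width, r$bin_width)
  expect_equal(r2$neuron_ids, r$neuron_ids)

  cfg <- critical_config(seed = 9, n_bins = 100, n_neurons = 20)
  pj <- withr::local_tempfile(fileext = ".json")
  write_config_json(cfg, pj)
  cfg2 <- read_config_json(pj)
  expect_equal(cfg2, cfg)
})
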