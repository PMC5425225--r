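test_that("a constant trace has zero dF/F and scaling leaves dF/F unchanged", {
  x <- rep(3.5, 100)
  expect_true(all(compute_dff(x, frame_rate = 4) == 0))
  withr::with_seed(1, {
    y <- 2 + abs(rnorm(200))
  })
  d1 <- compute_dff(y, frame_rate = 4)
  d2 <- compute_dff(7.3 * y, frame_rate = 4)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("sliding lower-half baseline matches direct recomputation", {
  # 41-frame trace with a single step, 4 Hz -> 40-frame window
  x <- c(rep(1, 25), rep(2, 16))
  got <- compute_dff(x, frame_rate = 4, window = 10, lower_fraction = 0.5)
  w <- 40
  n_low <- 20
  expected <- numeric(41)
  base <- numeric(41)
  for (t in w:41) {
    win <- x[(t - w + 1):t]
    base[t] <- mean(sort(win)[1:n_low])
  }
  base[1:(w - 1)] <- base[w]
  expected <- (x - base) / base
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("non-positive baselines are refused", {
  expect_error(compute_dff(rep(0, 100), frame_rate = 4), "baseline")
})

test_that("deconvolution concentrates a clean transient at its onset", {
  fr <- 4
  tr <- numeric(120)
  onset <- 30
  tr[onset:120] <- 0.5 * exp(-(0:(120 - onset)) / (fr * 0.8))
  s <- infer_spike_probability(tr, frame_rate = fr, decay_constant = 0.8,
                               lambda = 1e-6, max_iter = 2000)
  mass_near <- sum(s[(onset - 1):(onset + 1), 1]) / sum(s[, 1])
  expect_gte(mass_near, 0.9)
  # silent input stays silent
  expect_true(all(infer_spike_probability(numeric(50), frame_rate = fr) == 0))
})

test_that("population-RMS threshold matches the hand-computed value", {
  m <- matrix(0, 100, 10)  # 1000 entries, one of them 1
  m[5, 3] <- 1
  # theta = 3 * sqrt(1/1000) ~ 0.0949 < 1: the single event survives
  r <- threshold_spikes(m, k_sd = 3, frame_rate = 4)
  expect_equal(sum(r$values), 1)
  expect_equal(unname(r$values["n3", 5]), 1L)
  # scaling all probabilities leaves the binary output unchanged
  r2 <- threshold_spikes(0.037 * m, k_sd = 3, frame_rate = 4)
  expect_identical(r2$values, r$values)
})

test_that("raising the threshold never adds spikes", {
  withr::with_seed(7, {
    m <- matrix(abs(rnorm(600)), 200, 3)
  })
  r3 <- threshold_spikes(m, k_sd = 3)
  r4 <- threshold_spikes(m, k_sd = 4)
  expect_true(all(r4$values <= r3$values))
})

test_that("an all-flat probability matrix is a degenerate input", {
  expect_error(threshold_spikes(matrix(0, 10, 10)), "degenerate")
})

test_that("neuron exclusion drops the named columns and nothing else", {
  r <- burst_raster(n_neurons = 5, n_bins = 50, seed = 6)
  expect_identical(exclude_neurons(r, character()), r)
  r2 <- exclude_neurons(r, c("n2", "n4"))
  expect_equal(r2$neuron_ids, c("n1", "n3", "n5"))
  expect_equal(r2$values, r$values[c(1, 3, 5), ], ignore_attr = TRUE)
  expect_error(exclude_neurons(r, "nope"), "unknown neuron")
})

test_that("exclusion commutes with binarization on well-separated events", {
  # event amplitudes far above both pooled thresholds, noise far below
  withr::with_seed(9, {
    prob <- matrix(0.01 * runif(300), 60, 5)
    prob[cbind(sample.int(60, 20), sample.int(5, 20, replace = TRUE))] <- 1
  })
  colnames(prob) <- paste0("n", 1:5)
  drop2 <- c("n1", "n4")
  after <- exclude_neurons(threshold_spikes(prob, frame_rate = 4), drop2)
  before <- threshold_spikes(exclude_neurons(prob, drop2), frame_rate = 4)
  expect_identical(after$values, before$values)
  expect_identical(after$neuron_ids, before$neuron_ids)
})

test_that("spikes survive the full calcium round trip", {
  # 50-neuron low-rate fixture; 1 frame per 250 ms bin at 4 Hz
  withr::with_seed(42, {
    m <- matrix(rbinom(50 * 1200, 1, 0.02), 50, 1200)
  })
  r <- spike_raster(m, bin_width = 0.25)
  ca <- spikes_to_calcium(r, frame_rate = 4, decay_constant = 0.8,
                          amplitude = 0.25, noise_sd = 0.05, seed = 9,
                          baseline = 1)
  rec <- preprocess_traces(ca)
  true_m <- r$values
  rec_m <- rec$values[, seq_len(ncol(true_m)), drop = FALSE]
  near_hit <- function(from, to) {
    hits <- 0
    for (i in seq_len(nrow(from))) {
      fb <- which(from[i, ] == 1)
      tb <- which(to[i, ] == 1)
      if (length(fb) && length(tb)) {
        hits <- hits + sum(vapply(fb, function(t) any(abs(tb - t) <= 1),
                                  logical(1)))
      }
    }
    hits
  }
  recovery <- near_hit(true_m, rec_m) / sum(true_m)
  false_pos <- 1 - near_hit(rec_m, true_m) / max(1, sum(rec_m))
  expect_gte(recovery, 0.8)
  expect_lte(false_pos, 0.1)
})
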