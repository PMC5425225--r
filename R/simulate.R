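#' Branching-network configuration
#'
#' Parameters of the probabilistic branching network used to generate spike
#' rasters across dynamical regimes. Each neuron projects to
#' `connectivity_degree` fixed random targets; an active neuron transmits to
#' each target independently with probability `branching_parameter /
#' connectivity_degree`, so `branching_parameter` (sigma) is the expected
#' number of directly triggered descendants per active neuron. sigma = 1 is
#' the critical regime; < 1 subcritical, > 1 supercritical. Independently,
#' every neuron is externally activated each bin with probability
#' `drive_rate` (scalar, or one value per bin for time-varying drive).
#'
#' @param n_neurons number of neurons (positive integer).
#' @param branching_parameter sigma >= 0.
#' @param drive_rate external activation probability per neuron per bin, in
#'   \[0, 1\]; scalar or vector of length `n_bins`.
#' @param connectivity_degree fixed out-degree of every neuron
#'   (< `n_neurons`).
#' @param n_bins number of time bins to simulate.
#' @param bin_width bin width in seconds (one branching generation per bin).
#' @param seed integer seed; identical configs (including seed) give
#'   bit-identical rasters.
#' @return a `network_config` list.
#' @export
network_config <- function(n_neurons = 100, branching_parameter = 1,
                           drive_rate = 0.001, connectivity_degree = 10,
                           n_bins = 3000, bin_width = 0.25, seed = 1) {
  stopifnot(
    n_neurons >= 2, n_bins >= 1, bin_width > 0,
    branching_parameter >= 0,
    all(drive_rate >= 0), all(drive_rate <= 1),
    connectivity_degree >= 1, connectivity_degree < n_neurons
  )
  if (!(length(drive_rate) %in% c(1L, n_bins))) {
    stop("drive_rate must be scalar or length n_bins")
  }
  if (branching_parameter / connectivity_degree > 1) {
    stop("branching_parameter / connectivity_degree exceeds 1: ",
         "per-edge transmission is not a valid probability")
  }
  structure(
    list(n_neurons = as.integer(n_neurons),
         branching_parameter = branching_parameter,
         drive_rate = drive_rate,
         connectivity_degree = as.integer(connectivity_degree),
         n_bins = as.integer(n_bins), bin_width = bin_width,
         seed = as.integer(seed)),
    class = "network_config"
  )
}

#' Drive-rate time course for an emulated stimulus condition
#'
#' The three study conditions share identical recurrent dynamics (same sigma)
#' and differ only in the statistics of the external drive: constant
#' dark-level drive ("ongoing"), a periodic grating-like modulation
#' ("grating"), and naturalistic 1/f-like fluctuations ("movie").
#'
#' @param condition one of `"ongoing"`, `"grating"`, `"movie"`.
#' @param n_bins number of bins.
#' @param base_rate mean per-neuron per-bin drive probability.
#' @param bin_width seconds per bin (sets the grating period in bins).
#' @param period_s grating modulation period in seconds.
#' @param seed seed for the naturalistic fluctuations.
#' @return numeric vector of length `n_bins`, values in \[0, 1\].
#' @export
condition_drive <- function(condition = c("ongoing", "grating", "movie"),
                            n_bins, base_rate = 0.001, bin_width = 0.25,
                            period_s = 10, seed = 1) {
  condition <- match.arg(condition)
  t_idx <- seq_len(n_bins)
  d <- switch(condition,
    ongoing = rep(base_rate, n_bins),
    grating = base_rate * (1 + 0.8 * sin(2 * pi * t_idx * bin_width / period_s)),
    movie = {
      # smoothed log-normal fluctuations: heavy-ish tailed, positively
      # autocorrelated, mean pinned to base_rate
      z <- withr::with_seed(seed, stats::rnorm(n_bins))
      k <- max(3L, round(2 / bin_width))
      z <- stats::filter(z, rep(1 / k, k), sides = 1)
      z[is.na(z)] <- 0
      r <- exp(as.numeric(z))
      base_rate * r / mean(r)
    }
  )
  pmin(pmax(d, 0), 1)
}

#' Simulate the branching network
#'
#' Quenched random connectivity (drawn once from the seed, fixed for the run):
#' each neuron gets `connectivity_degree` distinct random targets. A neuron is
#' active in bin t+1 with probability `1 - (1 - p)^k * (1 - drive)`, where
#' `p = sigma / connectivity_degree` and `k` is its number of active
#' presynaptic partners in bin t.
#'
#' @param config a [network_config()].
#' @param initial_active optional integer indices of neurons forced active in
#'   bin 1 (in addition to drive), e.g. to seed single avalanches.
#' @return a [spike_raster()] of shape `n_neurons x n_bins`.
#' @export
simulate_branching_network <- function(config, initial_active = NULL) {
  stopifnot(inherits(config, "network_config"))
  N <- config$n_neurons
  Tn <- config$n_bins
  k_out <- config$connectivity_degree
  p_edge <- config$branching_parameter / config$connectivity_degree
  drive <- config$drive_rate
  if (length(drive) == 1L) drive <- rep(drive, Tn)

  withr::with_seed(config$seed, {
    # quenched connectivity: C[i, j] = 1 if i -> j
    conn <- matrix(FALSE, N, N)
    for (i in seq_len(N)) {
      tgt <- sample.int(N - 1L, k_out)  # no self-loops
      conn[i, tgt + (tgt >= i)] <- TRUE
    }
    raster <- matrix(0L, N, Tn)
    active <- stats::runif(N) < drive[1]
    if (!is.null(initial_active)) active[initial_active] <- TRUE
    raster[, 1L] <- as.integer(active)
    if (Tn > 1L) {
      for (t in 2:Tn) {
        if (any(active)) {
          k <- colSums(conn[active, , drop = FALSE])
          p_act <- 1 - (1 - p_edge)^k * (1 - drive[t])
        } else {
          p_act <- rep(drive[t], N)
        }
        active <- stats::runif(N) < p_act
        raster[, t] <- as.integer(active)
      }
    }
    spike_raster(raster, bin_width = config$bin_width)
  })
}

#' Render a spike raster into synthetic calcium fluorescence
#'
#' Forward model of somatic calcium-indicator signals: each spike adds an
#' instantaneous transient of `amplitude` (in dF/F units) that decays
#' exponentially with `decay_constant`, sampled on a frame grid at
#' `frame_rate`; white Gaussian noise of SD `noise_sd` is added per frame.
#' With `baseline = 0` (default) the returned values are the pure transient
#' signal in dF/F units; with `baseline > 0` the trace is
#' `baseline * (1 + signal + noise)`, i.e. raw fluorescence suitable for
#' [compute_dff()].
#'
#' @param raster a [spike_raster()].
#' @param frame_rate imaging frame rate in Hz (default 4.07, typical slow
#'   two-photon population imaging).
#' @param decay_constant indicator decay constant in seconds (default 0.8).
#' @param amplitude dF/F per spike.
#' @param noise_sd Gaussian noise SD in dF/F units.
#' @param seed integer seed for the noise.
#' @param baseline resting fluorescence level (arbitrary units); 0 keeps the
#'   trace in dF/F units.
#' @return a `calcium_traces` object: `values` (frames x neurons),
#'   `frame_rate`, `decay_constant`, `amplitude`, `noise_sd`, `baseline`.
#' @export
spikes_to_calcium <- function(raster, frame_rate = 4.07, decay_constant = 0.8,
                              amplitude = 0.2, noise_sd = 0, seed = 1,
                              baseline = 0) {
  stopifnot(inherits(raster, "spike_raster"))
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (decay_constant <= 0) stop("decay_constant must be positive")
  N <- nrow(raster$values)
  dur <- ncol(raster$values) * raster$bin_width
  n_frames <- max(1L, ceiling(dur * frame_rate))
  # assign each raster bin to the frame containing its start time
  bin_start <- (seq_len(ncol(raster$values)) - 1L) * raster$bin_width
  frame_of <- pmin(floor(bin_start * frame_rate) + 1L, n_frames)
  gamma <- exp(-1 / (frame_rate * decay_constant))
  sig <- matrix(0, n_frames, N)
  for (i in seq_len(N)) {
    impulses <- numeric(n_frames)
    sp <- raster$values[i, ]
    if (any(sp > 0)) {
      agg <- rowsum(as.numeric(sp), frame_of)
      impulses[as.integer(rownames(agg))] <- agg[, 1]
    }
    sig[, i] <- as.numeric(stats::filter(amplitude * impulses, gamma,
                                         method = "recursive"))
  }
  if (noise_sd > 0) {
    sig <- sig + withr::with_seed(seed,
      matrix(stats::rnorm(n_frames * N, sd = noise_sd), n_frames, N))
  }
  vals <- if (baseline > 0) baseline * (1 + sig) else sig
  colnames(vals) <- raster$neuron_ids
  structure(
    list(values = vals, frame_rate = frame_rate,
         decay_constant = decay_constant, amplitude = amplitude,
         noise_sd = noise_sd, baseline = baseline),
    class = "calcium_traces"
  )
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf("<calcium_traces> %d frames x %d neurons at %.3g Hz (decay %.3g s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate, x$decay_constant))
  invisible(x)
}

#' Shuffle spike times within each neuron
#'
#' Control for temporal structure: each neuron's spikes are relocated to
#' uniformly random distinct bins, exactly preserving every per-neuron spike
#' count (and hence all firing rates) while destroying inter-neuron
#' coordination. Large avalanches are abolished by this manipulation when the
#' original raster is near-critical.
#'
#' @param raster a [spike_raster()].
#' @param seed integer seed.
#' @return a [spike_raster()] of the same shape and per-row sums.
#' @export
shuffle_spike_times <- function(raster, seed = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  Tn <- ncol(raster$values)
  withr::with_seed(seed, {
    shuffled <- raster$values
    for (i in seq_len(nrow(shuffled))) {
      n_sp <- sum(shuffled[i, ])
      row <- integer(Tn)
      if (n_sp > 0) row[sample.int(Tn, n_sp)] <- 1L
      shuffled[i, ] <- row
    }
    spike_raster(shuffled, raster$bin_width, raster$neuron_ids)
  })
}

#' Write a network configuration as JSON
#' @param config a [network_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network configuration from JSON
#' @param path JSON file written by [write_config_json()].
#' @return a [network_config()].
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(network_config, x)
}
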