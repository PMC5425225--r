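#' Per-neuron interspike-interval statistics
#'
#' ISIs are differences of consecutive spike-bin times at the raster's
#' native resolution (irregularity is a single-neuron property, so no
#' re-binning). The coefficient of variation CV = SD(ISI)/mean(ISI) is
#' reported for neurons with at least `min_isis` intervals; all neurons get
#' a firing rate. CV > 1 marks spiking more irregular than a Poisson
#' process, the signature expected of a network near criticality. CV is
#' invariant under uniform time rescaling.
#'
#' @param raster a [spike_raster()].
#' @param min_isis minimum ISI count for a neuron to enter the CV summary.
#' @return a `spiketrain_stats`: `neurons` data.frame (`neuron_id`,
#'   `n_spikes`, `n_isis`, `isi_mean`, `isi_sd`, `cv`, `rate`), population
#'   `mean_cv`, `sem_cv`, `rate_skewness`, `n_eligible`, and `bin_width`.
#'   Zero eligible neurons gives NA summaries with a warning.
#' @export
compute_isi_stats <- function(raster, min_isis = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  bw <- raster$bin_width
  total_t <- ncol(raster$values) * bw
  rows <- lapply(seq_len(nrow(raster$values)), function(i) {
    t_sp <- which(raster$values[i, ] == 1L) * bw
    isi <- diff(t_sp)
    eligible <- length(isi) >= min_isis
    data.frame(
      neuron_id = raster$neuron_ids[i],
      n_spikes = length(t_sp), n_isis = length(isi),
      isi_mean = if (eligible) mean(isi) else NA_real_,
      isi_sd = if (eligible) stats::sd(isi) else NA_real_,
      cv = if (eligible) stats::sd(isi) / mean(isi) else NA_real_,
      rate = length(t_sp) / total_t
    )
  })
  neurons <- do.call(rbind, rows)
  cvs <- neurons$cv[!is.na(neurons$cv)]
  if (length(cvs) == 0L) {
    warning("no neuron has at least ", min_isis, " ISIs; CV summary is empty")
  }
  structure(
    list(neurons = neurons,
         mean_cv = if (length(cvs)) mean(cvs) else NA_real_,
         sem_cv = if (length(cvs) > 1) stats::sd(cvs) / sqrt(length(cvs))
                  else NA_real_,
         rate_skewness = e1071::skewness(neurons$rate),
         n_eligible = length(cvs), bin_width = bw),
    class = "spiketrain_stats"
  )
}

#' @export
print.spiketrain_stats <- function(x, ...) {
  cat(sprintf(
    "<spiketrain_stats> %d/%d neurons eligible; <CV> = %.3f +/- %.3f (SEM); rate skewness %.2f\n",
    x$n_eligible, nrow(x$neurons), x$mean_cv, x$sem_cv, x$rate_skewness))
  invisible(x)
}
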