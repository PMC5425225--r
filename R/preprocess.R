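#' Sliding-baseline dF/F normalization
#'
#' For each frame t the baseline b(t) is the mean of the lowest
#' `lower_fraction` of the samples in the trailing window `(t - window, t]`
#' (default: lower 50% of the previous 10 s). The output is
#' `(f(t) - b(t)) / b(t)`. Frames before the first complete window reuse the
#' first full window's baseline, keeping the output aligned with the input.
#' The result is invariant under multiplying the raw trace by any c > 0.
#'
#' @param trace numeric vector of raw nonnegative fluorescence, or a
#'   frames-by-neurons matrix (each column processed independently).
#' @param frame_rate sampling rate in Hz.
#' @param window baseline window length in seconds.
#' @param lower_fraction fraction of lowest samples averaged for the
#'   baseline.
#' @return dF/F series (or matrix) of the same length/shape.
#' @export
compute_dff <- function(trace, frame_rate, window = 10, lower_fraction = 0.5) {
  if (is.matrix(trace)) {
    out <- apply(trace, 2, compute_dff, frame_rate = frame_rate,
                 window = window, lower_fraction = lower_fraction)
    dimnames(out) <- dimnames(trace)
    return(out)
  }
  w <- max(2L, round(window * frame_rate))
  n <- length(trace)
  if (n <= w) stop("trace shorter than the baseline window")
  n_low <- max(1L, floor(w * lower_fraction))
  base <- numeric(n)
  for (t in w:n) {
    win <- trace[(t - w + 1L):t]
    base[t] <- mean(sort.int(win, partial = n_low)[seq_len(n_low)])
  }
  base[seq_len(w - 1L)] <- base[w]
  if (any(base <= 0)) {
    stop("non-positive baseline: input must be raw nonnegative fluorescence")
  }
  (trace - base) / base
}

#' Infer spike probability from dF/F by sparse non-negative deconvolution
#'
#' Solves, per neuron, `min_{s >= 0} ||y - K s||^2 + lambda * sum(s)` where K
#' is the causal exponential-decay kernel with the given decay constant
#' (discrete AR(1) impulse response), via projected FISTA with O(T) recursive
#' filters. This is a deliberately simple sparse deconvolution with the same
#' kernel assumption as fast non-negative methods used on calcium data. The
#' output is max-normalized per neuron, so entries lie in \[0, 1\] and each
#' non-silent neuron attains 1.
#'
#' @param dff numeric matrix frames x neurons (dF/F), or a vector for one
#'   neuron.
#' @param frame_rate frames per second.
#' @param decay_constant transient decay constant in seconds (default 0.8).
#' @param lambda L1 penalty; default `0.1 * sd(dff)` pooled over all entries.
#' @param max_iter,tol FISTA iteration cap and relative-change tolerance.
#' @return matrix (frames x neurons) of normalized spike probabilities.
#' @export
infer_spike_probability <- function(dff, frame_rate, decay_constant = 0.8,
                                    lambda = NULL, max_iter = 400,
                                    tol = 1e-8) {
  if (decay_constant <= 0) stop("decay_constant must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  y_mat <- if (is.matrix(dff)) dff else matrix(dff, ncol = 1)
  if (any(!is.finite(y_mat))) stop("dff must be finite")
  if (is.null(lambda)) lambda <- 0.1 * stats::sd(as.numeric(y_mat))
  gamma <- exp(-1 / (frame_rate * decay_constant))
  Tn <- nrow(y_mat)
  conv_fwd <- function(s) as.numeric(stats::filter(s, gamma, method = "recursive"))
  conv_adj <- function(r) rev(as.numeric(stats::filter(rev(r), gamma,
                                                       method = "recursive")))
  # Lipschitz bound for 2 K^T K: column sums of K bounded by 1/(1-gamma)
  L <- 2 / (1 - gamma)^2
  out <- matrix(0, Tn, ncol(y_mat))
  for (j in seq_len(ncol(y_mat))) {
    y <- y_mat[, j]
    if (all(y == 0)) next
    s <- z <- numeric(Tn)
    tk <- 1
    obj_old <- Inf
    for (it in seq_len(max_iter)) {
      grad <- 2 * conv_adj(conv_fwd(z) - y)
      s_new <- pmax(0, z - (grad + lambda) / L)
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- s_new + ((tk - 1) / tk_new) * (s_new - s)
      s <- s_new
      tk <- tk_new
      if (it %% 25L == 0L) {
        r <- conv_fwd(s) - y
        obj <- sum(r^2) + lambda * sum(s)
        if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(1, obj_old)) break
        obj_old <- obj
      }
    }
    out[, j] <- s
  }
  mx <- apply(out, 2, max)
  pos <- mx > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, mx[pos], "/")
  colnames(out) <- colnames(y_mat)
  out
}

#' Binarize spike probabilities at a population-SD threshold
#'
#' The threshold is `k_sd` times the population deviation about zero
#' (root-mean-square of all entries pooled across neurons); entries strictly
#' above it become 1. Measuring the deviation about 0 rather than the mean
#' follows the convention of thresholding "above 0"; set `about` to
#' `"mean"` for a centered SD instead. Scaling all probabilities by any
#' c > 0 leaves the output unchanged.
#'
#' @param prob matrix frames x neurons of spike probabilities.
#' @param k_sd threshold in population-SD units (default 3).
#' @param frame_rate frames per second (sets the raster bin width).
#' @param about `"zero"` (RMS, default) or `"mean"`.
#' @return a [spike_raster()] (neurons x frames) at frame resolution.
#' @export
threshold_spikes <- function(prob, k_sd = 3, frame_rate = 1,
                             about = c("zero", "mean")) {
  about <- match.arg(about)
  if (!is.matrix(prob) || length(prob) == 0L) stop("prob must be a nonempty matrix")
  pooled <- as.numeric(prob)
  sd0 <- if (about == "zero") sqrt(mean(pooled^2)) else stats::sd(pooled)
  if (sd0 == 0) stop("degenerate input: pooled SD is zero, no events inferable")
  theta <- k_sd * sd0
  spike_raster(t(1L * (prob > theta)), bin_width = 1 / frame_rate,
               neuron_ids = colnames(prob))
}

#' Full fluorescence-to-raster preprocessing chain
#'
#' Convenience wrapper: dF/F (only if `baseline_normalize`), sparse
#' deconvolution, population-SD thresholding, optional neuron exclusion.
#'
#' @param traces a `calcium_traces` object or numeric frames x neurons
#'   matrix.
#' @param frame_rate required if `traces` is a bare matrix.
#' @param decay_constant kernel decay in seconds.
#' @param k_sd threshold level in population SDs.
#' @param exclusion_list neuron labels to drop before processing.
#' @param baseline_normalize apply [compute_dff()] first (set `FALSE` when
#'   the input is already dF/F or zero-baselined).
#' @param window,lower_fraction passed to [compute_dff()].
#' @return a [spike_raster()] at frame resolution.
#' @export
preprocess_traces <- function(traces, frame_rate = NULL, decay_constant = 0.8,
                              k_sd = 3, exclusion_list = character(),
                              baseline_normalize = TRUE, window = 10,
                              lower_fraction = 0.5) {
  if (inherits(traces, "calcium_traces")) {
    frame_rate <- traces$frame_rate
    m <- traces$values
  } else {
    if (is.null(frame_rate)) stop("frame_rate required for matrix input")
    m <- as.matrix(traces)
  }
  if (length(exclusion_list)) m <- exclude_neurons(m, exclusion_list)
  dff <- if (baseline_normalize) {
    compute_dff(m, frame_rate, window, lower_fraction)
  } else m
  prob <- infer_spike_probability(dff, frame_rate, decay_constant)
  threshold_spikes(prob, k_sd = k_sd, frame_rate = frame_rate)
}
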