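#' Zero-lag pairwise Pearson correlations of binarized spike trains
#'
#' Pearson coefficients per neuron pair on the binary time series at native
#' raster resolution. Constant (all-0 or all-1) trains have no defined
#' correlation; those entries are NA and flagged in the `defined` matrix
#' rather than silently zeroed.
#'
#' @param raster a [spike_raster()] with >= 2 neurons and >= 2 bins.
#' @param condition optional condition label carried in the result.
#' @return a `correlation_matrix`: `values` (symmetric, unit diagonal for
#'   non-constant trains), `defined` (logical), `neuron_ids`, `condition`.
#' @export
pairwise_correlation <- function(raster, condition = NA_character_) {
  stopifnot(inherits(raster, "spike_raster"))
  if (nrow(raster$values) < 2 || ncol(raster$values) < 2) {
    stop("need at least 2 neurons and 2 bins")
  }
  x <- t(raster$values)
  r <- suppressWarnings(stats::cor(x))
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  defined <- !outer(const, const, "|")
  diag(defined) <- !const
  r[!defined] <- NA_real_
  diag(r)[!const] <- 1
  dimnames(r) <- list(raster$neuron_ids, raster$neuron_ids)
  structure(
    list(values = r, defined = defined, neuron_ids = raster$neuron_ids,
         condition = condition),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "<correlation_matrix> %d neurons%s; mean off-diagonal r = %.4f (%d undefined pairs)\n",
    length(x$neuron_ids),
    if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
    mean(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' Rate-matched significance of pairwise correlations
#'
#' Per pair, the null distribution of the Pearson coefficient between two
#' independent Bernoulli trains matched to the neurons' mean rates and
#' recording length. The null is sampled exactly without materializing
#' trains: with per-train counts `a ~ Bin(T, p1)` and `b ~ Bin(T, p2)`, the
#' co-active count is `m ~ Hypergeometric(a, T - a, b)` (random placement),
#' and `r = (T m - a b) / sqrt(a (T - a) b (T - b))`. The test is two-sided;
#' a pair is significant when the fraction of |null r| >= |observed r| falls
#' below `p_threshold` (default 0.1; no multiple-testing correction, an
#' exploratory per-pair rule). Pairs involving a zero-rate (or saturated)
#' neuron are untestable and flagged NA.
#'
#' @param cmat a [pairwise_correlation()] result.
#' @param raster the raster the matrix was computed from.
#' @param n_surrogates null draws per pair.
#' @param p_threshold per-pair significance level.
#' @param seed optional integer seed.
#' @return the `correlation_matrix` with a `significant` logical matrix
#'   (NA where untestable) and a `p_values` matrix added.
#' @export
correlation_significance <- function(cmat, raster, n_surrogates = 1000,
                                     p_threshold = 0.1, seed = NULL) {
  stopifnot(inherits(cmat, "correlation_matrix"),
            inherits(raster, "spike_raster"))
  Tn <- ncol(raster$values)
  counts <- rowSums(raster$values)
  N <- length(counts)
  run <- function() {
    pm <- matrix(NA_real_, N, N)
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        robs <- cmat$values[i, j]
        if (is.na(robs) || counts[i] %in% c(0L, Tn) || counts[j] %in% c(0L, Tn)) next
        a <- stats::rbinom(n_surrogates, Tn, counts[i] / Tn)
        b <- stats::rbinom(n_surrogates, Tn, counts[j] / Tn)
        ok <- a > 0 & a < Tn & b > 0 & b < Tn
        if (!any(ok)) next
        a <- a[ok]; b <- b[ok]
        m <- stats::rhyper(length(a), a, Tn - a, b)
        # doubles: the count products overflow 32-bit integers
        a <- as.numeric(a); b <- as.numeric(b); m <- as.numeric(m)
        rnull <- (Tn * m - a * b) / sqrt(a * (Tn - a) * b * (Tn - b))
        pm[i, j] <- pm[j, i] <- mean(abs(rnull) >= abs(robs))
      }
    }
    pm
  }
  pvals <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dimnames(pvals) <- dimnames(cmat$values)
  cmat$p_values <- pvals
  cmat$significant <- pvals < p_threshold
  cmat$p_threshold <- p_threshold
  cmat
}

#' Neuron ordering from complete-linkage clustering
#'
#' Agglomerates neurons on the distance `1 - r` (anticorrelated pairs are
#' maximally distant) with complete linkage and returns the dendrogram leaf
#' order. Neurons with undefined correlations are appended last,
#' unclustered. Deterministic given the input.
#'
#' @param cmat a [pairwise_correlation()] result.
#' @return integer permutation of neuron indices (leaf order first, then
#'   undefined neurons in original order).
#' @export
cluster_order <- function(cmat) {
  stopifnot(inherits(cmat, "correlation_matrix"))
  # clusterable = non-constant train (pairwise r defined among all of them)
  ok <- diag(cmat$defined)
  idx <- which(ok)
  if (length(idx) < 2) return(seq_along(cmat$neuron_ids))
  d <- stats::as.dist(1 - cmat$values[idx, idx])
  h <- stats::hclust(d, method = "complete")
  c(idx[h$order], which(!ok))
}

#' Reorder a correlation matrix by a reference neuron order
#'
#' Rows and columns are permuted to the reference ordering (as computed on
#' another condition, e.g. grating stimulation), so cross-condition
#' reorganization of the correlation structure is visible. Neurons present
#' in the reference but absent from this matrix are rendered as blank (NA)
#' rows/columns.
#'
#' @param cmat a [pairwise_correlation()] result.
#' @param reference_order character vector of neuron ids (or integer indices
#'   into `cmat$neuron_ids`) defining the target order.
#' @return a `correlation_matrix` in the reference order.
#' @export
reorder_by_reference <- function(cmat, reference_order) {
  stopifnot(inherits(cmat, "correlation_matrix"))
  ids <- if (is.numeric(reference_order)) cmat$neuron_ids[reference_order]
         else as.character(reference_order)
  n <- length(ids)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  def <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  present <- ids[ids %in% cmat$neuron_ids]
  out[present, present] <- cmat$values[present, present]
  def[present, present] <- cmat$defined[present, present]
  structure(
    list(values = out, defined = def, neuron_ids = ids,
         condition = cmat$condition),
    class = "correlation_matrix"
  )
}
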