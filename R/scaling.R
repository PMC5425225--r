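#' Mean avalanche size per duration
#'
#' @param avalanches an `avalanche_set` (or data.frame with `size` and
#'   `duration_bins`).
#' @return data.frame with `duration` (integer bins, sorted ascending) and
#'   `mean_size`.
#' @export
mean_size_by_duration <- function(avalanches) {
  if (nrow(avalanches) == 0L) stop("empty avalanche set")
  agg <- stats::aggregate(size ~ duration_bins, data = as.data.frame(avalanches),
                          FUN = mean)
  agg <- agg[order(agg$duration_bins), ]
  data.frame(duration = as.integer(agg$duration_bins), mean_size = agg$size)
}

#' Fit the size-duration scaling exponent beta
#'
#' Ordinary least squares of `log10(mean size)` on `log10(duration)` over
#' the per-duration means (one point per distinct duration, unweighted),
#' optionally restricted to durations within `fit_range` — typically the
#' `[s_min, s_max]` support of the duration power-law fit, so the regression
#' is evaluated on the power-law body only.
#'
#' @param durations integer durations (bins).
#' @param mean_sizes mean avalanche size at each duration.
#' @param fit_range optional `c(lo, hi)` duration window.
#' @return fitted slope `beta`.
#' @export
fit_beta <- function(durations, mean_sizes, fit_range = NULL) {
  stopifnot(length(durations) == length(mean_sizes))
  keep <- rep(TRUE, length(durations))
  if (!is.null(fit_range)) {
    keep <- durations >= fit_range[1] & durations <= fit_range[2]
  }
  d <- durations[keep]; m <- mean_sizes[keep]
  if (length(unique(d)) < 3) stop("need at least 3 distinct durations in range")
  unname(stats::coef(stats::lm(log10(m) ~ log10(d)))[2])
}

#' Scaling exponent predicted from the size and duration exponents
#'
#' At criticality, mean avalanche size scales with duration as
#' `<S> ~ D^beta` with `beta = (alpha - 1)/(tau - 1)`, where tau is the size
#' exponent and alpha the duration exponent.
#'
#' @param tau size-distribution exponent(s) (> 1); vectorized.
#' @param alpha duration-distribution exponent(s).
#' @return predicted beta.
#' @export
predicted_beta <- function(tau, alpha) {
  if (any(tau <= 1)) stop("predicted beta undefined for tau <= 1")
  (alpha - 1) / (tau - 1)
}

#' Full scaling-relation check for one avalanche set
#'
#' Computes the per-duration mean sizes, fits beta by log-log regression
#' (restricted to the duration fit's support when supplied), and compares it
#' with the beta predicted from the two power-law exponents.
#'
#' @param avalanches an `avalanche_set`.
#' @param size_fit,duration_fit `powerlaw_fit` objects for sizes and
#'   durations (duration fit's support sets the regression window when
#'   present).
#' @return a `scaling_result`: list with `durations`, `mean_sizes`,
#'   `beta_fitted`, `beta_predicted`, `fit_range`.
#' @export
scaling_relation <- function(avalanches, size_fit, duration_fit) {
  msd <- mean_size_by_duration(avalanches)
  rng <- if (!is.null(duration_fit)) c(duration_fit$s_min, duration_fit$s_max)
         else NULL
  bf <- fit_beta(msd$duration, msd$mean_size, fit_range = rng)
  bp <- predicted_beta(size_fit$exponent, duration_fit$exponent)
  structure(
    list(durations = msd$duration, mean_sizes = msd$mean_size,
         beta_fitted = bf, beta_predicted = bp, fit_range = rng),
    class = "scaling_result"
  )
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> beta fitted %.3f vs predicted %.3f (%d durations)\n",
              x$beta_fitted, x$beta_predicted, length(x$durations)))
  invisible(x)
}
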