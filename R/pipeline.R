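# deterministic sub-seed from a master seed and a stage name, kept < 2^31
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 10007 + h) %% .Machine$integer.max)
}

#' Pipeline run configuration
#'
#' One entry per condition: either a simulator [network_config()] or a path
#' to a time-by-neuron TSV (`input`, with `input_type` `"raster"` or
#' `"traces"`). All stage parameters carry the study defaults: 250 ms
#' avalanche bins, 3-SD spike threshold, 0.8 s decay, s_min candidates 1:3,
#' 1000 surrogates and 1000 bootstrap resamples, GOF level 0.05, correlation
#' p threshold 0.1. Every stochastic stage derives its seed from the master
#' seed and the stage name.
#'
#' @param conditions named list; each element a list with either `config`
#'   (a `network_config`) or `input` + `input_type`, and optionally
#'   `exclusion_list`.
#' @param bin_width avalanche analysis bin (seconds).
#' @param k_sd spike-probability threshold (population SDs).
#' @param decay_constant calcium kernel decay (seconds).
#' @param s_min_candidates candidate minimum sizes for power-law fits.
#' @param n_surrogates GOF surrogates per fit.
#' @param n_boot bootstrap resamples per fit (0 skips the bootstrap).
#' @param gof_alpha GOF rejection level.
#' @param corr_p_threshold per-pair correlation significance level.
#' @param run_correlations compute the correlation stage (quadratic in
#'   neurons; can be disabled for large batches).
#' @param seed master seed.
#' @param out_dir output directory for artifacts, or NULL to skip writing.
#' @return a `run_config` list.
#' @export
run_config <- function(conditions, bin_width = 0.25, k_sd = 3,
                       decay_constant = 0.8, s_min_candidates = 1:3,
                       n_surrogates = 1000, n_boot = 1000, gof_alpha = 0.05,
                       corr_p_threshold = 0.1, run_correlations = TRUE,
                       seed = 1, out_dir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  structure(
    list(conditions = conditions, bin_width = bin_width, k_sd = k_sd,
         decay_constant = decay_constant,
         s_min_candidates = s_min_candidates, n_surrogates = n_surrogates,
         n_boot = n_boot, gof_alpha = gof_alpha,
         corr_p_threshold = corr_p_threshold,
         run_correlations = run_correlations,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

condition_raster <- function(cond, cfg, name) {
  if (!is.null(cond$config)) {
    simulate_branching_network(cond$config)
  } else if (!is.null(cond$input)) {
    type <- if (is.null(cond$input_type)) "raster" else cond$input_type
    if (type == "raster") {
      read_matrix_tsv(cond$input, as = "raster")
    } else {
      m <- read_matrix_tsv(cond$input, as = "traces")
      preprocess_traces(m, frame_rate = attr(m, "frame_rate"),
                        decay_constant = cfg$decay_constant, k_sd = cfg$k_sd)
    }
  } else {
    stop("condition '", name, "' has neither a simulator config nor an input path")
  }
}

#' Run the full avalanche-criticality pipeline
#'
#' Per condition: obtain the raster (simulate, read, or preprocess traces),
#' apply the exclusion list, compute network activity and avalanches, fit
#' truncated power laws to sizes and durations, test goodness of fit,
#' bootstrap exponent SDs, evaluate the scaling relation, compute ISI
#' statistics and (optionally) the correlation matrix. A failed stage is
#' recorded in the report's `skipped` field and the remaining conditions
#' continue. With `shuffle_control = TRUE` each condition is re-analyzed on
#' a spike-time-shuffled raster.
#'
#' @param cfg a [run_config()].
#' @param shuffle_control also analyze shuffled-raster controls.
#' @return named list of condition reports (class `condition_report`), with
#'   shuffle controls under `<name>_shuffled`.
#' @export
run_pipeline <- function(cfg, shuffle_control = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  reports <- list()
  for (name in names(cfg$conditions)) {
    cond <- cfg$conditions[[name]]
    raster <- condition_raster(cond, cfg, name)
    if (!is.null(cond$exclusion_list)) {
      raster <- exclude_neurons(raster, cond$exclusion_list)
    }
    reports[[name]] <- analyze_condition(raster, cfg, name)
    if (shuffle_control) {
      sh <- shuffle_spike_times(raster, seed = derive_seed(cfg$seed,
                                                           paste0(name, "/shuffle")))
      reports[[paste0(name, "_shuffled")]] <-
        analyze_condition(sh, cfg, paste0(name, "_shuffled"))
    }
  }
  reports
}

analyze_condition <- function(raster, cfg, name) {
  skipped <- character()
  try_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      skipped <<- c(skipped, paste0(label, ": ", conditionMessage(e)))
      NULL
    })
  }
  act <- network_activity(raster, bin_width = cfg$bin_width)
  av <- extract_avalanches(act)
  fit_one <- function(x, label) {
    f <- try_stage(label, fit_truncated_power_law(
      x, s_min_candidates = cfg$s_min_candidates))
    if (!is.null(f)) {
      f <- try_stage(paste0(label, "/gof"), goodness_of_fit_test(
        f, n_surrogates = cfg$n_surrogates,
        seed = derive_seed(cfg$seed, paste0(name, "/", label, "/gof")),
        alpha = cfg$gof_alpha)) %||% f
      if (cfg$n_boot > 0) {
        bs <- try_stage(paste0(label, "/bootstrap"), bootstrap_exponent_sd(
          x, n_boot = cfg$n_boot,
          seed = derive_seed(cfg$seed, paste0(name, "/", label, "/boot")),
          s_min_candidates = cfg$s_min_candidates))
        if (!is.null(bs)) f$exponent_sd <- bs$sd
      }
    }
    f
  }
  size_fit <- fit_one(av$size, "size_fit")
  dur_fit <- fit_one(av$duration_bins, "duration_fit")
  scaling <- if (!is.null(size_fit) && !is.null(dur_fit)) {
    try_stage("scaling", scaling_relation(av, size_fit, dur_fit))
  }
  isi <- try_stage("isi", compute_isi_stats(raster))
  corr <- NULL
  if (isTRUE(cfg$run_correlations)) {
    corr <- try_stage("correlation", {
      cm <- pairwise_correlation(raster, condition = name)
      correlation_significance(cm, raster, n_surrogates = cfg$n_surrogates,
                               p_threshold = cfg$corr_p_threshold,
                               seed = derive_seed(cfg$seed, paste0(name, "/corr")))
    })
  }
  rep <- structure(
    list(condition = name, n_neurons = nrow(raster$values),
         n_bins = ncol(raster$values), activity = act, avalanches = av,
         size_fit = size_fit, duration_fit = dur_fit, scaling = scaling,
         isi_stats = isi, correlations = corr, skipped = skipped),
    class = "condition_report"
  )
  if (!is.null(cfg$out_dir)) write_condition_report(rep, cfg$out_dir)
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("== condition '%s' (%d neurons, %d bins) ==\n",
              x$condition, x$n_neurons, x$n_bins))
  cat(sprintf("  avalanches: %d (threshold %g)\n", nrow(x$avalanches),
              attr(x$avalanches, "threshold")))
  if (!is.null(x$size_fit)) { cat("  size "); print(x$size_fit) }
  if (!is.null(x$duration_fit)) { cat("  duration "); print(x$duration_fit) }
  if (!is.null(x$scaling)) { cat("  "); print(x$scaling) }
  if (!is.null(x$isi_stats)) { cat("  "); print(x$isi_stats) }
  if (length(x$skipped)) {
    cat("  skipped stages:\n")
    for (s in x$skipped) cat("   - ", s, "\n")
  }
  invisible(x)
}

write_condition_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_avalanches_csv(rep$avalanches,
                       file.path(out_dir, paste0(rep$condition, "_avalanches.csv")))
  to_fit <- function(f) if (is.null(f)) NULL else list(
    exponent = f$exponent, s_min = f$s_min, s_max = f$s_max, ks = f$ks,
    n_av = f$n_av, gof_p = f$gof_p, exponent_sd = f$exponent_sd,
    converged = f$converged, n_excluded_tail = length(f$excluded_tail))
  js <- list(
    condition = rep$condition, n_neurons = rep$n_neurons,
    n_bins = rep$n_bins, n_avalanches = nrow(rep$avalanches),
    activity_threshold = attr(rep$avalanches, "threshold"),
    size_fit = to_fit(rep$size_fit), duration_fit = to_fit(rep$duration_fit),
    scaling = if (!is.null(rep$scaling)) list(
      beta_fitted = rep$scaling$beta_fitted,
      beta_predicted = rep$scaling$beta_predicted) else NULL,
    mean_cv = if (!is.null(rep$isi_stats)) rep$isi_stats$mean_cv else NULL,
    sem_cv = if (!is.null(rep$isi_stats)) rep$isi_stats$sem_cv else NULL,
    rate_skewness = if (!is.null(rep$isi_stats)) rep$isi_stats$rate_skewness
                    else NULL,
    skipped = rep$skipped)
  jsonlite::write_json(js, file.path(out_dir, paste0(rep$condition, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(rep)
}

#' Paired comparison of exponents between two conditions
#'
#' Two-sided t-test on per-subject exponent differences between two named
#' conditions (paired by default, since each subject contributes one
#' exponent per condition). Degenerate zero-variance differences are handled
#' explicitly: all-zero differences give t = 0, p = 1; a constant nonzero
#' shift gives p = 0.
#'
#' @param exponents_a,exponents_b numeric vectors of per-subject exponents
#'   for the two conditions, aligned by `subjects`.
#' @param subjects subject labels (must be identical and aligned across
#'   conditions).
#' @param paired paired (default) or two-sample Welch test.
#' @return list with `t`, `p`, `df`, `mean_difference`, `n`.
#' @export
compare_exponents <- function(exponents_a, exponents_b, subjects = NULL,
                              paired = TRUE) {
  if (length(exponents_a) != length(exponents_b)) {
    stop("pairing error: conditions have different numbers of subjects")
  }
  if (!is.null(subjects) && anyDuplicated(subjects)) {
    stop("pairing error: duplicated subject labels")
  }
  if (length(exponents_a) < 3) stop("need at least 3 paired subjects")
  if (paired) {
    d <- exponents_a - exponents_b
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        return(list(t = 0, p = 1, df = length(d) - 1, mean_difference = 0,
                    n = length(d)))
      }
      return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                  mean_difference = mean(d), n = length(d)))
    }
    tt <- stats::t.test(d)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), mean_difference = mean(d), n = length(d))
  } else {
    tt <- stats::t.test(exponents_a, exponents_b)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter),
         mean_difference = mean(exponents_a) - mean(exponents_b),
         n = length(exponents_a))
  }
}
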