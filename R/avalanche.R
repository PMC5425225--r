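#' Network activity: population spike count per time bin
#'
#' Re-bins a raster to `bin_width` (default 250 ms) and counts, per bin,
#' either the number of neurons with at least one spike frame in the bin
#' (`rule = "neuron"`, default) or the total number of spike frames
#' (`rule = "sum"`). At typical slow imaging rates one 250 ms bin holds about
#' one frame and the two rules coincide. The avalanche threshold is set to
#' the median of the counts.
#'
#' @param raster a [spike_raster()] whose bin width divides `bin_width`
#'   (ratio within 1% of an integer).
#' @param bin_width analysis bin width in seconds.
#' @param rule counting rule within a bin, `"neuron"` or `"sum"`.
#' @return a `network_activity` object: `counts` (integer per bin),
#'   `bin_width`, `threshold` (median), `rule`.
#' @export
network_activity <- function(raster, bin_width = 0.25,
                             rule = c("neuron", "sum")) {
  rule <- match.arg(rule)
  stopifnot(inherits(raster, "spike_raster"))
  if (raster$bin_width > bin_width * (1 + 0.01)) {
    stop("raster resolution is coarser than the requested bin width")
  }
  ratio <- bin_width / raster$bin_width
  m <- round(ratio)
  if (abs(ratio - m) > 0.01 * m) {
    stop(sprintf(
      "bin_width (%g s) is not an integer multiple of raster resolution (%g s)",
      bin_width, raster$bin_width))
  }
  n_full <- ncol(raster$values) %/% m
  if (n_full < 1L) stop("raster too short for one analysis bin")
  grp <- rep(seq_len(n_full), each = m)
  v <- raster$values[, seq_len(n_full * m), drop = FALSE]
  # per neuron per bin: spike-frame count, then apply the counting rule
  per_bin <- t(apply(v, 1, function(row) {
    as.numeric(rowsum(row, grp))
  }))
  counts <- if (rule == "neuron") colSums(per_bin >= 1) else colSums(per_bin)
  counts <- as.integer(counts)
  structure(
    list(counts = counts, bin_width = bin_width,
         threshold = stats::median(counts), rule = rule),
    class = "network_activity"
  )
}

#' @export
print.network_activity <- function(x, ...) {
  cat(sprintf("<network_activity> %d bins of %g s, median threshold %g\n",
              length(x$counts), x$bin_width, x$threshold))
  invisible(x)
}

#' Segment network activity into neuronal avalanches
#'
#' An avalanche is a maximal run of consecutive bins whose counts are
#' strictly above the threshold (default: the median of the activity). Its
#' size S is the integrated activity over the run (raw sum by default;
#' `integrate = "excess"` subtracts the threshold) and its duration D the run
#' length in bins. Runs touching the first or last bin of the recording have
#' no observed crossing and are discarded.
#'
#' @param activity a [network_activity()] object (or integer vector of
#'   counts, in which case `threshold` defaults to its median).
#' @param threshold override the stored threshold.
#' @param integrate `"raw"` (default) or `"excess"` (threshold-subtracted).
#' @return an `avalanche_set`: data.frame with columns `start_bin`,
#'   `end_bin`, `size`, `duration_bins`, `duration_s`; attributes
#'   `bin_width`, `threshold`. Empty (zero rows) when the activity never
#'   crosses the threshold.
#' @export
extract_avalanches <- function(activity, threshold = NULL,
                               integrate = c("raw", "excess")) {
  integrate <- match.arg(integrate)
  if (is.numeric(activity) && is.null(dim(activity))) {
    activity <- structure(list(counts = as.integer(activity), bin_width = NA_real_,
                               threshold = stats::median(activity)),
                          class = "network_activity")
  }
  stopifnot(inherits(activity, "network_activity"))
  thr <- if (is.null(threshold)) activity$threshold else threshold
  counts <- activity$counts
  above <- counts > thr
  empty <- data.frame(start_bin = integer(), end_bin = integer(),
                      size = numeric(), duration_bins = integer(),
                      duration_s = numeric())
  if (!any(above)) {
    return(structure(empty, bin_width = activity$bin_width, threshold = thr,
                     class = c("avalanche_set", "data.frame")))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(counts)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) {
    return(structure(empty, bin_width = activity$bin_width, threshold = thr,
                     class = c("avalanche_set", "data.frame")))
  }
  size <- mapply(function(s, e) {
    x <- counts[s:e]
    if (integrate == "excess") sum(x - thr) else sum(x)
  }, starts, ends)
  dur <- ends - starts + 1L
  structure(
    data.frame(start_bin = starts, end_bin = ends, size = size,
               duration_bins = dur, duration_s = dur * activity$bin_width),
    bin_width = activity$bin_width, threshold = thr,
    class = c("avalanche_set", "data.frame")
  )
}

#' Write an avalanche set as CSV
#' @param avalanches an `avalanche_set`.
#' @param path output path (convention:
#'   `<subject>_<condition>_avalanches.csv`).
#' @return `path`, invisibly.
#' @export
write_avalanches_csv <- function(avalanches, path) {
  stopifnot(inherits(avalanches, "avalanche_set"))
  utils::write.csv(as.data.frame(avalanches), path, row.names = FALSE)
  invisible(path)
}
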