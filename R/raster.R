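#' Construct a spike raster
#'
#' The central container of the pipeline: a binary neurons-by-time-bins matrix
#' together with its temporal resolution. Rows are neurons, columns are time
#' bins of width `bin_width` seconds.
#'
#' @param values binary matrix (neurons x time bins); entries must be 0 or 1.
#' @param bin_width width of one time bin in seconds (> 0).
#' @param neuron_ids optional character labels, one per row. Defaults to
#'   `"n1"`, `"n2"`, ...
#' @return an object of class `spike_raster` with elements `values`,
#'   `bin_width`, `neuron_ids`.
#' @export
spike_raster <- function(values, bin_width, neuron_ids = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) {
    stop("spike raster entries must be binary (0/1)")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive scalar (seconds)")
  }
  if (is.null(neuron_ids)) {
    neuron_ids <- paste0("n", seq_len(nrow(values)))
  }
  if (length(neuron_ids) != nrow(values)) {
    stop("neuron_ids must match the number of rows")
  }
  storage.mode(values) <- "integer"
  rownames(values) <- neuron_ids
  structure(
    list(values = values, bin_width = bin_width,
         neuron_ids = as.character(neuron_ids)),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %d neurons x %d bins (%.4g s/bin, %.1f s total), %d spikes\n",
    nrow(x$values), ncol(x$values), x$bin_width,
    ncol(x$values) * x$bin_width, sum(x$values)
  ))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$values)

#' Total spike count of a raster
#' @param raster a `spike_raster`.
#' @return integer spike count.
#' @export
n_spikes <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  sum(raster$values)
}

#' Write a raster or trace matrix as delimited text
#'
#' Output is TSV with a leading `time` column (seconds, start of each bin or
#' frame) and one column per neuron, headed by the neuron labels. Rasters are
#' transposed to time-by-neuron on disk.
#'
#' @param x a `spike_raster` or `calcium_traces` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "spike_raster")) {
    m <- t(x$values)
    tm <- (seq_len(nrow(m)) - 1L) * x$bin_width
    ids <- x$neuron_ids
  } else if (inherits(x, "calcium_traces")) {
    m <- x$values
    tm <- (seq_len(nrow(m)) - 1L) / x$frame_rate
    ids <- colnames(m)
    if (is.null(ids)) ids <- paste0("n", seq_len(ncol(m)))
  } else {
    stop("x must be a spike_raster or calcium_traces object")
  }
  df <- data.frame(time = tm, m, check.names = FALSE)
  names(df) <- c("time", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-by-neuron TSV matrix
#'
#' Inverse of [write_matrix_tsv()]. The first column must be time in seconds
#' on a regular grid; remaining columns are neurons.
#'
#' @param path file path.
#' @param as one of `"raster"` (binary values expected; returns a
#'   `spike_raster`) or `"traces"` (returns a plain numeric matrix time x
#'   neuron with attributes `frame_rate` and `neuron_ids`).
#' @return see `as`.
#' @export
read_matrix_tsv <- function(path, as = c("raster", "traces")) {
  as <- match.arg(as)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  tm <- df[[1]]
  if (length(tm) < 2L) stop("need at least two time points")
  dt <- diff(tm)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("time column must be on a regular grid")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  ids <- colnames(m)
  if (as == "raster") {
    spike_raster(t(m), bin_width = dt[1], neuron_ids = ids)
  } else {
    structure(m, frame_rate = 1 / dt[1], neuron_ids = ids)
  }
}

#' Drop named neurons from a raster or trace matrix
#'
#' Replaces the by-eye exclusion of noisy cells with an explicit, auditable
#' label list. Order of the remaining neurons is preserved.
#'
#' @param x a `spike_raster`, a `calcium_traces` object, or a matrix with
#'   neuron columns.
#' @param exclusion_list character vector of neuron labels to drop (may be
#'   empty).
#' @return same type as `x` with the named neurons removed.
#' @export
exclude_neurons <- function(x, exclusion_list = character()) {
  exclusion_list <- as.character(exclusion_list)
  if (length(exclusion_list) == 0L) return(x)
  if (inherits(x, "spike_raster")) {
    miss <- setdiff(exclusion_list, x$neuron_ids)
    if (length(miss)) stop("unknown neuron label(s): ", paste(miss, collapse = ", "))
    keep <- !(x$neuron_ids %in% exclusion_list)
    spike_raster(x$values[keep, , drop = FALSE], x$bin_width,
                 x$neuron_ids[keep])
  } else if (inherits(x, "calcium_traces")) {
    ids <- colnames(x$values)
    miss <- setdiff(exclusion_list, ids)
    if (length(miss)) stop("unknown neuron label(s): ", paste(miss, collapse = ", "))
    x$values <- x$values[, !(ids %in% exclusion_list), drop = FALSE]
    x
  } else if (is.matrix(x)) {
    ids <- colnames(x)
    if (is.null(ids)) stop("matrix must have neuron column names")
    miss <- setdiff(exclusion_list, ids)
    if (length(miss)) stop("unknown neuron label(s): ", paste(miss, collapse = ", "))
    x[, !(ids %in% exclusion_list), drop = FALSE]
  } else {
    stop("unsupported input type")
  }
}
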