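#' Gate transfected cells
#'
#' Keeps cells whose gene-dosage reporter fluorescence exceeds a threshold,
#' by default the 99.9th percentile of an untransfected control's reporter
#' channel.
#'
#' @param dataset An `eq_flow_dataset`.
#' @param control An untransfected `eq_flow_dataset`, or a single numeric
#'   reporter threshold.
#' @param percentile Control percentile defining the threshold
#'   (default 0.999).
#' @return The gated `eq_flow_dataset` with attribute `gated_fraction` and
#'   `threshold`. An empty gate is returned (with a warning), not an error.
#' @export
gate_transfected <- function(dataset, control, percentile = 0.999) {
  stopifnot(inherits(dataset, "eq_flow_dataset"))
  threshold <- if (is.numeric(control) && length(control) == 1L) {
    control
  } else if (inherits(control, "eq_flow_dataset")) {
    stats::quantile(control$cells$reporter_fl, percentile, names = FALSE)
  } else {
    stop("`control` must be an eq_flow_dataset or a numeric threshold",
         call. = FALSE)
  }
  keep <- dataset$cells$reporter_fl > threshold
  if (!any(keep)) warning("gate is empty: no cell exceeds the threshold")
  out <- dataset
  out$cells <- dataset$cells[keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  attr(out, "gated_fraction") <- mean(keep)
  attr(out, "threshold") <- threshold
  out
}

#' Coefficient of variation
#'
#' Sample SD (n-1 denominator, the flow-cytometry software convention)
#' divided by the mean.
#'
#' @param values Numeric vector, length >= 2, with positive mean.
#' @return CV (dimensionless).
#' @examples
#' cv(c(0, 2))  # sqrt(2) / 1
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0", call. = FALSE)
  stats::sd(values) / m
}

#' Fano factor
#'
#' Sample variance divided by the mean. Unlike the CV, the Fano factor
#' carries the units of the input channel and scales with it, so it is not
#' comparable across channels or across distributions with different means.
#'
#' @inheritParams cv
#' @return Fano factor (units of the input).
#' @export
fano <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0", call. = FALSE)
  stats::var(values) / m
}

# Stable ordering by x then original index; partition of n rows into
# n_bins contiguous groups whose sizes differ by at most 1, remainder
# assigned to the lowest-index bins.
bin_partition <- function(x, n_bins) {
  n <- length(x)
  ord <- order(x, seq_along(x))  # stable tie-break on original index
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  list(ord = ord, bin = rep(seq_len(n_bins), times = sizes))
}

binned_curve <- function(x, y, ord, bin, n_bins) {
  xs <- x[ord]; ys <- y[ord]
  mean_x <- as.numeric(tapply(xs, bin, mean))
  mean_y <- as.numeric(tapply(ys, bin, mean))
  counts <- as.integer(tapply(xs, bin, length))
  out <- data.frame(bin_index = seq_len(n_bins),
                    mean_x = mean_x, mean_y = mean_y,
                    normalized_x = mean_x / mean_x[1],
                    normalized_y = mean_y / mean_y[1],
                    count = counts)
  class(out) <- c("eq_binned_curve", "data.frame")
  out
}

#' Equal-count binning of pooled single-cell data
#'
#' Sorts cells by the x channel, splits them into `n_bins` contiguous bins
#' with equal counts (remainder rows go to the earliest bins), computes the
#' per-bin means of both channels, and normalises each mean series to its
#' first bin.
#'
#' @param x,y Paired per-cell values (e.g. gene-dosage reporter and circuit
#'   output), `length(x) == length(y) >= n_bins`.
#' @param n_bins Number of bins (default 20).
#' @return A data frame of class `eq_binned_curve` with columns
#'   `bin_index`, `mean_x`, `mean_y`, `normalized_x`, `normalized_y`,
#'   `count`.
#' @examples
#' b <- equal_count_bins(1:40, 1:40, 20)
#' b$mean_x  # 1.5, 3.5, ..., 39.5
#' @export
equal_count_bins <- function(x, y, n_bins = 20) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < n_bins) {
    stop("fewer data points than bins", call. = FALSE)
  }
  pt <- bin_partition(x, n_bins)
  binned_curve(x, y, pt$ord, pt$bin, n_bins)
}

#' Percentile binning
#'
#' Bins cells by empirical percentiles of the x channel in windows of
#' `width_pct` percent (e.g. 5 % -> 20 bins) and reports per-bin means.
#' Ties are broken by stable sort on the original row order.
#'
#' @inheritParams equal_count_bins
#' @param width_pct Percentile width; must divide 100.
#' @return An `eq_binned_curve` data frame.
#' @export
percentile_bins <- function(x, y, width_pct = 5) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (100 %% width_pct != 0) {
    stop("`width_pct` must divide 100", call. = FALSE)
  }
  n_bins <- as.integer(100 / width_pct)
  if (length(x) < n_bins) stop("fewer data points than bins", call. = FALSE)
  ord <- order(x, seq_along(x))
  # empirical percentile of each sorted row; right-closed windows
  pct <- (seq_along(ord) - 1) / length(ord)
  bin <- pmin(floor(pct * n_bins) + 1L, n_bins)
  binned_curve(x, y, ord, bin, n_bins)
}

#' Fold change across a binned transfer curve
#'
#' Ratio of the last bin's mean y to the first bin's (i.e. the last
#' `normalized_y`) — the statistic used to compare how steeply circuit
#' output rises across the gene-dosage span.
#'
#' @param curve An `eq_binned_curve`.
#' @return The fold change (last mean / first mean).
#' @export
fold_change <- function(curve) {
  if (!is.data.frame(curve) || !("mean_y" %in% names(curve))) {
    stop("`curve` must be an eq_binned_curve", call. = FALSE)
  }
  if (nrow(curve) < 2) stop("need >= 2 bins", call. = FALSE)
  if (curve$mean_y[1] <= 0) {
    stop("first-bin mean must be > 0", call. = FALSE)
  }
  curve$mean_y[nrow(curve)] / curve$mean_y[1]
}
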