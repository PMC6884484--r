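#' Tissue fusion configuration
#'
#' Per-tissue constants of the piecewise fusion model: the three fusion weight
#' coefficients and the greyscale-range parameters (intensity span of the
#' tissue and the offset added to the highest histogram peak to obtain the
#' upper intensity bound). All intensity quantities are on the normalized
#' [0, 1] scale.
#'
#' @param name tissue identifier.
#' @param beta1,beta2,beta3 positive fusion weight coefficients.
#' @param span tissue pixel-value span, in (0, 1].
#' @param offset offset added to the peak-bin value to place the range's
#'   upper bound (may be negative).
#' @return An object of class `tissue_config`.
#' @export
tissue_config <- function(name, beta1, beta2, beta3, span, offset) {
  if (any(c(beta1, beta2, beta3) <= 0)) stop("beta coefficients must be > 0")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  structure(list(name = as.character(name), beta1 = beta1, beta2 = beta2,
                 beta3 = beta3, span = span, offset = offset),
            class = "tissue_config")
}

# Built-in constants for the six deep-brain structures.
.tissue_table <- list(
  thalamus    = list(beta1 = 3.13, beta2 = 1.25,  beta3 = 0.67, span = 0.6, offset = 0.15),
  hippocampus = list(beta1 = 3.13, beta2 = 1.67,  beta3 = 2.5,  span = 0.5, offset = 0),
  caudate     = list(beta1 = 3.13, beta2 = 0.625, beta3 = 0.83, span = 0.5, offset = 0),
  putamen     = list(beta1 = 3.13, beta2 = 0.72,  beta3 = 1,    span = 0.5, offset = 0.1),
  pallidum    = list(beta1 = 3.13, beta2 = 0.83,  beta3 = 1.25, span = 0.5, offset = 0.15),
  amygdala    = list(beta1 = 3.13, beta2 = 1,     beta3 = 0.25, span = 0.5, offset = -0.05)
)

#' Built-in tissue configurations
#'
#' `gplf_tissue()` returns the shipped configuration for one of the six deep
#' grey-matter structures; `gplf_tissues()` lists their names.
#'
#' @param name one of `gplf_tissues()`.
#' @return A [tissue_config()].
#' @export
gplf_tissue <- function(name) {
  row <- .tissue_table[[name]]
  if (is.null(row))
    stop("unknown tissue '", name, "'; known tissues: ",
         paste(names(.tissue_table), collapse = ", "))
  tissue_config(name, row$beta1, row$beta2, row$beta3, row$span, row$offset)
}

#' @rdname gplf_tissue
#' @export
gplf_tissues <- function() names(.tissue_table)

#' Load a tissue configuration from a JSON file
#'
#' The file must carry fields `name`, `beta1`, `beta2`, `beta3`, `span`,
#' `offset` (either at top level or as a named entry in a `tissues` map).
#'
#' @param path JSON file path.
#' @param name when the file holds several tissues, which one to load.
#' @return A [tissue_config()].
#' @export
load_tissue_config <- function(path, name = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$tissues)) {
    if (is.null(name)) stop("file holds several tissues; give `name`")
    x <- x$tissues[[name]]
    if (is.null(x)) stop("tissue '", name, "' not present in ", path)
    x$name <- name
  }
  need <- c("name", "beta1", "beta2", "beta3", "span", "offset")
  if (!all(need %in% names(x)))
    stop("tissue config missing fields: ", paste(setdiff(need, names(x)), collapse = ", "))
  tissue_config(x$name, x$beta1, x$beta2, x$beta3, x$span, x$offset)
}

.masked_values <- function(vol, mask) {
  if (is.null(mask)) {
    vol$data[vol$data != 0]
  } else {
    stopifnot(inherits(mask, "label_volume"))
    if (!identical(dim(mask$data), dim(vol$data))) stop("mask grid differs from volume grid")
    vol$data[mask$data == 1L]
  }
}

.hist_counts <- function(values, n_intervals) {
  if (any(values < 0 | values > 1)) stop("intensities must be normalized to [0, 1]")
  idx <- pmin(floor(values * n_intervals), n_intervals - 1L) + 1L
  tabulate(idx, nbins = n_intervals)
}

#' Greyscale histogram of a normalized volume
#'
#' Counts masked voxels over `n_intervals` equal-width bins partitioning
#' [0, 1]. Bin `k` (0-based) covers `[k/N, (k+1)/N)`; the last bin is closed
#' at 1. Counts sum to the mask size.
#'
#' @param vol normalized [intensity_volume()] (values in [0, 1]).
#' @param mask optional [label_volume()]; default mask is the nonzero
#'   foreground.
#' @param n_intervals number of bins, >= 2. Default 20.
#' @return Integer vector of per-bin counts.
#' @export
histogram_counts <- function(vol, mask = NULL, n_intervals = 20L) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (n_intervals < 2) stop("n_intervals must be >= 2")
  .hist_counts(.masked_values(vol, mask), as.integer(n_intervals))
}

#' Detect histogram peaks
#'
#' Bin `k` is a peak iff its count strictly exceeds both neighbours (edge bins
#' are never peaks, plateaus are not peaks) and carries at least
#' `min_fraction` of the total count (noise suppression).
#'
#' @param counts per-bin counts, length >= 3.
#' @param min_fraction minimum mass per peak, as a fraction of the total.
#'   Default 0.01.
#' @return 0-based indices of the peak bins (possibly empty).
#' @export
detect_peaks <- function(counts, min_fraction = 0.01) {
  n <- length(counts)
  if (n < 3) stop("need at least 3 bins to detect peaks")
  total <- sum(counts)
  if (total <= 0) return(integer(0))
  k <- 2:(n - 1)
  is_peak <- counts[k] > counts[k - 1] & counts[k] > counts[k + 1] &
    counts[k] >= min_fraction * total
  (k[is_peak]) - 1L
}

#' Set the target-tissue greyscale range by iterative re-binning
#'
#' Builds the masked intensity histogram at `n_start` bins and inspects its
#' peaks. With 2 or 3 peaks the range is accepted: the upper bound is the
#' value of the highest peak bin (its upper edge) plus the tissue offset, the
#' lower bound is `upper - span`, both clipped to [0, 1]. With a single peak
#' (or none) the histogram is rebuilt at twice the bins; with more than 3
#' peaks at half. At most `max_rounds` rounds are attempted, after which the
#' round whose peak count is closest to 2 wins.
#'
#' @param vol normalized [intensity_volume()].
#' @param mask optional [label_volume()].
#' @param cfg a [tissue_config()].
#' @param n_start starting number of intervals. Default 20.
#' @param max_rounds re-binning rounds cap. Default 4.
#' @param min_fraction peak mass filter, see [detect_peaks()].
#' @return An object of class `greyscale_model`: `n_intervals`, `bin_edges`,
#'   `counts`, `peak_bins` and `isn_max` (0-based), and
#'   `tissue_range = c(lower, upper)`.
#' @export
set_tissue_range <- function(vol, mask = NULL, cfg, n_start = 20L,
                             max_rounds = 4L, min_fraction = 0.01) {
  values <- if (is.numeric(vol)) vol else .masked_values(vol, mask)
  n <- as.integer(n_start)
  rounds <- list()
  chosen <- NULL
  for (r in seq_len(max_rounds)) {
    counts <- .hist_counts(values, n)
    peaks <- detect_peaks(counts, min_fraction)
    rounds[[r]] <- list(n = n, counts = counts, peaks = peaks)
    np <- length(peaks)
    if (np %in% c(2L, 3L)) { chosen <- rounds[[r]]; break }
    n <- if (np > 3L) max(4L, n %/% 2L) else n * 2L
  }
  if (is.null(chosen)) {
    np_all <- vapply(rounds, function(x) length(x$peaks), integer(1))
    ok <- which(np_all >= 1L)
    if (!length(ok)) stop("no histogram peaks at any binning scale; cannot set tissue range")
    chosen <- rounds[[ok[which.min(abs(np_all[ok] - 2L))]]]
  }
  isn_max <- max(chosen$peaks)
  value <- (isn_max + 1) / chosen$n            # upper edge of the peak bin
  upper <- min(1, value + cfg$offset)
  lower <- max(0, upper - cfg$span)
  if (lower >= upper) stop("degenerate tissue range [", lower, ", ", upper, "]")
  structure(list(n_intervals = chosen$n,
                 bin_edges = seq(0, 1, length.out = chosen$n + 1),
                 counts = chosen$counts,
                 peak_bins = chosen$peaks,
                 isn_max = isn_max,
                 tissue_range = c(lower, upper),
                 tissue = cfg$name),
            class = "greyscale_model")
}

#' Map an intensity to its histogram bin
#'
#' Uses the half-open convention of [histogram_counts()]: bin `k` (0-based)
#' covers `[k/N, (k+1)/N)`, last bin closed at 1.
#'
#' @param intensity value(s) in [0, 1].
#' @param model a `greyscale_model`.
#' @return 0-based bin indices.
#' @export
bin_index <- function(intensity, model) {
  if (any(intensity < 0 | intensity > 1)) stop("intensity outside [0, 1]")
  pmin(floor(intensity * model$n_intervals), model$n_intervals - 1L)
}

# 0-based bins whose interval overlaps the tissue range.
.in_range_bins <- function(model) {
  lo <- model$tissue_range[1]; hi <- model$tissue_range[2]
  e <- model$bin_edges
  which(e[-1] > lo & e[-length(e)] < hi) - 1L
}

#' @export
print.greyscale_model <- function(x, ...) {
  cat(sprintf("greyscale_model (%s): %d intervals, peaks at bins {%s}, ISNmax %d, tissue range [%.3f, %.3f]\n",
              x$tissue %||% "?", x$n_intervals,
              paste(x$peak_bins, collapse = ", "), x$isn_max,
              x$tissue_range[1], x$tissue_range[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
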