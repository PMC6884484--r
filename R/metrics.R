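.check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("label volumes are on different grids")
}

#' Dice similarity coefficient
#'
#' Volume overlap `2|T ∩ F| / (|T| + |F|)` between two binary voxel sets.
#' Defined as 1 when both sets are empty.
#'
#' @param t_vol,f_vol [label_volume()]s on the same grid (reference and
#'   segmentation).
#' @return Scalar in [0, 1].
#' @export
dice <- function(t_vol, f_vol) {
  .check_same_grid(t_vol, f_vol)
  nt <- sum(t_vol$data); nf <- sum(f_vol$data)
  if (nt + nf == 0) return(1)
  2 * sum(t_vol$data & f_vol$data) / (nt + nf)
}

#' Recall (sensitivity) of a segmentation
#'
#' `|T ∩ F| / |T|`. Undefined (returns `NA`) when the reference set is
#' empty, so averages are not silently biased.
#'
#' @inheritParams dice
#' @return Scalar in [0, 1], or `NA` when undefined.
#' @export
recall <- function(t_vol, f_vol) {
  .check_same_grid(t_vol, f_vol)
  nt <- sum(t_vol$data)
  if (nt == 0) return(NA_real_)
  sum(t_vol$data & f_vol$data) / nt
}

#' Precision (positive predictive value) of a segmentation
#'
#' `|T ∩ F| / |F|`. Undefined (returns `NA`) when the segmented set is
#' empty.
#'
#' @inheritParams dice
#' @return Scalar in [0, 1], or `NA` when undefined.
#' @export
precision <- function(t_vol, f_vol) {
  .check_same_grid(t_vol, f_vol)
  nf <- sum(f_vol$data)
  if (nf == 0) return(NA_real_)
  sum(t_vol$data & f_vol$data) / nf
}

# physical-mm coordinates of foreground voxels
.fg_coords <- function(vol, spacing) {
  idx <- which(vol$data == 1L, arr.ind = TRUE)
  sweep(idx, 2, spacing, "*")
}

# directed Hausdorff: max over rows of A of the min distance to B (chunked)
.directed_hd <- function(A, B) {
  worst <- 0
  bs2 <- rowSums(B^2)
  for (start in seq(1, nrow(A), by = 256)) {
    rows <- start:min(start + 255, nrow(A))
    Ac <- A[rows, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), bs2, "+") - 2 * Ac %*% t(B)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Hausdorff distance between two voxel sets
#'
#' Maximum over both directions of the farthest nearest-neighbour Euclidean
#' distance, over all foreground voxels of each set. Distances are physical
#' (mm) using the voxel spacing unless `voxel_units = TRUE`.
#'
#' @inheritParams dice
#' @param spacing voxel spacing (mm); default taken from `t_vol`.
#' @param voxel_units measure in voxel index units instead of mm.
#' @return Distance `>= 0`, or `NA` when either set is empty.
#' @export
hausdorff <- function(t_vol, f_vol, spacing = NULL, voxel_units = FALSE) {
  .check_same_grid(t_vol, f_vol)
  if (sum(t_vol$data) == 0 || sum(f_vol$data) == 0) return(NA_real_)
  sp <- if (voxel_units) c(1, 1, 1) else if (is.null(spacing)) t_vol$spacing else spacing
  A <- .fg_coords(t_vol, sp)
  B <- .fg_coords(f_vol, sp)
  max(.directed_hd(A, B), .directed_hd(B, A))
}

#' All four segmentation metrics at once
#'
#' @inheritParams hausdorff
#' @return An object of class `segmentation_metrics`: `dsc`, `recall`,
#'   `precision` (unitless) and `hd` (mm).
#' @export
evaluate_segmentation <- function(t_vol, f_vol, spacing = NULL, voxel_units = FALSE) {
  structure(list(dsc = dice(t_vol, f_vol),
                 recall = recall(t_vol, f_vol),
                 precision = precision(t_vol, f_vol),
                 hd = hausdorff(t_vol, f_vol, spacing, voxel_units)),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("Dsc %.4f | Recall %s | Precision %s | HD %s mm\n",
              x$dsc,
              ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)),
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$hd), "NA", sprintf("%.3f", x$hd))))
  invisible(x)
}
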