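#' Construct a 3D intensity volume
#'
#' An intensity volume is a 3D scalar grid together with its voxel spacing.
#' The third array axis is the slice (axial) axis; the physical position of
#' slice `k` (0-based) is `k * spacing[3]` millimetres.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis; all entries
#'   must be strictly positive.
#' @return An object of class `intensity_volume` with elements `data` and
#'   `spacing`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("intensity volume must be a 3D array, got ", length(dim(data)), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  structure(list(data = data, spacing = spacing), class = "intensity_volume")
}

#' Construct a binary label volume
#'
#' @param data 3D array with values in {0, 1}.
#' @inheritParams intensity_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("label volume must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("label volume values must be exactly 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing), class = "label_volume")
}

#' Pair a warped intensity image with its label image
#'
#' An atlas is a warped intensity image and the expert label image propagated
#' by the same registration, sharing one voxel grid.
#'
#' @param id character identifier.
#' @param intensity an [intensity_volume()].
#' @param label a [label_volume()] on the same grid.
#' @return An object of class `gplf_atlas`.
#' @export
atlas <- function(id, intensity, label) {
  stopifnot(inherits(intensity, "intensity_volume"), inherits(label, "label_volume"))
  if (!identical(dim(intensity$data), dim(label$data)))
    stop("atlas intensity and label dimensions differ")
  if (!isTRUE(all.equal(intensity$spacing, label$spacing)))
    stop("atlas intensity and label spacing differ")
  structure(list(id = as.character(id), intensity = intensity, label = label),
            class = "gplf_atlas")
}

#' Physical axial position of every slice
#'
#' @param vol an `intensity_volume` or `label_volume`.
#' @return Numeric vector of length `dim(vol$data)[3]`: position of slice k
#'   (0-based) is `k * spacing[3]`, in mm.
#' @export
axial_positions <- function(vol) {
  (seq_len(dim(vol$data)[3]) - 1) * vol$spacing[3]
}

#' Min-max normalize intensities to [0, 1]
#'
#' Rescales in-mask voxels so the in-mask minimum maps to 0 and the maximum to
#' 1; voxels outside the mask are set to 0. When no mask is given the
#' foreground (all nonzero voxels) is used. Idempotent on its own output and
#' invariant to positive affine transforms of the input.
#'
#' @param vol an [intensity_volume()].
#' @param mask optional [label_volume()] on the same grid; 1 marks in-mask.
#' @return A normalized `intensity_volume`.
#' @export
normalize_intensity <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (is.null(mask)) {
    # already-normalized volumes (whole-volume min exactly 0, max exactly 1)
    # pass through unchanged, which makes the maskless path idempotent even
    # though the minimum foreground voxel joins the zero background
    if (min(vol$data) == 0 && max(vol$data) == 1) return(vol)
    inmask <- vol$data != 0
  } else {
    stopifnot(inherits(mask, "label_volume"))
    if (!identical(dim(mask$data), dim(vol$data)))
      stop("mask grid differs from volume grid")
    inmask <- mask$data == 1L
  }
  if (!any(inmask)) stop("empty mask: nothing to normalize")
  v <- vol$data[inmask]
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0) stop("degenerate intensity range: all in-mask values equal")
  out <- array(0, dim(vol$data))
  out[inmask] <- (v - lo) / (hi - lo)
  intensity_volume(out, vol$spacing)
}

#' Select one structure code out of a multi-label image
#'
#' Multi-structure label files (e.g. IBSR-style) carry one integer code per
#' structure; this reduces such an image to the binary mask of a single code.
#'
#' @param vol an `intensity_volume` or `label_volume` whose voxels hold integer
#'   structure codes.
#' @param code the structure code mapped to 1; everything else becomes 0.
#' @return A [label_volume()].
#' @export
binarize_label <- function(vol, code) {
  label_volume(array(as.integer(vol$data == code), dim(vol$data)), vol$spacing)
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("intensity_volume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, |foreground| = %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$data)))
  invisible(x)
}

#' @export
print.gplf_atlas <- function(x, ...) {
  d <- dim(x$intensity$data)
  cat(sprintf("atlas '%s': %dx%dx%d, |label| = %d\n", x$id, d[1], d[2], d[3],
              sum(x$label$data)))
  invisible(x)
}
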