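#' Patch selection configuration
#'
#' @param sr search radius in mm around the target slice position; atlas
#'   slices within `[TSP - sr, TSP + sr]` (closed interval) take part in
#'   fusion. Default 3 mm.
#' @param k number of most-similar patches kept per voxel. Default 60.
#' @param patch_shape integer length-3, per-axis patch extent in voxels; each
#'   extent must be odd. Default `c(7, 7, 3)` (in-plane larger than
#'   through-plane to suit anisotropic 1.5 mm slices).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(sr = 3, k = 60, patch_shape = c(7L, 7L, 3L)) {
  patch_shape <- as.integer(patch_shape)
  if (sr < 0) stop("sr must be >= 0")
  if (k < 1) stop("k must be >= 1")
  if (length(patch_shape) != 3L || any(patch_shape < 1L) || any(patch_shape %% 2L == 0L))
    stop("patch_shape must be 3 odd positive integers")
  structure(list(sr = sr, k = as.integer(k), patch_shape = patch_shape),
            class = "selection_config")
}

#' Select atlas slices near a target slice position
#'
#' Atlas slices whose axial position lies within the closed interval
#' `[tsp - sr, tsp + sr]` are eligible for fusion; slices further away are
#' discarded. Positions are physical (mm), see [axial_positions()].
#'
#' @param atlases list of [atlas()] objects.
#' @param tsp target slice spatial position in mm.
#' @param sr search radius in mm.
#' @return A data.frame with columns `atlas` (list index), `id`, `slice`
#'   (1-based slice index) and `position` (mm).
#' @export
select_atlases_by_position <- function(atlases, tsp, sr) {
  if (sr < 0) stop("sr must be >= 0")
  rows <- lapply(seq_along(atlases), function(i) {
    pos <- axial_positions(atlases[[i]]$intensity)
    keep <- which(pos >= tsp - sr & pos <= tsp + sr)
    if (!length(keep)) return(NULL)
    data.frame(atlas = i, id = atlases[[i]]$id, slice = keep,
               position = pos[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("no atlas slices within TSP +/- SR; widen the search radius")
  out
}

# Clamped (edge-replicating) patch row extraction: for n centers and a fixed
# patch shape, returns an n x len matrix of intensities in raster order
# (dx fastest, then dy, then dz).
.patch_matrix <- function(arr, centers, patch_shape, center_slice = NULL) {
  d <- dim(arr)
  r <- (patch_shape - 1L) %/% 2L
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  n <- nrow(centers)
  len <- nrow(off)
  ci <- centers[, 1]; cj <- centers[, 2]
  ck <- if (is.null(center_slice)) centers[, 3] else rep(center_slice, n)
  out <- matrix(0, n, len)
  for (t in seq_len(len)) {
    xi <- pmin(pmax(ci + off$dx[t], 1L), d[1])
    yj <- pmin(pmax(cj + off$dy[t], 1L), d[2])
    zk <- pmin(pmax(ck + off$dz[t], 1L), d[3])
    out[, t] <- arr[cbind(xi, yj, zk)]
  }
  out
}

#' Extract a vectorized patch around a voxel
#'
#' Out-of-bounds positions are filled by edge replication, so every voxel has
#' a full-length patch vector. The vector is in fixed raster order (first axis
#' fastest, then second, then slice axis).
#'
#' @param vol an `intensity_volume` or `label_volume`.
#' @param center integer length-3 voxel coordinate (1-based).
#' @param patch_shape integer length-3 odd extents.
#' @param source_id identifier recorded on the patch (default `"target"`).
#' @return An object of class `gplf_patch` with fields `vector`, `center`,
#'   `source_id`.
#' @export
extract_patch <- function(vol, center, patch_shape, source_id = "target") {
  patch_shape <- as.integer(patch_shape)
  if (any(patch_shape < 1L) || any(patch_shape %% 2L == 0L))
    stop("patch_shape must be odd positive integers")
  center <- as.integer(center)
  v <- .patch_matrix(vol$data, matrix(center, 1), patch_shape)[1, ]
  structure(list(vector = v, center = center, source_id = source_id),
            class = "gplf_patch")
}

#' Normalized correlation coefficient between two patch vectors
#'
#' Pearson-type similarity in `[-1, 1]`; returns 0 when either vector is
#' constant (zero variance). Symmetric and invariant under positive affine
#' rescaling of either argument.
#'
#' @param a,b numeric vectors of equal length >= 2 (or `gplf_patch` objects).
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  if (inherits(a, "gplf_patch")) a <- a$vector
  if (inherits(b, "gplf_patch")) b <- b$vector
  if (length(a) != length(b)) stop("ncc: vectors have different lengths")
  if (length(a) < 2L) stop("ncc: vectors must have length >= 2")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(-1, sum(a * b) / (na * nb)))
}

# Row-wise NCC between an n x len target matrix and n x len candidate matrix.
.ncc_rows <- function(A, B) {
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  den <- na * nb
  out <- ifelse(den > 0, rowSums(A * B) / den, 0)
  pmin(1, pmax(-1, out))
}

#' Build the over-complete patch dictionary for one voxel
#'
#' Ranks candidate atlas patches by NCC similarity to the target patch
#' (descending, ties stable in input order) and keeps the top
#' `min(k, #candidates)` with their similarities and centre labels.
#'
#' @param target_patch `gplf_patch` or numeric vector.
#' @param candidates list; each element a list with `patch` (`gplf_patch` or
#'   numeric vector) and `label` (0 or 1).
#' @param k number of patches to keep.
#' @return An object of class `patch_library`: `columns` (len x m matrix, the
#'   dictionary), `center_labels` (length m in {0,1}), `similarities`
#'   (non-increasing, length m).
#' @export
build_patch_library <- function(target_patch, candidates, k = 60) {
  if (!length(candidates)) stop("no candidate patches")
  tv <- if (inherits(target_patch, "gplf_patch")) target_patch$vector else as.numeric(target_patch)
  cols <- vapply(candidates, function(c_) {
    v <- if (inherits(c_$patch, "gplf_patch")) c_$patch$vector else as.numeric(c_$patch)
    if (length(v) != length(tv)) stop("candidate patch length differs from target")
    v
  }, numeric(length(tv)))
  cols <- matrix(cols, nrow = length(tv))
  labels <- vapply(candidates, function(c_) as.integer(c_$label), integer(1))
  if (!all(labels %in% c(0L, 1L))) stop("center labels must be 0 or 1")
  sims <- vapply(seq_len(ncol(cols)), function(j) ncc(tv, cols[, j]), numeric(1))
  ord <- order(-sims)                       # radix order: stable for ties
  keep <- ord[seq_len(min(k, length(ord)))]
  structure(list(columns = cols[, keep, drop = FALSE],
                 center_labels = labels[keep],
                 similarities = sims[keep]),
            class = "patch_library")
}
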