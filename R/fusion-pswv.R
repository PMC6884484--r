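#' Weighted vote over binary labels
#'
#' The weighted-voting fusion value is the weight-normalized label mass,
#' `fv = sum(w_i * l_i) / sum(w_i)`, with the convention `fv = 0` when all
#' weights are zero (no atlas evidence supports the tissue).
#'
#' @param weights nonnegative numeric vector.
#' @param labels binary vector (0/1) of the same length.
#' @return A list of class `vote_result`: `fv` in `[0, 1]` and `n_effective`,
#'   the number of strictly positive weights.
#' @export
weighted_vote <- function(weights, labels) {
  if (length(weights) != length(labels) || !length(weights))
    stop("weights and labels must have equal positive length")
  if (any(weights < 0)) stop("negative weight: clamp weights upstream")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  sw <- sum(weights)
  fv <- if (sw > 0) sum(weights * labels) / sw else 0
  structure(list(fv = fv, n_effective = sum(weights > 0)), class = "vote_result")
}

#' Patch-similarity weighted voting at one voxel
#'
#' NCC similarities of the retained patches act as vote weights; negative
#' similarities carry no vote mass and are clamped to zero.
#'
#' @param library a [build_patch_library()] result.
#' @return A `vote_result` (see [weighted_vote()]).
#' @export
pswv_fuse_voxel <- function(library) {
  stopifnot(inherits(library, "patch_library"))
  weighted_vote(pmax(library$similarities, 0), library$center_labels)
}

#' Binarize a fusion value
#'
#' Labels a voxel 1 when the fusion value reaches the threshold (`>=`).
#'
#' @param fv fusion value(s).
#' @param threshold scalar in `[0, 1]`, default 0.5.
#' @return Integer 0/1, same shape as `fv`.
#' @export
binarize <- function(fv, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- as.integer(fv >= threshold)
  if (!is.null(dim(fv))) dim(out) <- dim(fv)
  out
}
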