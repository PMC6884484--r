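#' Thresholds of the piecewise fusion model
#'
#' @param high upper cut: a fusion value above it labels the voxel tissue
#'   outright. Default 0.9.
#' @param low lower cut separating the weak-evidence branches. Default 0.4.
#' @param decision cut applied to the weighted fusion products. Default 0.5.
#' @return An object of class `gplf_thresholds`.
#' @export
gplf_thresholds <- function(high = 0.9, low = 0.4, decision = 0.5) {
  if (low >= high) stop("low threshold must be below high threshold")
  structure(list(high = high, low = low, decision = decision),
            class = "gplf_thresholds")
}

# Vectorized piecewise decision. Branches in printed order, first match wins:
#   (1) fs > high or fp > high                      -> 1
#   (2) low < fs <= high and low < fp < high        -> 1{beta1*fs*fp*p > decision}
#   (3) fs <= low                                   -> 1{beta2*fs*p    > decision}
#   (4) fp <= low                                   -> 1{beta3*fp*p    > decision}
#   residual uncovered combinations                 -> branch (2)'s rule
.gplf_decide <- function(fs, fp, p, cfg, th) {
  lf1 <- as.integer(cfg$beta1 * fs * fp * p > th$decision)
  out <- lf1                                        # fall-through default
  b4 <- fp <= th$low
  if (any(b4)) out[b4] <- as.integer(cfg$beta3 * fp[b4] * p[b4] > th$decision)
  b3 <- fs <= th$low
  if (any(b3)) out[b3] <- as.integer(cfg$beta2 * fs[b3] * p[b3] > th$decision)
  b2 <- fs > th$low & fs <= th$high & fp > th$low & fp < th$high
  out[b2] <- lf1[b2]
  b1 <- fs > th$high | fp > th$high
  out[b1] <- 1L
  out
}

#' Piecewise greyscale-probability label fusion at one voxel
#'
#' Combines the sparse-representation fusion value `fs`, the
#' similarity-weighted voting fusion value `fp` and the greyscale probability
#' `p` of the voxel's intensity bin. Branches are evaluated in fixed order
#' (first match wins): very strong evidence from either method labels the
#' voxel directly; otherwise the products `beta1*fs*fp*p`, `beta2*fs*p` or
#' `beta3*fp*p` are compared against the decision threshold, depending on
#' which method's evidence is weak. Combinations matching no branch use the
#' joint-product rule.
#'
#' @param fs,fp fusion values in [0, 1].
#' @param p greyscale probability in [0, 1].
#' @param cfg a [tissue_config()] providing the beta coefficients.
#' @param th a [gplf_thresholds()].
#' @return Integer label 0 or 1 (vectorized over the inputs).
#' @export
gplf_fuse_voxel <- function(fs, fp, p, cfg, th = gplf_thresholds()) {
  if (any(fs < 0 | fs > 1) || any(fp < 0 | fp > 1))
    stop("fusion values must be in [0, 1]")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  .gplf_decide(fs, fp, p, cfg, th)
}

# Candidate atlas slices for target slice position tsp: data.frame(atlas, slice).
.candidates_for_slice <- function(atlases, tsp, sr) {
  rows <- lapply(seq_along(atlases), function(a) {
    pos <- axial_positions(atlases[[a]]$intensity)
    keep <- which(pos >= tsp - sr & pos <= tsp + sr)
    if (!length(keep)) return(NULL)
    data.frame(atlas = a, slice = keep)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(atlas = integer(0), slice = integer(0)) else out
}

#' Per-voxel SRLF and PSWV fusion values over a whole volume
#'
#' For every target voxel, candidate patches are taken from each selected
#' atlas slice (axial position within `sel$sr` mm of the voxel's slice) at the
#' same in-plane coordinate, ranked by NCC, and fused by both
#' similarity-weighted voting and sparse coding.
#'
#' With `speed_path = TRUE` (default), voxels whose candidate centre labels
#' are all background are skipped: there both fusion values are exactly 0
#' (the vote numerator vanishes for any weights), so the skip is bit-identical
#' to exhaustive evaluation.
#'
#' @param target [intensity_volume()], normalized (or `normalize = TRUE`).
#' @param atlases list of [atlas()] on the same grid.
#' @param sel a [selection_config()].
#' @param srlf_cfg an [srlf_config()].
#' @param speed_path skip provably-background voxels.
#' @param normalize min-max normalize target and atlas intensities first.
#' @return An object of class `fusion_scores`: arrays `fv_srlf`, `fv_pswv`
#'   (target grid, values in [0, 1]) and logical array `computed`.
#' @export
fusion_scores <- function(target, atlases, sel = selection_config(),
                          srlf_cfg = srlf_config(), speed_path = TRUE,
                          normalize = TRUE) {
  stopifnot(inherits(target, "intensity_volume"))
  d <- dim(target$data)
  for (a in atlases) {
    if (!identical(dim(a$intensity$data), d))
      stop("atlas '", a$id, "' grid differs from target grid")
  }
  if (normalize) {
    target <- normalize_intensity(target)
    atlases <- lapply(atlases, function(a)
      atlas(a$id, normalize_intensity(a$intensity), a$label))
  }
  ps <- sel$patch_shape
  fv_s <- array(0, d)
  fv_p <- array(0, d)
  computed <- array(FALSE, d)
  ij <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
  dz <- target$spacing[3]

  for (k in seq_len(d[3])) {
    cand <- .candidates_for_slice(atlases, (k - 1) * dz, sel$sr)
    nc <- nrow(cand)
    if (!nc) next
    labm <- matrix(0L, nrow(ij), nc)
    for (c_ in seq_len(nc))
      labm[, c_] <- atlases[[cand$atlas[c_]]]$label$data[cbind(ij, cand$slice[c_])]
    proc <- if (speed_path) which(rowSums(labm) > 0) else seq_len(nrow(ij))
    if (!length(proc)) next
    for (chunk in split(proc, ceiling(seq_along(proc) / 512))) {
      centers <- ij[chunk, , drop = FALSE]
      pt_m <- .patch_matrix(target$data, cbind(centers, k), ps)
      sims <- matrix(0, length(chunk), nc)
      pcs <- vector("list", nc)
      for (c_ in seq_len(nc)) {
        pcs[[c_]] <- .patch_matrix(atlases[[cand$atlas[c_]]]$intensity$data,
                                   centers, ps, center_slice = cand$slice[c_])
        sims[, c_] <- .ncc_rows(pt_m, pcs[[c_]])
      }
      labs <- labm[chunk, , drop = FALSE]
      keep_all <- nc <= sel$k
      for (v in seq_along(chunk)) {
        kept <- if (keep_all) seq_len(nc) else order(-sims[v, ])[seq_len(sel$k)]
        w <- pmax(sims[v, kept], 0)
        lv <- labs[v, kept]
        sw <- sum(w)
        fv_p[centers[v, 1], centers[v, 2], k] <- if (sw > 0) sum(w * lv) / sw else 0
        D <- vapply(pcs[kept], function(M) M[v, ], numeric(ncol(pt_m)))
        sol <- sparse_code(pt_m[v, ], matrix(D, nrow = ncol(pt_m)), srlf_cfg)
        ws <- pmax(sol$alpha, 0)
        sws <- sum(ws)
        fv_s[centers[v, 1], centers[v, 2], k] <- if (sws > 0) sum(ws * lv) / sws else 0
        computed[centers[v, 1], centers[v, 2], k] <- TRUE
      }
    }
  }
  structure(list(fv_srlf = fv_s, fv_pswv = fv_p, computed = computed,
                 spacing = target$spacing),
            class = "fusion_scores")
}

# Per-voxel greyscale probability map from trained coefficients.
.p_map <- function(intensity_data, pcoeffs) {
  v <- pmin(pmax(intensity_data, 0), 1)
  arr <- pcoeffs$p[bin_index(v, pcoeffs$model) + 1L]
  array(arr, dim(intensity_data))
}

#' Segment a target volume by greyscale-probability label fusion
#'
#' Runs the full pipeline at every voxel: patch-library construction, PSWV
#' and SRLF fusion values, greyscale probability lookup at the voxel's
#' intensity bin (zero outside the tissue range), and the piecewise decision
#' of [gplf_fuse_voxel()].
#'
#' @param target [intensity_volume()].
#' @param atlases list of [atlas()] sharing the target grid.
#' @param pcoeffs trained [p_coefficients()].
#' @param cfg a [tissue_config()].
#' @param sel a [selection_config()].
#' @param srlf_cfg an [srlf_config()].
#' @param th a [gplf_thresholds()].
#' @param method `"gplf"` (default), or `"pswv"` / `"srlf"` for the standalone
#'   baselines (fusion value thresholded at `th$decision`; `pcoeffs` unused).
#' @param speed_path see [fusion_scores()].
#' @param normalize min-max normalize inputs first.
#' @param scores optional precomputed [fusion_scores()] to reuse.
#' @return A [label_volume()] on the target grid.
#' @export
segment_volume <- function(target, atlases, pcoeffs = NULL, cfg = NULL,
                           sel = selection_config(), srlf_cfg = srlf_config(),
                           th = gplf_thresholds(), method = c("gplf", "pswv", "srlf"),
                           speed_path = TRUE, normalize = TRUE, scores = NULL) {
  method <- match.arg(method)
  if (normalize) target <- normalize_intensity(target)
  if (is.null(scores))
    scores <- fusion_scores(target, atlases, sel, srlf_cfg,
                            speed_path = speed_path, normalize = normalize)
  lab <- switch(method,
    pswv = binarize(scores$fv_pswv, th$decision),
    srlf = binarize(scores$fv_srlf, th$decision),
    gplf = {
      if (is.null(pcoeffs) || is.null(cfg))
        stop("gplf segmentation needs trained `pcoeffs` and a tissue `cfg`")
      pmap <- .p_map(target$data, pcoeffs)
      .gplf_decide(scores$fv_srlf, scores$fv_pswv, pmap, cfg, th)
    })
  label_volume(array(lab, dim(target$data)), target$spacing)
}
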