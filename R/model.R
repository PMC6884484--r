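#' Fit a greyscale-probability label-fusion model
#'
#' The fitting step of the pipeline: the target image sets the tissue
#' greyscale range from its own intensity histogram, and the per-bin
#' probabilities are trained by leave-one-out coordinate ascent on the summed
#' Dice of the spatially selected atlases ([train_p()]). The returned object
#' carries everything needed to segment: use [predict.gplf()].
#'
#' @param target [intensity_volume()] to be segmented.
#' @param atlases list of [atlas()] objects co-registered to the target grid;
#'   also used as the training set.
#' @param tissue tissue name (see [gplf_tissues()]) or a [tissue_config()].
#' @param sel a [selection_config()].
#' @param srlf_cfg an [srlf_config()].
#' @param th a [gplf_thresholds()].
#' @param grid training probability grid (see [train_p()]).
#' @param max_sweeps coordinate-ascent sweep cap.
#' @param seed recorded for provenance (training is deterministic).
#' @param mask optional brain mask for normalization / histogram.
#' @return An object of class `gplf` with elements `pcoeffs`, `report`,
#'   `tissue`, `selection`, `srlf`, `thresholds`, `target`, `atlases`.
#' @seealso [predict.gplf()], [coef.gplf()], [plot.gplf()]
#' @export
gplf_train <- function(target, atlases, tissue = "thalamus",
                       sel = selection_config(), srlf_cfg = srlf_config(),
                       th = gplf_thresholds(), grid = seq(0, 1, 0.1),
                       max_sweeps = 5L, seed = NULL, mask = NULL) {
  cfg <- if (inherits(tissue, "tissue_config")) tissue else gplf_tissue(tissue)
  target_n <- normalize_intensity(target, mask)
  model <- set_tissue_range(target_n, mask = mask, cfg = cfg)
  fit <- train_p(atlases, cfg, sel, srlf_cfg, th, grid = grid,
                 max_sweeps = max_sweeps, seed = seed, model = model)
  structure(list(pcoeffs = fit$pcoeffs, report = fit$report, tissue = cfg,
                 selection = sel, srlf = srlf_cfg, thresholds = th,
                 target = target_n, atlases = atlases, call = match.call()),
            class = "gplf")
}

#' Segment with a fitted label-fusion model
#'
#' @param object a fitted `gplf` model.
#' @param target optional new [intensity_volume()]; default is the target the
#'   model was fitted for.
#' @param atlases optional atlas list; default is the fitted set.
#' @param method `"gplf"` (full model), `"pswv"` or `"srlf"` (baselines).
#' @param speed_path see [fusion_scores()].
#' @param ... unused.
#' @return A [label_volume()].
#' @export
predict.gplf <- function(object, target = NULL, atlases = NULL,
                         method = c("gplf", "pswv", "srlf"),
                         speed_path = TRUE, ...) {
  method <- match.arg(method)
  if (is.null(target)) target <- object$target
  if (is.null(atlases)) atlases <- object$atlases
  segment_volume(target, atlases, pcoeffs = object$pcoeffs, cfg = object$tissue,
                 sel = object$selection, srlf_cfg = object$srlf,
                 th = object$thresholds, method = method,
                 speed_path = speed_path)
}

#' @export
coef.gplf <- function(object, ...) {
  p <- object$pcoeffs$p
  e <- object$pcoeffs$model$bin_edges
  names(p) <- sprintf("[%.3f,%.3f)", e[-length(e)], e[-1])
  p
}

#' @export
print.gplf <- function(x, ...) {
  cat("Greyscale-probability label fusion model\n")
  cat(sprintf("  tissue: %s (beta = %.3g / %.3g / %.3g)\n", x$tissue$name,
              x$tissue$beta1, x$tissue$beta2, x$tissue$beta3))
  cat(sprintf("  tissue greyscale range: [%.3f, %.3f] (%d bins, ISNmax %d)\n",
              x$pcoeffs$model$tissue_range[1], x$pcoeffs$model$tissue_range[2],
              x$pcoeffs$model$n_intervals, x$pcoeffs$model$isn_max))
  cat(sprintf("  training: %d atlases, leave-one-out mean Dsc %.4f\n",
              x$report$n_atlases, x$report$objective / x$report$n_atlases))
  invisible(x)
}

#' @export
summary.gplf <- function(object, ...) {
  print(object)
  cat("  per-atlas training Dsc:",
      paste(sprintf("%.3f", object$report$dsc_vector), collapse = " "), "\n")
  p <- coef(object)
  nz <- p[p > 0]
  if (length(nz)) {
    cat("  nonzero bin probabilities:\n")
    for (i in seq_along(nz)) cat(sprintf("    %s  %.2f\n", names(nz)[i], nz[i]))
  } else cat("  all bin probabilities are zero\n")
  invisible(object)
}

#' Plot trained bin probabilities
#'
#' Bar plot of the per-bin greyscale probability with the detected tissue
#' range shaded and the histogram peak bins marked.
#'
#' @param x a fitted `gplf` model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gplf <- function(x, ...) {
  m <- x$pcoeffs$model
  mids <- (m$bin_edges[-1] + m$bin_edges[-length(m$bin_edges)]) / 2
  bp <- graphics::barplot(x$pcoeffs$p, names.arg = sprintf("%.2f", mids),
                          xlab = "intensity bin midpoint",
                          ylab = "P(tissue | bin)", ylim = c(0, 1),
                          las = 2, ...)
  usr_y <- c(0, 1)
  inb <- .in_range_bins(m) + 1L
  if (length(inb))
    graphics::rect(bp[min(inb)] - 0.6, usr_y[1], bp[max(inb)] + 0.6, usr_y[2],
                   border = NA, col = grDevices::adjustcolor("steelblue", 0.15))
  graphics::points(bp[m$peak_bins + 1L], rep(0.02, length(m$peak_bins)),
                   pch = 17, col = "firebrick")
  invisible(bp)
}
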