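#' Per-bin greyscale probability coefficients
#'
#' One probability per intensity bin of a [set_tissue_range()] model; bins
#' outside the tissue range must be zero (the tissue cannot live there by
#' construction).
#'
#' @param model a `greyscale_model`.
#' @param p numeric vector of length `model$n_intervals`, values in [0, 1].
#' @param tissue tissue name.
#' @return An object of class `p_coefficients`.
#' @export
p_coefficients <- function(model, p, tissue) {
  stopifnot(inherits(model, "greyscale_model"))
  if (length(p) != model$n_intervals) stop("p must have one value per intensity bin")
  if (any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  outside <- setdiff(seq_len(model$n_intervals) - 1L, .in_range_bins(model))
  if (any(p[outside + 1L] != 0)) stop("p must be 0 outside the tissue range")
  structure(list(model = model, p = as.numeric(p), tissue = as.character(tissue)),
            class = "p_coefficients")
}

# Leave-one-out fusion cache: Fv_SRLF / Fv_PSWV do not depend on p, so they
# are computed once per pseudo-target and reused for every candidate p.
# Only voxels with computed scores can ever be labelled 1 (all decision
# branches vanish at fs = fp = 0), so the cache is restricted to them.
.ptrain_cache <- function(training_set, sel, srlf_cfg, model) {
  lapply(seq_along(training_set), function(i) {
    tgt <- normalize_intensity(training_set[[i]]$intensity)
    sc <- fusion_scores(tgt, training_set[-i], sel, srlf_cfg,
                        speed_path = TRUE, normalize = TRUE)
    idx <- which(sc$computed)
    list(fs = sc$fv_srlf[idx],
         fp = sc$fv_pswv[idx],
         bin = bin_index(tgt$data[idx], model),
         truth = training_set[[i]]$label$data[idx],
         n_truth = sum(training_set[[i]]$label$data))
  })
}

.cache_dice <- function(entry, pvals, cfg, th) {
  pv <- pvals[entry$bin + 1L]
  seg <- .gplf_decide(entry$fs, entry$fp, pv, cfg, th)
  nf <- sum(seg)
  if (entry$n_truth + nf == 0) return(1)
  2 * sum(seg & entry$truth) / (entry$n_truth + nf)
}

.drop_empty_atlases <- function(training_set) {
  empty <- vapply(training_set, function(a) sum(a$label$data) == 0, logical(1))
  if (any(empty)) {
    warning(sum(empty), " training atlas(es) with empty tissue label excluded")
    training_set <- training_set[!empty]
  }
  if (length(training_set) < 2)
    stop("need at least 2 non-empty training atlases for leave-one-out training")
  training_set
}

#' Evaluate the training objective of a candidate coefficient set
#'
#' Each training atlas in turn acts as pseudo-target and is segmented by the
#' piecewise fusion model from the remaining atlases; its Dice against its own
#' label image is recorded. The objective is the l1 sum of the Dice vector.
#'
#' @param p a [p_coefficients()].
#' @param training_set list of [atlas()] (size >= 2).
#' @param cfg a [tissue_config()].
#' @param sel a [selection_config()].
#' @param srlf_cfg an [srlf_config()].
#' @param th a [gplf_thresholds()].
#' @param cache internal fusion-score cache (recomputed when `NULL`).
#' @return An object of class `training_report`: `dsc_vector`, `objective`,
#'   `n_atlases`, `iterations`.
#' @export
evaluate_p_objective <- function(p, training_set, cfg, sel = selection_config(),
                                 srlf_cfg = srlf_config(), th = gplf_thresholds(),
                                 cache = NULL) {
  stopifnot(inherits(p, "p_coefficients"))
  training_set <- .drop_empty_atlases(training_set)
  if (is.null(cache)) cache <- .ptrain_cache(training_set, sel, srlf_cfg, p$model)
  dsc <- vapply(cache, .cache_dice, numeric(1), pvals = p$p, cfg = cfg, th = th)
  structure(list(dsc_vector = dsc, objective = sum(dsc),
                 n_atlases = length(cache), iterations = NA_integer_),
            class = "training_report")
}

#' Train the per-bin greyscale probabilities
#'
#' Deterministic coordinate ascent over the in-range intensity bins: bins are
#' swept in fixed order and each bin takes the grid value maximizing the
#' summed leave-one-out Dice with all other bins held fixed, until a full
#' sweep changes nothing or `max_sweeps` is reached. The objective is
#' piecewise-constant in p (every fusion branch thresholds a product), so a
#' finite grid search is the natural optimizer. Ties go to the smaller grid
#' value. Initialization is p = 0.5 on in-range bins, 0 elsewhere.
#'
#' @inheritParams evaluate_p_objective
#' @param grid finite candidate probabilities; must contain 0 and 1.
#'   Default `seq(0, 1, 0.1)`.
#' @param max_sweeps sweep cap. Default 5.
#' @param seed optional integer; the optimizer is deterministic, the seed is
#'   recorded for provenance only.
#' @param model optional `greyscale_model`; when `NULL`, built from the pooled
#'   masked intensities of the training set via [set_tissue_range()].
#' @return A list with elements `pcoeffs` ([p_coefficients()]) and `report`
#'   (`training_report`).
#' @export
train_p <- function(training_set, cfg, sel = selection_config(),
                    srlf_cfg = srlf_config(), th = gplf_thresholds(),
                    grid = seq(0, 1, 0.1), max_sweeps = 5L, seed = NULL,
                    model = NULL) {
  if (!length(training_set)) stop("empty training set")
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid < 0 | grid > 1) || !(0 %in% grid) || !(1 %in% grid))
    stop("grid must lie in [0, 1] and contain 0 and 1")
  training_set <- .drop_empty_atlases(training_set)
  if (is.null(model)) {
    values <- unlist(lapply(training_set, function(a)
      .masked_values(normalize_intensity(a$intensity), NULL)))
    model <- set_tissue_range(values, cfg = cfg)
  }
  cache <- .ptrain_cache(training_set, sel, srlf_cfg, model)
  inb <- .in_range_bins(model)
  pvals <- numeric(model$n_intervals)
  pvals[inb + 1L] <- 0.5
  obj <- function(pv) sum(vapply(cache, .cache_dice, numeric(1),
                                 pvals = pv, cfg = cfg, th = th))
  cur <- obj(pvals)
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    changed <- FALSE
    for (b in inb) {
      best_val <- pvals[b + 1L]
      best_obj <- cur
      for (g in grid) {                    # ascending: ties keep the smaller value
        if (g == pvals[b + 1L]) next
        cand <- pvals
        cand[b + 1L] <- g
        o <- obj(cand)
        if (o > best_obj || (o == best_obj && g < best_val)) {
          best_obj <- o
          best_val <- g
        }
      }
      if (best_val != pvals[b + 1L]) {
        pvals[b + 1L] <- best_val
        cur <- best_obj
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pc <- p_coefficients(model, pvals, cfg$name)
  dsc <- vapply(cache, .cache_dice, numeric(1), pvals = pvals, cfg = cfg, th = th)
  report <- structure(list(dsc_vector = dsc, objective = sum(dsc),
                           n_atlases = length(cache), iterations = sweeps,
                           seed = seed),
                      class = "training_report")
  list(pcoeffs = pc, report = report)
}

#' Save / load trained coefficients as JSON
#'
#' The JSON file carries the tissue name, the greyscale model (bin count,
#' edges, peaks, tissue range) and the per-bin probabilities, and round-trips
#' exactly.
#'
#' @param p a [p_coefficients()].
#' @param path file path.
#' @return `save_p` returns `path` invisibly; `load_p` returns the
#'   [p_coefficients()].
#' @export
save_p <- function(p, path) {
  stopifnot(inherits(p, "p_coefficients"))
  x <- list(tissue = p$tissue,
            n_intervals = p$model$n_intervals,
            bin_edges = p$model$bin_edges,
            peak_bins = p$model$peak_bins,
            isn_max = p$model$isn_max,
            tissue_range = p$model$tissue_range,
            p = p$p)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_p
#' @export
load_p <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot parse coefficient file: ", conditionMessage(e)))
  need <- c("tissue", "n_intervals", "bin_edges", "peak_bins", "isn_max",
            "tissue_range", "p")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("coefficient file missing fields: ", paste(miss, collapse = ", "))
  model <- structure(list(n_intervals = as.integer(x$n_intervals),
                          bin_edges = as.numeric(x$bin_edges),
                          counts = NULL,
                          peak_bins = as.integer(x$peak_bins),
                          isn_max = as.integer(x$isn_max),
                          tissue_range = as.numeric(x$tissue_range),
                          tissue = x$tissue),
                     class = "greyscale_model")
  p_coefficients(model, as.numeric(x$p), x$tissue)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("training report: %d atlases, objective %.4f (mean Dsc %.4f), %s sweep(s)\n",
              x$n_atlases, x$objective, x$objective / x$n_atlases,
              ifelse(is.na(x$iterations), "?", x$iterations)))
  invisible(x)
}

#' @export
print.p_coefficients <- function(x, ...) {
  cat(sprintf("p_coefficients (%s): %d bins, tissue range [%.3f, %.3f], %d nonzero\n",
              x$tissue, x$model$n_intervals, x$model$tissue_range[1],
              x$model$tissue_range[2], sum(x$p > 0)))
  invisible(x)
}
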