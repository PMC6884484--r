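# run expr with a private, restored RNG state (Mersenne-Twister / Inversion)
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Phantom specification
#'
#' Describes a piecewise-constant head phantom: shape primitives (ellipsoids
#' or boxes) painted in order onto a zero background, additive Gaussian
#' intensity noise inside the head, and one primitive flagged as the target
#' tissue. The default emulates an IBSR-like axial block at desk scale:
#' 48x48x12 voxels, 1x1x1.5 mm spacing, a brain ellipsoid (intensity 0.35), a
#' deep white-matter-like ellipsoid (0.55) and a bright deep-grey target
#' nucleus (0.8), noise s.d. 0.03.
#'
#' @param grid_shape integer length-3 volume dimensions.
#' @param spacing voxel size in mm.
#' @param tissue_shapes list of primitives: each a list with `type`
#'   (`"ellipsoid"` or `"box"`), `center` (voxel coords), `size` (semi-axes /
#'   half-extents in voxels), `intensity` (mean), and optionally
#'   `target = TRUE` marking the labelled structure (exactly one).
#' @param noise_sigma intensity noise s.d. Default 0.03.
#' @param background_intensity background mean. Default 0.
#' @param check_separability require every tissue mean to differ from the
#'   background by at least `2 * noise_sigma`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 12L),
                         spacing = c(1, 1, 1.5),
                         tissue_shapes = NULL,
                         noise_sigma = 0.03,
                         background_intensity = 0,
                         check_separability = TRUE) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(tissue_shapes)) {
    c0 <- (grid_shape + 1) / 2
    tissue_shapes <- list(
      list(type = "ellipsoid", center = c0, size = c(20, 20, 5),
           intensity = 0.35),
      list(type = "ellipsoid", center = c0, size = c(13, 13, 3.6),
           intensity = 0.55),
      list(type = "ellipsoid", center = c0 + c(3, -2.5, 0), size = c(6, 6, 2.5),
           intensity = 0.8, target = TRUE)
    )
  }
  n_target <- sum(vapply(tissue_shapes, function(s) isTRUE(s$target), logical(1)))
  if (n_target != 1L) stop("exactly one tissue shape must be flagged target = TRUE")
  if (check_separability) {
    means <- vapply(tissue_shapes, function(s) s$intensity, numeric(1))
    if (any(abs(means - background_intensity) < 2 * noise_sigma))
      stop("tissue means closer than 2*noise_sigma to the background; ",
           "set check_separability = FALSE to override")
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 tissue_shapes = tissue_shapes, noise_sigma = noise_sigma,
                 background_intensity = background_intensity),
            class = "phantom_spec")
}

#' Warp specification
#'
#' Controls the synthetic stand-in for residual registration error: per atlas,
#' a smooth random displacement field (white noise Gaussian-smoothed at scale
#' `smoothness`, rescaled to per-axis s.d. `displacement_sigma` voxels) warps
#' intensity (trilinear) and label (nearest-neighbour) with the same field,
#' followed by a per-atlas linear intensity jitter.
#'
#' @param n_atlases number of warped atlases. Default 6.
#' @param displacement_sigma displacement amplitude (per-axis s.d., voxels).
#'   Default 1.
#' @param smoothness Gaussian smoothing scale of the field (voxels). Default 3.
#' @param intensity_jitter list with `scale` and `shift` ranges (uniform).
#' @param seed RNG seed; atlas `i` uses `seed + i`.
#' @return An object of class `warp_spec`.
#' @export
warp_spec <- function(n_atlases = 6L, displacement_sigma = 1, smoothness = 3,
                      intensity_jitter = list(scale = c(0.9, 1.1),
                                              shift = c(-0.05, 0.05)),
                      seed = 1L) {
  if (n_atlases < 1) stop("n_atlases must be >= 1")
  if (displacement_sigma < 0) stop("displacement_sigma must be >= 0")
  structure(list(n_atlases = as.integer(n_atlases),
                 displacement_sigma = displacement_sigma,
                 smoothness = smoothness,
                 intensity_jitter = intensity_jitter,
                 seed = as.integer(seed)),
            class = "warp_spec")
}

.shape_mask <- function(shape, dims) {
  x <- seq_len(dims[1]); y <- seq_len(dims[2]); z <- seq_len(dims[3])
  cx <- shape$center; sz <- shape$size
  if (shape$type == "ellipsoid") {
    qx <- ((x - cx[1]) / sz[1])^2
    qy <- ((y - cx[2]) / sz[2])^2
    qz <- ((z - cx[3]) / sz[3])^2
    outer(outer(qx, qy, "+"), qz, "+") <= 1
  } else if (shape$type == "box") {
    bx <- abs(x - cx[1]) <= sz[1]
    by <- abs(y - cx[2]) <= sz[2]
    bz <- abs(z - cx[3]) <= sz[3]
    outer(outer(bx, by, "&"), bz, "&")
  } else stop("unknown shape type '", shape$type, "'")
}

#' Generate a noisy piecewise-constant phantom
#'
#' Primitives are painted in list order (a later primitive overwrites earlier
#' ones where they overlap, with a warning); Gaussian noise is added inside
#' the head (background voxels stay exactly 0); intensities are min-max
#' normalized to [0, 1] over the head and clipped. The label marks the
#' primitive flagged `target` (pre-noise membership). Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return List with `intensity` ([intensity_volume()], values in [0, 1]) and
#'   `label` ([label_volume()]).
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  img <- array(spec$background_intensity, d)
  claimed <- array(FALSE, d)
  lab <- array(0L, d)
  head <- array(FALSE, d)
  for (shape in spec$tissue_shapes) {
    m <- .shape_mask(shape, d)
    if (!any(m)) stop("tissue shape lies outside the grid")
    ov <- sum(m & claimed)
    if (ov > 0)   # nested anatomy is the normal case, so log rather than warn
      message("tissue shape overlaps ", ov, " voxel(s) of an earlier shape; later shape wins")
    img[m] <- shape$intensity
    claimed <- claimed | m
    head <- head | m
    if (isTRUE(shape$target)) lab <- array(as.integer(m), d)
  }
  .with_seed(seed, {
    if (spec$noise_sigma > 0)
      img[head] <- img[head] + stats::rnorm(sum(head), 0, spec$noise_sigma)
  })
  vol <- intensity_volume(img, spec$spacing)
  vol <- if (any(head)) {
    mask <- label_volume(array(as.integer(head), d), spec$spacing)
    normalize_intensity(vol, mask)
  } else vol
  vol$data <- pmin(pmax(vol$data, 0), 1)
  vol$data <- array(vol$data, d)
  list(intensity = vol, label = label_volume(lab, spec$spacing))
}

.gauss_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  for (axis in 1:3) {
    d <- dim(arr)
    n <- d[axis]
    out <- array(0, d)
    for (t in -r:r) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)
      shifted <- switch(axis,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[t + r + 1] * shifted
    }
    arr <- out
  }
  arr
}

.trilinear_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2]); zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L); z0 <- pmin(floor(zi), d[3] - 1L)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  g <- function(a, b, c) arr[cbind(a, b, c)]
  v000 <- g(x0, y0, z0);     v100 <- g(x0 + 1, y0, z0)
  v010 <- g(x0, y0 + 1, z0); v110 <- g(x0 + 1, y0 + 1, z0)
  v001 <- g(x0, y0, z0 + 1); v101 <- g(x0 + 1, y0, z0 + 1)
  v011 <- g(x0, y0 + 1, z0 + 1); v111 <- g(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

.nearest_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  arr[cbind(pmin(pmax(round(xi), 1), d[1]),
            pmin(pmax(round(yi), 1), d[2]),
            pmin(pmax(round(zi), 1), d[3]))]
}

#' Generate warped atlases from a ground-truth pair
#'
#' @param truth list with `intensity` and `label` (as from [make_phantom()]).
#' @param warp a [warp_spec()].
#' @return List of [atlas()] objects of length `warp$n_atlases`.
#' @export
make_warped_atlases <- function(truth, warp) {
  stopifnot(inherits(warp, "warp_spec"))
  d <- dim(truth$intensity$data)
  if (!identical(d, dim(truth$label$data))) stop("truth volumes are on different grids")
  grid_ <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  lapply(seq_len(warp$n_atlases), function(i) {
    .with_seed(warp$seed + i, {
      if (warp$displacement_sigma > 0) {
        u <- lapply(1:3, function(ax) {
          f <- .gauss_smooth3d(array(stats::rnorm(prod(d)), d), warp$smoothness)
          s <- stats::sd(as.numeric(f))
          if (s > 0) f * (warp$displacement_sigma / s) else f
        })
      } else {
        u <- lapply(1:3, function(ax) array(0, d))
      }
      xi <- grid_$x + as.numeric(u[[1]]); yi <- grid_$y + as.numeric(u[[2]])
      zi <- grid_$z + as.numeric(u[[3]])
      img <- array(.trilinear_sample(truth$intensity$data, xi, yi, zi), d)
      lab <- array(as.integer(.nearest_sample(truth$label$data, xi, yi, zi)), d)
      jit <- warp$intensity_jitter
      if (!is.null(jit)) {
        sc <- stats::runif(1, jit$scale[1], jit$scale[2])
        sh <- stats::runif(1, jit$shift[1], jit$shift[2])
        nz <- img > 0
        img <- img * sc
        img[nz] <- img[nz] + sh
        img <- pmin(pmax(img, 0), 1)
        img <- array(img, d)
      }
      atlas(sprintf("atlas%02d", i),
            intensity_volume(img, truth$intensity$spacing),
            label_volume(lab, truth$label$spacing))
    })
  })
}

#' Write a reproducible phantom dataset to disk
#'
#' Writes, per subject, a target intensity/label pair and `warp$n_atlases`
#' warped atlas pairs as uncompressed NIfTI files plus a JSON manifest
#' (specs, seeds, RNG kind) that allows exact regeneration.
#'
#' @param spec a [phantom_spec()].
#' @param warp a [warp_spec()].
#' @param n_subjects number of independent subjects. Default 1.
#' @param out_dir output directory (created if missing; must be empty unless
#'   `force`).
#' @param seed base seed; subject s uses phantom seed `seed + 1000*s` and warp
#'   seed `seed + 1000*s + 500`.
#' @param force allow writing into a non-empty directory.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
make_dataset <- function(spec, warp, n_subjects = 1L, out_dir, seed = warp$seed,
                         force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory is not empty: ", out_dir, " (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema_version = 1L, rng = "Mersenne-Twister/Inversion",
                   base_seed = seed, n_subjects = n_subjects,
                   phantom_spec = unclass(spec), warp_spec = unclass(warp),
                   subjects = list())
  for (s in seq_len(n_subjects)) {
    sdir <- file.path(out_dir, sprintf("subject%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    pseed <- seed + 1000L * s
    wseed <- seed + 1000L * s + 500L
    truth <- make_phantom(spec, pseed)
    w <- warp
    w$seed <- wseed
    atl <- make_warped_atlases(truth, w)
    write_volume(truth$intensity, file.path(sdir, "target_intensity.nii"))
    write_volume(truth$label, file.path(sdir, "target_label.nii"))
    for (i in seq_along(atl)) {
      write_volume(atl[[i]]$intensity, file.path(sdir, sprintf("atlas%02d_intensity.nii", i)))
      write_volume(atl[[i]]$label, file.path(sdir, sprintf("atlas%02d_label.nii", i)))
    }
    manifest$subjects[[s]] <- list(dir = basename(sdir), phantom_seed = pseed,
                                   warp_seed = wseed, n_atlases = warp$n_atlases)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset directory written by [make_dataset()]
#'
#' @param dir subject directory holding `target_*.nii` and `atlasNN_*.nii`.
#' @return List with `target` (`intensity_volume`), `truth` (`label_volume`)
#'   and `atlases` (list of [atlas()]).
#' @export
read_dataset <- function(dir) {
  target <- read_volume(file.path(dir, "target_intensity.nii"))
  truth <- read_volume(file.path(dir, "target_label.nii"), as_label = TRUE)
  ifiles <- sort(dir(dir, pattern = "^atlas[0-9]+_intensity\\.nii(\\.gz)?$", full.names = TRUE))
  atlases <- lapply(ifiles, function(f) {
    lf <- sub("_intensity\\.nii", "_label.nii", f)
    atlas(sub("_intensity\\.nii(\\.gz)?$", "", basename(f)),
          read_volume(f), read_volume(lf, as_label = TRUE))
  })
  list(target = target, truth = truth, atlases = atlases)
}
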