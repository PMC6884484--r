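# Fixtures are built in code at test time; nothing binary on disk.

# Small phantom world for fast pipeline tests (32x32x8, ~100-voxel nucleus).
small_spec <- function(noise_sigma = 0.03) {
  phantom_spec(grid_shape = c(32L, 32L, 8L), spacing = c(1, 1, 1.5),
               tissue_shapes = list(
                 list(type = "ellipsoid", center = c(16.5, 16.5, 4.5),
                      size = c(13, 13, 3.5), intensity = 0.35),
                 list(type = "ellipsoid", center = c(16.5, 16.5, 4.5),
                      size = c(9, 9, 2.6), intensity = 0.55),
                 list(type = "ellipsoid", center = c(18.5, 14.5, 4.5),
                      size = c(4.5, 4.5, 1.8), intensity = 0.8, target = TRUE)),
               noise_sigma = noise_sigma)
}

small_world <- function(seed = 1, n_atlases = 4, displacement_sigma = 1,
                        noise_sigma = 0.03) {
  truth <- suppressMessages(make_phantom(small_spec(noise_sigma), seed = seed))
  atl <- make_warped_atlases(truth, warp_spec(n_atlases = n_atlases,
                                              displacement_sigma = displacement_sigma,
                                              seed = seed + 1000))
  list(truth = truth, atlases = atl)
}

# label volume from explicit foreground voxel coordinates
label_from_coords <- function(coords, dims, spacing = c(1, 1, 1)) {
  arr <- array(0L, dims)
  if (length(coords)) arr[coords] <- 1L
  label_volume(arr, spacing)
}

random_mask <- function(dims, n_max = 30) {
  n <- sample.int(n_max, 1)
  idx <- sample.int(prod(dims), n)
  arr <- array(0L, dims)
  arr[idx] <- 1L
  label_volume(arr, c(1, 1, 1))
}

# Brute-force Hausdorff oracle: O(|T| * |F|) pairwise distances.
brute_hausdorff <- function(t_vol, f_vol, spacing = t_vol$spacing) {
  A <- which(t_vol$data == 1L, arr.ind = TRUE)
  B <- which(f_vol$data == 1L, arr.ind = TRUE)
  if (!nrow(A) || !nrow(B)) return(NA_real_)
  A <- sweep(A, 2, spacing, "*"); B <- sweep(B, 2, spacing, "*")
  directed <- function(X, Y) {
    max(vapply(seq_len(nrow(X)), function(i)
      min(sqrt(colSums((t(Y) - X[i, ])^2))), numeric(1)))
  }
  max(directed(A, B), directed(B, A))
}

# Exhaustive L0 oracle: best residual over all supports of size <= max_support.
brute_l0 <- function(pt, D, max_support) {
  m <- ncol(D)
  best <- sqrt(sum(pt^2))                       # empty support
  for (s in seq_len(max_support)) {
    for (idx in utils::combn(m, s, simplify = FALSE)) {
      cf <- qr.coef(qr(D[, idx, drop = FALSE]), pt)
      cf[is.na(cf)] <- 0
      r <- sqrt(sum((pt - D[, idx, drop = FALSE] %*% cf)^2))
      best <- min(best, r)
    }
  }
  best
}
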