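make_slab_atlas <- function(id, n_slices, dz = 1.5, fill = 0.5) {
  arr <- array(fill, c(4, 4, n_slices))
  atlas(id, intensity_volume(arr, c(1, 1, dz)),
        label_volume(array(0L, c(4, 4, n_slices)), c(1, 1, dz)))
}

test_that("atlas slice selection keeps the closed interval [TSP-SR, TSP+SR]", {
  atl <- list(make_slab_atlas("a", 50), make_slab_atlas("b", 50))
  sel <- select_atlases_by_position(atl, tsp = 60, sr = 3)
  # boundary positions 57 and 63 are retained
  expect_setequal(unique(sel$position), c(57, 58.5, 60, 61.5, 63))
  expect_equal(nrow(sel), 2 * 5)

  only <- select_atlases_by_position(atl, tsp = 60, sr = 0)
  expect_equal(unique(only$position), 60)

  expect_error(select_atlases_by_position(atl, tsp = 500, sr = 1), "widen")
})

test_that("widening the search radius returns a superset of slices", {
  atl <- list(make_slab_atlas("a", 30))
  s1 <- select_atlases_by_position(atl, tsp = 20, sr = 2)
  s2 <- select_atlases_by_position(atl, tsp = 20, sr = 5)
  expect_true(all(s1$slice %in% s2$slice))
})

test_that("patch extraction vectorizes in raster order with edge replication", {
  arr <- array(seq_len(3 * 3 * 2), c(3, 3, 2))
  v <- intensity_volume(arr)

  p1 <- extract_patch(v, c(2, 2, 1), c(1, 1, 1))
  expect_equal(p1$vector, arr[2, 2, 1])

  # 3x3x1 patch at the (1,1,1) corner: offsets clamp to the edge
  p2 <- extract_patch(v, c(1, 1, 1), c(3, 3, 1))
  expected <- c(arr[1, 1, 1], arr[1, 1, 1], arr[2, 1, 1],   # dy = -1 -> col 1
                arr[1, 1, 1], arr[1, 1, 1], arr[2, 1, 1],   # dy =  0
                arr[1, 2, 1], arr[1, 2, 1], arr[2, 2, 1])   # dy = +1
  expect_equal(p2$vector, expected)
  expect_length(p2$vector, 9)

  expect_identical(extract_patch(v, c(2, 2, 1), c(3, 3, 1))$vector,
                   extract_patch(v, c(2, 2, 1), c(3, 3, 1))$vector)
  expect_error(extract_patch(v, c(1, 1, 1), c(2, 3, 1)), "odd")
})

test_that("ncc behaves as a Pearson similarity", {
  a <- c(1, 2, 3, 5)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a), -1)
  expect_equal(ncc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(ncc(a, rep(2, 4)), 0)      # constant vector convention
  expect_error(ncc(a, c(1, 2)), "length")

  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(ncc(x, y), ncc(y, x))
    s <- runif(1, 0.1, 4); t <- rnorm(1)
    expect_equal(ncc(s * x + t, y), ncc(x, y), tolerance = 1e-12)
  }
})

test_that("patch library ranks by similarity, stable, capped at K", {
  set.seed(5)
  tv <- rnorm(12)
  # candidates engineered to have decreasing correlation with tv
  mix <- function(w) w * (tv - mean(tv)) + (1 - w) * rnorm(12)
  cands <- list(list(patch = mix(0.95), label = 1),
                list(patch = mix(0.05), label = 0),
                list(patch = mix(0.6), label = 1))
  lib <- build_patch_library(tv, cands, k = 2)
  expect_equal(ncol(lib$columns), 2)
  expect_true(all(diff(lib$similarities) <= 0))
  sims_all <- sapply(cands, function(c_) ncc(tv, c_$patch))
  expect_equal(lib$similarities, sort(sims_all, decreasing = TRUE)[1:2])

  # K larger than the candidate pool keeps everything
  lib_all <- build_patch_library(tv, cands, k = 60)
  expect_equal(ncol(lib_all$columns), 3)
  expect_true(all(diff(lib_all$similarities) <= 0))

  # exact ties keep input order (duplicate candidate)
  cands_tie <- list(list(patch = mix(0.5), label = 1),
                    list(patch = cands[[1]]$patch, label = 0),
                    list(patch = cands[[1]]$patch, label = 1))
  lib_tie <- build_patch_library(tv, cands_tie, k = 3)
  expect_equal(lib_tie$center_labels[1:2], c(0L, 1L))

  expect_error(build_patch_library(tv, list(), k = 2), "candidate")
})
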