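test_that("noiseless phantoms are piecewise constant and seeded runs reproduce", {
  spec <- small_spec(noise_sigma = 0)
  ph <- suppressMessages(make_phantom(spec, seed = 1))
  vals <- sort(unique(as.numeric(ph$intensity$data)))
  # background 0 plus three normalized tissue levels
  expect_lte(length(vals), 4)
  expect_equal(min(vals), 0)
  expect_equal(max(vals), 1)

  ph2 <- suppressMessages(make_phantom(small_spec(), seed = 9))
  ph3 <- suppressMessages(make_phantom(small_spec(), seed = 9))
  expect_identical(ph2$intensity$data, ph3$intensity$data)
  expect_identical(ph2$label$data, ph3$label$data)
  ph4 <- suppressMessages(make_phantom(small_spec(), seed = 10))
  expect_false(identical(ph2$intensity$data, ph4$intensity$data))

  expect_true(all(ph2$intensity$data >= 0 & ph2$intensity$data <= 1))
  expect_true(all(ph2$label$data %in% c(0L, 1L)))
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(suppressMessages(make_phantom(small_spec(), seed = 5)))
  expect_identical(runif(1), a)
})

test_that("target label equals brute-force ellipsoid membership", {
  spec <- small_spec()
  ph <- suppressMessages(make_phantom(spec, seed = 2))
  sh <- spec$tissue_shapes[[3]]
  count <- 0L
  for (x in 1:32) for (y in 1:32) for (z in 1:8) {
    if (((x - sh$center[1]) / sh$size[1])^2 +
        ((y - sh$center[2]) / sh$size[2])^2 +
        ((z - sh$center[3]) / sh$size[3])^2 <= 1) count <- count + 1L
  }
  expect_equal(sum(ph$label$data), count)
})

test_that("zero displacement and no jitter reproduce the truth exactly", {
  ph <- suppressMessages(make_phantom(small_spec(), seed = 3))
  atl <- make_warped_atlases(ph, warp_spec(n_atlases = 2, displacement_sigma = 0,
                                           intensity_jitter = NULL, seed = 7))
  expect_equal(length(atl), 2)
  for (a in atl) {
    expect_identical(a$intensity$data, ph$intensity$data)
    expect_identical(a$label$data, ph$label$data)
  }
})

test_that("warped labels stay binary and share the displacement field with intensity", {
  ph <- suppressMessages(make_phantom(small_spec(), seed = 4))
  atl <- make_warped_atlases(ph, warp_spec(n_atlases = 3, displacement_sigma = 1.5,
                                           seed = 8))
  for (a in atl) {
    expect_true(all(a$label$data %in% c(0L, 1L)))
    expect_true(all(a$intensity$data >= 0 & a$intensity$data <= 1))
    # label moved together with intensity: bright voxels concentrate on the label
    expect_gt(mean(a$intensity$data[a$label$data == 1L]),
              mean(a$intensity$data[a$label$data == 0L & a$intensity$data > 0]))
  }
})

test_that("label agreement with the truth decays as displacement grows", {
  ph <- suppressMessages(make_phantom(small_spec(), seed = 6))
  mean_dice <- vapply(c(0, 1, 2), function(ds) {
    atl <- make_warped_atlases(ph, warp_spec(n_atlases = 5,
                                             displacement_sigma = ds, seed = 21))
    mean(vapply(atl, function(a) dice(ph$label, a$label), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
  expect_equal(mean_dice[1], 1)
})

test_that("datasets regenerate bit-identically and refuse dirty directories", {
  spec <- small_spec()
  warp <- warp_spec(n_atlases = 2, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_dataset(spec, warp, n_subjects = 1, out_dir = d1, seed = 5)
  make_dataset(spec, warp, n_subjects = 1, out_dir = d2, seed = 5)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  expect_equal(sum(grepl("atlas", f1)), 4)         # 2 atlases x 2 channels
  expect_true("manifest.json" %in% basename(f1))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     info = f)

  expect_error(make_dataset(spec, warp, out_dir = d1, seed = 5), "not empty")
  expect_no_error(suppressMessages(
    make_dataset(spec, warp, out_dir = d1, seed = 5, force = TRUE)))

  ds <- read_dataset(file.path(d1, "subject01"))
  expect_length(ds$atlases, 2)
  expect_identical(dim(ds$target$data), c(32L, 32L, 8L))
})
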