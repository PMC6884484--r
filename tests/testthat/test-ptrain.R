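# quick world shared by the training tests
ptrain_world <- function(seed = 13, n_atlases = 3) {
  w <- small_world(seed = seed, n_atlases = n_atlases)
  cfg <- gplf_tissue("thalamus")
  values <- unlist(lapply(w$atlases, function(a)
    gplfuse:::.masked_values(normalize_intensity(a$intensity), NULL)))
  model <- set_tissue_range(values, cfg = cfg)
  list(w = w, cfg = cfg, model = model,
       sel = selection_config(patch_shape = c(5, 5, 3)))
}

test_that("p_coefficients enforces range and bound invariants", {
  m <- set_tissue_range(c(rep(0.42, 50), rep(0.62, 40)), cfg = gplf_tissue("thalamus"))
  p <- numeric(m$n_intervals)
  expect_s3_class(p_coefficients(m, p, "thalamus"), "p_coefficients")
  p_bad <- p; p_bad[1] <- 1.2
  expect_error(p_coefficients(m, p_bad, "thalamus"), "\\[0, 1\\]")
  outside <- setdiff(seq_len(m$n_intervals) - 1L, gplfuse:::.in_range_bins(m))
  if (length(outside)) {
    p_out <- p; p_out[outside[1] + 1L] <- 0.5
    expect_error(p_coefficients(m, p_out, "thalamus"), "outside")
  }
})

test_that("objective equals independently computed per-atlas Dice", {
  pw <- ptrain_world()
  fit <- train_p(pw$w$atlases, pw$cfg, pw$sel, model = pw$model)
  rep_ <- evaluate_p_objective(fit$pcoeffs, pw$w$atlases, pw$cfg, pw$sel)
  expect_equal(rep_$objective, sum(rep_$dsc_vector))
  expect_equal(rep_$n_atlases, 3)
  expect_true(all(rep_$dsc_vector >= 0 & rep_$dsc_vector <= 1))

  # cross-check one pseudo-target against the metrics module:
  # segment atlas 1 from atlases 2..3 with the same coefficients
  seg1 <- segment_volume(pw$w$atlases[[1]]$intensity, pw$w$atlases[-1],
                         pcoeffs = fit$pcoeffs, cfg = pw$cfg, sel = pw$sel)
  expect_equal(rep_$dsc_vector[1], dice(pw$w$atlases[[1]]$label, seg1),
               tolerance = 1e-12)
})

test_that("identical atlases with SR = 0 reach the objective upper bound", {
  truth <- suppressMessages(make_phantom(small_spec(), seed = 17))
  atl <- make_warped_atlases(truth, warp_spec(n_atlases = 3,
                                              displacement_sigma = 0,
                                              intensity_jitter = NULL, seed = 1))
  sel <- selection_config(sr = 0, patch_shape = c(3, 3, 1))
  cfg <- gplf_tissue("thalamus")
  fit <- train_p(atl, cfg, sel)
  # every pseudo-target is reproduced exactly (branch 1 fires on fv = 1)
  expect_equal(fit$report$objective, 3, tolerance = 1e-12)
  expect_true(all(fit$report$dsc_vector == 1))
  # the objective is flat in p here (branch 1 decides everything), so every
  # bin ties across the grid and falls to the smallest value
  expect_true(all(fit$pcoeffs$p == 0))
})

test_that("training excludes empty-label atlases and needs two usable ones", {
  pw <- ptrain_world()
  d <- dim(pw$w$truth$label$data)
  hollow <- atlas("empty", pw$w$atlases[[1]]$intensity,
                  label_volume(array(0L, d), pw$w$atlases[[1]]$label$spacing))
  expect_warning(
    fit <- train_p(c(pw$w$atlases, list(hollow)), pw$cfg, pw$sel, model = pw$model),
    "empty")
  expect_equal(fit$report$n_atlases, 3)
  expect_error(suppressWarnings(train_p(list(hollow, hollow), pw$cfg, pw$sel,
                                        model = pw$model)),
               "at least 2")
  expect_error(train_p(list(), pw$cfg), "empty")
})

test_that("coordinate ascent never loses to its own initialization", {
  pw <- ptrain_world(seed = 19)
  fit <- train_p(pw$w$atlases, pw$cfg, pw$sel, model = pw$model,
                 grid = c(0, 0.25, 0.5, 0.75, 1))
  init <- numeric(pw$model$n_intervals)
  init[gplfuse:::.in_range_bins(pw$model) + 1L] <- 0.5
  o0 <- evaluate_p_objective(p_coefficients(pw$model, init, "thalamus"),
                             pw$w$atlases, pw$cfg, pw$sel)
  expect_gte(fit$report$objective, o0$objective)
  expect_true(all(fit$pcoeffs$p %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("trained probabilities concentrate on the bins the tissue occupies", {
  # noiseless world: pure tissue sits at intensity 1 and its partial-volume
  # blends stay above mid-grey, so nonzero p must live in the upper bins
  w <- small_world(seed = 29, n_atlases = 3, displacement_sigma = 0.7,
                   noise_sigma = 0)
  cfg <- gplf_tissue("thalamus")
  # a model whose range [0.4, 1] covers both tissue and mid-grey background
  model <- set_tissue_range(c(rep(0.42, 300), rep(0.83, 200)), cfg = cfg)
  sel <- selection_config(patch_shape = c(5, 5, 3))
  fit <- train_p(w$atlases, cfg, sel, model = model)
  p <- fit$pcoeffs$p
  expect_gt(max(p), 0)
  # p peaks at the pure-tissue bin (intensity 1), and the upper bins where
  # tissue mass concentrates dominate the lower, background-heavy bins
  expect_equal(which.max(p) - 1L, bin_index(1, model))
  expect_gte(max(p[(14:19) + 1L]), max(p[(8:13) + 1L]))
})

test_that("coefficients JSON round-trips exactly and is validated", {
  pw <- ptrain_world(seed = 31)
  fit <- train_p(pw$w$atlases, pw$cfg, pw$sel, model = pw$model)
  path <- withr::local_tempfile(fileext = ".json")
  save_p(fit$pcoeffs, path)
  back <- load_p(path)
  expect_equal(back$p, fit$pcoeffs$p)
  expect_equal(back$model$tissue_range, fit$pcoeffs$model$tissue_range)
  expect_equal(back$model$bin_edges, fit$pcoeffs$model$bin_edges)
  expect_identical(back$tissue, fit$pcoeffs$tissue)

  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$p[1] <- 1.2
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(x, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_p(bad), "\\[0, 1\\]")
  x$p <- NULL
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(x, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(load_p(bad2), "missing")
})
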