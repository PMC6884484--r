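vol_from_values <- function(values) {
  # pad into a 3D array; zeros are outside the default foreground mask,
  # so shift any true zeros slightly is the caller's concern
  n <- length(values)
  d <- c(n, 1, 1)
  intensity_volume(array(values, d))
}

test_that("histogram binning follows the half-open convention", {
  v <- vol_from_values(c(0.1, 0.12, 0.9))
  counts <- histogram_counts(v, n_intervals = 20)
  expect_equal(sum(counts), 3)
  expect_equal(counts[2 + 1], 2)      # bin 2 (0-based) = [0.10, 0.15)
  expect_equal(counts[18 + 1], 1)     # bin 18 = [0.90, 0.95)

  cl <- histogram_counts(vol_from_values(c(1, 0.5)), n_intervals = 20)
  expect_equal(cl[20], 1)             # 1.0 closed into the last bin
  expect_error(histogram_counts(vol_from_values(c(0.5, 1.2))), "normalized")
  expect_error(histogram_counts(v, n_intervals = 1), "n_intervals")
})

test_that("histogram counts sum to the mask size", {
  set.seed(8)
  arr <- array(runif(6 * 6 * 3), c(6, 6, 3))
  m <- label_volume(array(rbinom(6 * 6 * 3, 1, 0.5), c(6, 6, 3)))
  counts <- histogram_counts(intensity_volume(arr), m, 20)
  expect_equal(sum(counts), sum(m$data))
})

test_that("peak detection requires strict local maxima with enough mass", {
  expect_equal(detect_peaks(c(1, 5, 1)), 1L)
  expect_equal(detect_peaks(c(1, 2, 3, 4)), integer(0))       # monotone
  expect_equal(detect_peaks(c(0, 3, 3, 0)), integer(0))       # plateau
  expect_equal(detect_peaks(c(5, 1, 1)), integer(0))          # edges never peak
  counts <- c(0, 50, 0, 1, 0, 60, 0)
  expect_equal(detect_peaks(counts, min_fraction = 0.05), c(1L, 5L))  # bin 3 too light
  expect_equal(detect_peaks(counts, min_fraction = 0), c(1L, 3L, 5L))
  expect_equal(detect_peaks(10 * counts, min_fraction = 0.05),
               detect_peaks(counts, min_fraction = 0.05))     # scaling invariance
})

test_that("tissue range derives from the highest peak bin's upper edge", {
  # bimodal: peaks in 0-based bins 8 and 12 of 20
  values <- c(rep(0.42, 300), rep(0.37, 40), rep(0.47, 40),
              rep(0.62, 200), rep(0.57, 30), rep(0.67, 30))
  m <- set_tissue_range(values, cfg = gplf_tissue("thalamus"))
  expect_equal(m$n_intervals, 20L)
  expect_setequal(m$peak_bins, c(8L, 12L))
  expect_equal(m$isn_max, 12L)
  # value(ISNmax) = 0.65, thalamus offset +0.15 span 0.6 -> [0.2, 0.8]
  expect_equal(m$tissue_range, c(0.2, 0.8))
  # width equals the configured span when not clipped
  expect_equal(diff(m$tissue_range), 0.6)
})

test_that("a unimodal histogram triggers re-binning at twice the intervals", {
  # one clear mode at 20 bins; modes at 0.30/0.36 merge into adjacent
  # equal-count bins (plateau, not peaks) until 40 bins separate them
  values <- c(rep(0.10, 500), rep(0.30, 300), rep(0.36, 300))
  m <- set_tissue_range(values, cfg = gplf_tissue("hippocampus"))
  expect_equal(m$n_intervals, 40L)
  expect_setequal(m$peak_bins, c(4L, 12L, 14L))
  expect_equal(m$isn_max, 14L)
  # upper = 15/40 + 0 = 0.375; lower clipped at 0
  expect_equal(m$tissue_range, c(0, 0.375))
})

test_that("range detection errors when no scale yields peaks", {
  # an empty foreground has no histogram mass at any binning scale
  expect_error(set_tissue_range(numeric(0), cfg = gplf_tissue("caudate")),
               "peak")
})

test_that("a single sharp mode is accepted via the closest-to-2-peaks fallback", {
  m <- set_tissue_range(rep(0.5, 100), cfg = gplf_tissue("caudate"))
  expect_equal(length(m$peak_bins), 1L)
  expect_equal(m$tissue_range[2], (m$isn_max + 1) / m$n_intervals)
})

test_that("bin lookup matches the histogram convention", {
  m <- set_tissue_range(c(rep(0.42, 100), rep(0.62, 80), rep(0.2, 10)),
                        cfg = gplf_tissue("thalamus"))
  expect_equal(m$n_intervals, 20L)
  expect_equal(bin_index(0, m), 0L)
  expect_equal(bin_index(1, m), 19L)
  expect_equal(bin_index(0.05, m), 1L)
  expect_error(bin_index(1.5, m), "intensity")
})

test_that("shipped tissue config file matches the built-in table", {
  path <- system.file("extdata", "tissues.json", package = "gplfuse")
  for (tn in gplf_tissues()) {
    file_cfg <- load_tissue_config(path, tn)
    builtin <- gplf_tissue(tn)
    expect_equal(unclass(file_cfg), unclass(builtin))
  }
  expect_error(load_tissue_config(path, "cerebellum"), "not present")
  expect_error(gplf_tissue("cortex"), "unknown tissue")
})
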