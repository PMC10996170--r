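test_that("area surrogate is the landmark-span product", {
  s <- makeSeries(rep(60, 5), left_x = 30, right_x = 70, top_y = 40)
  expect_equal(unname(areaSeries(s)), rep(40 * 20, 5))
  # degenerate zero width
  s0 <- makeSeries(rep(60, 3), left_x = 50, right_x = 50)
  expect_equal(unname(areaSeries(s0)), rep(0, 3))
  # missing samples propagate
  sm <- makeSeries(rep(60, 5), missing = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(areaSeries(sm)[2]))
  # ellipse-derived landmarks: constant 800 px^2
  ell <- ellipseContour(360, a = 20, b = 10)
  ch <- maxDiameterChord(ell)
  ext <- verticalExtents(ell, ch$center[["x"]])
  expect_equal((ch$right[["x"]] - ch$left[["x"]]) *
                 (ext$bottom[["y"]] - ext$top[["y"]]), 800,
               tolerance = 1e-8)
})

test_that("base elevation is the Bottom_y excursion over ok samples", {
  expect_equal(baseElevation(c(60, 58, 55, 58, 60)), 5)
  expect_equal(baseElevation(rep(61.2, 8)), 0)
  expect_true(is.na(baseElevation(c(60, NA, NA))))      # < 2 ok samples
  expect_equal(baseElevation(c(60, NA, 55, NA, 58)), 5) # NA excluded
  expect_gte(baseElevation(rnorm(10, 60)), 0)
  s <- makeSeries(c(60, 58, 55, 58, 60))
  expect_equal(baseElevation(s), 5)
})

test_that("channel features match hand-computed and DFT-definition values", {
  f <- computeChannelFeatures(c(0, 1, 0, 2, 0), 2.4)
  expect_equal(unname(f["number_of_peaks_1"]), 2)
  expect_equal(unname(f["maximum"]), 2)
  expect_equal(unname(f["mean"]), 0.6)

  # |FFT_1| of one sine period over 8 samples is N/2 = 4
  x <- sin(2 * pi * (0:7) / 8)
  expect_equal(unname(computeChannelFeatures(x, 2.4)["abs_fft_coefficient_1"]),
               4, tolerance = 1e-10)

  # period-10-sample sinusoid, N = 40 at 2.4 Hz -> bin 4 -> 0.24 Hz
  xs <- sin(2 * pi * (0:39) / 10)
  expect_equal(unname(computeChannelFeatures(xs, 2.4)["dominant_frequency_hz"]),
               0.24)

  # constant series: no spread, no spectrum, no peaks
  k <- computeChannelFeatures(rep(7, 10), 2.4)
  expect_equal(unname(k["standard_deviation"]), 0)
  expect_equal(unname(k[paste0("abs_fft_coefficient_", 1:4)]),
               rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(k["number_of_peaks_1"]), 0)
  expect_equal(unname(k["range"]), 0)
})

test_that("too-short or gapped series yield missing features, not errors", {
  f <- computeChannelFeatures(c(5, NA, 7, 8, NA, 6), 2.4)
  expect_false(is.na(f["mean"]))
  expect_false(is.na(f["standard_deviation"]))
  # spectral features require a gap-free series
  expect_true(all(is.na(f[c("abs_fft_coefficient_1",
                            "dominant_frequency_hz", "spectral_energy")])))
  # support-3 peaks need at least 7 samples
  expect_true(is.na(f["number_of_peaks_3"]))
  f1 <- computeChannelFeatures(c(NA, 3, NA), 2.4)
  expect_equal(unname(f1["mean"]), 3)
  expect_true(is.na(f1["standard_deviation"]))
})

test_that("Parseval identity links spectral energy to the variance", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    x <- rnorm(n, 50, 4)
    f <- computeChannelFeatures(x, 2.4)
    z <- x - mean(x)
    expect_equal(unname(f["spectral_energy"]), n * mean(z^2),
                 tolerance = 1e-6)
  }
})

test_that("features are translation-invariant except the location moments", {
  set.seed(41)
  x <- rnorm(12, 60, 2)
  shift <- 7.3
  f0 <- computeChannelFeatures(x, 2.4)
  f1 <- computeChannelFeatures(x + shift, 2.4)
  inv <- c("range", "standard_deviation", "variance", "mean_abs_change",
           "count_above_mean", "number_of_peaks_1", "number_of_peaks_3",
           paste0("abs_fft_coefficient_", 1:4), "dominant_frequency_hz",
           "spectral_energy", "autocorrelation_lag1",
           "linear_trend_slope")
  expect_equal(f1[inv], f0[inv], tolerance = 1e-9)
  expect_equal(unname(f1["mean"] - f0["mean"]), shift)
  # base elevation and area are invariant when the whole geometry shifts
  expect_equal(baseElevation(x + shift), baseElevation(x))
  s <- makeSeries(x)
  s2 <- makeSeries(x + shift, top_y = 40 + shift)
  expect_equal(areaSeries(s2), areaSeries(s))
})

test_that("the feature table drops exactly the missing columns", {
  clean <- makeCleanSeriesSet(10L)
  expect_message(tab <- buildFeatureTable(clean), "0 excluded")
  n_cat <- length(featureCatalogue())
  expect_equal(attr(tab, "n_features_after"), 11 * n_cat + 1)
  expect_length(attr(tab, "dropped_columns"), 0L)
  expect_equal(nrow(tab), 10L)
  expect_true(!anyNA(tab))

  # one clip with a single gap: exactly the spectral columns (6 per
  # channel, 11 channels) become missing dataset-wide and are dropped
  gapped <- makeCleanSeriesSet(10L)
  gapped[[4]] <- makeSeries(c(60, 61, NA, 60, 59, 60, 61, 60, 59, 60),
                            clip_id = "fix04",
                            missing = c(rep(FALSE, 2), TRUE, rep(FALSE, 7)))
  tab2 <- suppressMessages(buildFeatureTable(gapped))
  spectral <- c(paste0("abs_fft_coefficient_", 1:4),
                "dominant_frequency_hz", "spectral_energy")
  expected <- as.vector(outer(c(pfmus:::landmarkChannels(), "Area"),
                              spectral, paste, sep = "__"))
  expect_setequal(attr(tab2, "dropped_columns"), expected)
  expect_equal(attr(tab2, "n_features_after"), 11 * n_cat + 1 - 66)

  # clips with zero usable samples are dropped as rows, with a message
  allmiss <- makeSeries(rep(60, 10), clip_id = "dead",
                        missing = rep(TRUE, 10))
  expect_message(tab3 <- buildFeatureTable(c(clean, list(allmiss))),
                 "zero non-missing")
  expect_equal(nrow(tab3), 10L)
  expect_error(suppressMessages(buildFeatureTable(list(allmiss))),
               "zero usable")
})

test_that("feature tables serialize byte-identically for identical inputs", {
  clean <- makeCleanSeriesSet(6L)
  t1 <- suppressMessages(buildFeatureTable(clean))
  t2 <- suppressMessages(buildFeatureTable(makeCleanSeriesSet(6L)))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  writeFeatureTable(t1, f1)
  writeFeatureTable(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
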