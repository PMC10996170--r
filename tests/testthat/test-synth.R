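test_that("recording length, event log and ground truth follow the protocol", {
  cfg <- simulationConfig(n_contractions = 4L, contraction_s = 3,
                          rest_s = 3, fps = 24, seed = 2L)
  rec <- simulateRecording(cfg, c("CORRECT", "NONE", "FAILURE",
                                  "UNDETERMINABLE"))
  expect_equal(nFrames(rec@stack), 4 * 6 * 24)
  expect_equal(nrow(rec@events), 8L)
  expect_true(isTRUE(validateEventLog(rec@events)))
  # k-th contraction interval = [k-th contract call, k-th rest call]
  expect_equal(rec@events$time_s[rec@events$kind == "contract"],
               c(0, 6, 12, 18))
  expect_equal(rec@events$time_s[rec@events$kind == "rest"],
               c(3, 9, 15, 21))
  expect_length(rec@labels, 4L)
  expect_length(rec@contours, nFrames(rec@stack))
  expect_true(all(rec@stack@frames >= 0 & rec@stack@frames <= 255))
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- simulationConfig(frame_width = 64L, frame_height = 64L,
                          semi_axis_x = 16, semi_axis_y = 10,
                          n_contractions = 1L, contraction_s = 1,
                          rest_s = 1, seed = 99L)
  r1 <- simulateRecording(cfg, "UNDETERMINABLE")
  r2 <- simulateRecording(cfg, "UNDETERMINABLE")
  expect_identical(r1@stack@frames, r2@stack@frames)
  expect_identical(r1@landmarks, r2@landmarks)
  expect_identical(r1@corrupted, r2@corrupted)
})

test_that("NONE is static and zero amplitudes collapse onto NONE", {
  cfg <- simulationConfig(jitter_px = 0)
  rest <- contourAt(0, "NONE", c(0, 3), cfg)
  for (t in c(0.5, 1.5, 2.9))
    expect_equal(contourAt(t, "NONE", c(0, 3), cfg), rest)
  # CORRECT with zero base amplitude is trajectory-identical to NONE
  cfg0 <- simulationConfig(frame_width = 64L, frame_height = 64L,
                           semi_axis_x = 16, semi_axis_y = 10,
                           n_contractions = 1L, contraction_s = 1,
                           rest_s = 1, base_amplitude_px = 0, seed = 5L)
  ra <- simulateRecording(cfg0, "CORRECT")
  rb <- simulateRecording(cfg0, "NONE")
  expect_identical(ra@stack@frames, rb@stack@frames)
  expect_identical(ra@landmarks[, -1], rb@landmarks[, -1])
  # FAILURE with zero translation likewise
  cfg0@translation_amplitude_px <- 0
  rc <- simulateRecording(cfg0, "FAILURE")
  expect_identical(rc@stack@frames, rb@stack@frames)
})

test_that("class motion separates in the ground-truth trajectories", {
  cfg <- simulationConfig(jitter_px = 0, base_amplitude_px = 10,
                          translation_amplitude_px = 8,
                          n_contractions = 1L, seed = 3L)
  for (lab in c("CORRECT", "FAILURE", "NONE")) {
    rec <- simulateRecording(cfg, lab)
    by <- rec@landmarks$Bottom_y
    ty <- rec@landmarks$Top_y
    if (lab == "CORRECT") {
      expect_equal(max(by) - min(by), 10, tolerance = 1e-8)
      expect_equal(max(ty) - min(ty), 0)        # superior wall static
    } else if (lab == "FAILURE") {
      # rigid motion: the base moves, but not relative to the top
      expect_equal(max(by) - min(by), 8, tolerance = 1e-8)
      expect_equal(max(by - ty) - min(by - ty), 0, tolerance = 1e-10)
    } else {
      expect_equal(max(by) - min(by), 0)
    }
  }
})

test_that("CORRECT bottom vertex reaches resting y minus amplitude at the bump peak", {
  cfg <- simulationConfig(jitter_px = 0, base_amplitude_px = 10)
  rest <- contourAt(0, "NONE", c(0, 3), cfg)
  peak <- contourAt(1.5, "CORRECT", c(0, 3), cfg)   # bump midpoint
  expect_equal(max(peak[, 2]), max(rest[, 2]) - 10, tolerance = 1e-8)
  # upper boundary untouched
  expect_equal(min(peak[, 2]), min(rest[, 2]))
})

test_that("rendering is anechoic-inside, deterministic, and threshold-separable", {
  cfg <- simulationConfig(speckle_var = 0, jitter_px = 0)
  ct <- contourAt(0, "NONE", c(0, 3), cfg)
  fr <- renderFrame(ct, cfg)
  expect_length(unique(as.vector(fr)), 2L)        # noiseless: binary
  inside <- fr == min(fr)
  expect_lt(mean(fr[inside]), mean(fr[!inside]))

  cfgS <- simulationConfig(speckle_var = 0.05, jitter_px = 0)
  set.seed(21)
  f1 <- renderFrame(ct, cfgS)
  set.seed(21)
  f2 <- renderFrame(ct, cfgS)
  expect_identical(f1, f2)                        # same rng state

  # inside/outside histograms separable by one threshold on >= 99% of
  # pixels over 100 seeded frames
  mask <- fr == min(fr)
  set.seed(33)
  thr <- sqrt(20 * 180)     # geometric midpoint of the two levels
  ok_frac <- vapply(1:100, function(i) {
    f <- renderFrame(ct, cfgS)
    mean((f < thr) == mask)
  }, numeric(1))
  expect_true(all(ok_frac >= 0.99))
})

test_that("generator rejects invalid inputs", {
  cfg <- simulationConfig()
  expect_error(contourAt(0, "WRONG", c(0, 3), cfg), "unknown")
  expect_error(simulateRecording(cfg, c("CORRECT", "NONE")), "label")
  big <- ellipseContour(90, a = 200, b = 100, cx = 64, cy = 64)
  expect_error(renderFrame(big, cfg), "bounds")
  expect_error(simulationConfig(dropout_prob = 1.5))
  expect_error(simulationConfig(semi_axis_x = -1))
})
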