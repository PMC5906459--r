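test_that("ROI mean averages the first, middle and last frames", {
  st <- array(rep(c(10, 20, 30, 40, 50), each = 4), dim = c(2, 2, 5))
  expect_equal(roi_mean_intensity(st), 30)
  expect_equal(roi_mean_intensity(st, frame_picks = "all"), 30)
  expect_equal(roi_mean_intensity(st, frame_picks = c(2, 4)), 30)
  uniform <- array(7, dim = c(8, 8, 3))
  expect_equal(roi_mean_intensity(uniform, roi = c(2, 3, 4, 4)), 7)
  expect_error(roi_mean_intensity(uniform, roi = c(6, 6, 4, 4)), "ROI out of")
  expect_error(roi_mean_intensity(uniform, frame_picks = 9), "out of range")
})

test_that("rendered image stacks close the loop back to the scan intensities", {
  m <- carryover_assay_map()
  scan <- gen_carryover_scan(m, carryover_preset(frames_per_well = 5),
                             seed = 6)
  stack <- scan_to_stack(scan, "A1")
  roi <- c(20, 20, 25, 25)  # centred ROI for 64x64 frames
  got <- roi_mean_intensity(stack, roi) * 4096
  want <- scan_well_intensities(scan)[["A1"]]
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("TIFF write/read preserves a rendered stack", {
  m <- carryover_assay_map()
  scan <- gen_carryover_scan(m, carryover_preset(frames_per_well = 3),
                             seed = 6)
  stack <- scan_to_stack(scan, "A2", width = 32, height = 32)
  path <- withr::local_tempfile(fileext = ".tif")
  frames <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  back <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(back), dim = dim(stack))
  expect_equal(arr, stack, tolerance = 1e-6)
})

test_that("carryover arithmetic matches the baseline-subtract-and-ratio definition", {
  m <- carryover_assay_map(plate_spec(NULL, rows = 1, cols = 2,
                                      well_capacity_ul = 600,
                                      well_depth_mm = 11))
  iv <- c(A1 = 1100, A2 = 103.2)
  tab <- carryover_table(iv, m, baseline = 100)
  expect_equal(tab$percent, 0.32)
  # buffer equal to baseline reads zero carryover
  tab0 <- carryover_table(c(A1 = 1100, A2 = 100), m, baseline = 100)
  expect_equal(tab0$percent, 0)
  # dye not above baseline is undefined
  expect_error(carryover_table(c(A1 = 99, A2 = 100), m, baseline = 100),
               "not above baseline")
  # baseline can be given as a well reference
  m4 <- carryover_assay_map(plate_spec(NULL, rows = 1, cols = 4,
                                       well_capacity_ul = 600,
                                       well_depth_mm = 11))
  iv4 <- c(A1 = 1100, A2 = 103.2, A3 = 1100, A4 = 103.2)
  tab4 <- carryover_table(iv4, m4, baseline = "A2")
  expect_equal(nrow(tab4), 2)
})

test_that("noiseless synthetic scans recover the residual fraction exactly", {
  m <- carryover_assay_map()
  scan <- gen_carryover_scan(m, exact_preset(f = 0.0032), seed = 1)
  tab <- analyze_carryover(scan)
  expect_equal(nrow(tab), 48)
  expect_equal(tab$percent, rep(0.32, 48), tolerance = 1e-12)
  expect_equal(attr(tab, "mean"), 0.32, tolerance = 1e-12)
})

test_that("the default synthetic scan recovers mean carryover near 0.32%", {
  scan <- gen_carryover_scan(carryover_assay_map(), seed = 0)
  tab <- analyze_carryover(scan)
  expect_equal(nrow(tab), 48)
  expect_equal(attr(tab, "mean"), 0.32, tolerance = 0.1)
  expect_true(all(tab$percent >= 0))
})

test_that("dF/F0 is zero for constant traces, one for doubling, and scale-invariant", {
  t_s <- seq(0, 10, 0.1)
  expect_equal(dff(rep(50, length(t_s)), t_s, 5), rep(0, length(t_s)))
  f <- ifelse(t_s < 5, 100, 200)
  expect_equal(max(dff(f, t_s, 5)), 1)
  expect_error(dff(rep(0, length(t_s)), t_s, 5), "non-positive F0")
  expect_error(dff(f, t_s, 0), "empty F0 window")

  set.seed(13)
  for (rep in 1:20) {
    raw <- 100 + cumsum(rnorm(length(t_s)))
    raw <- raw - min(raw) + 10
    k <- runif(1, 0.1, 50)
    d1 <- dff(raw, t_s, 5)
    d2 <- dff(k * raw, t_s, 5)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_equal(peak_response(d1, t_s, 5, 2),
                 peak_response(d2, t_s, 5, 2), tolerance = 1e-12)
  }
})

test_that("peak response reads the window maximum", {
  t_s <- seq(0, 30, 0.1)
  bump <- 0.8 * pmax(0, 1 - abs(t_s - 10) / 2)
  expect_equal(peak_response(bump, t_s, 5, 10), 0.8)
  expect_error(peak_response(bump, t_s, 40, 5), "empty peak window")
  # noiseless zero-concentration trace peaks at zero
  ts <- gen_dose_response(awa = neuron_preset("AWA", noise_sd = 0),
                          ash = neuron_preset("ASH", noise_sd = 0),
                          n_animals = 1, pulses = 1,
                          concentrations = c(0, 1e-7, 1e-6, 1e-5),
                          animal_sd = 0, seed = 0)
  pk <- trace_peaks(ts, smooth_s = 0)
  expect_equal(pk$peak[pk$conc == 0], c(0, 0))
})

test_that("saturating synthetic responses peak near the preset r_max", {
  ts <- gen_dose_response(n_animals = 6, pulses = 2,
                          concentrations = c(0, 1.15e-7, 1.15e-5, 1.15e-3),
                          seed = 2)
  pk <- trace_peaks(ts)
  sat <- pk[pk$neuron == "AWA" & pk$conc == 1.15e-3, ]
  expect_equal(mean(sat$peak), 1.0, tolerance = 0.15)
})

test_that("staining curves segment the ten steps and locate the onset lag", {
  sp <- staining_protocol()
  tl <- compile_protocol(sp$map, sp$steps)
  ser <- gen_staining_timecourse(tl, seed = 0)
  sc <- staining_curve(ser, tl)
  expect_equal(nrow(sc$segments), 10)
  expect_equal(sc$onset_min, 15, tolerance = 2)
  # intensities before phalloidin stay at background level
  expect_equal(sc$segments$mean_intensity[2], 10, tolerance = 1)
  # flat series: no onset detected
  flat <- ser
  flat$intensity <- 10 + 0 * flat$intensity
  sc0 <- staining_curve(flat, tl)
  expect_true(is.na(sc0$onset_min))
  # truncated series is rejected
  expect_error(staining_curve(ser[1:40, ], tl), "shorter than")
})
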