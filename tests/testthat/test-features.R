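test_that("basic statistics match hand arithmetic", {
  expect_equal(unname(basic_stats(rep(2.5, 6))),
               c(2.5, 2.5, 0, 15, 15, 0, 2.5))
  expect_equal(unname(basic_stats(c(1, -1, 1, -1))),
               c(0, 0, 1, 0, 4, 2, 1))
  expect_equal(unname(basic_stats(3)), c(3, 3, 0, 3, 3, 0, 3))
  expect_error(basic_stats(numeric(0)), "empty")
})

test_that("zero-crossing rate counts strict sign changes after centering", {
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1)), 1)
  expect_equal(zero_crossing_rate(rep(7, 10)), 0)
  t <- seq(0, 6.9, by = 0.1)
  x <- sin(2 * pi * 1 * t)
  expect_equal(zero_crossing_rate(x), oracle_zcr(x))
  expect_error(zero_crossing_rate(1), "at least 2")
})

test_that("average variation is the mean absolute successive difference", {
  expect_equal(avg_variation(rep(3, 5)), 0)
  expect_equal(avg_variation(c(0, 1, 0, 1)), 1)
  expect_equal(avg_variation(seq(0, 9, by = 0.75)), 0.75)  # ramp -> |slope|
})

test_that("shape moments use population central moments with the degenerate convention", {
  expect_equal(unname(shape_moments(c(-1, 0, 1))["skewness"]), 0)
  expect_equal(unname(shape_moments(rep(4, 8))), c(0, 0))
  sm <- shape_moments(c(0, 0, 0, 1))
  expect_equal(unname(sm["skewness"]), 2 / sqrt(3), tolerance = 1e-9)  # ~1.1547
  expect_equal(unname(sm["kurtosis"]), -2 / 3, tolerance = 1e-9)
})

test_that("time between peaks averages the local-maximum spacing", {
  t <- seq(0, 6.9, by = 0.1)
  expect_equal(time_between_peaks(sin(2 * pi * t), fs = 10), 1, tolerance = 0.05)
  expect_equal(time_between_peaks(1:50, fs = 10), 0)  # monotone, no interior max
  x <- numeric(70); x[c(11, 31, 61)] <- 5            # impulses at samples 10, 30, 60
  expect_equal(time_between_peaks(x, fs = 10), mean(c(2, 3)))
  # plateau takes its first index: peaks at samples 2 and 5 -> gap 3
  y <- c(0, 1, 1, 0, 2, 0)
  expect_equal(time_between_peaks(y, fs = 1), 3)
})

test_that("spectral features find the dominant periodogram line", {
  t <- seq(0, 6.9, by = 0.1)
  sp <- spectral_features(sin(2 * pi * 2 * t), fs = 10)
  expect_equal(unname(sp["dominant_frequency"]), 2)
  sp0 <- spectral_features(rep(1, 70), fs = 10)
  expect_equal(unname(sp0["dominant_frequency"]), 0)  # constant: no oscillation
  expect_equal(unname(sp0["dominant_spectral_density"]), 0)
  mix <- sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 3 * t)
  expect_equal(unname(spectral_features(mix, fs = 10)["dominant_frequency"]), 3)
  expect_equal(unname(spectral_features(mix, 10)),
               unname(oracle_spectral(mix, 10)), tolerance = 1e-9)
})

test_that("feature vector has 112 named finite entries and is deterministic", {
  rec <- generate_event("walking", seed = 4)
  w <- segment_windows(rec, frame = "world")[[1]]
  fv <- extract_features(w)
  expect_length(fv, 112)
  expect_true(all(is.finite(fv)))
  expect_equal(names(fv)[1:3], c("ax__mean", "ax__median", "ax__std"))
  expect_equal(names(fv)[112], "wmag__dominant_spectral_density")
  expect_identical(fv, extract_features(w))

  # all-zero window collapses to all-zero features (degenerate conventions)
  wz <- w
  wz$channels[] <- 0
  expect_true(all(extract_features(wz) == 0))

  # rms^2 = mean^2 + std^2 (population convention)
  for (ch in feature_channels) {
    expect_equal(fv[paste0(ch, "__rms")]^2,
                 fv[paste0(ch, "__mean")]^2 + fv[paste0(ch, "__std")]^2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("every feature agrees with the independent brute-force oracle", {
  for (s in 1:100) {
    w <- random_window(s)
    expect_equal(unname(extract_features(w)), oracle_feature_vector(w),
                 tolerance = 1e-9)
  }
})

test_that("windowing modes produce the expected window counts", {
  mount <- generate_event("active_mounting", seed = 1, duration_s = 9)
  expect_length(segment_windows(mount, mode = "first"), 1)
  expect_equal(nrow(segment_windows(mount)[[1]]$channels), 70)

  graze <- generate_event("grazing", seed = 2, duration_s = 180)
  expect_length(segment_windows(graze, mode = "tiled"), 25)  # floor(1800/70)

  short <- generate_event("resting", seed = 3, duration_s = 8)
  short$data <- short$data[1:50, ]
  expect_warning(wins <- segment_windows(short), "shorter")
  expect_length(wins, 0)
})

test_that("stationary world-frame window shows gravity on z only", {
  rec <- generate_event("resting", seed = 21)
  w <- segment_windows(rec, frame = "world")[[1]]
  expect_equal(mean(w$channels$az), 9.807, tolerance = 0.1)
  expect_lt(abs(mean(w$channels$ax)), 0.1)
  expect_lt(abs(mean(w$channels$ay)), 0.1)
})

test_that("design matrix encodes the one-vs-rest task with shared gyro columns", {
  db <- c(lapply(1:3, function(s) generate_event("active_mounting", seed = s)),
          lapply(4:8, function(s) generate_event("walking", seed = s)))
  d <- build_design_matrix(db, frame = "body")
  expect_equal(dim(d$X), c(8, 112))
  expect_equal(d$y, c(1, 1, 1, 0, 0, 0, 0, 0))

  dw <- build_design_matrix(db, frame = "world")
  gyro_cols <- grep("^(wx|wy|wz|wmag)__", colnames(d$X))
  expect_equal(d$X[, gyro_cols], dw$X[, gyro_cols])
  acc_cols <- grep("^(ax|ay|az|amag)__", colnames(d$X))
  expect_false(isTRUE(all.equal(d$X[, acc_cols], dw$X[, acc_cols])))

  # identity orientation: body and world matrices coincide
  n <- 80
  ident <- make_orientation_trace(n, wobble_deg_s = 0)
  rec_i <- generate_event("walking", seed = 5, orientation = ident,
                          duration_s = n / 10)
  d_b <- build_design_matrix(list(rec_i), frame = "body")
  d_w <- build_design_matrix(list(rec_i), frame = "world")
  expect_equal(d_b$X, d_w$X, tolerance = 1e-12)
})
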