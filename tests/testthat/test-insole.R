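test_that("lowpass filter preserves DC and attenuates per the analytic response", {
  fs <- 100
  expect_equal(lowpass_filter(rep(3.7, 200), fs), rep(3.7, 200),
               tolerance = 1e-8)
  t <- seq(0, 40, by = 1 / fs)
  for (f in c(1, 30)) {
    y <- lowpass_filter(sin(2 * pi * f * t), fs)
    g <- measure_tone_amplitude(y, f, fs)
    expect_equal(g, butterworth_gain(f, fs), tolerance = 0.02)
  }
  # 1 Hz passes nearly untouched, 30 Hz is crushed
  expect_gt(measure_tone_amplitude(
    lowpass_filter(sin(2 * pi * 1 * t), fs), 1, fs), 0.99)
  expect_lt(measure_tone_amplitude(
    lowpass_filter(sin(2 * pi * 30 * t), fs), 30, fs), 0.01)
})

test_that("zero-phase mode does not shift a symmetric pulse; errors are explicit", {
  x <- dnorm(seq(-2, 2, by = 0.01), 0, 0.3)
  expect_equal(which.max(lowpass_filter(x, 100)), which.max(x))
  expect_error(lowpass_filter(rnorm(10), 100), "too short")
  expect_error(lowpass_filter(rnorm(100), 100, cutoff = 50), "Nyquist")
})

test_that("stride detection follows the threshold-and-persistence rule", {
  fs <- 100
  expect_identical(nrow(detect_strides(numeric(0), fs)), 0L)
  expect_identical(nrow(detect_strides(rep(0, 100), fs)), 0L)

  # 500-ms pulse: IC at the first sample above 30 N, FC at the first
  # sample after it below 30 N (hand-computed from the pulse edges)
  f <- fixture_pulse(500)
  st <- detect_strides(f, fs)
  expect_identical(nrow(st), 1L)
  expect_identical(st$initial_contact, 21L)  # lead of 20 zero samples
  expect_identical(st$final_contact, 71L)    # 50 samples at 400 N

  # a 200-ms pulse violates the 300-ms persistence rule
  expect_identical(nrow(detect_strides(fixture_pulse(200), fs)), 0L)

  # exactly 300 ms is kept ("at least")
  expect_identical(nrow(detect_strides(fixture_pulse(300), fs)), 1L)
})

test_that("stride detection is invariant to sub-threshold swing noise", {
  fs <- 100
  f <- c(fixture_pulse(500), fixture_pulse(600))
  base <- detect_strides(f, fs)
  set.seed(11)
  noise <- runif(length(f), 0, 29.9)
  noisy <- ifelse(f == 0, noise, f)
  expect_identical(detect_strides(noisy, fs), base)
})

test_that("force normalization is the stated linear map", {
  expect_equal(normalize_force(700, 700), 100)
  expect_equal(normalize_force(0, 700), 0)
  expect_equal(normalize_force(840, 700), 120)
  # scaling force and body weight together leaves %BW unchanged
  f <- runif(50, 0, 900)
  expect_equal(normalize_force(f, 700), normalize_force(3 * f, 2100))
  expect_error(normalize_force(100, 0), "positive")
})

test_that("regional pressures follow the per-sensor normalization algebra", {
  lay <- sensor_layout()
  p <- matrix(0, 10, 16)
  expect_true(all(as.matrix(regional_pressures(p, lay, 700)) == 0))

  # constant channels: region value = 100 * p / BW regardless of size
  p[] <- 5
  r <- regional_pressures(p, lay, 700)
  expect_equal(r$forefoot, rep(100 * 5 / 700, 10))
  expect_equal(r$hindfoot, r$forefoot)

  # single-sensor region equals that channel normalized
  lay1 <- sensor_layout(forefoot = 9, hindfoot = 1:8)
  q <- matrix(runif(160), 10, 16)
  expect_equal(regional_pressures(q, lay1, 650)$forefoot,
               normalize_force(q[, 9], 650))

  # union identity: value of a merged region is the sensor-count-weighted
  # mean of the two parts
  layA <- sensor_layout(forefoot = 9:12, hindfoot = 1:8)
  layB <- sensor_layout(forefoot = 13:16, hindfoot = 1:8)
  layU <- sensor_layout(forefoot = 9:16, hindfoot = 1:8)
  a <- regional_pressures(q, layA, 650)$forefoot
  b <- regional_pressures(q, layB, 650)$forefoot
  u <- regional_pressures(q, layU, 650)$forefoot
  expect_equal(u, (4 * a + 4 * b) / 8)

  expect_error(sensor_layout(forefoot = integer(0)), "empty")
  expect_error(sensor_layout(forefoot = 1:8, hindfoot = 5:12), "disjoint")
})

test_that("stride features take maxima over the contact interval", {
  sim <- generate_insole_recording(
    gait_signal_config(n_strides = 4, peak_force_pct_bw = 120,
                       body_weight = 700, seed = 2))
  st <- detect_strides(sim$recording$total_force_n, 100)
  ft <- extract_stride_features(sim$recording, st)
  expect_equal(ft$max_total_force_pbw, rep(120, 4), tolerance = 1e-10)

  # constant force during the stance window
  rec <- sim$recording
  rec$total_force_n[] <- 0
  rec$total_force_n[31:90] <- 200
  ft2 <- extract_stride_features(
    rec, tibble::tibble(stride = 1L, initial_contact = 31L,
                        final_contact = 91L))
  expect_equal(ft2$max_total_force_pbw, normalize_force(200, 700))

  # sine of amplitude A entirely inside stance
  rec$gyro_y_dps <- 150 * sin(2 * pi * 2.5 * rec$time_s)
  ft3 <- extract_stride_features(
    rec, tibble::tibble(stride = 1L, initial_contact = 31L,
                        final_contact = 91L))
  expect_equal(ft3$max_angular_velocity_ml, 150, tolerance = 1e-3)

  expect_error(
    extract_stride_features(
      rec, tibble::tibble(stride = 1L, initial_contact = 1L,
                          final_contact = nrow(rec) + 5L)),
    "out of range")
})

test_that("middle-stride selection centres the window and warns on few strides", {
  st <- tibble::tibble(stride = 1:9, initial_contact = 1:9 * 100L,
                       final_contact = 1:9 * 100L + 60L)
  expect_identical(select_middle_strides(st, 5)$stride, 3:7)
  expect_identical(select_middle_strides(st[1:8, ], 5)$stride, 2:6)
  expect_warning(kept <- select_middle_strides(st[1:5, ], 5), "interior")
  expect_identical(kept$stride, 2:4)
  expect_error(select_middle_strides(st[1:2, ], 5), "at least 3")
})

test_that("visit summary is the arithmetic mean of the stride features", {
  ft <- tibble::tibble(stride = 1:5,
                       max_total_force_pbw = c(100, 110, 120, 130, 140),
                       max_forefoot_p = 20, max_hindfoot_p = 21,
                       max_lateral_p = 15, max_medial_p = 14,
                       max_angular_velocity_ml = 200)
  s <- summarize_visit(ft)
  expect_equal(s$max_total_force_pbw, 120)
  expect_identical(s$n_strides_used, 5L)
  one <- summarize_visit(ft[2, ])
  expect_equal(one$max_total_force_pbw, 110)
  expect_identical(one$n_strides_used, 1L)
  expect_error(summarize_visit(ft[0, ]), "empty")
})

test_that("insole CSV round trip is lossless and the pipeline deterministic", {
  sim <- generate_insole_recording(gait_signal_config(
    n_strides = 8, sensor_noise_sd = 1, seed = 33))
  path <- file.path(withr::local_tempdir(), "walk.csv")
  write_insole_csv(sim$recording, path)
  back <- read_insole_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$recording),
               tolerance = 1e-12)
  expect_identical(body_weight(back), body_weight(sim$recording))
  g1 <- extract_gait(sim$recording)
  g2 <- extract_gait(back)
  expect_equal(g1, g2, tolerance = 1e-12)
  # identical input -> bit-identical features
  expect_identical(extract_gait(back), extract_gait(back))
})
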