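test_that("the walk generator honours its construction contracts", {
  cfg <- gait_signal_config(n_strides = 5, sensor_noise_sd = 0,
                            peak_force_pct_bw = 120, body_weight = 700,
                            seed = 4)
  sim <- generate_insole_recording(cfg)
  expect_length(sim$truth$initial_contacts, 5)
  expect_length(sim$truth$final_contacts, 5)
  # IC/FC strictly increasing and alternating
  ev <- rbind(sim$truth$initial_contacts, sim$truth$final_contacts)
  expect_true(all(diff(as.vector(ev)) > 0))
  # exact peak scaling
  expect_equal(max(sim$recording$total_force_n), 840)
  # nonnegative everywhere, exactly zero between FC and next IC
  f <- sim$recording$total_force_n
  expect_true(all(f >= 0))
  for (s in 1:4) {
    expect_true(all(f[sim$truth$final_contacts[s]:
                        (sim$truth$initial_contacts[s + 1] - 1)] == 0))
  }
  # channel sum reconstructs total force (unit area factor)
  p <- as.matrix(sim$recording[, sprintf("p%02d", 1:16)])
  expect_equal(rowSums(p), f, tolerance = 1e-6)
})

test_that("the walk generator is bit-reproducible and validates its config", {
  a <- generate_insole_recording(gait_signal_config(sensor_noise_sd = 2,
                                                    seed = 9))
  b <- generate_insole_recording(gait_signal_config(sensor_noise_sd = 2,
                                                    seed = 9))
  expect_identical(a$recording, b$recording)
  expect_error(gait_signal_config(stance_duration = 0.25), "0.3")
  expect_error(gait_signal_config(n_strides = 0), "at least 1")
  expect_error(gait_signal_config(double_hump_ratio = 1.5), "0, 1")
})

test_that("cohort dropout and noise switches behave as configured", {
  full <- generate_cohort(cohort_sim_config(
    n_patients = 40, dropout_hazard_per_visit = 0, seed = 5))$cohort
  expect_identical(nrow(full), 40L * 6L)

  det <- generate_cohort(cohort_sim_config(
    n_patients = 30, dropout_hazard_per_visit = 0,
    random_intercept_sd = 0, residual_sd = 0, seed = 6))$cohort
  # same-stratum patients have identical T scores at each visit
  strata <- dplyr::count(det, sex, hypertension, visit_day, ph_t)
  per <- dplyr::count(det, sex, hypertension, visit_day)
  expect_identical(nrow(strata), nrow(per))
})

test_that("cohort empirical means recover the generating fixed effects", {
  cfg <- cohort_sim_config(n_patients = 2000,
                           dropout_hazard_per_visit = 0, seed = 7)
  out <- generate_cohort(cfg)
  ch <- out$cohort
  # centre of the sex/hypertension shifts in this draw
  shift <- cfg$sex_effect * mean(ch$sex == "male") +
    cfg$hypertension_effect * mean(ch$hypertension)
  tot_sd <- sqrt(cfg$random_intercept_sd^2 + cfg$residual_sd^2)
  for (v in seq_along(cfg$visit_days)) {
    sub <- ch[ch$visit_day == cfg$visit_days[v], ]
    se <- tot_sd / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$ph_t) -
                    (cfg$promis_fixed_effects$physical_health[v] + shift)),
              3 * se + 0.2)  # 0.2 covers the sampled shift composition
  }
  # random-intercept variance within 10% of the configured value
  expect_lt(abs(sd(out$truth$random_intercepts) -
                  cfg$random_intercept_sd) / cfg$random_intercept_sd, 0.1)
  # gait values positive (BCCG-ready) and rising toward the plateau
  expect_true(all(ch$max_force_pbw > 0))
  m <- tapply(ch$max_force_pbw, ch$visit_day, mean)
  expect_true(all(diff(m) > 0))
})

test_that("cohort CSV round trip preserves the table", {
  ch <- generate_cohort(cohort_sim_config(n_patients = 12, seed = 8))$cohort
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(ch, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ch), tolerance = 1e-12)
})
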