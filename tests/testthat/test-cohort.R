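test_that("interval bins respect the day boundaries", {
  expect_equal(as.character(assign_interval(c(0, 15))),
               rep("preinjury/first-week", 2))
  expect_equal(as.character(assign_interval(c(16, 55))), rep("6-weeks", 2))
  expect_equal(as.character(assign_interval(c(56, 110))), rep("3-months", 2))
  expect_equal(as.character(assign_interval(c(111, 200))), rep("6-months", 2))
  expect_equal(as.character(assign_interval(c(201, 300))), rep("9-months", 2))
  expect_equal(as.character(assign_interval(c(301, 2000))), rep("1-year", 2))
  expect_error(assign_interval(-1), "nonnegative")
})

test_that("dedupe keeps the last visit per interval and is idempotent", {
  tab <- tibble::tibble(
    patient_id = c("A", "A", "A", "B", "B"),
    visit_day = c(60, 100, 42, 60, 60),
    value = 1:5
  ) |> add_intervals()
  out <- dedupe_last_per_interval(tab)
  # A: day 100 wins within 3-months; the day-42 visit is its own interval
  expect_setequal(out$value[out$patient_id == "A"], c(2, 3))
  # B: tied days -> later row wins
  expect_identical(out$value[out$patient_id == "B"], 5L)
  expect_identical(dedupe_last_per_interval(out), out)
  # never more than 6 rows per patient
  ch <- generate_cohort(cohort_sim_config(n_patients = 50, seed = 3))$cohort
  dd <- dedupe_last_per_interval(add_intervals(ch))
  expect_lte(max(table(dd$patient_id)), 6)
})

test_that("the LMM identifies generating effects exactly when noiseless", {
  cfg <- cohort_sim_config(n_patients = 30, dropout_hazard_per_visit = 0,
                           random_intercept_sd = 0, residual_sd = 0,
                           seed = 21)
  ch <- add_intervals(generate_cohort(cfg)$cohort)
  # degenerate zero-variance data: lme4 flags the boundary fit
  fit <- suppressWarnings(fit_lmm(ch, "ph_t"))
  td <- tidy(fit)
  fe <- cfg$promis_fixed_effects$physical_health
  # interval contrasts equal the generating offsets
  for (j in 2:6) {
    est <- td$estimate[td$term == paste0("interval", interval_levels()[j])]
    expect_equal(est, fe[j] - fe[1], tolerance = 1e-6)
  }
  expect_equal(td$estimate[td$term == "sexmale"], cfg$sex_effect,
               tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "hypertensionTRUE"],
               cfg$hypertension_effect, tolerance = 1e-6)
})

test_that("the LMM recovers noisy effects and rejects singular designs", {
  cfg <- cohort_sim_config(n_patients = 400, seed = 22)
  ch <- dedupe_last_per_interval(add_intervals(generate_cohort(cfg)$cohort))
  td <- tidy(fit_lmm(ch, "ph_t"))
  sex <- td[td$term == "sexmale", ]
  expect_lt(abs(sex$estimate - cfg$sex_effect), 3 * sex$std.error)
  ht <- td[td$term == "hypertensionTRUE", ]
  expect_lt(abs(ht$estimate - cfg$hypertension_effect), 3 * ht$std.error)
  # variance components near the generator's
  gl <- glance(fit_lmm(ch, "ph_t"))
  expect_equal(gl$sd_intercept, cfg$random_intercept_sd, tolerance = 0.2)
  expect_equal(gl$sd_residual, cfg$residual_sd, tolerance = 0.2)

  one <- ch[ch$interval == "6-weeks", ]
  expect_error(fit_lmm(one, "ph_t"), "singular")
})

test_that("covariate selection keeps only large coefficients", {
  cfg <- cohort_sim_config(n_patients = 600, sex_effect = 4,
                           hypertension_effect = 0, residual_sd = 2,
                           seed = 23)
  ch <- dedupe_last_per_interval(add_intervals(generate_cohort(cfg)$cohort))
  fit <- fit_lmm(ch, "ph_t", covariates = c("sex", "hypertension"))
  kept <- select_covariates(fit, threshold = 1)
  expect_true("sex" %in% kept)
  expect_false("hypertension" %in% kept)
})

test_that("Spearman correlations behave under monotone structure and nulls", {
  set.seed(31)
  n <- 200
  base <- tibble::tibble(
    patient_id = as.character(1:n), visit_day = 91,
    ph_t = rnorm(n, 45, 8), mh_t = rnorm(n, 47, 8), pi_t = rnorm(n, 55, 8)
  )
  base$max_force_pbw <- exp(base$ph_t / 10)   # monotone in ph_t
  base$med_p <- -base$ph_t^3                  # decreasing monotone
  base$lat_p <- rnorm(n); base$ff_p <- rnorm(n); base$hf_p <- rnorm(n)
  base$max_av_ml <- rnorm(n)
  tab <- add_intervals(base)
  rho <- spearman_matrix(tab, "3-months")
  expect_equal(rho$rho[rho$promis == "ph_t" & rho$gait == "max_force_pbw"], 1)
  expect_equal(rho$rho[rho$promis == "ph_t" & rho$gait == "med_p"], -1)
  expect_true(all(rho$n == n))
  # invariance under strictly increasing transforms / sign flip negation
  r1 <- cor(base$mh_t, base$lat_p, method = "spearman")
  expect_equal(cor(exp(base$mh_t / 5), base$lat_p, method = "spearman"), r1)
  expect_equal(cor(-base$mh_t, base$lat_p, method = "spearman"), -r1)
  # undefined for < 3 complete pairs
  small <- add_intervals(base[1:2, ])
  expect_true(is.na(spearman_matrix(small, "3-months")$rho[1]))
})

test_that("Pearson chi-square matches the textbook statistic and symmetries", {
  tab <- matrix(c(3, 16, 35, 30), 2)
  res <- pearson_chi_square(tab)
  # independent oracle: stats::chisq.test without continuity correction
  oracle <- chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(res$p.value, oracle$p.value, tolerance = 1e-12)
  # O = E exactly -> 0
  expect_equal(pearson_chi_square(matrix(c(10, 20, 10, 20), 2))$statistic, 0)
  # transposition and permutation invariance
  expect_equal(pearson_chi_square(t(tab))$statistic, res$statistic)
  expect_equal(pearson_chi_square(tab[2:1, ])$statistic, res$statistic)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 3), 2)), "margin")
})

test_that("rank-sum comparison handles identical, separated and null groups", {
  x <- c(1, 2, 3, 4, 5)
  same <- rank_sum_test(x, x)
  expect_gt(same$p_wilcoxon, 0.99)
  expect_equal(same$statistic_f, 0, tolerance = 1e-12)
  sep <- rank_sum_test(1:10, 101:110)
  expect_equal(sep$statistic_w, 0)   # complete separation: extremal W
  expect_error(rank_sum_test(numeric(0), x), "nonempty")
  # null calibration of the Wilcoxon p-value
  set.seed(41)
  rej <- mean(replicate(4000, {
    rank_sum_test(rnorm(12), rnorm(12))$p_wilcoxon < 0.05
  }))
  expect_gt(rej, 0.04); expect_lt(rej, 0.06)
})

test_that("p-values are formatted in journal style", {
  expect_identical(format_pvalue(c(0.0004, 0.0344, 0.975)),
                   c("<.001", ".034", ".975"))
})
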