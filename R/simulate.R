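#' Configuration for a synthetic insole walk
#'
#' Parameters of the idealized gait signal generator. Defaults describe a
#' healthy adult walking a 10-m walkway: ~10 strides, stance 0.6 s, swing
#' 0.5 s, peak vertical force 115 %BW with a double-hump (two-peak) stance
#' curve.
#'
#' @param sampling_rate Hz (default 100).
#' @param n_strides number of strides (>= 1).
#' @param body_weight Newtons.
#' @param stance_duration stance time in seconds; must be >= 0.3 s so the
#'   ground truth satisfies the 300-ms contact-persistence detection rule.
#' @param swing_duration swing time in seconds.
#' @param peak_force_pct_bw peak of the noiseless total force, in %BW.
#' @param double_hump_ratio depth of the midstance valley relative to the
#'   peaks, in (0, 1]; 1 gives a single broad arc.
#' @param sensor_noise_sd SD of additive Gaussian noise per pressure
#'   channel (same units as the channel); 0 for noiseless.
#' @param gyro_amplitude amplitude of the mediolateral angular-velocity
#'   swing oscillation, deg/s.
#' @param seed integer RNG seed.
#' @return a list of class `gait_signal_config`.
#' @export
gait_signal_config <- function(sampling_rate = 100, n_strides = 10,
                               body_weight = 700, stance_duration = 0.6,
                               swing_duration = 0.5,
                               peak_force_pct_bw = 115,
                               double_hump_ratio = 0.8,
                               sensor_noise_sd = 0,
                               gyro_amplitude = 200,
                               seed = 1L) {
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (n_strides < 1) abort("`n_strides` must be at least 1.")
  if (stance_duration < 0.3) {
    abort(paste("`stance_duration` below 0.3 s would make the ground truth",
                "undetectable under the 300-ms contact rule."))
  }
  if (peak_force_pct_bw <= 0) abort("`peak_force_pct_bw` must be positive.")
  if (double_hump_ratio <= 0 || double_hump_ratio > 1) {
    abort("`double_hump_ratio` must lie in (0, 1].")
  }
  if (sensor_noise_sd < 0) abort("`sensor_noise_sd` must be >= 0.")
  structure(as.list(environment()), class = "gait_signal_config")
}

# Stance-phase shape on u in (0,1): a sharp-onset arc carrying two Gaussian
# bumps (loading and push-off peaks). The arc term sin(pi*u)^0.3 guarantees
# the force rises well above typical detection thresholds within one sample
# of true initial contact, so threshold-detected events coincide with the
# ground-truth support edges.
stance_shape <- function(u, hump_ratio) {
  arc <- sin(pi * u)^0.3
  g1 <- exp(-(u - 0.30)^2 / (2 * 0.10^2))
  g2 <- exp(-(u - 0.70)^2 / (2 * 0.10^2))
  valley <- 1 - (1 - hump_ratio) * exp(-(u - 0.5)^2 / (2 * 0.12^2))
  0.5 * arc * valley + 0.5 * arc * (g1 + g2)
}

#' Generate a synthetic insole recording with known gait events
#'
#' Produces an [insole_recording()] whose noiseless total force follows a
#' two-peak stance curve scaled so its maximum equals
#' `peak_force_pct_bw/100 * body_weight` exactly, is exactly zero during
#' swing, and distributes force over the 16 sensors as a hindfoot-to-
#' forefoot roll-over wave. The mediolateral gyroscope channel carries a
#' stride-periodic oscillation. Ground truth holds the exact initial/final
#' contact samples of the noiseless signal.
#'
#' @param config a [gait_signal_config()].
#' @return list with elements `recording` (an [insole_recording()]) and
#'   `truth` (list: `initial_contacts`, `final_contacts` sample indices,
#'   `peak_force_n`, and the per-stride noiseless feature maxima in
#'   `stride_maxima`).
#' @examples
#' sim <- generate_insole_recording(gait_signal_config(n_strides = 5))
#' sim$truth$initial_contacts
#' @export
generate_insole_recording <- function(config) {
  stopifnot(inherits(config, "gait_signal_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n_st <- round(config$stance_duration * fs)
  n_sw <- round(config$swing_duration * fs)
  pad <- round(0.5 * fs)
  n <- pad + config$n_strides * (n_st + n_sw) + pad
  peak_n <- config$peak_force_pct_bw / 100 * config$body_weight

  # stance samples at u in (0,1) exclusive: force > 0 on every stance
  # sample and exactly 0 outside
  u <- (seq_len(n_st)) / (n_st + 1)
  shape <- stance_shape(u, config$double_hump_ratio)
  shape <- shape / max(shape) * peak_n

  force <- numeric(n)
  ic <- integer(config$n_strides)
  fc <- integer(config$n_strides)
  for (s in seq_len(config$n_strides)) {
    start <- pad + (s - 1L) * (n_st + n_sw) + 1L
    force[start:(start + n_st - 1L)] <- shape
    ic[s] <- start
    fc[s] <- start + n_st  # first sample back at zero force
  }

  # hindfoot -> forefoot roll-over: row r of the 4x4 grid (heel = row 1)
  # activates around stance phase centre 0.2 + 0.2*(r-1); column weights
  # uniform. Weights renormalized per sample so the 16 channels sum to the
  # total force exactly (unit sensor area factor).
  rows <- rep(1:4, each = 4)
  centre <- 0.2 + 0.2 * (rows - 1)
  pmat <- matrix(0, n, 16)
  wmat <- exp(-outer(u, centre, function(ui, ci) (ui - ci)^2) / (2 * 0.18^2))
  wmat <- wmat / rowSums(wmat)
  for (s in seq_len(config$n_strides)) {
    start <- pad + (s - 1L) * (n_st + n_sw) + 1L
    pmat[start:(start + n_st - 1L), ] <- wmat * shape
  }

  # mediolateral angular velocity: one oscillation per stride cycle
  tt <- (seq_len(n) - 1) / fs
  cyc <- config$stance_duration + config$swing_duration
  gyro_y <- config$gyro_amplitude * sin(2 * pi * (tt - pad / fs) / cyc)
  gyro <- cbind(gyro_x = 0.3 * gyro_y, gyro_y = gyro_y, gyro_z = 0.2 * gyro_y)

  truth_layout <- sensor_layout(side = "right")
  truth_features <- list(
    max_total_force_pbw = 100 * peak_n / config$body_weight,
    max_regional_p = {
      reg <- regional_pressures(wmat * shape, truth_layout,
                                config$body_weight)
      vapply(reg, max, numeric(1))
    }
  )

  if (config$sensor_noise_sd > 0) {
    pmat <- pmat + matrix(rnorm(n * 16, 0, config$sensor_noise_sd), n, 16)
    gyro <- gyro + matrix(rnorm(n * 3, 0, config$sensor_noise_sd), n, 3)
    force_out <- rowSums(pmat)
  } else {
    force_out <- force
  }

  rec <- insole_recording(pressure = pmat, total_force = force_out,
                          gyro = gyro, body_weight = config$body_weight,
                          sampling_rate = fs, side = "right", injured = TRUE)
  list(recording = rec,
       truth = list(initial_contacts = ic, final_contacts = fc,
                    peak_force_n = peak_n, stride_maxima = truth_features))
}

#' Configuration for a synthetic longitudinal cohort
#'
#' Generating parameters for a fracture-recovery cohort: per-patient
#' demographics and comorbidities, a fixed visit schedule, PROMIS T-score
#' trajectories built as interval fixed effects plus sex/hypertension
#' effects, a patient random intercept and residual noise, and gait
#' parameters following a saturating-exponential recovery. Defaults emulate
#' an 85-patient lower-leg-fracture cohort followed for a year: baseline in
#' the first post-surgical week, then visits near 6 weeks, 3, 6, 9 and 12
#' months, with attrition thinning later visits.
#'
#' @param n_patients number of patients.
#' @param visit_days strictly increasing days post-surgery.
#' @param dropout_hazard_per_visit probability of permanent dropout after
#'   each completed visit (missing completely at random).
#' @param promis_fixed_effects named list per construct
#'   (`physical_health`, `mental_health`, `pain_interference`) of T-score
#'   means per visit (same length as `visit_days`). Defaults trace the
#'   recovery shape: worst scores at 6 weeks to 3 months, return toward
#'   preinjury values by 1 year.
#' @param sex_effect additive T-score shift for male patients (applied with
#'   its sign to physical/mental health and with opposite sign to pain
#'   interference, where lower is better health).
#' @param hypertension_effect additive T-score shift for hypertensive
#'   patients (same sign convention as `sex_effect`).
#' @param random_intercept_sd SD of the per-patient random intercept,
#'   T-score points.
#' @param residual_sd residual SD, T-score points.
#' @param gait_recovery_rate per-day rate of the saturating-exponential
#'   gait recovery.
#' @param gait_plateau plateau of the peak total force, %BW.
#' @param gait_baseline first-week value of the peak total force, %BW.
#' @param gait_cv multiplicative (lognormal) coefficient of variation of
#'   gait parameters around their trajectory.
#' @param seed integer RNG seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_patients = 85,
    visit_days = c(7, 42, 91, 180, 270, 365),
    dropout_hazard_per_visit = 0.25,
    promis_fixed_effects = list(
      physical_health = c(50.9, 38, 40, 43.3, 47, 49.3),
      mental_health = c(51.2, 45, 44, 45.2, 48, 50.9),
      pain_interference = c(51.2, 60, 61, 57.6, 55, 53.9)
    ),
    sex_effect = 2, hypertension_effect = -2,
    random_intercept_sd = 6, residual_sd = 4,
    gait_recovery_rate = 0.02, gait_plateau = 115, gait_baseline = 55,
    gait_cv = 0.12, seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  if (any(diff(visit_days) <= 0)) {
    abort("`visit_days` must be strictly increasing.")
  }
  if (dropout_hazard_per_visit < 0 || dropout_hazard_per_visit > 1) {
    abort("`dropout_hazard_per_visit` must be a probability.")
  }
  if (random_intercept_sd < 0 || residual_sd < 0 || gait_cv < 0) {
    abort("SDs must be >= 0.")
  }
  bad <- vapply(promis_fixed_effects, function(x) {
    length(x) != length(visit_days)
  }, logical(1))
  if (any(bad)) {
    abort("each `promis_fixed_effects` entry needs one mean per visit day.")
  }
  structure(
    list(n_patients = n_patients, visit_days = visit_days,
         dropout_hazard_per_visit = dropout_hazard_per_visit,
         promis_fixed_effects = promis_fixed_effects,
         sex_effect = sex_effect, hypertension_effect = hypertension_effect,
         random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
         gait_recovery_rate = gait_recovery_rate, gait_plateau = gait_plateau,
         gait_baseline = gait_baseline, gait_cv = gait_cv, seed = seed),
    class = "cohort_sim_config")
}

# relative scale of each gait parameter's trajectory vs the peak total force
gait_param_scales <- c(max_force_pbw = 1, ff_p = 0.20, hf_p = 0.18,
                       lat_p = 0.14, med_p = 0.16, max_av_ml = 3.5)

#' Generate a synthetic longitudinal cohort
#'
#' Simulates the patient-by-visit table the longitudinal analyses consume.
#' PROMIS T scores are generated as
#' `interval mean + sex effect + hypertension effect + patient random
#' intercept + residual`; gait parameters follow
#' `plateau - (plateau - baseline) * exp(-rate * day)` with a per-patient
#' multiplicative level and lognormal visit-to-visit noise (gait values stay
#' positive). Dropout is permanent, missing completely at random, with the
#' configured per-visit hazard.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (tibble: one row per retained patient-visit,
#'   columns `patient_id, sex, age, bmi, smoking, hypertension, diabetes,
#'   cancer, previous_injury, fracture_type, implant_type, visit_day,
#'   ph_t, mh_t, pi_t, max_force_pbw, ff_p, hf_p, lat_p, med_p, max_av_ml`)
#'   and `truth` (the generating parameter values, for recovery tests).
#' @examples
#' cohort <- generate_cohort(cohort_sim_config(n_patients = 20))$cohort
#' head(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  np <- config$n_patients
  nv <- length(config$visit_days)

  patients <- tibble(
    patient_id = sprintf("P%04d", seq_len(np)),
    sex = ifelse(runif(np) < 46 / 85, "male", "female"),
    age = pmin(pmax(rnorm(np, 50.8, 17.1), 18), 90),
    bmi = pmax(rnorm(np, 26.9, 4.2), 16),
    smoking = runif(np) < 19 / 84,
    hypertension = runif(np) < 13 / 85,
    diabetes = runif(np) < 8 / 85,
    cancer = runif(np) < 2 / 85,
    previous_injury = runif(np) < 13 / 85,
    fracture_type = sample(c("proximal tibia", "tibial shaft", "malleolar"),
                           np, replace = TRUE, prob = c(20, 22, 43) / 85),
    implant_type = ifelse(runif(np) < 17 / 85, "nail", "plate"),
    b_i = rnorm(np, 0, config$random_intercept_sd),
    gait_level = exp(rnorm(np, 0, config$gait_cv / 2))
  )

  # MCAR attrition: patient completes visits 1..K, drops out after each
  # completed visit with the configured hazard
  n_completed <- vapply(seq_len(np), function(i) {
    k <- nv
    for (v in seq_len(nv - 1)) {
      if (runif(1) < config$dropout_hazard_per_visit) { k <- v; break }
    }
    k
  }, integer(1))

  grid <- tidyr::expand_grid(idx = seq_len(np), visit = seq_len(nv)) %>%
    filter(.data$visit <= n_completed[.data$idx])

  fe <- config$promis_fixed_effects
  rows <- patients[grid$idx, ]
  day <- config$visit_days[grid$visit]
  male <- rows$sex == "male"
  shift <- config$sex_effect * male +
    config$hypertension_effect * rows$hypertension
  nr <- nrow(grid)

  traj <- function(scale) {
    scale * (config$gait_plateau -
               (config$gait_plateau - config$gait_baseline) *
               exp(-config$gait_recovery_rate * day))
  }
  gait_noise <- function() exp(rnorm(nr, 0, config$gait_cv / 2))

  cohort <- rows %>%
    mutate(
      visit_day = day,
      ph_t = fe$physical_health[grid$visit] + shift + .data$b_i +
        rnorm(nr, 0, config$residual_sd),
      mh_t = fe$mental_health[grid$visit] + shift + .data$b_i +
        rnorm(nr, 0, config$residual_sd),
      pi_t = fe$pain_interference[grid$visit] - shift - .data$b_i +
        rnorm(nr, 0, config$residual_sd),
      max_force_pbw = traj(gait_param_scales["max_force_pbw"]) *
        .data$gait_level * gait_noise(),
      ff_p = traj(gait_param_scales["ff_p"]) * .data$gait_level * gait_noise(),
      hf_p = traj(gait_param_scales["hf_p"]) * .data$gait_level * gait_noise(),
      lat_p = traj(gait_param_scales["lat_p"]) * .data$gait_level *
        gait_noise(),
      med_p = traj(gait_param_scales["med_p"]) * .data$gait_level *
        gait_noise(),
      max_av_ml = traj(gait_param_scales["max_av_ml"]) * .data$gait_level *
        gait_noise()
    ) %>%
    select(-"b_i", -"gait_level")

  list(cohort = cohort,
       truth = list(
         promis_fixed_effects = fe,
         sex_effect = config$sex_effect,
         hypertension_effect = config$hypertension_effect,
         random_intercept_sd = config$random_intercept_sd,
         residual_sd = config$residual_sd,
         random_intercepts = setNames(patients$b_i, patients$patient_id),
         gait_recovery_rate = config$gait_recovery_rate,
         gait_plateau = config$gait_plateau,
         n_completed_visits = setNames(n_completed, patients$patient_id)
       ))
}

#' Write / read the tidy cohort CSV schema
#'
#' @param cohort tibble as returned by [generate_cohort()].
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
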