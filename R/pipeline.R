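#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate/ingest, gait extraction, PROMIS scoring, the
#' longitudinal analyses and the location-scale-shape models, writing
#' versioned CSV/JSON outputs plus a machine-readable run manifest (seed,
#' parameters, input hashes). Any stage failure aborts with a
#' stage-attributed error; outputs of completed stages are retained.
#'
#' The config is a YAML (or already-parsed list) with blocks:
#' \describe{
#'   \item{seed}{integer; fanned out to per-stage substreams so stages are
#'     individually reproducible.}
#'   \item{simulate}{optional: `n_patients`, `n_walks`, plus any
#'     [cohort_sim_config()] / [gait_signal_config()] fields. When absent,
#'     `cohort_csv` must point at an existing cohort file.}
#'   \item{cohort_csv}{input cohort (ignored when simulating).}
#'   \item{detection}{optional gait-pipeline overrides: `threshold_n`,
#'     `min_contact_ms`, `cutoff_hz`, `order`, `k_strides`.}
#'   \item{gamlss}{optional: `interval` (default `"3-months"`), `outcomes`
#'     (default all six gait parameters), `knots`, `lambda`.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @return invisibly, a list with the output paths and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("[config] file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stop("config needs `out_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- function(k) (seed * 97L + k * 1009L) %% 2147483647L
  paths <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }

  # -- simulate or ingest ----------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$simulate)) {
      sim_cfg <- config$simulate
      cc <- cohort_sim_config(
        n_patients = sim_cfg$n_patients %||% 85,
        dropout_hazard_per_visit = sim_cfg$dropout_hazard_per_visit %||% 0.25,
        seed = stage_seed(1L))
      cohort <- generate_cohort(cc)$cohort
      paths$cohort <- file.path(out_dir, "cohort.csv")
      write_cohort_csv(cohort, paths$cohort)
      cohort
    } else {
      if (is.null(config$cohort_csv) || !file.exists(config$cohort_csv)) {
        abort("no simulate block and no existing `cohort_csv` input.")
      }
      paths$cohort <- config$cohort_csv
      read_cohort_csv(config$cohort_csv)
    }
  })

  # -- extract gait from simulated walks (demonstration stream) --------
  det <- config$detection %||% list()
  n_walks <- config$simulate$n_walks %||% 0
  if (n_walks > 0) {
    gait_feats <- run_stage("extract-gait", {
      purrr::map(seq_len(n_walks), function(i) {
        sim <- generate_insole_recording(
          gait_signal_config(seed = stage_seed(100L + i)))
        g <- extract_gait(
          sim$recording,
          threshold = det$threshold_n %||% 30,
          min_contact = (det$min_contact_ms %||% 300) / 1000,
          cutoff = det$cutoff_hz %||% 6,
          order = det$order %||% 4,
          k = det$k_strides %||% 5)
        mutate(g, walk = i)
      }) %>% purrr::list_rbind()
    })
    paths$gait_features <- file.path(out_dir, "gait_features.csv")
    readr::write_csv(gait_feats, paths$gait_features)
  }

  # -- score PROMIS (items, when present) ------------------------------
  cohort <- run_stage("score-promis", {
    if (all(c("g01", "pi1") %in% names(cohort))) {
      score_promis(cohort)
    } else cohort    # T scores already present
  })

  # -- longitudinal analyses -------------------------------------------
  analysis <- run_stage("analyze", {
    tab <- cohort %>% add_intervals() %>% dedupe_last_per_interval()
    demo <- demographics_table(tab)
    lmms <- purrr::map(
      c(ph_t = "ph_t", mh_t = "mh_t", pi_t = "pi_t"),
      function(oc) tidy(fit_lmm(tab, oc)))
    rho <- purrr::map(
      c("6-weeks", "3-months", "6-months"),
      function(iv) mutate(spearman_matrix(tab, iv), interval = iv)) %>%
      purrr::list_rbind()
    list(table = tab, demographics = demo, lmms = lmms, spearman = rho)
  })
  paths$demographics <- file.path(out_dir, "table1_demographics.csv")
  readr::write_csv(analysis$demographics, paths$demographics)
  for (oc in names(analysis$lmms)) {
    p <- file.path(out_dir, paste0("lmm_", oc, ".csv"))
    readr::write_csv(analysis$lmms[[oc]], p)
    paths[[paste0("lmm_", oc)]] <- p
  }
  paths$spearman <- file.path(out_dir, "spearman_by_interval.csv")
  readr::write_csv(analysis$spearman, paths$spearman)

  # -- GAMLSS at the chosen interval -----------------------------------
  gm <- config$gamlss %||% list()
  fits <- run_stage("gamlss", {
    iv <- gm$interval %||% "3-months"
    sub <- filter(analysis$table, .data$interval == iv)
    outcomes <- gm$outcomes %||% c("max_force_pbw", "med_p", "lat_p",
                                   "ff_p", "hf_p", "max_av_ml")
    spl <- pb_spec(n_interior_knots = gm$knots %||% 20,
                   lambda = gm$lambda %||% "auto")
    fits <- purrr::map(setNames(outcomes, outcomes), function(oc) {
      fit_gamlss_bccg(sub, oc, spline = spl)
    })
    fits
  })
  paths$gamlss <- file.path(out_dir, "gamlss_coefficients.csv")
  readr::write_csv(gamlss_report(fits), paths$gamlss)
  paths$gamlss_json <- file.path(out_dir, "gamlss_fits.json")
  jsonlite::write_json(
    purrr::map(fits, function(f) as.list(glance(f))),
    paths$gamlss_json, auto_unbox = TRUE, digits = NA)

  # -- manifest ---------------------------------------------------------
  files <- unlist(paths)
  manifest <- list(
    seed = seed,
    config = config,
    outputs = as.list(setNames(unname(tools::md5sum(files)), names(paths)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, manifest = manifest,
                 manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
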