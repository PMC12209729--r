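interval_breaks <- c(0, 15, 55, 110, 200, 300, Inf)

#' Visit-interval labels
#'
#' The six disjoint day-interval bins used to align follow-up visits:
#' 0-15 days (preinjury level for PROMIS, first week for gait), 16-55 days
#' (6 weeks), 56-110 days (3 months), 111-200 days (6 months), 201-300 days
#' (9 months), and more than 300 days (1 year).
#'
#' @return character vector of the six labels in temporal order.
#' @export
interval_levels <- function() {
  c("preinjury/first-week", "6-weeks", "3-months", "6-months",
    "9-months", "1-year")
}

#' Assign a visit day to its interval
#'
#' @param visit_day nonnegative days post-surgery.
#' @return factor with levels [interval_levels()].
#' @examples
#' assign_interval(c(15, 16, 301))
#' @export
assign_interval <- function(visit_day) {
  if (any(visit_day < 0, na.rm = TRUE)) {
    abort("`visit_day` must be nonnegative.")
  }
  cut(visit_day, breaks = interval_breaks, labels = interval_levels(),
      include.lowest = TRUE, right = TRUE)
}

#' Add interval labels to a cohort table
#'
#' @param data cohort tibble with a `visit_day` column.
#' @return `data` with an `interval` factor column.
#' @export
add_intervals <- function(data) {
  mutate(data, interval = assign_interval(.data$visit_day))
}

#' Keep the last visit per patient and interval
#'
#' When a patient has more than one measurement inside the same interval,
#' only the last one enters the analysis set: the row with the largest
#' `visit_day`, ties broken by file order (later row wins). Idempotent.
#'
#' @param data cohort tibble with `patient_id`, `visit_day` and `interval`
#'   columns (see [add_intervals()]).
#' @return deduplicated tibble, at most one row per patient-interval.
#' @export
dedupe_last_per_interval <- function(data) {
  if (!"interval" %in% names(data)) {
    abort("assign intervals first (see add_intervals()).")
  }
  data %>%
    mutate(.row = row_number()) %>%
    group_by(.data$patient_id, .data$interval) %>%
    arrange(.data$visit_day, .data$.row, .by_group = TRUE) %>%
    slice(n()) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row")
}

#' Random-intercept mixed model for a longitudinal outcome
#'
#' Fits `outcome ~ interval + covariates + (1 | patient_id)` by REML with
#' Satterthwaite degrees of freedom for the fixed-effect tests, on the
#' deduplicated analysis set. The interval reference level is the
#' preinjury/first-week bin; rows missing the outcome or any covariate are
#' dropped (complete-case).
#'
#' @param data cohort tibble with `interval` assigned.
#' @param outcome name of the outcome column (e.g. `"ph_t"`).
#' @param covariates character vector of additional fixed effects
#'   (default `c("sex", "hypertension")`).
#' @return object of class `gp_lmm` wrapping the `lmerTest` fit.
#' @export
fit_lmm <- function(data, outcome, covariates = c("sex", "hypertension")) {
  if (!outcome %in% names(data)) {
    abort(paste0("outcome `", outcome, "` not found."))
  }
  use <- data[complete.cases(data[, c(outcome, "interval", covariates)]), ]
  if (length(unique(use$interval)) < 2) {
    abort("singular design: need visits in at least two intervals.")
  }
  if (length(unique(use$patient_id)) < 2) {
    abort("need at least two patients.")
  }
  fml <- stats::reformulate(c("interval", covariates, "(1 | patient_id)"),
                            response = outcome)
  fit <- lmerTest::lmer(fml, data = use, REML = TRUE)
  structure(list(fit = fit, outcome = outcome, covariates = covariates,
                 n_obs = nrow(use),
                 n_patients = length(unique(use$patient_id))),
            class = "gp_lmm")
}

#' @exportS3Method generics::tidy
tidy.gp_lmm <- function(x, ...) {
  sm <- as.data.frame(summary(x$fit)$coefficients)
  tibble(
    term = rownames(sm),
    estimate = sm$Estimate,
    std.error = sm$`Std. Error`,
    df = sm$df,
    statistic = sm$`t value`,
    p.value = sm$`Pr(>|t|)`
  )
}

#' @exportS3Method generics::glance
glance.gp_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(
    outcome = x$outcome,
    n_obs = x$n_obs,
    n_patients = x$n_patients,
    sd_intercept = vc$sdcor[vc$grp == "patient_id"],
    sd_residual = vc$sdcor[vc$grp == "Residual"],
    REML = as.numeric(stats::logLik(x$fit))
  )
}

#' @export
print.gp_lmm <- function(x, ...) {
  cat("Random-intercept LMM for", x$outcome, "\n")
  cat(x$n_obs, "observations,", x$n_patients, "patients\n\n")
  print(tidy(x))
  invisible(x)
}

#' Covariates retained by the coefficient-size rule
#'
#' The full-to-final model reduction: keep covariates whose fixed-effect
#' coefficient exceeds `threshold` in absolute value (default 1 T-score
#' point). Interval terms and the intercept are never candidates.
#'
#' @param fit a [fit_lmm()] object (the full model).
#' @param threshold minimum absolute coefficient size.
#' @return character vector of retained covariate names.
#' @export
select_covariates <- function(fit, threshold = 1) {
  td <- tidy(fit)
  big <- td$term[abs(td$estimate) > threshold &
                   !grepl("^interval|^\\(Intercept\\)", td$term)]
  fit$covariates[vapply(fit$covariates,
                        function(cv) any(startsWith(big, cv)), logical(1))]
}

#' Interval-wise Spearman correlations of PROMIS vs gait
#'
#' Pairwise-complete Spearman rank correlations (average-rank ties) between
#' the three PROMIS T scores and the six gait parameters, within one
#' visit interval of the deduplicated analysis set. Pairs with fewer than
#' 3 complete observations are reported as `NA`.
#'
#' @param data cohort tibble with `interval` assigned (deduplicated).
#' @param interval one of [interval_levels()].
#' @param promis_cols,gait_cols column names to correlate.
#' @return tibble with columns `promis`, `gait`, `rho`, `n`.
#' @export
spearman_matrix <- function(data, interval,
                            promis_cols = c("ph_t", "mh_t", "pi_t"),
                            gait_cols = c("max_force_pbw", "med_p", "lat_p",
                                          "ff_p", "hf_p", "max_av_ml")) {
  interval <- match.arg(interval, interval_levels())
  sub <- filter(data, .data$interval == !!interval)
  grid <- tidyr::expand_grid(promis = promis_cols, gait = gait_cols)
  grid %>%
    mutate(purrr::pmap(list(.data$promis, .data$gait), function(p, g) {
      x <- sub[[p]]; y <- sub[[g]]
      ok <- !is.na(x) & !is.na(y)
      tibble(rho = if (sum(ok) >= 3) {
        cor(x[ok], y[ok], method = "spearman")
      } else NA_real_, n = sum(ok))
    }) %>% purrr::list_rbind())
}

#' Pearson chi-square test of a contingency table
#'
#' The classical statistic `sum((O - E)^2 / E)` with expected counts from
#' the row/column margins and `(r-1)(c-1)` degrees of freedom. No
#' continuity correction is applied.
#'
#' @param counts matrix of nonnegative integer counts with positive
#'   row and column margins.
#' @return tibble with `statistic`, `df`, `p.value`.
#' @examples
#' pearson_chi_square(matrix(c(3, 16, 35, 30), 2))
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be nonnegative.")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    abort("every row and column margin must be positive.")
  }
  expected <- outer(rs, cs) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  tibble(statistic = stat, df = df,
         p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-group comparison of a continuous variable
#'
#' Runs the two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction, no continuity correction) and, alongside it, the
#' one-way ANOVA F statistic on 1 and n-2 degrees of freedom. Both are
#' reported because published demographic tables sometimes label one with
#' the other's name; neither is hidden behind the other.
#'
#' @param x,y numeric samples for the two groups (each nonempty).
#' @return one-row tibble: `statistic_w`, `p_wilcoxon`, `statistic_f`,
#'   `df1`, `df2`, `p_f`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be nonempty.")
  }
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  dat <- data.frame(v = c(x, y),
                    g = rep(c("a", "b"), c(length(x), length(y))))
  av <- anova(aov(v ~ g, data = dat))
  tibble(statistic_w = unname(w$statistic), p_wilcoxon = w$p.value,
         statistic_f = av$`F value`[1],
         df1 = av$Df[1], df2 = av$Df[2], p_f = av$`Pr(>F)`[1])
}

#' Demographics summary with sex comparisons
#'
#' Builds a Table-1-style summary: per continuous variable the by-sex means
#' (SD) with the rank-sum/ANOVA comparison, per binary or categorical
#' variable the by-sex counts with the Pearson chi-square test.
#'
#' @param data cohort tibble, one row per patient-visit; patient-level
#'   variables are taken from each patient's first row.
#' @return tibble with one row per variable: `variable`, `type`,
#'   `female`, `male`, `statistic`, `df`, `p.value`.
#' @export
demographics_table <- function(data) {
  pat <- data %>% group_by(.data$patient_id) %>% slice(1) %>% ungroup()
  cont <- c("age", "bmi")
  bin <- c("smoking", "hypertension", "diabetes", "cancer",
           "previous_injury")
  rows <- list()
  for (v in intersect(cont, names(pat))) {
    xf <- pat[[v]][pat$sex == "female"]; xm <- pat[[v]][pat$sex == "male"]
    ts <- rank_sum_test(xf, xm)
    rows[[v]] <- tibble(
      variable = v, type = "continuous",
      female = sprintf("%.1f (%.1f)", mean(xf), sd(xf)),
      male = sprintf("%.1f (%.1f)", mean(xm), sd(xm)),
      statistic = ts$statistic_f, df = ts$df1, p.value = ts$p_f)
  }
  chisq_row <- function(v, tab) {
    ct <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      tibble(statistic = NA_real_, df = NA_real_, p.value = NA_real_)
    } else pearson_chi_square(tab)
    tibble(variable = v, type = "categorical",
           female = paste(tab[, 1], collapse = "/"),
           male = paste(tab[, 2], collapse = "/"),
           statistic = ct$statistic, df = ct$df, p.value = ct$p.value)
  }
  for (v in intersect(bin, names(pat))) {
    ok <- !is.na(pat[[v]])
    tab <- table(factor(pat[[v]][ok], levels = c(TRUE, FALSE)),
                 pat$sex[ok])[, c("female", "male"), drop = FALSE]
    rows[[v]] <- chisq_row(v, tab)
  }
  for (v in intersect(c("implant_type", "fracture_type"), names(pat))) {
    tab <- table(pat[[v]], pat$sex)[, c("female", "male"), drop = FALSE]
    rows[[v]] <- chisq_row(v, tab)
  }
  purrr::list_rbind(rows)
}

#' Format p-values in journal style
#'
#' Three decimals, with values below 0.001 floored to `"<.001"` and the
#' leading zero dropped.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @examples
#' format_pvalue(c(0.0004, 0.0345, 0.98))
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
}
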