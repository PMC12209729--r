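#' Plot recovery trajectories over the visit intervals
#'
#' Interval means with standard-error bars for the PROMIS T scores or the
#' gait parameters, the standard way such longitudinal trajectories are
#' displayed.
#'
#' @param data cohort tibble with `interval` assigned (see
#'   [add_intervals()]).
#' @param vars columns to plot (default the three PROMIS T scores).
#' @return a ggplot object.
#' @export
plot_trajectories <- function(data, vars = c("ph_t", "mh_t", "pi_t")) {
  long <- data %>%
    select("interval", all_of(vars)) %>%
    tidyr::pivot_longer(all_of(vars), names_to = "measure") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$interval, .data$measure) %>%
    summarise(mean = mean(.data$value),
              se = sd(.data$value) / sqrt(n()), .groups = "drop")
  ggplot(long, aes(x = .data$interval, y = .data$mean, group = 1)) +
    geom_ribbon(aes(ymin = .data$mean - .data$se,
                    ymax = .data$mean + .data$se), alpha = 0.25) +
    geom_line() +
    geom_point() +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "interval post-surgery", y = "mean ± SE") +
    theme_minimal()
}

#' Centile curves of a fitted gait model
#'
#' Shows the conditional distribution of the gait parameter against one
#' PROMIS score: predicted centile curves with the remaining covariates
#' held at their training medians, over the observed points.
#'
#' @param object a [fit_gamlss_bccg()] fit.
#' @param var covariate to vary (default `"pi_t"`).
#' @param centiles probabilities of the curves to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gp_gamlss <- function(object, var = "pi_t",
                               centiles = c(0.1, 0.5, 0.9), ...) {
  dat <- object$data
  grid <- tibble(!!sym(var) := seq(min(dat[[var]]), max(dat[[var]]),
                                   length.out = 80))
  for (v in setdiff(names(dat), c(var, object$outcome))) {
    grid[[v]] <- median(dat[[v]])
  }
  curves <- purrr::map(centiles, function(p) {
    tibble(x = grid[[var]], centile = paste0(100 * p, "%"),
           y = predict_centile(object, grid, p = p))
  }) %>% purrr::list_rbind()
  ggplot(curves, aes(x = .data$x, y = .data$y)) +
    geom_point(data = tibble(x = dat[[var]], y = dat[[object$outcome]]),
               alpha = 0.4, inherit.aes = TRUE) +
    geom_line(aes(group = .data$centile, linetype = .data$centile)) +
    labs(x = var, y = object$outcome) +
    theme_minimal()
}

#' Plot an interval's Spearman correlation matrix
#'
#' @param rho tibble from [spearman_matrix()].
#' @return a ggplot object.
#' @export
plot_spearman <- function(rho) {
  ggplot(rho, aes(x = .data$gait, y = .data$rho)) +
    geom_col() +
    facet_wrap(~promis) +
    labs(x = NULL, y = "Spearman ρ") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
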