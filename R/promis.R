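#' Read and validate a PROMIS score map
#'
#' A score map defines, per construct, the contributing item columns, an
#' optional per-item recode table (e.g. reverse-coded items), and the
#' raw-score-to-T-score lookup table. The official conversion tables are
#' licensed and are therefore configuration, not package content: the map
#' shipped with the package (`default_score_map()`) uses the standard item
#' groupings of Global Health v1.2 (four items per component, with the
#' symptom items reverse-coded) and Pain Interference 8a, but carries
#' clearly labelled *synthetic* raw-to-T tables. Replace them with the
#' licensed tables for real scoring.
#'
#' @param path path to a score-map JSON file, or an equivalent named list.
#' @return a list of class `score_map` with elements `constructs`,
#'   `recodes`, `raw_to_t`.
#' @export
read_score_map <- function(path) {
  map <- if (is.list(path)) {
    path
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_score_map(map)
}

#' @rdname read_score_map
#' @export
default_score_map <- function() {
  read_score_map(system.file("extdata", "promis_scoremap_synthetic.json",
                             package = "gaitpromis", mustWork = TRUE))
}

validate_score_map <- function(map) {
  if (!all(c("constructs", "raw_to_t") %in% names(map))) {
    abort("a score map needs `constructs` and `raw_to_t` entries.")
  }
  if (is.null(map$recodes)) map$recodes <- list()
  for (con in names(map$constructs)) {
    items <- map$constructs[[con]]
    tab <- map$raw_to_t[[con]]
    if (is.null(tab)) {
      abort(paste0("no raw_to_t table for construct `", con, "`."))
    }
    raws <- as.numeric(names(tab))
    # attainable raw range given the recodes (default identity on 1..5)
    rng <- vapply(items, function(it) {
      rc <- map$recodes[[it]]
      pts <- if (is.null(rc)) 1:5 else as.numeric(unlist(rc))
      c(min(pts), max(pts))
    }, numeric(2))
    lo <- sum(rng[1, ]); hi <- sum(rng[2, ])
    if (!all(lo:hi %in% raws)) {
      abort(paste0("raw_to_t table for `", con,
                   "` does not cover the attainable raw range ",
                   lo, "..", hi, "."))
    }
    if (any(!is.finite(as.numeric(unlist(tab))))) {
      abort("T scores in the lookup must be finite.")
    }
  }
  structure(map, class = "score_map")
}

recode_item <- function(x, item, map) {
  rc <- map$recodes[[item]]
  if (is.null(rc)) return(as.numeric(x))
  rc <- unlist(rc)
  out <- unname(as.numeric(rc[as.character(x)]))
  out[is.na(x)] <- NA_real_
  if (any(!is.na(x) & is.na(out))) {
    abort(paste0("response outside the recode table for item `", item, "`."))
  }
  out
}

#' Raw PROMIS score for one construct
#'
#' Sums the recoded contributing items. A visit with any contributing item
#' missing gets `NA` for this construct (it is excluded for this score
#' only; other constructs of the same visit are unaffected).
#'
#' @param responses data frame with one row per visit and one column per
#'   item (`g01..g10`, `pi1..pi8`), ordinal responses or `NA`.
#' @param construct construct id present in the map (e.g.
#'   `"physical_health"`, `"mental_health"`, `"pain_interference"`).
#' @param map a [read_score_map()] object.
#' @return numeric vector of raw scores, `NA` where excluded.
#' @export
compute_raw_score <- function(responses, construct,
                              map = default_score_map()) {
  if (!construct %in% names(map$constructs)) {
    abort(paste0("unknown construct `", construct, "`."))
  }
  items <- map$constructs[[construct]]
  missing_cols <- setdiff(items, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("missing item columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  pts <- vapply(items, function(it) recode_item(responses[[it]], it, map),
                numeric(nrow(responses)))
  pts <- matrix(pts, nrow = nrow(responses))
  rowSums(pts)   # NA whenever any contributing item is missing
}

#' Convert a raw score to a T score by table lookup
#'
#' Exact lookup, no interpolation; a non-missing raw score outside the
#' table's domain is an error. `NA` (excluded) passes through.
#'
#' @param raw numeric raw scores.
#' @inheritParams compute_raw_score
#' @return numeric T scores.
#' @export
raw_to_t <- function(raw, construct, map = default_score_map()) {
  if (!construct %in% names(map$raw_to_t)) {
    abort(paste0("unknown construct `", construct, "`."))
  }
  tab <- unlist(map$raw_to_t[[construct]])
  out <- unname(as.numeric(tab[as.character(raw)]))
  bad <- !is.na(raw) & is.na(out)
  if (any(bad)) {
    abort(paste0("raw score(s) ", paste(unique(raw[bad]), collapse = ", "),
                 " outside the lookup domain for `", construct, "`."))
  }
  out[is.na(raw)] <- NA_real_
  out
}

#' Score PROMIS item responses into T scores
#'
#' Computes the three construct T scores (`ph_t`, `mh_t`, `pi_t`) from item
#' response columns, applying the per-construct exclusion rule: a visit
#' with a missing response loses only the affected construct.
#'
#' @param data data frame with item columns `g01..g10` and `pi1..pi8`.
#' @inheritParams compute_raw_score
#' @return `data` with `ph_t`, `mh_t`, `pi_t` columns appended.
#' @export
score_promis <- function(data, map = default_score_map()) {
  data %>% mutate(
    ph_t = raw_to_t(compute_raw_score(data, "physical_health", map),
                    "physical_health", map),
    mh_t = raw_to_t(compute_raw_score(data, "mental_health", map),
                    "mental_health", map),
    pi_t = raw_to_t(compute_raw_score(data, "pain_interference", map),
                    "pain_interference", map)
  )
}

#' Clinically meaningful T-score change
#'
#' A change of at least `threshold` T-score points between two visits
#' (default 5 points, i.e. half a population SD) is flagged as clinically
#' meaningful; the boundary is inclusive. Missing (excluded) inputs yield
#' `NA`.
#'
#' @param t_before,t_after T scores.
#' @param threshold minimum absolute change, T-score points.
#' @return logical vector.
#' @examples
#' meaningful_change(50, 45)  # TRUE: boundary inclusive
#' meaningful_change(50, 46)  # FALSE
#' @export
meaningful_change <- function(t_before, t_after, threshold = 5) {
  abs(t_after - t_before) >= threshold
}
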