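# small fixture score map: identity recodes, linear raw-to-T tables
fixture_score_map <- function() {
  tab <- function(lo, hi, a, b) {
    as.list(setNames(a + b * (lo:hi - lo), lo:hi))
  }
  read_score_map(list(
    constructs = list(
      physical_health = c("g03", "g06", "g07", "g08"),
      mental_health = c("g02", "g04", "g05", "g10"),
      pain_interference = paste0("pi", 1:8)
    ),
    recodes = list(),
    raw_to_t = list(
      physical_health = tab(4, 20, 20, 3),
      mental_health = tab(4, 20, 21, 3),
      pain_interference = tab(8, 40, 38, 1.2)
    )
  ))
}

# one row of item responses, all set to `value`
fixture_responses <- function(n = 1, value = 3) {
  cols <- c(sprintf("g%02d", 1:10), paste0("pi", 1:8))
  out <- as.data.frame(matrix(value, nrow = n, ncol = length(cols)))
  names(out) <- cols
  tibble::as_tibble(out)
}

# square force pulse: `ms` milliseconds at `level` N inside a zero baseline
fixture_pulse <- function(ms, level = 400, fs = 100, lead = 20, tail = 20) {
  c(rep(0, lead), rep(level, round(ms / 1000 * fs)), rep(0, tail))
}

# measured amplitude of a pure tone in `y` over an integer-cycle window
measure_tone_amplitude <- function(y, f, fs) {
  t <- (seq_along(y) - 1) / fs
  n_cyc <- floor((max(t) / 2 - max(t) / 4) * f)
  w <- t >= max(t) / 4 & t < max(t) / 4 + n_cyc / f
  sqrt((2 * mean(y[w] * sin(2 * pi * f * t[w])))^2 +
         (2 * mean(y[w] * cos(2 * pi * f * t[w])))^2)
}
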