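#' Construct an insole recording
#'
#' Bundles the multichannel time series of one instrumented-insole walk
#' (16 plantar-pressure channels, total vertical force, triaxial angular
#' velocity) with its metadata (body weight, side, injured flag, sampling
#' rate) into a tibble with the class `insole_recording`. All channel
#' columns must have equal length; time is implied by the sampling rate.
#'
#' @param pressure numeric matrix or data frame with 16 columns, one per
#'   pressure sensor, in recording order `p01..p16`.
#' @param total_force numeric vector, total vertical force in Newtons.
#' @param gyro numeric matrix or data frame with 3 columns
#'   (`gyro_x_dps`, `gyro_y_dps`, `gyro_z_dps`), angular velocity in deg/s.
#' @param body_weight body weight in Newtons (> 0).
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param side `"left"` or `"right"`.
#' @param injured logical, whether this is the injured side.
#'
#' @return a tibble of class `insole_recording` with columns `time_s`,
#'   `p01..p16`, `total_force_n`, `gyro_x_dps`, `gyro_y_dps`, `gyro_z_dps`
#'   and attributes `body_weight_n`, `side`, `injured`, `sampling_rate_hz`.
#' @export
insole_recording <- function(pressure, total_force, gyro, body_weight,
                             sampling_rate = 100, side = "right",
                             injured = TRUE) {
  pressure <- as.matrix(pressure)
  gyro <- as.matrix(gyro)
  n <- length(total_force)
  if (ncol(pressure) != 16) abort("`pressure` must have 16 channels.")
  if (ncol(gyro) != 3) abort("`gyro` must have 3 channels.")
  if (nrow(pressure) != n || nrow(gyro) != n) {
    abort("all channels of an insole recording must have the same length.")
  }
  if (!is.numeric(body_weight) || body_weight <= 0) {
    abort("`body_weight` must be a positive number of Newtons.")
  }
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  side <- match.arg(side, c("left", "right"))
  colnames(pressure) <- sprintf("p%02d", 1:16)
  colnames(gyro) <- c("gyro_x_dps", "gyro_y_dps", "gyro_z_dps")
  out <- tibble(time_s = (seq_len(n) - 1) / sampling_rate)
  out <- dplyr::bind_cols(out, as_tibble(pressure),
                          tibble(total_force_n = as.numeric(total_force)),
                          as_tibble(gyro))
  structure(out,
            body_weight_n = body_weight,
            side = side,
            injured = injured,
            sampling_rate_hz = sampling_rate,
            class = c("insole_recording", class(out)))
}

#' Sampling rate of a recording
#' @param recording an [insole_recording()].
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(recording) attr(recording, "sampling_rate_hz")

#' Body weight of a recording
#' @param recording an [insole_recording()].
#' @return body weight in Newtons.
#' @export
body_weight <- function(recording) attr(recording, "body_weight_n")

#' Low-pass Butterworth filter
#'
#' Applies the study pipeline's noise filter: a fourth-order Butterworth
#' low-pass at 6 Hz by default. The default mode runs the filter
#' forward and backward (zero phase), so event timing is not lagged; the
#' effective attenuation is then the squared one-pass magnitude response.
#' A causal single-pass mode is available.
#'
#' @param x numeric series.
#' @param sampling_rate sampling rate of `x` in Hz.
#' @param order filter order (default 4).
#' @param cutoff cutoff frequency in Hz (default 6); must be below Nyquist.
#' @param mode `"zero-phase"` (default) or `"causal"`.
#' @return filtered series, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' lowpass_filter(sin(2 * pi * t), sampling_rate = 100)[1:5]
#' @export
lowpass_filter <- function(x, sampling_rate, order = 4, cutoff = 6,
                           mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    abort("`cutoff` must lie strictly between 0 and the Nyquist frequency.")
  }
  if (length(x) <= 3 * (order + 1)) {
    abort("series too short to filter at this order.")
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  if (mode == "zero-phase") {
    # odd-reflection padding so start-up transients of the forward and
    # backward passes decay outside the data window
    n <- length(x)
    np <- min(n - 1, max(3 * (order + 1),
                         ceiling(15 * sampling_rate / cutoff)))
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - np)]
    y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
    y[np + seq_len(n)]
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Analytic magnitude response of the low-pass filter
#'
#' Closed-form gain of the digital Butterworth design used by
#' [lowpass_filter()] at frequency `f`:
#' `1 / sqrt(1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order))`, i.e. the
#' analog Butterworth response evaluated at bilinear-prewarped frequencies
#' (the two coincide well below the Nyquist frequency, where
#' `tan(x) ~ x`). Zero-phase (forward-backward) filtering squares the gain.
#'
#' @inheritParams lowpass_filter
#' @param f frequency in Hz at which to evaluate the response.
#' @return gain in (0, 1].
#' @export
butterworth_gain <- function(f, sampling_rate, order = 4, cutoff = 6,
                             mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  g <- 1 / sqrt(1 + (tan(pi * f / sampling_rate) /
                       tan(pi * cutoff / sampling_rate))^(2 * order))
  if (mode == "zero-phase") g^2 else g
}

#' Filter every channel of a recording
#'
#' Applies [lowpass_filter()] to all pressure, force and gyroscope channels.
#'
#' @inheritParams lowpass_filter
#' @param recording an [insole_recording()].
#' @return the recording with all signal channels filtered.
#' @export
filter_recording <- function(recording, order = 4, cutoff = 6,
                             mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  fs <- sampling_rate(recording)
  chans <- setdiff(names(recording), "time_s")
  for (ch in chans) {
    recording[[ch]] <- lowpass_filter(recording[[ch]], fs,
                                      order = order, cutoff = cutoff,
                                      mode = mode)
  }
  recording
}

#' Detect strides from total vertical force
#'
#' Threshold-and-persistence gait-event detection. Initial contact (IC) is
#' the first sample at which the force exceeds the threshold and stays above
#' it for at least `min_contact` seconds; final contact (FC) is the first
#' sample after IC at which the force drops back under the threshold.
#' Above-threshold episodes shorter than the persistence criterion are
#' discarded, as are episodes that never release before the series ends.
#'
#' @param force total vertical force in Newtons (filtered, not normalized).
#' @param sampling_rate sampling rate in Hz.
#' @param threshold contact threshold in Newtons (default 30).
#' @param min_contact minimum contact duration in seconds (default 0.300).
#' @return tibble with columns `stride`, `initial_contact`, `final_contact`
#'   (1-based sample indices, `initial_contact < final_contact`); zero rows
#'   if no stride is found.
#' @examples
#' f <- c(rep(0, 10), rep(400, 50), rep(0, 10))
#' detect_strides(f, sampling_rate = 100)
#' @export
detect_strides <- function(force, sampling_rate, threshold = 30,
                           min_contact = 0.300) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  if (min_contact <= 0) abort("`min_contact` must be positive.")
  empty <- tibble(stride = integer(), initial_contact = integer(),
                  final_contact = integer())
  n <- length(force)
  if (n == 0) return(empty)
  above <- force > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ic <- integer(0); fc <- integer(0)
  for (k in keep) {
    s <- starts[k]; e <- ends[k]
    if (e >= n) next                       # never released before end
    if (force[e + 1L] >= threshold) next   # lingered at the threshold
    if ((e - s + 1L) / sampling_rate < min_contact - 1e-12) next
    ic <- c(ic, s); fc <- c(fc, e + 1L)
  }
  tibble(stride = seq_along(ic), initial_contact = ic, final_contact = fc)
}

#' Normalize force to percent body weight
#'
#' @param force force in Newtons.
#' @param body_weight body weight in Newtons (> 0).
#' @return force as a percentage of body weight (`100 * force / body_weight`).
#' @export
normalize_force <- function(force, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      body_weight <= 0) {
    abort("`body_weight` must be a single positive number of Newtons.")
  }
  100 * force / body_weight
}

#' Sensor layout: regional groupings of the 16 pressure sensors
#'
#' Defines which sensors make up the forefoot, hindfoot, lateral and medial
#' regions. The default assumes a 4x4 anatomical grid indexed row-major from
#' the heel: rows 1-2 (sensors 1-8) are hindfoot, rows 3-4 (sensors 9-16)
#' forefoot; columns 1-2 medial and 3-4 lateral for a right insole, mirrored
#' for a left one. Real insoles number sensors differently, so the mapping
#' is fully user-configurable.
#'
#' @param forefoot,hindfoot,lateral,medial integer vectors of sensor indices
#'   in `1..16`; forefoot/hindfoot must be disjoint, as must lateral/medial,
#'   and every region must be nonempty.
#' @param side `"left"` or `"right"`; mirrors the medial/lateral defaults.
#' @return a list of class `sensor_layout`.
#' @export
sensor_layout <- function(forefoot = 9:16, hindfoot = 1:8,
                          lateral = NULL, medial = NULL,
                          side = "right") {
  side <- match.arg(side, c("left", "right"))
  cols <- (0:15) %% 4 + 1   # column of each sensor in the 4x4 grid
  if (is.null(medial)) {
    medial <- if (side == "right") which(cols <= 2) else which(cols >= 3)
  }
  if (is.null(lateral)) {
    lateral <- if (side == "right") which(cols >= 3) else which(cols <= 2)
  }
  layout <- list(forefoot = as.integer(forefoot),
                 hindfoot = as.integer(hindfoot),
                 lateral = as.integer(lateral),
                 medial = as.integer(medial))
  for (nm in names(layout)) {
    idx <- layout[[nm]]
    if (length(idx) == 0) abort(paste0("region `", nm, "` is empty."))
    if (any(idx < 1 | idx > 16)) {
      abort("sensor indices must lie in 1..16.")
    }
  }
  if (length(intersect(layout$forefoot, layout$hindfoot)) > 0) {
    abort("forefoot and hindfoot regions must be disjoint.")
  }
  if (length(intersect(layout$lateral, layout$medial)) > 0) {
    abort("lateral and medial regions must be disjoint.")
  }
  structure(layout, class = "sensor_layout")
}

#' Regional plantar pressures in percent body weight per sensor
#'
#' For each anatomical region, sums the member sensor channels, normalizes
#' to percent body weight, and divides by the number of sensors combined:
#' `region = (100 / body_weight) * rowSums(pressure[, region]) / n_region`.
#'
#' @param pressure numeric matrix/data frame with 16 sensor columns.
#' @param layout a [sensor_layout()].
#' @param body_weight body weight in Newtons.
#' @return tibble with columns `forefoot`, `hindfoot`, `lateral`, `medial`
#'   (same number of rows as `pressure`), each in %BW per sensor.
#' @export
regional_pressures <- function(pressure, layout, body_weight) {
  if (!inherits(layout, "sensor_layout")) {
    abort("`layout` must be a sensor_layout object.")
  }
  pressure <- as.matrix(pressure)
  if (ncol(pressure) != 16) abort("`pressure` must have 16 channels.")
  one <- function(region) {
    idx <- layout[[region]]
    normalize_force(rowSums(pressure[, idx, drop = FALSE]), body_weight) /
      length(idx)
  }
  tibble(forefoot = one("forefoot"), hindfoot = one("hindfoot"),
         lateral = one("lateral"), medial = one("medial"))
}

#' Per-stride maxima of the analysis signals
#'
#' For each detected stride, extracts the maximum over the contact interval
#' `[IC, FC)` of: total force (%BW), the four regional pressures (%BW per
#' sensor), and the mediolateral angular velocity (deg/s, signed).
#'
#' @param recording an [insole_recording()] (typically filtered).
#' @param strides output of [detect_strides()] on the same recording.
#' @param layout a [sensor_layout()]; defaults to the recording's side.
#' @param ml_axis name of the gyroscope channel holding the mediolateral
#'   axis (default `"gyro_y_dps"`).
#' @return tibble, one row per stride: `stride`, `max_total_force_pbw`,
#'   `max_forefoot_p`, `max_hindfoot_p`, `max_lateral_p`, `max_medial_p`,
#'   `max_angular_velocity_ml`.
#' @export
extract_stride_features <- function(recording, strides, layout = NULL,
                                    ml_axis = "gyro_y_dps") {
  if (is.null(layout)) layout <- sensor_layout(side = attr(recording, "side"))
  n <- nrow(recording)
  if (nrow(strides) > 0 &&
      (min(strides$initial_contact) < 1 || max(strides$final_contact) > n)) {
    abort("stride indices out of range for this recording.")
  }
  if (!ml_axis %in% names(recording)) {
    abort(paste0("channel `", ml_axis, "` not found in recording."))
  }
  bw <- body_weight(recording)
  pmat <- as.matrix(recording[, sprintf("p%02d", 1:16)])
  force_pbw <- normalize_force(recording$total_force_n, bw)
  regions <- regional_pressures(pmat, layout, bw)
  gyro_ml <- recording[[ml_axis]]
  rows <- purrr::pmap(
    list(strides$stride, strides$initial_contact, strides$final_contact),
    function(id, ic, fc) {
      idx <- ic:(fc - 1L)
      tibble(
        stride = id,
        max_total_force_pbw = max(force_pbw[idx]),
        max_forefoot_p = max(regions$forefoot[idx]),
        max_hindfoot_p = max(regions$hindfoot[idx]),
        max_lateral_p = max(regions$lateral[idx]),
        max_medial_p = max(regions$medial[idx]),
        max_angular_velocity_ml = max(gyro_ml[idx])
      )
    }
  )
  if (length(rows) == 0) {
    return(tibble(stride = integer(), max_total_force_pbw = double(),
                  max_forefoot_p = double(), max_hindfoot_p = double(),
                  max_lateral_p = double(), max_medial_p = double(),
                  max_angular_velocity_ml = double()))
  }
  purrr::list_rbind(rows)
}

#' Keep the middle strides of a walk
#'
#' Discards gait initiation and termination by keeping the `k` strides
#' centred on the midpoint of the sequence. When centring is ambiguous the
#' window shifts toward the earlier stride. If fewer than `k + 2` strides
#' are available, all interior strides (everything but the first and last)
#' are kept and a warning is raised; fewer than 3 strides is an error since
#' no interior stride exists.
#'
#' @param strides tibble from [detect_strides()] (or any stride-indexed
#'   tibble ordered in time).
#' @param k number of strides to keep (default 5).
#' @return the selected rows of `strides`.
#' @export
select_middle_strides <- function(strides, k = 5) {
  n <- nrow(strides)
  if (n < 3) abort("need at least 3 strides to select interior strides.")
  if (n < k + 2) {
    warn(sprintf(
      "only %d strides detected; keeping all %d interior strides instead of %d.",
      n, n - 2L, k))
    return(strides[2:(n - 1L), , drop = FALSE])
  }
  start <- floor((n - k) / 2) + 1L
  strides[start:(start + k - 1L), , drop = FALSE]
}

#' Average stride features into a per-visit gait summary
#'
#' @param features tibble from [extract_stride_features()]; must be nonempty.
#' @return one-row tibble with the arithmetic mean of each feature column
#'   and `n_strides_used`.
#' @export
summarize_visit <- function(features) {
  if (nrow(features) == 0) abort("cannot summarize an empty feature set.")
  out <- features %>%
    dplyr::summarise(dplyr::across(-dplyr::any_of("stride"), mean))
  out$n_strides_used <- nrow(features)
  out
}

#' Full gait pipeline for one recording
#'
#' Filter, detect strides, keep the middle `k`, extract per-stride maxima
#' and average them: the per-visit gait summary used in all downstream
#' analyses.
#'
#' @inheritParams extract_stride_features
#' @inheritParams lowpass_filter
#' @param threshold contact threshold in Newtons.
#' @param min_contact minimum contact duration in seconds.
#' @param k number of middle strides to average.
#' @return one-row tibble: per-visit means of the stride maxima plus
#'   `n_strides_used`.
#' @export
extract_gait <- function(recording, layout = NULL, order = 4, cutoff = 6,
                         mode = "zero-phase", threshold = 30,
                         min_contact = 0.300, k = 5,
                         ml_axis = "gyro_y_dps") {
  filt <- filter_recording(recording, order = order, cutoff = cutoff,
                           mode = mode)
  strides <- detect_strides(filt$total_force_n, sampling_rate(recording),
                            threshold = threshold, min_contact = min_contact)
  mid <- select_middle_strides(strides, k = k)
  feats <- extract_stride_features(filt, mid, layout = layout,
                                   ml_axis = ml_axis)
  summarize_visit(feats)
}

#' Read / write the insole CSV schema
#'
#' One CSV per walk with columns
#' `time_s,p01..p16,total_force_n,gyro_x_dps,gyro_y_dps,gyro_z_dps` plus a
#' JSON sidecar (`<file>.json`) holding `body_weight_n`, `side`, `injured`
#' and `sampling_rate_hz`. The round trip is lossless.
#'
#' @param recording an [insole_recording()].
#' @param path path of the CSV file; the sidecar is written next to it.
#' @return `write_insole_csv` returns `path` invisibly; `read_insole_csv`
#'   returns an [insole_recording()].
#' @export
write_insole_csv <- function(recording, path) {
  readr::write_csv(as_tibble(recording), path)
  meta <- list(body_weight_n = body_weight(recording),
               side = attr(recording, "side"),
               injured = attr(recording, "injured"),
               sampling_rate_hz = sampling_rate(recording))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_insole_csv
#' @export
read_insole_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  insole_recording(
    pressure = dat[, sprintf("p%02d", 1:16)],
    total_force = dat$total_force_n,
    gyro = dat[, c("gyro_x_dps", "gyro_y_dps", "gyro_z_dps")],
    body_weight = as.numeric(meta$body_weight_n),
    sampling_rate = as.numeric(meta$sampling_rate_hz),
    side = meta$side,
    injured = meta$injured
  )
}
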