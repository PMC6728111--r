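# Preprocessing: read raw recordings, reduce 5-minute samples to hourly
# averages, screen the fever/hypothermia exclusion criteria, and fill small
# gaps so downstream recurrence analysis sees complete 24-point series.

#' Read temperature recordings from CSV
#'
#' Expects a long-format table with columns `patient_id`, `group`, `phase`,
#' `timestamp` (ISO-8601) and `temp_c`. Lines starting with `#` are treated
#' as metadata comments. Rows are sorted by time within each
#' (patient, phase); duplicate timestamps and temperatures outside the
#' plausible physiological band 30-43 degC are rejected.
#'
#' @param path CSV file path.
#' @return list of [cbt_series()], one per (patient, phase).
#' @export
read_recordings <- function(path) {
  if (!file.exists(path)) stop("recordings file not found: ", path)
  df <- read_meta_csv(path)
  recordings_to_series(df)
}

#' Reduce a 5-minute series to hourly averages
#'
#' Hour bins are anchored at the recording's first sample (bin h covers
#' `[h, h+1)` hours since start), preserving exactly 24 bins for a full-day
#' recording regardless of the clock start time. Each bin value is the
#' arithmetic mean of its samples; bins with fewer than `min_samples`
#' samples (default 6 of the 12 expected at 5-min sampling) are marked
#' missing rather than averaged.
#'
#' @param series a raw-resolution [cbt_series()].
#' @param min_samples minimum samples for a bin to count as observed.
#' @return an hourly [cbt_series()] on the 0..23 hour grid (`NA` = missing).
#' @export
hourly_average <- function(series, min_samples = 6) {
  stopifnot(inherits(series, "cbt_series"))
  if (series$resolution != "raw_5min") {
    stop("`hourly_average()` expects a raw 5-minute series")
  }
  bins <- floor(series$time_h)
  hours <- 0:max(23, max(bins))
  vals <- rep(NA_real_, length(hours))
  for (h in hours) {
    in_bin <- series$values[bins == h & !is.na(series$values)]
    if (length(in_bin) >= min_samples) vals[h + 1] <- mean(in_bin)
  }
  vals <- vals[1:24]
  cbt_series(vals, time_h = 0:23, start_hour = series$start_hour,
             patient_id = series$patient_id, group = series$group,
             phase = series$phase, resolution = "hourly")
}

#' Screen a series against the fever/hypothermia exclusion criteria
#'
#' The emulated protocol excludes recordings with fever (CBT >= 38.5 degC)
#' or hypothermia (CBT <= 36.5 degC); both comparisons are inclusive.
#' Inclusion additionally requires at most `max_missing_hours` missing
#' hourly bins.
#'
#' @param series an hourly [cbt_series()].
#' @param fever_threshold,hypothermia_threshold degC thresholds.
#' @param max_missing_hours maximum missing hours still considered complete.
#' @return one-row data.frame: `patient_id`, `phase`, `max_temp`,
#'   `min_temp`, `fever`, `hypothermia`, `n_missing_hours`, `included`.
#' @examples
#' s <- cbt_series(rep(c(37, 38.6), 12))
#' screen_exclusions(s)$fever
#' @export
screen_exclusions <- function(series, fever_threshold = 38.5,
                              hypothermia_threshold = 36.5,
                              max_missing_hours = 2) {
  stopifnot(inherits(series, "cbt_series"))
  if (series$resolution != "hourly") {
    stop("`screen_exclusions()` expects an hourly series")
  }
  v <- series$values
  max_temp <- suppressWarnings(max(v, na.rm = TRUE))
  min_temp <- suppressWarnings(min(v, na.rm = TRUE))
  n_missing <- 24L - sum(!is.na(v))
  fever <- is.finite(max_temp) && max_temp >= fever_threshold
  hypo <- is.finite(min_temp) && min_temp <= hypothermia_threshold
  data.frame(
    patient_id = series$patient_id, group = series$group,
    phase = series$phase,
    max_temp = max_temp, min_temp = min_temp,
    fever = fever, hypothermia = hypo,
    n_missing_hours = n_missing,
    included = !fever && !hypo && n_missing <= max_missing_hours,
    stringsAsFactors = FALSE
  )
}

#' Screen a list of series
#'
#' @param series_list list of hourly [cbt_series()].
#' @param ... passed to [screen_exclusions()].
#' @return data.frame with one row per series.
#' @export
screen_cohort <- function(series_list, ...) {
  do.call(rbind, lapply(series_list, screen_exclusions, ...))
}

#' Fill small gaps to obtain a complete 24-point series
#'
#' Interior runs of at most `max_gap_hours` missing hours are linearly
#' interpolated between their neighbours. Missing hours at the boundaries
#' (which have only one neighbour) are extended from the nearest observed
#' value, but only up to 2 in total. Longer interior gaps or more than 2
#' missing boundary hours raise a classed error
#' (`circarq_gap_error`) rather than silently imputing: such series are
#' unusable for recurrence analysis (the cosinor fit can still use the
#' observed points directly).
#'
#' @param series an hourly [cbt_series()] on the 0..23 grid.
#' @param max_gap_hours longest interior gap that may be interpolated.
#' @return a complete 24-point hourly [cbt_series()].
#' @export
fill_gaps <- function(series, max_gap_hours = 2) {
  stopifnot(inherits(series, "cbt_series"))
  if (series$resolution != "hourly") stop("`fill_gaps()` expects an hourly series")
  if (any(abs(series$time_h - round(series$time_h)) > 1e-8)) {
    stop("hourly series must lie on an integer hour grid")
  }
  v <- rep(NA_real_, 24)
  v[round(series$time_h) + 1] <- series$values
  obs <- which(!is.na(v))
  reject <- function(msg) {
    stop(structure(
      class = c("circarq_gap_error", "error", "condition"),
      list(message = sprintf("series %s/%s rejected for RQA: %s",
                             series$patient_id, series$phase, msg),
           call = sys.call(-1))))
  }
  if (length(obs) == 0) reject("no observed hours")
  n_lead <- obs[1] - 1L
  n_trail <- 24L - obs[length(obs)]
  if (n_lead + n_trail > 2) {
    reject(sprintf("%d missing boundary hours (max 2)", n_lead + n_trail))
  }
  if (length(obs) >= 2) {
    gaps <- diff(obs) - 1L
    if (any(gaps > max_gap_hours)) {
      reject(sprintf("interior gap of %d h exceeds max_gap_hours = %d",
                     max(gaps), max_gap_hours))
    }
    interp <- approx(x = obs, y = v[obs], xout = 1:24, method = "linear",
                     rule = 2)$y
  } else {
    interp <- rep(v[obs], 24)
  }
  cbt_series(interp, time_h = 0:23, start_hour = series$start_hour,
             patient_id = series$patient_id, group = series$group,
             phase = series$phase, resolution = "hourly")
}
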