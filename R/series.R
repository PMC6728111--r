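#' Construct a core body temperature series
#'
#' A `cbt_series` holds one patient-phase 24-hour temperature curve: sample
#' times in hours since the start of the recording, temperatures in degrees
#' Celsius, the local clock hour at which the recording started, and
#' provenance labels. Hourly series have at most 24 points; missing hours are
#' `NA` values on the hour grid.
#'
#' @param values numeric temperatures (degrees C); `NA` marks a missing hour
#'   in hourly series.
#' @param time_h sample times in hours since the first sample (strictly
#'   increasing). Defaults to `0, 1, ...` for hourly data.
#' @param start_hour local clock hour (0-24) of the first sample. Recordings
#'   in the emulated protocol start between 9 and 10 a.m., so the default
#'   is 9.
#' @param patient_id,group,phase provenance labels; `phase` must be one of
#'   `"entry"`, `"septic_shock"`, `"exit"` (or `NA`).
#' @param resolution `"hourly"` (one value per hour) or `"raw_5min"`.
#' @return An object of class `cbt_series`.
#' @examples
#' s <- cbt_series(37 + 0.4 * cos(2 * pi * ((9 + 0:23) - 19) / 24))
#' s
#' @export
cbt_series <- function(values, time_h = seq_along(values) - 1, start_hour = 9,
                       patient_id = NA_character_, group = NA_character_,
                       phase = NA_character_,
                       resolution = c("hourly", "raw_5min")) {
  resolution <- match.arg(resolution)
  values <- as.numeric(values)
  time_h <- as.numeric(time_h)
  if (length(values) == 0L) stop("empty series: no temperature values")
  if (length(values) != length(time_h)) {
    stop("`values` and `time_h` must have the same length")
  }
  if (any(!is.finite(time_h))) stop("`time_h` must be finite")
  if (length(time_h) > 1L && any(diff(time_h) <= 0)) {
    stop("`time_h` must be strictly increasing")
  }
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("temperature values must be finite or NA")
  }
  if (resolution == "hourly" && length(values) > 24L) {
    stop("hourly series cannot exceed 24 points")
  }
  if (!is.na(phase) && !phase %in% c("entry", "septic_shock", "exit")) {
    stop("`phase` must be one of 'entry', 'septic_shock', 'exit'")
  }
  if (!is.numeric(start_hour) || start_hour < 0 || start_hour >= 24) {
    stop("`start_hour` must be a clock hour in [0, 24)")
  }
  structure(
    list(values = values, time_h = time_h, start_hour = start_hour,
         patient_id = as.character(patient_id), group = as.character(group),
         phase = as.character(phase), resolution = resolution),
    class = "cbt_series"
  )
}

#' @export
print.cbt_series <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf("<cbt_series> %s / %s / %s: %d %s points%s\n",
              x$patient_id, x$group, x$phase, length(x$values),
              if (x$resolution == "hourly") "hourly" else "5-min",
              if (n_na) sprintf(" (%d missing)", n_na) else ""))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  start %02.0f:00 local, range %.2f-%.2f degC\n",
              x$start_hour, rng[1], rng[2]))
  invisible(x)
}

# Hours since local midnight for each sample (may exceed 24; the cosinor
# model is periodic so only the value mod 24 matters).
abs_time_h <- function(series) series$start_hour + series$time_h
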