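# Synthetic CBT cohort generator. Emulates the study design the analysis
# assumes: three patient groups (A = septic shock at ICU entry, B = in-ICU
# septic shock, C = non-septic controls), each patient recorded for 24 h per
# phase, afebrile range (36.5, 38.5) degC, cosine circadian component with
# group/phase-specific amplitude, AR(1) within-patient noise, and clinical
# severity scores negatively coupled to circadian amplitude.

phases_for_group <- function(group) {
  switch(group,
         A = c("entry", "exit"),
         B = c("entry", "septic_shock", "exit"),
         C = c("entry", "exit"),
         stop(sprintf("unknown group '%s' (expected A, B or C)", group)))
}

#' Default group/phase circadian parameter table
#'
#' Entry amplitudes are the group means reported for afebrile ICU cohorts
#' (0.28, 0.32 and 0.45 degC with SDs 0.18, 0.13, 0.19 for initial septic
#' shock, in-ICU septic shock and non-septic controls respectively); the
#' acrophase sits in the evening (19:00 +/- 1.5 h, i.e. the 18:00-20:00
#' band). The mesor is 37.4 +/- 0.12 degC, centred in the afebrile band:
#' an afebrile curve with an amplitude in the upper tail of the configured
#' distributions (up to ~0.8 degC) needs its trough comfortably above the
#' 36.5 degC hypothermia bound and its crest below 38.5 degC, otherwise the
#' rejection sampler would systematically discard the large-amplitude
#' patients the group means call for and bias the cohort mean amplitude
#' well below its configured value. Exit recordings are given a larger amplitude
#' (0.50 +/- 0.15 degC) to encode the recovery of periodicity at ICU
#' discharge; the septic-shock phase of group B mirrors the entry level of
#' group A.
#'
#' @return data.frame with one row per (group, phase) and columns
#'   `mesor_mean`, `mesor_sd`, `amplitude_mean`, `amplitude_sd`,
#'   `acrophase_mean`, `acrophase_sd` (clock hours of the peak).
#' @export
default_curve_params <- function() {
  data.frame(
    group = c("A", "A", "B", "B", "B", "C", "C"),
    phase = c("entry", "exit", "entry", "septic_shock", "exit",
              "entry", "exit"),
    mesor_mean = 37.4, mesor_sd = 0.12,
    amplitude_mean = c(0.28, 0.50, 0.32, 0.28, 0.50, 0.45, 0.50),
    amplitude_sd = c(0.18, 0.15, 0.13, 0.15, 0.15, 0.19, 0.15),
    acrophase_mean = 19, acrophase_sd = 1.5,
    stringsAsFactors = FALSE
  )
}

#' Default clinical score model
#'
#' Each score is a linear function of the patient's true entry circadian
#' amplitude plus Gaussian residual: `score = intercept + slope * A + e`.
#' Slopes and residual SDs are calibrated so that, at the default amplitude
#' spread (SD ~ 0.17 degC), the population amplitude-score correlation is
#' about -0.7 for the severity scores (APACHE II, SAPS II, entry SOFA) and
#' about -0.6 for lengths of stay, with marginal means and SDs matching
#' typical ICU cohorts (APACHE II ~ 19 +/- 5.5, SAPS II ~ 44 +/- 15,
#' SOFA ~ 7.5 +/- 3.5, ICU LOS ~ 10 +/- 9 d, hospital LOS ~ 24 +/- 20 d).
#' Survival flags are Bernoulli with log-odds increasing in amplitude.
#'
#' @return list with elements `scores` (data.frame: score, intercept, slope,
#'   residual_sd, floor), `survival` (per-flag baseline probability and
#'   log-odds slope), and `ref_amplitude` (amplitude at which the marginal
#'   means are anchored).
#' @export
default_score_model <- function() {
  list(
    scores = data.frame(
      score = c("apache_ii", "saps_ii", "entry_sofa", "icu_los",
                "hospital_los"),
      intercept = c(27.0, 64.4, 12.4, 20.5, 47.3),
      slope = c(-22.6, -61.8, -14.4, -31.8, -70.6),
      residual_sd = c(3.9, 10.7, 2.5, 7.2, 16.0),
      floor = c(0, 0, 0, 1, 1),
      stringsAsFactors = FALSE
    ),
    survival = list(
      icu_survival = list(base_prob = 0.85, slope = 3),
      hospital_survival = list(base_prob = 0.80, slope = 3)
    ),
    ref_amplitude = 0.33
  )
}

#' Parameters for synthetic cohort generation
#'
#' @param n_patients named integer vector: patients per group (defaults to
#'   the 10/6/5 design of the emulated study).
#' @param sampling_interval minutes between samples: 5 or 60.
#' @param curve per group x phase circadian parameters; see
#'   [default_curve_params()].
#' @param ar1_rho lag-1 autocorrelation of the within-patient noise
#'   (|rho| < 1).
#' @param noise_sd marginal SD (degC) of the within-patient noise.
#' @param afebrile if `TRUE`, patient curves are constrained to the open
#'   afebrile interval `afebrile_range` by rejection sampling (fresh
#'   parameter and noise draws, never clipping).
#' @param afebrile_range exclusive (hypothermia, fever) bounds in degC.
#' @param max_retries rejection-sampling cap per patient-phase.
#' @param start_hour local clock hour at which recordings start.
#' @param score_model clinical score model; see [default_score_model()].
#' @param seed master integer seed; per-patient seeds are derived from it
#'   and a stable hash of the patient id and phase, so cohorts are
#'   reproducible under reordering.
#' @return list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_patients = c(A = 10, B = 6, C = 5),
                              sampling_interval = 60,
                              curve = default_curve_params(),
                              ar1_rho = 0.5, noise_sd = 0.1,
                              afebrile = TRUE,
                              afebrile_range = c(36.5, 38.5),
                              max_retries = 100,
                              start_hour = 9,
                              score_model = default_score_model(),
                              seed = 1L) {
  if (is.null(names(n_patients))) names(n_patients) <- c("A", "B", "C")
  if (!all(names(n_patients) %in% c("A", "B", "C"))) {
    stop("`n_patients` must be named with groups A, B, C")
  }
  if (any(n_patients < 1)) stop("n_patients must be >= 1 per group")
  if (!sampling_interval %in% c(5, 60)) {
    stop("`sampling_interval` must be 5 or 60 minutes")
  }
  if (abs(ar1_rho) >= 1) stop("|ar1_rho| must be < 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  req <- c("group", "phase", "mesor_mean", "mesor_sd", "amplitude_mean",
           "amplitude_sd", "acrophase_mean", "acrophase_sd")
  if (!all(req %in% names(curve))) {
    stop("`curve` is missing columns: ",
         paste(setdiff(req, names(curve)), collapse = ", "))
  }
  if (any(curve$amplitude_mean < 0)) stop("amplitude_mean must be >= 0")
  structure(
    list(n_patients = n_patients, sampling_interval = sampling_interval,
         curve = curve, ar1_rho = ar1_rho, noise_sd = noise_sd,
         afebrile = afebrile, afebrile_range = afebrile_range,
         max_retries = max_retries, start_hour = start_hour,
         score_model = score_model, seed = as.integer(seed)),
    class = "cohort_gen_params"
  )
}

curve_row <- function(params, group, phase) {
  if (!phase %in% phases_for_group(group)) {
    stop(sprintf("invalid group/phase combination: group %s has no '%s' phase",
                 group, phase))
  }
  row <- params$curve[params$curve$group == group & params$curve$phase == phase, ]
  if (nrow(row) != 1L) {
    stop(sprintf("curve parameter table has %d rows for group %s, phase %s",
                 nrow(row), group, phase))
  }
  row
}

# Truncated-normal amplitude draw (A >= 0): redraw, falling back to the
# folded value if the mean is far below zero. Amplitude is nonnegative by
# definition.
draw_amplitude <- function(mean, sd) {
  if (sd == 0) return(mean)
  for (i in 1:100) {
    a <- rnorm(1, mean, sd)
    if (a >= 0) return(a)
  }
  abs(rnorm(1, mean, sd))
}

#' Generate one synthetic patient-phase temperature series
#'
#' Draws per-patient circadian parameters (mesor, amplitude, peak clock
#' time) from the group/phase distributions in `params$curve`, evaluates
#' `M + A * cos(2*pi*(t - peak)/24)` on the configured sampling grid, and
#' adds stationary AR(1) noise. Under the afebrile constraint the whole
#' draw (parameters and noise) is rejected and redrawn until every sample
#' lies strictly inside `afebrile_range`, up to `params$max_retries`
#' attempts.
#'
#' @param params a [cohort_gen_params()] object.
#' @param group `"A"`, `"B"` or `"C"`.
#' @param phase `"entry"`, `"septic_shock"` (group B only) or `"exit"`.
#' @param patient_id stable identifier; with `params$seed` it determines the
#'   RNG stream, so the same id always yields the same curve.
#' @return list with `series` (a [cbt_series()]) and `truth`
#'   (list: `mesor`, `amplitude`, `acrophase_h` = true peak clock time).
#' @examples
#' p <- cohort_gen_params(seed = 42)
#' generate_patient_series(p, "C", "entry", "C01")$truth
#' @export
generate_patient_series <- function(params, group, phase, patient_id) {
  stopifnot(inherits(params, "cohort_gen_params"))
  row <- curve_row(params, group, phase)
  step_h <- params$sampling_interval / 60
  t_rel <- seq(0, 24 - step_h, by = step_h)
  t_abs <- params$start_hour + t_rel
  lo <- params$afebrile_range[1]
  hi <- params$afebrile_range[2]

  with_local_seed(derive_seed(params$seed, patient_id, phase), {
    for (try in seq_len(params$max_retries)) {
      M <- rnorm(1, row$mesor_mean, row$mesor_sd)
      A <- draw_amplitude(row$amplitude_mean, row$amplitude_sd)
      acro <- rnorm(1, row$acrophase_mean, row$acrophase_sd) %% 24
      signal <- M + A * cos(2 * pi * (t_abs - acro) / 24)
      vals <- signal + ar1_noise(length(t_abs), params$ar1_rho, params$noise_sd)
      if (!params$afebrile || all(vals > lo & vals < hi)) {
        series <- cbt_series(
          vals, time_h = t_rel, start_hour = params$start_hour,
          patient_id = patient_id, group = group, phase = phase,
          resolution = if (params$sampling_interval == 5) "raw_5min" else "hourly"
        )
        return(list(series = series,
                    truth = list(mesor = M, amplitude = A, acrophase_h = acro)))
      }
    }
    stop(sprintf(
      paste0("afebrile constraint unsatisfiable for patient %s (%s/%s) after ",
             "%d attempts: amplitude too large for the mesor relative to ",
             "(%.1f, %.1f) degC"),
      patient_id, group, phase, params$max_retries, lo, hi))
  })
}

#' Generate clinical covariates from true circadian amplitudes
#'
#' Severity scores and lengths of stay are linear in the patient's true
#' entry amplitude plus Gaussian residual (see [default_score_model()]);
#' survival flags are Bernoulli with log-odds increasing in amplitude. With
#' negative slopes this yields the negative amplitude-severity correlations
#' the analysis pipeline is meant to detect.
#'
#' @param amplitudes data.frame with columns `patient_id`, `group`,
#'   `amplitude` (true entry amplitude, degC), one row per patient.
#' @param score_model see [default_score_model()].
#' @param seed integer seed for the residual and survival draws.
#' @return data.frame: `patient_id`, `group`, one column per score,
#'   `icu_survival`, `hospital_survival` (0/1).
#' @export
generate_clinical_scores <- function(amplitudes,
                                     score_model = default_score_model(),
                                     seed = 1L) {
  stopifnot(is.data.frame(amplitudes),
            all(c("patient_id", "group", "amplitude") %in% names(amplitudes)))
  if (anyDuplicated(amplitudes$patient_id)) {
    stop("one amplitude per patient required: duplicated patient_id")
  }
  sm <- score_model$scores
  if (any(sm$residual_sd < 0)) stop("residual_sd must be >= 0")
  n <- nrow(amplitudes)
  out <- data.frame(patient_id = amplitudes$patient_id,
                    group = amplitudes$group, stringsAsFactors = FALSE)
  with_local_seed(derive_seed(seed, "clinical-scores"), {
    for (i in seq_len(nrow(sm))) {
      v <- sm$intercept[i] + sm$slope[i] * amplitudes$amplitude +
        rnorm(n, 0, sm$residual_sd[i])
      out[[sm$score[i]]] <- pmax(v, sm$floor[i])
    }
    dev <- amplitudes$amplitude - score_model$ref_amplitude
    for (flag in names(score_model$survival)) {
      s <- score_model$survival[[flag]]
      p <- plogis(qlogis(s$base_prob) + s$slope * dev)
      out[[flag]] <- rbinom(n, 1, p)
    }
  })
  out
}

#' Generate a complete synthetic cohort
#'
#' Produces, for every patient in every group, a full 24-h recording per
#' study phase (entry and exit for groups A and C; entry, septic shock and
#' exit for group B), clinical covariates coupled to the true entry
#' amplitudes, and the table of true generating parameters.
#'
#' @param params a [cohort_gen_params()] object.
#' @return list of class `cbt_cohort` with data.frames `recordings`
#'   (`patient_id`, `group`, `phase`, `timestamp` ISO-8601, `temp_c`),
#'   `clinical`, and `true_params` (`patient_id`, `group`, `phase`, true
#'   `mesor`, `amplitude`, `acrophase_h`), plus the `params` used.
#' @examples
#' co <- generate_cohort(cohort_gen_params(n_patients = c(A = 2, B = 2, C = 2)))
#' table(co$recordings$group, co$recordings$phase)
#' @export
generate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  phase_day <- c(entry = 1, septic_shock = 4, exit = 8)
  base <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  rec <- list(); truth <- list(); amps <- list()
  k <- 0
  for (group in names(params$n_patients)) {
    for (i in seq_len(params$n_patients[[group]])) {
      patient_id <- sprintf("%s%02d", group, i)
      for (phase in phases_for_group(group)) {
        gen <- generate_patient_series(params, group, phase, patient_id)
        s <- gen$series
        t0 <- base + ((phase_day[[phase]] - 1) * 24 + params$start_hour) * 3600
        k <- k + 1
        rec[[k]] <- data.frame(
          patient_id = patient_id, group = group, phase = phase,
          timestamp = format(t0 + s$time_h * 3600, "%Y-%m-%dT%H:%M:%S"),
          temp_c = s$values, stringsAsFactors = FALSE
        )
        truth[[k]] <- data.frame(
          patient_id = patient_id, group = group, phase = phase,
          mesor = gen$truth$mesor, amplitude = gen$truth$amplitude,
          acrophase_h = gen$truth$acrophase_h, stringsAsFactors = FALSE
        )
        if (phase == "entry") {
          amps[[length(amps) + 1]] <- data.frame(
            patient_id = patient_id, group = group,
            amplitude = gen$truth$amplitude, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  clinical <- generate_clinical_scores(do.call(rbind, amps),
                                       params$score_model, params$seed)
  structure(
    list(recordings = do.call(rbind, rec), clinical = clinical,
         true_params = do.call(rbind, truth), params = params),
    class = "cbt_cohort"
  )
}

#' @export
print.cbt_cohort <- function(x, ...) {
  cat(sprintf("<cbt_cohort> %d patients (%s), %d recordings, seed %d\n",
              nrow(x$clinical),
              paste(sprintf("%s=%d", names(x$params$n_patients),
                            x$params$n_patients), collapse = ", "),
              nrow(unique(x$recordings[c("patient_id", "phase")])),
              x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `recordings.csv`, `clinical.csv` and `true_params.csv` (each with
#' a `#` metadata header carrying package version and seed) plus the
#' generation configuration echoed as `sim_config.yaml`.
#'
#' @param cohort a `cbt_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cbt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- circarq_meta(seed = cohort$params$seed,
                       extra = paste0("config=", config_fingerprint(cohort$params)))
  write_meta_csv(cohort$recordings, file.path(dir, "recordings.csv"), meta)
  write_meta_csv(cohort$clinical, file.path(dir, "clinical.csv"), meta)
  write_meta_csv(cohort$true_params, file.path(dir, "true_params.csv"), meta)
  cfg <- cohort$params
  cfg$curve <- as.list(cfg$curve)
  cfg$score_model$scores <- as.list(cfg$score_model$scores)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Split a cohort (or long recordings table) into per-patient-phase series
#'
#' @param x a `cbt_cohort` or a recordings data.frame with columns
#'   `patient_id`, `group`, `phase`, `timestamp`, `temp_c`.
#' @return list of [cbt_series()] objects, one per (patient, phase).
#' @export
cohort_to_series <- function(x) {
  df <- if (inherits(x, "cbt_cohort")) x$recordings else x
  recordings_to_series(df)
}

recordings_to_series <- function(df) {
  req <- c("patient_id", "group", "phase", "timestamp", "temp_c")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("recordings table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(ts) & !is.na(df$timestamp)
  if (any(bad)) {
    stop("unparseable timestamp(s), e.g. '", df$timestamp[which(bad)[1]],
         "' (expected ISO-8601, YYYY-MM-DDTHH:MM:SS)")
  }
  if (any(df$temp_c < 30 | df$temp_c > 43, na.rm = TRUE)) {
    stop("temperature outside the plausible physiological range 30-43 degC")
  }
  key <- paste(df$patient_id, df$phase, sep = "\r")
  dup <- duplicated(paste(key, df$timestamp, sep = "\r"))
  if (any(dup)) {
    d <- df[which(dup)[1], ]
    stop(sprintf("duplicate timestamp for patient %s, phase %s: %s",
                 d$patient_id, d$phase, d$timestamp))
  }
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, ]
    ts_i <- ts[idx]
    o <- order(ts_i)
    sub <- sub[o, ]; ts_i <- ts_i[o]
    time_h <- as.numeric(difftime(ts_i, ts_i[1], units = "hours"))
    step <- if (length(time_h) > 1) median(diff(time_h)) else 1
    start_hour <- as.numeric(format(ts_i[1], "%H")) +
      as.numeric(format(ts_i[1], "%M")) / 60
    cbt_series(sub$temp_c, time_h = time_h, start_hour = start_hour,
               patient_id = sub$patient_id[1], group = sub$group[1],
               phase = sub$phase[1],
               resolution = if (step < 0.5) "raw_5min" else "hourly")
  })
  names(out) <- vapply(out, function(s) paste(s$patient_id, s$phase, sep = "."),
                       character(1))
  out[order(names(out))]
}
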