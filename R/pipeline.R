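# End-to-end orchestration: simulate (or read) -> hourly averaging ->
# exclusion screening -> gap filling -> cosinor -> RQA -> cohort statistics,
# with reproducibility metadata on every output and a Markdown report.

#' Pipeline configuration
#'
#' Either `simulate` (a [cohort_gen_params()]) or `recordings` +
#' `clinical` (CSV paths) must be provided; paths are validated up front so
#' a misconfigured run fails before any output is written.
#'
#' @param simulate [cohort_gen_params()] for a synthetic cohort, or `NULL`
#'   when reading recorded data.
#' @param recordings,clinical input CSV paths (ignored when simulating).
#' @param cosinor_alpha rhythm-detection significance level.
#' @param rqa an [rqa_config()].
#' @param max_gap_hours gap-filling limit for RQA input.
#' @param base_alpha,n_comparisons,feature_cols,covariate_cols statistics
#'   configuration; see [build_comparison_suite()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed master seed; overrides `simulate$seed` when given.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = cohort_gen_params(),
                            recordings = NULL, clinical = NULL,
                            cosinor_alpha = 0.05, rqa = rqa_config(),
                            max_gap_hours = 2,
                            base_alpha = 0.05, n_comparisons = NULL,
                            feature_cols = default_feature_cols(),
                            covariate_cols = default_covariate_cols(),
                            out_dir = NULL, seed = NULL) {
  if (is.null(recordings)) {
    if (!inherits(simulate, "cohort_gen_params")) {
      stop("either `simulate` (cohort_gen_params) or `recordings` must be given")
    }
    if (!is.null(seed)) simulate$seed <- as.integer(seed)
  } else {
    if (!file.exists(recordings)) {
      stop("recordings file not found: ", recordings)
    }
    if (!is.null(clinical) && !file.exists(clinical)) {
      stop("clinical file not found: ", clinical)
    }
    simulate <- NULL
  }
  structure(
    list(simulate = simulate, recordings = recordings, clinical = clinical,
         cosinor_alpha = cosinor_alpha, rqa = rqa,
         max_gap_hours = max_gap_hours, base_alpha = base_alpha,
         n_comparisons = n_comparisons, feature_cols = feature_cols,
         covariate_cols = covariate_cols, out_dir = out_dir,
         seed = seed %||% (if (!is.null(simulate)) simulate$seed else NULL)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages: obtain recordings (simulate or read), reduce any 5-minute series
#' to hourly averages, screen fever/hypothermia exclusions, fit the
#' cosinor model per series, run RQA on gap-filled complete series, and
#' compute the cohort comparison suite. Screened-out series are dropped
#' from the feature tables but reported in the screening table and the
#' report; every written CSV carries a `#` metadata header with package
#' version, seed and config fingerprint (no timestamps, so reruns are
#' byte-identical).
#'
#' @param config a [pipeline_config()].
#' @return list of class `circarq_run`: `cohort` (when simulated),
#'   `screening`, `cosinor`, `rqa`, `features`, `comparison`, `config`,
#'   and `out_dir` when outputs were written.
#' @examples
#' cfg <- pipeline_config(simulate = cohort_gen_params(
#'   n_patients = c(A = 3, B = 3, C = 3), seed = 7))
#' run <- run_pipeline(cfg)
#' run$comparison$alpha$threshold_3dp
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- NULL
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    series <- cohort_to_series(cohort)
    clinical <- cohort$clinical
  } else {
    series <- read_recordings(config$recordings)
    clinical <- if (!is.null(config$clinical)) read_meta_csv(config$clinical)
                else NULL
  }

  hourly <- lapply(series, function(s) {
    if (s$resolution == "raw_5min") hourly_average(s) else s
  })

  screening <- screen_cohort(hourly)
  rownames(screening) <- NULL
  keep_key <- paste(screening$patient_id, screening$phase)[screening$included]
  kept <- hourly[paste(screening$patient_id, screening$phase) %in% keep_key]

  if (length(kept) == 0) stop("no series passed exclusion screening")

  cosinor <- cosinor_table(kept, alpha = config$cosinor_alpha)
  rqa <- rqa_table(kept, config = config$rqa,
                   max_gap_hours = config$max_gap_hours)
  features <- merge(cosinor, rqa[, setdiff(names(rqa), "group")],
                    by = c("patient_id", "phase"), sort = TRUE)

  comparison <- if (!is.null(clinical)) {
    build_comparison_suite(features, clinical,
                           feature_cols = config$feature_cols,
                           covariate_cols = config$covariate_cols,
                           base_alpha = config$base_alpha,
                           n_comparisons = config$n_comparisons)
  } else NULL

  run <- structure(
    list(cohort = cohort, screening = screening, cosinor = cosinor,
         rqa = rqa, features = features, comparison = comparison,
         config = config, out_dir = config$out_dir),
    class = "circarq_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(run)
  run
}

write_run_outputs <- function(run) {
  dir <- run$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # fingerprint the analysis configuration only: where the outputs land
  # must not change what they contain
  cfg_core <- run$config[setdiff(names(run$config), "out_dir")]
  meta <- circarq_meta(seed = run$config$seed,
                       extra = paste0("config=", config_fingerprint(cfg_core)))
  if (!is.null(run$cohort)) write_cohort(run$cohort, dir)
  write_meta_csv(run$screening, file.path(dir, "screening.csv"), meta)
  write_meta_csv(run$cosinor, file.path(dir, "cosinor.csv"), meta)
  write_meta_csv(run$rqa, file.path(dir, "rqa.csv"), meta)
  if (!is.null(run$comparison)) {
    write_meta_csv(run$comparison$comparisons,
                   file.path(dir, "comparisons.csv"), meta)
    write_meta_csv(run$comparison$correlations,
                   file.path(dir, "correlations.csv"), meta)
  }
  writeLines(render_report(run), file.path(dir, "report.md"))
  invisible(dir)
}

group_summary <- function(features, cols) {
  out <- list()
  for (g in sort(unique(features$group))) {
    for (ph in intersect(c("entry", "septic_shock", "exit"),
                         unique(features$phase[features$group == g]))) {
      sub <- features[features$group == g & features$phase == ph, ]
      for (col in cols) {
        v <- sub[[col]][!is.na(sub[[col]])]
        out[[length(out) + 1]] <- data.frame(
          group = g, phase = ph, feature = col, n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1) sd(v) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

render_report <- function(run) {
  cfg <- run$config
  feat_cols <- intersect(c(cfg$feature_cols, "Lmean"), names(run$features))
  summ <- group_summary(run$features, feat_cols)
  fmt_tab <- function(df) {
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(row)
        paste0("| ", paste(trimws(row), collapse = " | "), " |")))
  }
  summ$mean <- sprintf("%.3f", summ$mean)
  summ$sd <- sprintf("%.3f", summ$sd)
  lines <- c(
    "# circarq pipeline report",
    "",
    sprintf("- package version: %s", utils::packageVersion("circarq")),
    sprintf("- seed: %s", cfg$seed %||% "(none)"),
    sprintf("- config fingerprint: %s",
            config_fingerprint(cfg[setdiff(names(cfg), "out_dir")])),
    sprintf("- patients screened: %d series, %d included, %d excluded",
            nrow(run$screening), sum(run$screening$included),
            sum(!run$screening$included)),
    sprintf("- cosinor fits failing the rhythm gate: %d",
            sum(!run$cosinor$rhythm_detected)),
    "",
    "## Group feature summaries (mean +/- SD per phase)",
    "",
    fmt_tab(summ),
    ""
  )
  if (!is.null(run$comparison)) {
    comp <- run$comparison
    lines <- c(lines,
      sprintf("## Statistics (Bonferroni-adjusted alpha = %.5f = %.2g/%d)",
              comp$alpha$threshold, comp$alpha$alpha,
              comp$alpha$n_comparisons),
      "")
    if (!is.null(comp$comparisons)) {
      cc <- comp$comparisons
      cc$statistic <- sprintf("%.3f", cc$statistic)
      cc$p_value <- sprintf("%.4f", cc$p_value)
      lines <- c(lines, "### Group comparisons", "", fmt_tab(cc), "")
    }
    cr <- comp$correlations
    cr$r <- sprintf("%.3f", cr$r)
    cr$p_value <- sprintf("%.4f", cr$p_value)
    lines <- c(lines, "### Feature-covariate correlations", "", fmt_tab(cr))
  }
  lines
}

#' @export
print.circarq_run <- function(x, ...) {
  cat("<circarq_run>\n")
  cat(sprintf("  %d series screened (%d included), %d feature rows\n",
              nrow(x$screening), sum(x$screening$included),
              nrow(x$features)))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Export a recurrence plot to a PNG file
#'
#' @param rm a [recurrence_matrix()].
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
export_recurrence_plot <- function(rm, path, width = 480, height = 480) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(rm)
  invisible(path)
}
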