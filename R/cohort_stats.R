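# Cohort-level statistics: exact Wilcoxon signed-rank within groups (paired
# phases), Kruskal-Wallis between groups, Pearson correlations of entry
# features with clinical covariates, Bonferroni-adjusted significance.

#' Wilcoxon signed-rank test with exact small-sample p value
#'
#' Two-sided test of paired differences. Zero differences are dropped and
#' tied absolute differences mid-ranked. For `n <= exact_max_n` pairs the p
#' value is exact: the null distribution of the positive-rank sum `W` is
#' obtained over all `2^n` equally likely sign assignments (computed by
#' convolution, so mid-ranks and ties are handled exactly);
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. Beyond that, the normal
#' approximation with tie correction and continuity correction is used —
#' the cohorts this package targets (5-30 patients per group) always take
#' the exact path.
#'
#' @param x,y paired numeric vectors, or differences in `x` if `y` is NULL.
#' @param exact_max_n largest n for the exact enumeration.
#' @return list: `statistic` (W, sum of positive ranks), `p_value`, `n`
#'   (pairs after dropping zero differences), `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 5, 7, 8, 9), c(1, 2, 3, 4, 5, 6))$p_value
#' # 0.03125 = 2/2^6: all differences positive and distinct
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no non-missing paired differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # convolution over sign assignments on doubled ranks (integers even
    # with mid-ranked ties; total 2*sum(r) = n(n+1) <= 650 for n <= 25)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = as.integer(n), method = method)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (mid-rank ties, tie
#' correction, chi-square reference with k-1 df) that handles the
#' degenerate all-identical case explicitly: H is reported as 0 with p = 1
#' and a warning instead of `NaN`.
#'
#' @param values list of numeric vectors (one per group), or a single
#'   numeric vector with `groups` giving group labels.
#' @param groups group labels when `values` is a vector.
#' @return list: `statistic` (H), `p_value`, `df`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 4.571
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    lens <- lengths(values)
    if (any(lens == 0)) stop("every group must be nonempty")
    groups <- factor(rep(seq_along(values), lens))
    values <- unlist(values, use.names = FALSE)
  } else {
    values <- as.numeric(values)
    groups <- factor(groups)
    if (any(table(groups) == 0)) stop("every group must be nonempty")
  }
  if (length(values) < 3) stop("Kruskal-Wallis requires total n >= 3")
  k <- nlevels(groups)
  if (length(unique(values)) == 1L) {
    warning("all observations identical; H = 0, p = 1")
    return(list(statistic = 0, p_value = 1, df = k - 1L,
                n = length(values)))
  }
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Pearson correlation with two-sided t-test
#'
#' Wrapper over [stats::cor.test()]; constant inputs are reported as
#' missing with a reason instead of erroring.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @return list: `r`, `p_value`, `n`, and `reason` when undefined.
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(list(r = NA_real_, p_value = NA_real_, n = n,
                reason = "fewer than 3 complete pairs"))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n,
                reason = "constant input"))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha base significance level.
#' @param n_comparisons number of analyses performed.
#' @return list: `threshold` (`alpha / n_comparisons`, full precision),
#'   `threshold_3dp` (rounded to 3 decimals, the reporting convention),
#'   `alpha`, `n_comparisons`.
#' @examples
#' bonferroni_alpha(0.05, 15)$threshold_3dp  # 0.003
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  thr <- alpha / n_comparisons
  list(threshold = thr, threshold_3dp = round(thr, 3), alpha = alpha,
       n_comparisons = as.integer(n_comparisons))
}

default_feature_cols <- function() {
  c("mesor", "amplitude", "peak_time",          # circadian
    "REC", "DET", "LAM", "Lmax", "DIV")         # RQA
}

default_covariate_cols <- function() {
  c("apache_ii", "saps_ii", "entry_sofa", "icu_los", "hospital_los",
    "icu_survival", "hospital_survival")
}

#' Build the full cohort comparison suite
#'
#' Runs, on a joined feature table (cosinor + RQA, one row per patient and
#' phase) and clinical covariate table:
#' * within-group paired Wilcoxon signed-rank tests for every feature and
#'   phase pair available to the group (entry/exit; additionally
#'   entry/septic-shock and septic-shock/exit where a septic-shock phase
#'   exists),
#' * between-group Kruskal-Wallis tests per phase shared by all groups,
#' * the entry-phase feature x covariate Pearson correlation matrix,
#' with significance flagged at the Bonferroni-adjusted threshold. By
#' default 8 features (3 circadian + 5 RQA) and 7 clinical parameters give
#' the divisor 8 + 7 = 15, i.e. an adjusted threshold of 0.05/15 = 0.003;
#' the divisor is recomputed from the configured lists and can be
#' overridden.
#'
#' Cosinor-derived features of fits that failed the rhythm-detection gate
#' are excluded from all statistics (the exclusion count is reported);
#' comparisons with fewer than 2 usable patients are skipped with a reason.
#'
#' @param features data.frame with columns `patient_id`, `group`, `phase`,
#'   `rhythm_detected`, and the feature columns.
#' @param clinical data.frame with `patient_id` and the covariate columns.
#' @param feature_cols,covariate_cols feature/covariate sets; circadian
#'   columns among `feature_cols` are gated on `rhythm_detected`.
#' @param base_alpha base significance level.
#' @param n_comparisons Bonferroni divisor; default
#'   `length(feature_cols) + length(covariate_cols)`.
#' @param correlation_phase phase whose features enter the correlation
#'   matrix (default `"entry"`).
#' @return list of class `cohort_comparison`: `comparisons` (data.frame),
#'   `correlations` (data.frame with r, p, significant per feature x
#'   covariate), `alpha` (from [bonferroni_alpha()]), `n_gated_out`
#'   (cosinor rows failing the rhythm gate), `skipped` (data.frame of
#'   skipped comparisons with reasons).
#' @export
build_comparison_suite <- function(features, clinical,
                                   feature_cols = default_feature_cols(),
                                   covariate_cols = default_covariate_cols(),
                                   base_alpha = 0.05,
                                   n_comparisons = NULL,
                                   correlation_phase = "entry") {
  stopifnot(all(c("patient_id", "group", "phase") %in% names(features)))
  miss_f <- setdiff(feature_cols, names(features))
  if (length(miss_f)) stop("features table lacks column(s): ",
                           paste(miss_f, collapse = ", "))
  miss_c <- setdiff(covariate_cols, names(clinical))
  if (length(miss_c)) stop("clinical table lacks column(s): ",
                           paste(miss_c, collapse = ", "))
  if (!"patient_id" %in% names(clinical)) stop("clinical table lacks patient_id")

  circadian_cols <- intersect(
    c("mesor", "amplitude", "peak_time", "acrophase_rad", "percent_rhythm",
      "model_data_correlation"), feature_cols)
  n_gated <- 0L
  if ("rhythm_detected" %in% names(features) && length(circadian_cols)) {
    gate <- !features$rhythm_detected %in% TRUE
    n_gated <- sum(gate)
    features[gate, circadian_cols] <- NA_real_
  }

  n_comparisons <- n_comparisons %||%
    (length(feature_cols) + length(covariate_cols))
  alpha <- bonferroni_alpha(base_alpha, n_comparisons)

  comparisons <- list(); skipped <- list()
  add_skip <- function(kind, feature, label, reason) {
    skipped[[length(skipped) + 1]] <<- data.frame(
      kind = kind, feature = feature, label = label, reason = reason,
      stringsAsFactors = FALSE)
  }

  # -- within-group paired tests -------------------------------------------
  for (group in sort(unique(features$group))) {
    sub <- features[features$group == group, ]
    phases <- intersect(c("entry", "septic_shock", "exit"), unique(sub$phase))
    if (length(phases) < 2) next
    pairs <- utils::combn(phases, 2, simplify = FALSE)
    for (pp in pairs) {
      a <- sub[sub$phase == pp[1], ]; b <- sub[sub$phase == pp[2], ]
      common <- intersect(a$patient_id, b$patient_id)
      label <- sprintf("group %s: %s vs %s", group, pp[1], pp[2])
      for (feat in feature_cols) {
        va <- a[[feat]][match(common, a$patient_id)]
        vb <- b[[feat]][match(common, b$patient_id)]
        ok <- !is.na(va) & !is.na(vb)
        if (sum(ok) < 2) {
          add_skip("within_paired", feat, label,
                   "fewer than 2 usable patients")
          next
        }
        res <- suppressWarnings(wilcoxon_signed_rank(va[ok], vb[ok]))
        comparisons[[length(comparisons) + 1]] <- data.frame(
          kind = "within_paired", feature = feat, label = label,
          statistic = res$statistic, p_value = res$p_value, n = sum(ok),
          significant = res$p_value < alpha$threshold,
          stringsAsFactors = FALSE)
      }
    }
  }

  # -- between-group tests per shared phase --------------------------------
  groups <- sort(unique(features$group))
  if (length(groups) >= 2) {
    shared <- Reduce(intersect,
                     lapply(groups,
                            function(g) unique(features$phase[features$group == g])))
    for (ph in shared) {
      sub <- features[features$phase == ph, ]
      label <- sprintf("between groups: %s", ph)
      for (feat in feature_cols) {
        byg <- split(sub[[feat]], sub$group)
        byg <- lapply(byg, function(v) v[!is.na(v)])
        if (any(lengths(byg) < 2) || sum(lengths(byg)) < 3) {
          add_skip("between_groups", feat, label,
                   "fewer than 2 usable patients in some group")
          next
        }
        res <- suppressWarnings(kruskal_wallis(byg))
        comparisons[[length(comparisons) + 1]] <- data.frame(
          kind = "between_groups", feature = feat, label = label,
          statistic = res$statistic, p_value = res$p_value, n = res$n,
          significant = res$p_value < alpha$threshold,
          stringsAsFactors = FALSE)
      }
    }
  }

  # -- entry feature x covariate correlation matrix ------------------------
  entry <- features[features$phase == correlation_phase, ]
  joined <- merge(entry, clinical, by = "patient_id",
                  suffixes = c("", ".clin"))
  cors <- list()
  for (feat in feature_cols) {
    for (cov in covariate_cols) {
      res <- pearson_correlation(joined[[feat]], joined[[cov]])
      cors[[length(cors) + 1]] <- data.frame(
        feature = feat, covariate = cov, r = res$r, p_value = res$p_value,
        n = res$n,
        significant = !is.na(res$p_value) && res$p_value < alpha$threshold,
        stringsAsFactors = FALSE)
    }
  }

  structure(
    list(comparisons = if (length(comparisons)) do.call(rbind, comparisons)
                       else NULL,
         correlations = do.call(rbind, cors),
         alpha = alpha,
         n_gated_out = n_gated,
         skipped = if (length(skipped)) do.call(rbind, skipped) else NULL),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> adjusted alpha %.5f (%.2g / %d)\n",
              x$alpha$threshold, x$alpha$alpha, x$alpha$n_comparisons))
  nc <- if (is.null(x$comparisons)) 0 else nrow(x$comparisons)
  cat(sprintf("  %d group comparisons (%d significant), %d correlations (%d significant)\n",
              nc, if (nc) sum(x$comparisons$significant) else 0,
              nrow(x$correlations), sum(x$correlations$significant)))
  if (x$n_gated_out > 0) {
    cat(sprintf("  %d cosinor fits failed the rhythm gate and were excluded\n",
                x$n_gated_out))
  }
  invisible(x)
}
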