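# Nonparametric tests, correlations, Bonferroni threshold, and the
# comparison suite.

test_that("exact Wilcoxon signed-rank reproduces hand-enumerable cases", {
  # all 6 differences positive and distinct: p = 2/2^6
  res <- wilcoxon_signed_rank(c(2, 3, 5, 7, 8, 9), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$statistic, 21)   # sum of ranks 1..6
  expect_match(res$method, "exact")
  # identical vectors: all differences zero
  expect_warning(res0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res0$p_value, 1)
  # symmetric pair (1, -1)
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)
})

test_that("exact Wilcoxon p equals full enumeration, including mid-ranked ties", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # integer ties likely
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_wilcoxon_enum(d),
                 tolerance = 1e-12, label = paste("tied case", i))
  }
})

test_that("tie-free exact Wilcoxon agrees with wilcox.test(exact = TRUE)", {
  set.seed(42)
  for (i in 1:15) {
    n <- sample(5:15, 1)
    d <- rnorm(n)   # continuous, no ties
    ours <- wilcoxon_signed_rank(d)$p_value
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12, label = paste("case", i))
  }
})

test_that("Kruskal-Wallis reproduces the hand-computed rank formula", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)  # 4.571 to 3 dp
  expect_equal(round(res$statistic, 3), 4.571)
  expect_equal(res$df, 2)
  expect_warning(flat <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1))),
                 "identical")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "nonempty")
})

test_that("two-group Kruskal-Wallis p matches the rank-sum oracle", {
  set.seed(43)
  for (i in 1:10) {
    a <- rnorm(sample(4:9, 1))
    b <- rnorm(sample(4:9, 1), mean = 0.5)
    expect_equal(kruskal_wallis(list(a, b))$p_value, oracle_ranksum_p(a, b),
                 tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(44)
  groups <- list(rnorm(6), rnorm(5, 0.4), rnorm(7, 1))
  h0 <- kruskal_wallis(groups)$statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(v) 3 * v - 10))$statistic,
               h0)
})

test_that("Pearson correlation matches hand computation and its invariances", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  set.seed(45)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(2 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -y)$r, -r0, tolerance = 1e-12)
  const <- pearson_correlation(rep(1, 10), rnorm(10))
  expect_true(is.na(const$r))
  expect_match(const$reason, "constant")
})

test_that("Bonferroni threshold follows alpha / m with 3-decimal reporting", {
  b <- bonferroni_alpha(0.05, 15)
  expect_equal(b$threshold, 0.05 / 15)
  expect_equal(b$threshold_3dp, 0.003)
  expect_equal(bonferroni_alpha(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_alpha(0.01, 5)$threshold, 0.002)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

strong_cohort_tables <- function(seed = 71, n = 30) {
  p <- cohort_gen_params(n_patients = c(A = n, B = n, C = n), seed = seed)
  co <- generate_cohort(p)
  series <- cohort_to_series(co)
  feats <- merge(cosinor_table(series),
                 rqa_table(series)[, -2],   # drop duplicate group column
                 by = c("patient_id", "phase"))
  list(features = feats, clinical = co$clinical)
}

test_that("the default comparison suite reproduces the 15-way Bonferroni design", {
  tabs <- strong_cohort_tables(seed = 72, n = 8)
  comp <- build_comparison_suite(tabs$features, tabs$clinical)
  expect_equal(comp$alpha$n_comparisons, 15)  # 8 features + 7 covariates
  expect_equal(comp$alpha$threshold_3dp, 0.003)
  expect_equal(nrow(comp$correlations), 8 * 7)
  expect_true(all(c("within_paired", "between_groups") %in%
                    comp$comparisons$kind))
  # significance flag is exactly p < adjusted threshold
  expect_equal(comp$correlations$significant,
               !is.na(comp$correlations$p_value) &
                 comp$correlations$p_value < comp$alpha$threshold)
})

test_that("strong amplitude-severity coupling is detected as negative and significant", {
  tabs <- strong_cohort_tables(seed = 73, n = 30)
  comp <- build_comparison_suite(tabs$features, tabs$clinical)
  r_saps <- subset(comp$correlations,
                   feature == "amplitude" & covariate == "saps_ii")
  expect_lt(r_saps$r, 0)
  expect_true(r_saps$significant)
  r_apache <- subset(comp$correlations,
                     feature == "amplitude" & covariate == "apache_ii")
  expect_lt(r_apache$r, 0)
})

test_that("permuting covariates destroys the amplitude-severity signal", {
  tabs <- strong_cohort_tables(seed = 74, n = 30)
  clin <- tabs$clinical
  set.seed(99)
  perm <- clin
  perm[, setdiff(names(clin), c("patient_id", "group"))] <-
    clin[sample(nrow(clin)), setdiff(names(clin), c("patient_id", "group"))]
  comp <- build_comparison_suite(tabs$features, perm)
  # 56 correlated nulls at threshold 0.0033: a handful of flags at most
  expect_lte(sum(comp$correlations$significant), 4)
})

test_that("cosinor features failing the rhythm gate are excluded but counted", {
  tabs <- strong_cohort_tables(seed = 75, n = 6)
  feats <- tabs$features
  feats$rhythm_detected[] <- TRUE
  feats$rhythm_detected[1:4] <- FALSE
  comp <- build_comparison_suite(feats, tabs$clinical)
  expect_equal(comp$n_gated_out, 4)
  # RQA features of the gated rows are still used
  expect_true(all(subset(comp$correlations, feature == "REC")$n >=
                    subset(comp$correlations, feature == "amplitude")$n))
})

test_that("comparisons with fewer than 2 usable patients are skipped with a reason", {
  feats <- data.frame(
    patient_id = c("P1", "P2", "P1", "P2"),
    group = "A", phase = rep(c("entry", "exit"), each = 2),
    amplitude = c(0.3, NA, 0.5, NA), rhythm_detected = TRUE,
    stringsAsFactors = FALSE)
  clin <- data.frame(patient_id = c("P1", "P2"), saps_ii = c(40, 50))
  comp <- build_comparison_suite(feats, clin, feature_cols = "amplitude",
                                 covariate_cols = "saps_ii")
  expect_null(comp$comparisons)
  expect_match(comp$skipped$reason[1], "fewer than 2")
})
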