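# Synthetic cohort generator: determinism, noise-free closed form,
# convergence to the configured group amplitudes, afebrile constraint, and
# the amplitude-score coupling of the clinical table.

noise_free_params <- function(amplitude = 0.5, peak = 19, interval = 60) {
  curve <- default_curve_params()
  curve$mesor_mean <- 37
  curve$mesor_sd <- 0
  curve$amplitude_sd <- 0
  curve$acrophase_sd <- 0
  curve$amplitude_mean <- amplitude
  curve$acrophase_mean <- peak
  cohort_gen_params(n_patients = c(A = 1, B = 1, C = 1),
                    sampling_interval = interval, curve = curve,
                    noise_sd = 0, afebrile = FALSE, seed = 11)
}

test_that("noise-free generation reproduces the exact cosine with the configured peak", {
  gen <- generate_patient_series(noise_free_params(), "A", "entry", "A01")
  s <- gen$series
  t_abs <- s$start_hour + s$time_h
  expect_equal(s$values, 37 + 0.5 * cos(2 * pi * (t_abs - 19) / 24),
               tolerance = 1e-12)
  expect_equal(gen$truth$amplitude, 0.5)
  expect_equal(gen$truth$acrophase_h, 19)
  # peak lands on the sample taken at 19:00 local
  expect_equal(t_abs[which.max(s$values)] %% 24, 19)
})

test_that("generation is deterministic given the seed, independent of call order", {
  p <- cohort_gen_params(n_patients = c(A = 3, B = 2, C = 2), seed = 99)
  co1 <- generate_cohort(p)
  co2 <- generate_cohort(p)
  expect_identical(co1$recordings, co2$recordings)
  expect_identical(co1$clinical, co2$clinical)
  # a patient's curve depends only on (seed, patient id, phase)
  direct <- generate_patient_series(p, "B", "entry", "B02")
  expect_identical(
    direct$series$values,
    co1$recordings$temp_c[co1$recordings$patient_id == "B02" &
                            co1$recordings$phase == "entry"])
})

test_that("cohort layout matches the configured design", {
  p5 <- cohort_gen_params(n_patients = c(A = 2, B = 1, C = 1),
                          sampling_interval = 5, seed = 2)
  co5 <- generate_cohort(p5)
  counts <- table(paste(co5$recordings$patient_id, co5$recordings$phase))
  expect_true(all(counts == 288))   # 24 * 60 / 5
  p60 <- cohort_gen_params(n_patients = c(A = 10, B = 6, C = 5), seed = 2)
  co60 <- generate_cohort(p60)
  counts60 <- table(paste(co60$recordings$patient_id, co60$recordings$phase))
  expect_true(all(counts60 == 24))
  expect_equal(nrow(co60$clinical), 21)
  # phases per group: A and C entry/exit, B adds septic shock
  ph <- unique(co60$recordings[c("group", "phase")])
  expect_setequal(ph$phase[ph$group == "A"], c("entry", "exit"))
  expect_setequal(ph$phase[ph$group == "B"],
                  c("entry", "septic_shock", "exit"))
  expect_setequal(ph$phase[ph$group == "C"], c("entry", "exit"))
})

test_that("invalid group/phase combinations are rejected", {
  p <- cohort_gen_params(seed = 1)
  expect_error(generate_patient_series(p, "A", "septic_shock", "A01"),
               "invalid group/phase")
  expect_error(generate_patient_series(p, "D", "entry", "D01"),
               "unknown group")
})

test_that("afebrile mode keeps all temperatures strictly inside (36.5, 38.5)", {
  co <- generate_cohort(cohort_gen_params(seed = 5))
  expect_true(all(co$recordings$temp_c > 36.5 & co$recordings$temp_c < 38.5))
})

test_that("an unsatisfiable afebrile constraint is rejected with a clear message", {
  curve <- default_curve_params()
  curve$amplitude_mean <- 3   # peak-to-trough 6 degC cannot fit in a 2 degC band
  curve$amplitude_sd <- 0
  p <- cohort_gen_params(curve = curve, seed = 1, max_retries = 20)
  expect_error(generate_patient_series(p, "A", "entry", "A01"),
               "afebrile constraint unsatisfiable")
})

test_that("mean true amplitude converges to the configured group value", {
  p <- cohort_gen_params(n_patients = c(A = 1, B = 1, C = 600), seed = 31)
  co <- generate_cohort(p)
  amps <- co$true_params$amplitude[co$true_params$group == "C" &
                                     co$true_params$phase == "entry"]
  # generating mean 0.45, SD 0.19; SE ~ 0.008, truncation bias < 0.003
  expect_equal(mean(amps), 0.45, tolerance = 0.03)
  expect_true(all(amps >= 0))
})

test_that("clinical scores are exactly anti-linear in amplitude when noiseless", {
  sm <- default_score_model()
  sm$scores$residual_sd[] <- 0
  amps <- data.frame(patient_id = sprintf("P%02d", 1:20), group = "A",
                     amplitude = seq(0.1, 0.6, length.out = 20))
  clin <- generate_clinical_scores(amps, sm, seed = 4)
  expect_equal(cor(amps$amplitude, clin$saps_ii), -1, tolerance = 1e-12)
  expect_equal(cor(amps$amplitude, clin$apache_ii), -1, tolerance = 1e-12)
})

test_that("zero slope yields null amplitude-score correlation on average", {
  sm <- default_score_model()
  sm$scores$slope[] <- 0
  rs <- vapply(1:200, function(i) {
    amps <- data.frame(patient_id = sprintf("P%02d", 1:30), group = "A",
                       amplitude = with_seed_runif(i, 30, 0.1, 0.6))
    clin <- generate_clinical_scores(amps, sm, seed = i)
    cor(amps$amplitude, clin$saps_ii)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("default slopes give sample amplitude-severity correlations near -0.7", {
  rs <- vapply(1:50, function(i) {
    amps <- data.frame(
      patient_id = sprintf("P%02d", 1:30), group = "A",
      amplitude = pmax(with_seed_rnorm(i, 30, 0.33, 0.17), 0))
    clin <- generate_clinical_scores(amps, default_score_model(), seed = i)
    cor(amps$amplitude, clin$saps_ii)
  }, numeric(1))
  expect_equal(mean(rs), -0.7, tolerance = 0.2)
  expect_true(all(rs < 0))
})

test_that("negative residual SD is rejected", {
  sm <- default_score_model()
  sm$scores$residual_sd[1] <- -1
  amps <- data.frame(patient_id = "P1", group = "A", amplitude = 0.3)
  expect_error(generate_clinical_scores(amps, sm, seed = 1),
               "residual_sd")
})

test_that("written cohort round-trips through the CSV reader", {
  co <- generate_cohort(cohort_gen_params(n_patients = c(A = 2, B = 1, C = 1),
                                          seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("recordings.csv", "clinical.csv", "true_params.csv",
           "sim_config.yaml")))))
  series <- read_recordings(file.path(dir, "recordings.csv"))
  direct <- cohort_to_series(co)
  expect_equal(length(series), length(direct))
  expect_equal(series[["A01.entry"]]$values, direct[["A01.entry"]]$values,
               tolerance = 1e-6)  # CSV text round-trip precision
})
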