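# circarq

Circadian cosinor rhythmometry and recurrence quantification analysis (RQA)
of 24-hour core body temperature (CBT) curves in critically ill patients.

Septic shock blunts the circadian temperature rhythm. `circarq` is for
researchers analysing 24-h CBT recordings from ICU cohorts — typically a
septic-shock-at-entry group, an in-ICU septic-shock group and non-septic
controls, each patient recorded at ICU entry and exit (plus shock onset
where applicable). It provides:

* **Single-cosinor fitting** of `CBT(t) = M + A·cos(2πt/24 + φ)` by exact
  linearized least squares: mesor `M`, amplitude `A`, acrophase `φ`
  (convention: acrophase 0 = peak at local midnight), reported as peak
  clock time; the **zero-amplitude rhythm-detection F-test**
  (`F = (MSS/2)/(RSS/(n−3))` on `(2, n−3)` df) gating every fit; and
  **percent rhythm** (squared model–data correlation).
* **RQA** of the same curves: time-delay embedding, thresholded recurrence
  matrices, and REC, DET, LAM, Lmean, Lmax and DIV = 1/Lmax from the
  diagonal/vertical line structures, with explicit Theiler-window and
  line-of-identity conventions.
* **Preprocessing**: 5-minute recordings to hourly bin means, inclusive
  fever (≥ 38.5 °C) / hypothermia (≤ 36.5 °C) exclusion screening, and
  bounded gap filling with explicit rejection of unusable series.
* **Cohort statistics**: exact small-sample Wilcoxon signed-rank within
  groups, Kruskal–Wallis between groups, Pearson feature–covariate
  correlations, and a Bonferroni threshold recomputed from the configured
  feature/covariate lists (default 0.05/15 = 0.003).
* A seeded **synthetic cohort generator** emulating afebrile ICU
  temperature curves (group-specific cosine amplitudes, AR(1) noise,
  severity scores anti-correlated with amplitude) so the whole pipeline is
  testable without patient data.

See `vignettes/circarq-methods.Rmd` for the model details, parameter
defaults and design choices.

## Worked example

```r
library(circarq)

cfg <- pipeline_config(
  simulate = cohort_gen_params(n_patients = c(A = 10, B = 6, C = 5),
                               seed = 42),
  out_dir = "circarq_out")
run <- run_pipeline(cfg)
run
#> <circarq_run>
#>   48 series screened (48 included), 48 feature rows
#> <cohort_comparison> adjusted alpha 0.00333 (0.05 / 15)
#>   56 group comparisons (0 significant), 56 correlations (9 significant)
#>   2 cosinor fits failed the rhythm gate and were excluded

fit <- fit_cosinor(cohort_to_series(run$cohort)[["C01.entry"]])
fit
#> <cosinor_fit> n=24, period=24 h
#>   mesor 37.462 degC, amplitude 0.460 degC, peak 19.48 h
#>   rhythm detection: F=123, p=2.47e-12 -> rhythm detected
#>   model-data correlation 0.960, percent rhythm 0.922
```

The 21 simulated patients (10/6/5 across groups) yield 48 patient-phase
series. For patient C01 at entry the fitted amplitude (0.46 °C) and evening
peak (~19:30) match the generating distribution for non-septic controls;
the F-test p-value far below 0.05 means the rhythm parameters pass the gate
into the cohort statistics. `circarq_out/` then contains the per-series
`cosinor.csv` and `rqa.csv`, `screening.csv`, the comparison and
correlation tables with Bonferroni-adjusted significance flags, and a
Markdown report; rerunning with the same seed reproduces every file
byte-for-byte.

A command-line wrapper exposes the same stages:

```sh
Rscript exec/circarq run --out circarq_out --seed 42
Rscript exec/circarq simulate --out sim --seed 1 --interval 5
```

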