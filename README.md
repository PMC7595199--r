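# qeegstroke

Quantitative EEG (qEEG) analysis of short resting-state recordings from
low-cost portable EEG headbands, aimed at one clinical question: can a
3-minute bedside recording help grade acute ischemic stroke severity for
prehospital triage?

Cerebral ischemia slows the EEG in a graded, lateralised way.  The package
computes the standard qEEG markers of that slowing from a four-electrode
headband (TP9/TP10 ear clips, AF7/AF8 frontal) plus its motion sensors, and
feeds them to bagged classification trees:

* **Morlet wavelet spectra** — wavenumber 15, 0.5–31 Hz in 0.1 Hz steps,
  time-averaged per channel;
* **pdBSI** — pairwise-derived brain symmetry index,
  `mean |R−L|/(R+L)` over homologous electrode pairs and 1–30 Hz
  frequencies, with low/high (split 10 Hz) and frontal variants;
* **slowing ratios** — DAR = δ/α and DTABR = (δ+θ)/(α+β) on summed band
  powers (δ 1–3, θ 4–7, α 8–13, β 14–20 Hz, closed intervals);
* **aperiodic fit** — robust two-pass log–log line through the 1/f
  background, giving intercept and exponent;
* **motion variability** — per-axis RMS and SD of the accelerometer (g)
  and gyroscope (deg/s) streams;
* **classification** — 200 bootstrap-aggregated CART trees (Gini splits,
  grown to purity) with out-of-bag confusion matrices, ACC/SE/SP and a
  majority-class chance baseline, for three tasks: 4-class severity,
  stroke vs control, and moderate-or-large vs the rest.

No clinical recordings ship with the package.  A synthetic-cohort
generator (`synth_cohort()`) emulates the assumed statistical structure —
1/f background, band oscillations, severity-scaled delta boost and alpha
suppression over the lesioned hemisphere, axis-dependent motion
variability — so the whole chain is testable end-to-end.  Session I/O
covers MuseLSL-style delimited directories and 16-bit EDF, plus a cohort
manifest format; `inst/extdata/` carries a 25-participant demographics
table and published confusion counts used by the acceptance checks.

## Worked example

Simulate a small cohort, build the triage-relevant design matrix and
score it out-of-bag:

```r
library(qeegstroke)

params <- synthesis_params(seed = 42, duration = 60,
                           n_per_group = c(control = 4, small = 2,
                                           moderate = 3, large = 3))
sim <- synth_cohort(params)
cfg <- list(spectral = spectral_config(f_min = 1, f_max = 31),
            fit_range = c(1, 30))
dm <- build_design_matrix(sim$cohort, sim$recordings,
                          task = "moderate_large_vs_rest", config = cfg)
model <- fit_bagged_trees(dm, n_trees = 200, seed = 42)
model
#> bagged_trees: 200 trees, 12 samples, classes: rest, moderate_large
#>   OOB accuracy: 1.000
cm <- oob_confusion(model)
cm
#> confusion_matrix (positive = moderate_large): TP=6 FP=0 FN=0 TN=6
m <- confusion_metrics(cm)
sprintf("accuracy %.2f, sensitivity %.2f, specificity %.2f (chance %.2f)",
        m$accuracy, m$sensitivity, m$specificity, chance_accuracy(dm$label))
#> "accuracy 1.00, sensitivity 1.00, specificity 1.00 (chance 0.50)"
head(sort(model$feature_importance, decreasing = TRUE), 3)
#>   pdbsi_low       pdbsi         age
#> 0.377986111 0.069444444 0.007361111
```

Every out-of-bag vote is correct here — the generator's default severity
gains (delta ×4, alpha ×0.4 for large strokes) are strong, and the most
informative predictor is the low-frequency pdBSI, exactly where a
lateralised delta boost creates asymmetry.  On real data the published
counterpart of this task reached 76% accuracy against a 52% baseline;
green synthetic results demonstrate that the pipeline recovers effects of
the stated form, not that clinical accuracy would match.

Scoring published confusion counts needs no recordings at all:

```r
metrics_from_counts(system.file("extdata", "example_confusion_counts.csv",
                                package = "qeegstroke"))
#>  moderate_large_vs_rest row: accuracy 0.76, sensitivity 0.64,
#>  specificity 0.86 ...
```

## Command line

```sh
Rscript inst/cli/qeegstroke-cli.R run \
    --out-dir run1 --seed 7 --task moderate_large_vs_rest \
    --n-per-group 9,4,9,3 --duration 180
Rscript inst/cli/qeegstroke-cli.R metrics --counts counts.csv
```

Subcommands `simulate`, `features`, `classify`, `run`, `metrics`,
`report`; exit codes 0 (success), 2 (validation), 3 (stage failure).
Artifacts land in `--out-dir`: `manifest.csv`, per-session directories,
`features.csv` (stable column order: `id`, the 26 predictors of
`qeeg_predictors()`, then labels), `model_report.csv`, `importance.csv`,
`summary.txt`, and `manifest.json` with the config hash and seed.

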