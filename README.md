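# scdemd

Prediction of sudden cardiac death (SCD) episodes from raw single-lead
ECG, up to 25 minutes before the annotated onset of the fatal arrhythmia.

`scdemd` is aimed at biomedical-signal researchers who want a complete,
reproducible implementation of an EMD-plus-nonlinear-features prediction
pipeline: it reads ECG records (WFDB-dialect or CSV), resamples them to a
common 128 Hz rate, cuts one-minute analysis windows referenced to the
SCD onset, decomposes each window by empirical mode decomposition,
computes five complexity indices per intrinsic mode function, screens the
resulting features by one-way ANOVA, and classifies windows with a small
multilayer perceptron trained by Levenberg–Marquardt on bounding-box
augmented features. A seeded synthetic ECG generator makes the whole
chain runnable and testable with no external data.

## The method

Each one-minute window `x(t)` is decomposed by the sifting process into
intrinsic mode functions and a residue,

    x(t) = IMF_1(t) + ... + IMF_N(t) + r_N(t),

where each IMF satisfies the usual two conditions (extrema and
zero-crossing counts differ by at most one; zero local envelope mean).
On each of the first six IMFs five indices are computed:

* **KI** — Katz fractal dimension, `log10(L/a) / log10(d/a)`;
* **HI** — Higuchi fractal dimension, the negated log–log slope of the
  pooled multiscale curve length `L(p) ~ p^(-D)`;
* **BDI** — box dimension, `-ln(L/Δt) / ln(Δt)`;
* **SEI** — Shannon entropy (bits) of the window quantised to `2^12`
  levels;
* **PEI** — normalized permutation entropy of ordinal patterns
  (order `m = 3`, lag `τ = 1`).

The 30 features are ranked by one-way ANOVA between the normal and
pre-SCD groups; the top pair feeds a 2–10–1 logistic MLP (normal → 0,
SCD → 1, threshold 0.5). Training uses a patient-level 45/55 split and,
per class, 400 points drawn uniformly inside the bounding box of the
training features; accuracy is reported for each of the 25 pre-onset
minutes on held-out patients.

See the vignette `vignettes/scd-prediction-methods.Rmd` for the design
decisions, parameter defaults and the limits of the synthetic-data
evidence.

## Worked example

```r
library(scdemd)

## one synthetic normal record and its feature vector
rec <- synthesize_ecg(synth_config("normal", duration_s = 60, seed = 7))
rec
#> <ecg_record synth-normal-7: 7680 samples @ 128 Hz (60.0 s), label=normal>

w  <- random_normal_window(rec, 1L)
fv <- extract_features(w)
fv[fv$imf == 3, ][1:5, ]
#>        subject_id  label minute index imf      value
#> 11 synth-normal-7 normal      0    KI   3  3.0524060
#> 12 synth-normal-7 normal      0    HI   3  1.8584613
#> 13 synth-normal-7 normal      0   BDI   3  2.0782703
#> 14 synth-normal-7 normal      0   SEI   3 10.4209125
#> 15 synth-normal-7 normal      0   PEI   3  0.6707784
```

The 30-row feature vector holds one value per (index, IMF) pair: here
IMF 3 of a normal window has Higuchi dimension 1.86 (noise-dominated
mid-band) and permutation entropy 0.67.

```r
## a small end-to-end run on a synthetic cohort
cfg <- default_config()
cfg$synth$n_normal <- 6L; cfg$synth$n_scd <- 6L
cfg$synth$scd$duration_s <- 7 * 60     # 5 analysed minutes + onset margin
cfg$io$n_minutes <- 5L
res <- run_all(cfg, output_dir = tempfile())

res$selection$top[, c("index", "imf", "F", "p", "mean_normal", "mean_scd")]
#>   index imf        F            p mean_normal  mean_scd
#> 1    HI   1 9007.494 8.181607e-43   1.9494022 1.8605785
#> 2   PEI   2 3386.615 1.231476e-35   0.8030692 0.6457505

res$model
#> <scd_mlp 2-10-1: loss 4.145e-08 after 10 LM iterations>

res$evaluation$per_minute
#>   minute n accuracy
#> 1      1 6      100
#> ...
#> 5      5 6      100
res$evaluation$mean_accuracy
#> [1] 100
```

ANOVA picks the two most discriminant features (on this small synthetic
cohort the injected separation is broadband, so IMF 1–2 indices win; on
annotated clinical data the selected pair is HI of IMF 3 and PEI of
IMF 5), the MLP trains to a near-zero loss in 10 Levenberg–Marquardt
iterations, and every pre-onset minute of the held-out patients is
classified correctly.

A command-line interface wrapping the same functions is installed at
`system.file("exec", "scdemd", package = "scdemd")`, with subcommands
`simulate`, `decompose`, `features`, `select`, `train`, `predict`,
`evaluate` and `run-all` over a single YAML configuration.

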