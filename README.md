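# plvsleep

Functional-connectivity analysis of sleep EEG: phase-locking-value (PLV)
networks per frequency band, band discriminability ranking, and sleep-stage
classification with band-fusion strategies.

## The problem

Most automatic sleep-staging features are computed channel by channel and
ignore how brain regions synchronize with each other. This package takes
the connectivity view: a night of polysomnography EEG is cut into 30 s
epochs labelled REM, N2 or N3, each epoch is decomposed into six frequency
bands (delta 0.5–4 Hz, theta 4–8, alpha 8–13, beta1 13–22, beta2 22–30,
gamma 30–40), and within each band the phase synchrony of every channel
pair is measured with the PLV

    PLV = | (1/T) Σ_t exp(i (φ_a(t) − φ_b(t))) |  ∈ [0, 1],

where φ are instantaneous phases from the analytic signal. The 66-entry
upper triangle of each epoch's 12×12 PLV matrix is that epoch's feature
vector. On top of this the package builds:

* **stage-average networks**, binarized at the no-isolated-node threshold
  (τ = min over nodes of the node's strongest edge) plus signed
  stage-difference matrices and one-way ANOVA stage/band comparisons;
* **band evaluation** — every (stage-pair, band, channel-pair) feature is
  scored with the point-biserial r² (= squared Pearson correlation with
  the class indicator), ranked globally; summaries include top-k band
  percentages and the top-36 discriminative ratio per stage pair;
* **classification** — Gaussian-kernel SVM (libsvm, one-against-one) on
  single bands and under three fusion strategies: feature concatenation
  ("C"), stacking over per-band classifiers ("E"), and stacking over
  feature-fused band pairs ("E(C)"), with stratified 75/25 splits;
* **a calibrated synthetic generator** — stage-labelled multichannel
  epochs with planted band-specific phase coupling whose expected PLV is
  analytically known (exp(−σ²/2) for wrapped-normal phase jitter σ), so
  the whole pipeline is testable without clinical recordings;
* **I/O** — a minimal EDF reader/writer, plain-text hypnogram parsing
  (with the three-rule curation of unreliable stage labels), and tidy
  delimited-text outputs for every table.

It is aimed at EEG methods researchers who want a reproducible, tested
reference implementation of PLV band-fusion staging, in tidyverse style:
tables in, tibbles out, `tidy()`/`glance()`/`autoplot()` on the results.

## Worked example

Generate a synthetic dataset under the default stage contrasts, rank the
bands, and classify with six-band feature fusion:

```r
library(plvsleep)

cfg <- generator_config(n_channels = 12, sampling_rate = 128,
                        epochs_per_stage = 15, seed = 42)
epochs <- synth_dataset(cfg)
epochs
#> <epoch_set> 45 epochs x 12 channels x 3840 samples @ 128 Hz
#>   stages: N2=15, N3=15, REM=15

features <- plv_features(filter_bank(epochs))
head(features, 3)
#> # A tibble: 3 × 6
#>   epoch stage band  pair_index pair        plv
#>   <int> <chr> <chr>      <int> <chr>     <dbl>
#> 1     1 N2    delta          1 ch01|ch02 0.595
#> 2     1 N2    delta          2 ch01|ch03 0.564
#> 3     1 N2    delta          3 ch01|ch04 0.556

ranking <- score_all(features)
top_k_band_percentage(ranking, k = 95)
#> # A tibble: 6 × 2
#>   band  percent
#>   <fct>   <dbl>
#> 1 delta    67.4
#> 2 theta     0
#> 3 alpha    32.6
#> 4 beta1     0
#> 5 beta2     0
#> 6 gamma     0

split <- split_train_test(epochs$labels, seed = 42)
classify_bands(features, band_order(), split)
#> <classification_report> strategy=C bands=[delta,theta,alpha,beta1,beta2,gamma]
#>   accuracy: 100.00% (n_test=12)
#>   per-class TPR (%): N2=100.00, N3=100.00, REM=100.00
```

The top-95 ranking concentrates in delta and alpha — the two bands whose
coupling the default generator raises from N2 to N3 — and the fused
classifier separates the three planted stages perfectly at this effect
size. `run_pipeline(pipeline_config(input = cfg))` runs the same chain end
to end (EDF input works the same way: `input = list(edf = ..., hypnogram
= ...)`), and `run_experiment_grid()` reproduces the full
single-band/two/three/four/six-band × C/E/E(C) table. Plots:
`plot_stage_band_plv()`, `plot_band_percentages()`,
`plot_discriminative_ratio()`, `plot_2d_features()`, and `autoplot()` on
reports and rankings.

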