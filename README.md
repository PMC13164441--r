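# nccthist

Time-histogram metrics for acute ischemic stroke (AIS) lesions on
non-contrast CT (NCCT).

Early ischemic change is subtle on hyperacute NCCT. This package quantifies
it with first-order statistics of the Hounsfield-unit (HU) distribution
inside a lesion ROI — the within-ROI standard deviation (SD), bias-corrected
skewness (G1) and excess kurtosis (G2), and the Shannon entropy
(−Σ pᵢ log₂ pᵢ, in bits) of a standardized 100-bin histogram over −40..60 HU
(1 HU per bin) — using the contralateral mirrored ROI as the within-subject
control. Tracked across scans at minutes post-onset, SD and entropy separate
heterogeneous cortical infarcts from uniform basal-ganglia (BG) infarcts,
define a peak diagnostic window, and reveal a lesion-over-control mean-HU
crossover in a subset of cortical cases.

It is written for imaging researchers who want a tested, reproducible
implementation of this analysis: ROI tools on HU arrays (extraction,
midline estimation, mask mirroring, the ≥1 cm² area rule, NIfTI I/O),
temporal trajectory analysis (percent HU decrease, HU gap, interpolated
crossover detection, a coverage-guarded sliding-window search), the group
statistics battery (one-way ANOVA, pooled t with Bonferroni correction,
Cohen's d, percentile bootstrap CIs, repeated-measures ANOVA), and — since
the patient images behind the published tables are unavailable — a fully
synthetic cohort generator whose pixel distributions are *jointly calibrated*
to prescribed (SD, entropy) targets by nested bisection over a two-component
Gaussian mixture, so every pipeline stage is testable without any download.

## Worked example

```r
library(nccthist)

# one calibrated cortical-lesion ROI: SD 5.16 HU and entropy 4.34 bits jointly
pmf <- calibrate_joint_pmf(target_sd = 5.16, target_entropy = 4.34, mean_hu = 26.71)
metric_set(sample_roi(pmf, n_px = 1e5, seed = 7))
#> HU metric set (n = 100000 px): mean 26.68 HU, SD 5.17 HU, skew 0.003,
#>   exkurt -0.903, entropy 4.339 bits
```

The SD lands ~0.01 above the pmf target (uniform within-bin jitter adds
1/12 HU² of variance); the entropy is recovered to ~0.001 bits. The full
cohort workflow lives in `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R    # synthetic cohort -> results/metrics.csv
Rscript analysis/02_group_comparison.R   # cortical vs BG at baseline
Rscript analysis/03_temporal_analysis.R  # crossovers + peak window
Rscript analysis/04_phantom_demo.R       # NIfTI round trip on a head phantom
```

Stage 2 prints the baseline comparison (seed 101):

```
  sd                5.17 +- 1.06 vs  3.94 +- 0.41 | diff   1.23 | F  21.76 | t  4.66 | p_adj 0.00012 | d  1.42 *
  skewness         -0.00 +- 0.01 vs -0.00 +- 0.01 | diff   0.00 | F   0.15 | t  0.38 | p_adj 1      | d  0.12
  kurtosis_excess   0.28 +- 1.03 vs  0.17 +- 0.80 | diff   0.11 | F   0.13 | t  0.37 | p_adj 1      | d  0.11
  entropy_bits      4.34 +- 0.30 vs  3.99 +- 0.15 | diff   0.35 | F  21.36 | t  4.62 | p_adj 0.00014 | d  1.41 *
Significant after correction: sd, entropy_bits
```

— SD and entropy separate the lesion classes strongly (the generator's
calibration targets are 5.16/3.94 HU and 4.34/3.99 bits); the shape metrics
do not, because each synthetic subject draws its mixture family (bimodal vs
heavy-tailed) at random, leaving no group signal in the third and fourth
moments. Stage 3 reports the temporal results:

```
Crossover: 33.3% of cortical cases (median time 97 min), 0.0% of BG cases
Peak diagnostic window: [73, 85) min (score 1.9e-07)
  in-window cortical: SD 5.67, entropy 4.52 | BG: SD 4.06, entropy 4.05
```

— the detector recovers the planted one-third crossover fraction near 94
min, its absence in BG lesions, and a peak window overlapping the 76–87-min
anchor where cortical entropy reaches 4.52 bits.

See `vignettes/time-histogram-methods.Rmd` for the models, the entropy
feasibility bound (at fixed SD no binned distribution can out-entropy the
Gaussian — which constrains what any generator can realize jointly), and
every tunable default.

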