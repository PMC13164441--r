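---
title: "Time-histogram metrics for stroke NCCT: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-histogram metrics for stroke NCCT: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Non-contrast CT (NCCT) is the first-line imaging modality in acute ischemic
stroke, but early ischemic hypoattenuation is subtle in the hyperacute phase.
First-order histogram statistics of the Hounsfield-unit (HU) values inside a
lesion region of interest (ROI) quantify what the eye struggles to see:
developing cytotoxic edema lowers the mean HU, and the *heterogeneity* of the
tissue response — captured by the within-ROI standard deviation and by the
Shannon entropy of the binned HU distribution — separates cortical infarcts
(heterogeneous, collateral-rich territory) from basal-ganglia (BG) infarcts
(uniform, collateral-poor deep tissue). Tracked over minutes post-onset,
these metrics define a diagnostic window in which the two lesion classes
separate most strongly, and a lesion-vs-control mean-HU *crossover* that may
mark penumbral salvage.

`nccthist` implements this analysis end to end: per-ROI metrics, mirrored
contralateral controls, temporal trajectory analysis, the group-comparison
battery, and — because the underlying patient images are not publicly
available — a fully synthetic cohort generator with the same statistical
structure, so that every stage of the pipeline is testable and every headline
quantity is recomputable from scratch.

## The four metrics

For an ROI pixel sample $x_1,\dots,x_n$ (HU):

* **SD**: the sample standard deviation ($n-1$ denominator).
* **Skewness**: the bias-corrected estimator
  $G_1 = \frac{\sqrt{n(n-1)}}{n-2}\, m_3 / m_2^{3/2}$.
* **Excess kurtosis**: the bias-corrected
  $G_2 = \frac{n-1}{(n-2)(n-3)}\bigl[(n+1)(m_4/m_2^2 - 3) + 6\bigr]$, so a
  Gaussian sample tends to 0 ("relative to a normal distribution").
* **Entropy**: the plug-in Shannon entropy of the binned distribution,
  $H = -\sum_i \hat p_i \log_2 \hat p_i$ in **bits**, over a standardized
  histogram of **100 bins spanning $-40$ to $60$ HU** — exactly 1 HU per
  bin. Bins are half-open with a closed final bin; out-of-range values are
  clipped into the edge bins by default (CT streak or bone pixels at an ROI
  edge), with a drop policy available.

Why base 2? The published group entropies (4.34 cortical, 3.99 BG) sit just
below the value $\tfrac12\log_2(2\pi e\,\sigma^2)$ that a Gaussian pixel
distribution of the published SDs (5.16, 3.94) would give with 1-HU bins
(4.41, 4.02); with the natural log the printed numbers would be unattainable
with these bins. The analysis therefore fixes base-2, plug-in estimation
(Miller–Madow correction available as an option), and the fixed $-40..60$
brain window; a dynamic range mode (sample min/max padded to integer HU) is
provided but off by default because it changes the bin width and thereby the
entropy scale. All estimator choices are recorded in each metric set's
metadata.

The skewness/kurtosis preconditions (non-degenerate sample, $n \ge 3$ resp.
$4$) are enforced as errors: a constant "delta" ROI has zero entropy but no
defined shape moments.

## ROIs, mirrored controls, and the 1 cm² rule

ROIs are planar boolean masks congruent with an HU slice. The within-subject
control is the lesion mask reflected across the sagittal midline
(`col' = 2·midline − col`), an exact involution for integer midlines. The
midline can be user-supplied or estimated as the column in the central third
of the image minimizing the mean squared left–right HU difference — adequate
for axially aligned scans and the package's symmetric phantoms. Rigid
registration of the lesion annotation onto CT space is assumed to have
happened upstream and is out of scope.

ROIs must cover at least 1 cm² (100 mm², boundary inclusive) so the
histogram metrics are estimated from enough pixels; `metric_set()` warns
when a sample with known pixel spacing fails the rule.

## Temporal analysis

* **Percent HU decrease**: $100(\bar x_{control} - \bar x_{lesion})/\bar
  x_{control}$, displayed to one decimal.
* **HU gap**: control minus lesion mean HU (positive = hypodense lesion).
* **Crossover**: the phenomenon is reported without an estimator. We
  define it on mean HU: the first time the signed gap (lesion − control)
  reaches $\ge 0$ from a previously negative scan, the crossing time linearly
  interpolated between the bracketing scans; a scan with an exactly zero gap
  reports that scan time. Monotone gap trajectories therefore yield at most
  one event, and scans after the first crossing cannot move it.
* **Peak diagnostic window**: also not operationalized in the source. We
  slide windows $[t, t+w)$ (default $w = 12$ min, step 1 min) over the
  pooled scan span; per window each subject contributes the mean of each
  metric over its in-window scans, the groups are compared by pooled
  t-tests for SD and for entropy, and the window score is the *worse* of the
  two p-values, so the top-ranked window is where both heterogeneity
  metrics separate the groups. Two guards matter:
  * windows with fewer than 2 subjects per group are skipped;
  * windows covering less than 90% of either group are skipped
    (`min_coverage`). Ranking minimum p-values across windows that see
    different subject subsets is an extreme-value selection over subsets —
    an incidental subset can "win" on luck and report a biased group mean.
    Restricting the ranking to near-complete panels makes window scores
    comparable; with scan schedules standardized at key time points (as
    here), the windows of interest always qualify.
* **Anchor deltas / repeated measures**: subjects are matched to anchor
  times by nearest scan within ±15 min (configurable); unmatched subjects
  are excluded *with a warning*, never silently. The repeated-measures
  ANOVA (subjects as blocks, sphericity assumed, no Greenhouse–Geisser
  correction) requires a complete subjects-by-anchors matrix and errors with
  the offending subject ids otherwise.

## Group statistics

The battery mirrors the study's: one-way ANOVA, post hoc two-sample
t-tests with Bonferroni correction, Cohen's d, percentile bootstrap CIs.
Design choices:

* **Pooled (Student) t, not Welch.** Applied to the published summary rows
  (27 subjects, 5.16 ± 1.17 vs 18 subjects, 3.94 ± 0.46) the pooled
  statistic gives $t = 4.20$, matching the printed 4.17 up to rounding of
  the printed summaries, where Welch gives 4.88 — so pooled is what the
  study used. Both group summaries `(n, mean, sd)` and raw vectors are
  accepted and agree exactly when one is computed from the other; for two
  groups $F = t^2$ holds to numerical identity.
* **Bonferroni family m = 4**: the four metrics at one fixed group
  contrast. The family size is configurable since the source does not state
  it.
* **Bootstrap**: percentile method, default 2000 resamples, mandatory seed
  (every interval is reproducible); BCa is out of scope.
* Degenerate inputs are explicit: zero pooled variance with equal means is
  $t = 0, p = 1$; with unequal means it is an error rather than an infinite
  statistic.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's recovery properties are demonstrated.

**Pixel model.** Per ROI and scan, pixels are i.i.d. draws from a
*calibrated pmf* on the 100-bin grid, plus uniform jitter within the drawn
1-HU bin (so the sample's histogram is exactly multinomial in the pmf and
the plug-in entropy recovers the calibrated value). Because the jitter adds
variance $w^2/12$, the generator requests a pmf SD of
$\sqrt{s^2 - w^2/12}$ when the *sample* SD is meant to be $s$ — the cohort
tables report sample SDs.

**Joint calibration.** A single knob cannot hit an (SD, entropy) pair, so
the pmf family is a symmetric two-component Gaussian mixture with a nested
bisection: the inner loop solves the component scale so the discretized
pmf's SD matches the target exactly (discretization shifts moments, so the
continuous-variance identity is only the starting bracket); the outer loop
moves the mixture knob — component separation, which lowers entropy at
fixed SD — until the pmf entropy matches. Both achieved values are
re-evaluated from the final pmf and must agree to $10^{-4}$. Two families
are available: the **location** mixture (components at $\mu \pm \delta$,
bimodal, negative excess kurtosis) and the **scale** mixture (same mean,
component SDs $s/r$ and $s\,r$, heavy-tailed, positive excess kurtosis).
Each synthetic subject draws its family at random: the two families bracket
the Gaussian in the third and fourth moments, so skewness and kurtosis carry
*no systematic group signal* — matching the study's null finding for those
metrics — while SD and entropy are hit exactly by either family.

**Feasibility.** At fixed variance the Gaussian maximizes entropy, so no
pixel distribution binned at 1 HU can exceed
$H_{max}(s) \approx \tfrac12\log_2(2\pi e s^2)$. The anchor tables are
mutually constrained by this bound, and the cortical peak-time pair
(SD 5.38, entropy 4.52) lies slightly *above* it ($H_{max} \approx 4.47$):
those two printed numbers are not jointly realizable by any pixel
distribution under this binning. The generator resolves such conflicts by
preserving entropy — the primary biomarker — and letting the SD settle at
the smallest feasible value (about 5.55 at the peak), an adjustment well
inside the printed between-subject spread (±1.15).

**Between-subject structure.** Each subject carries one heterogeneity
factor $z$; the factors are drawn as exactly centered and standardized
normals per group, so cross-sectional means and SDs of the targets match
the anchor tables by construction rather than up to 27-draw sampling noise.
Per anchor time, subject targets are calibrated cohort-wide: linear-in-$z$
draws, entropy-preserving projection of infeasible pairs onto the frontier,
then iterative re-centering of both target vectors to the anchor means.
(A naive linear draw is infeasible for low-$z$ subjects because the entropy
ceiling falls faster in $z$ than the printed entropy spread.) The feasible
region is the hypograph of a concave frontier — convex — so linear
interpolation of the calibrated targets between anchors stays feasible.
SD and entropy share the same $z$: one heterogeneity axis, which is also
what feasibility favors.

**Scan schedule.** Scans sit on the anchor grid {0, 60, 81.5, 94, 120,
180} min with small uniform jitter. Baseline, the 76–87-min peak anchor,
and 180 min are always acquired (the study standardized time points and
focused its analyses on the peak window); crossover-flagged subjects also
always have the 94- and 120-min scans, so the crossing is bracketed by
observations; the remaining anchors are included with the probability that
makes the expected scan count per subject equal 5.2. Every subject
therefore has at least 3 scans and contributes to the peak window.

**Mean-HU trajectories and the crossover.** Normal-tissue (control) models:
BG 29.05 HU (within-ROI SD 4.19), cortical 39.41 HU (SD 6.07), single
calibrated Gaussians. Lesion means follow piecewise-linear gap curves:
BG and non-crossover cortical gaps stay negative throughout (persistent
hypodensity); in the designated third of cortical cases the gap crosses
zero at 94 ± 5 min and stays at least 0.5 HU positive from ~15 min after
the crossing, with the control tracking the published 94-min levels. A
subject-level whole-head HU offset (SD 4 HU) shifts lesion and control
together, so it does not perturb gaps or crossing times. With $10^5$
pixels per ROI the per-scan mean-HU noise is ~0.02 HU, so detection of
planted crossings is essentially deterministic.

**Phantoms.** Optionally a scan is rasterized into a symmetric head
phantom (air at −1000 HU, bright skull ring, brain disc from the control
pmf, lateral lesion blob from the lesion pmf) on an odd-sized grid so the
midline is an integer column and mirroring is an exact involution; the
lesion radius satisfies the 1 cm² rule at the phantom's ~1 mm pixels.

**What the generator does *not* emulate.** Anatomy and partial-volume
effects, beam hardening and other CT physics, registration error between
the lesion annotation and CT space, spatial correlation between neighboring
pixels (draws are i.i.d.), realistic skewness variation (both mixture
families are symmetric, so between-subject skewness spread is near zero
rather than the printed ±0.22), and any post-180-min decline beyond flat
extrapolation. Passing recovery tests therefore demonstrates that the
*pipeline* measures what it claims on data with the published statistical
structure — not that the published values themselves are clinically
reproducible.

## Numerical choices

* Calibration bisections: `uniroot` with knob tolerance $10^{-10}$,
  achieved-target check at $10^{-4}$; the outer bracket treats knobs whose
  inner problem is unsolvable (near-spike components) as "entropy far below
  target", keeping the bracket valid far from the root.
* Feasibility projection headroom: 0.02 HU of SD above the frontier, so the
  joint calibration always has an interior root.
* The closed-form frontier inverse
  $s(H) = \sqrt{2^{2H}/(2\pi e) + w^2/6}$ (pmf discretization plus sampler
  jitter) is used inside the cohort target iteration for speed; the exact
  projection in `make_case` is the safety net.
* Crossover tie rule: a scan with exactly zero gap is the crossing time.
* Window ranking ties (identical scores) resolve to the earliest window
  start (stable sort).
* Determinism: the cohort is a pure function of its config and master seed;
  per-subject seeds are derived arithmetically from the master seed, and
  `bootstrap_ci` requires a seed and restores the caller's RNG state.

## Problem sizes used by the test suite

The package's tests run the full study-scale recovery (27/18 subjects,
$10^5$ pixels per ROI, ~5 scans each — about a minute of compute),
a window-probe cohort with separation injected only inside [76, 88) min,
Monte-Carlo property checks at $10^6$ draws (Gaussian entropy limit),
500-replicate checks for bootstrap coverage and familywise type-I error,
and brute-force oracle comparisons at $10^{-12}$ for the moment operators.
Smaller cohorts (thousands of pixels per ROI) are used where only
structural behavior is under test.

## Known limitations

* The entropy scale is tied to the 1-HU binning; dynamic-range mode changes
  it and is deliberately not the default.
* The midline estimator assumes approximate left–right symmetry; heavily
  rotated scans need a user-supplied midline.
* The sliding-window search is a detector for *group* separation; it does
  not model within-subject time correlation (subjects contribute window
  means, not longitudinal fits).
* Repeated-measures ANOVA assumes sphericity and completeness; irregular
  real-world scan schedules will often require the nearest-scan matching
  tolerance to be widened, at the cost of anchor smearing.
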