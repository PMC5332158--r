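---
title: "Models and methods behind replispan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replispan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replispan)
```

`replispan` analyses replicative lifespan (RLS) data from single-cell
catch-channel assays of fission yeast, and ships a ground-truthed
simulator of such data so that every downstream stage is testable without
a microscope. This vignette documents the models, the defaults and their
units, the numerical choices, and the places where the design was
genuinely open.

## Survival model

Lifespans are counted in whole divisions. The survivor function
$S(g)$ is the probability of being alive after generation $g$; two
families are fitted:

* exponential decay, $S(g) = e^{-\alpha g}$, with constant hazard
  $\lambda(g) = \alpha$ — a population whose per-generation risk of death
  never changes (non-aging);
* Gompertz, $S(g) = e^{(\alpha/\beta)(1 - e^{\beta g})}$, with hazard
  $\lambda(g) = \alpha e^{\beta g}$ — risk grows exponentially with
  replicative age at rate $\beta$ (aging).

Both coefficients are per-generation and dimensionless; $\alpha > 0$
scales the hazard, $\beta \ge 0$ time-scales it, and the Gompertz family
degenerates continuously to the exponential one as $\beta \to 0$. The RLS
is the age at which the fitted $S$ crosses $1/2$:
$\mathrm{RLS} = \ln 2/\alpha$ (exponential) and
$\mathrm{RLS} = \ln(1 + \beta \ln 2/\alpha)/\beta$ (Gompertz). Both
closed forms satisfy $S(\mathrm{RLS}) = 1/2$ to $10^{-9}$, which the test
suite asserts directly.

### Estimation

With no right censoring (lost or ejected cells are excluded, not
censored), the Kaplan–Meier product-limit estimate equals the empirical
survivor fraction $\hat S(g) = \#\{\text{lifespan} > g\}/n$, and that is
what `km_estimate()` computes; `survival::survfit` serves as an
independent cross-check in the tests. Fits are nonlinear least squares
(`minpack.lm::nlsLM`) on $(g, \hat S(g))$ at integer generations,
weighted $1/\hat S(g)$ so old-age points, which few cells reach, still
constrain the coefficients. Points with $\hat S = 0$ are excluded (their
weight is undefined). Fitting at integer generations rather than at every
acquisition timepoint reflects that division counts, not clock time, are
the age variable.

Numerical details that matter:

* **Starting values.** The exponential start comes from the log-linear
  regression of $\log \hat S$ on $g$. The Gompertz fit is seeded from the
  empirical log-hazard regression ($\log \lambda$ is linear in $g$ under
  the model), then falls back to a small ladder of alternative starts;
  without the hazard-based seed, cohort-sized fits occasionally converge
  to poor local optima and inflate the apparent aging signal.
* **Boundaries.** Coefficients are box-constrained to
  $[10^{-12}, 10]$ ($\alpha$) and $[10^{-12}, 5]$ ($\beta$); an
  exponential truth fitted by the Gompertz family lands on the
  $\beta \approx 0$ boundary rather than failing.
* **Degenerate input.** A curve with no decay information (all
  $\hat S = 1$ before a single collapse, as in a point-mass bootstrap
  resample) collapses to the zero-hazard boundary deterministically, so
  bootstrap CIs of point-mass data have zero width rather than erroring.
* **Model selection.** The family with the higher adjusted $r^2$ wins;
  ties within $10^{-4}$ go to the exponential model (fewer parameters).
  Adjusted $r^2$ for the weighted fit is
  $1 - (1 - r^2_w)(n-1)/(n-p-1)$ with $r^2_w$ computed on weighted
  residuals about the weighted mean — one of several defensible variants;
  it is used consistently for both families so the comparison is fair.

### Uncertainty

Confidence intervals are percentile bootstrap over cells (not curve
points), default 1000 resamples, deterministic given a seed. When a fit
is bootstrapped, the replicate coefficients are kept, so hazard fold
changes between strains (`normalize_hazard`) get ratio-of-resamples CIs.

### Aging classification

`classify_aging` calls a population non-aging when the exponential model
is selected, or when the Gompertz $\beta$ CI includes zero. The second
prong matters: on finite cohorts the extra Gompertz parameter can win the
adjusted-$r^2$ comparison by overfitting noise, but its $\beta$ interval
then hugs zero. The test suite calibrates both directions at the study's
cohort size (440 cells): exponential cohorts are classified non-aging and
strongly aging cohorts ($\beta \gg \alpha$) aging, each in at least 90%
of replicates.

## The lineage simulator

The simulator draws death generations by inverse-CDF on the discrete
probability mass $S(g-1) - S(g)$, so the implied survivor function
matches the model exactly at integer ages — for the exponential family
this is a geometric draw with per-generation death probability
$1 - e^{-\alpha}$, chosen over the small-$\alpha$ approximation
$p = \alpha$ for exactness. An independently coded per-generation
Bernoulli-walk sampler cross-checks it in the tests.

Growth within a generation is bilinear: fission yeast grows by tip
extension, monopolar (old pole) from birth until new end take-off (NETO)
at about 30% of the cycle, then bipolar and faster until medial fission.
Defaults (units in parentheses) are the wild-type values:

| parameter | default | meaning |
|---|---|---|
| `birth_length_mean/sd` | 8.3 / 1.5 (µm) | length at birth |
| `division_length_mean/sd` | 16 / 2.2 (µm) | length at fission |
| `doubling_time_mean/sd` | 2.05 / 0.45 (h) | generation time |
| `neto_fraction` | 0.3 | cycle fraction at NETO |
| `monopolar_rate_share` | 0.35 | pre-NETO / post-NETO rate ratio |
| `sampling_interval` | 2 (min) | imaging cadence |
| mortality `alpha` | 0.02 | wild-type per-generation hazard |

`monopolar_rate_share` is defined as the ratio of the monopolar to the
bipolar elongation rate. With the NETO break at 0.3 this puts roughly 13%
of the per-generation extension before NETO and produces the slope
*increase* that single-cell traces show; defining the parameter instead
as the pre-NETO share of total extension with a value above 0.3 would
invert the acceleration, which is why the rate-ratio reading was chosen.

Other generator choices where the underlying quantity is not published:
the post-division reset is division length × a truncated normal
(mean 0.5, sd 0.02, support (0.4, 0.6)) — medial fission is nearly
symmetric but not perfectly so; all positive-valued draws use
truncated-normal redraws to avoid unphysical negatives; division-length
draws that fall below the birth length are redrawn. Terminal phenotypes:
a `short` death truncates a normal cycle partway (uniform fraction
0.25–0.85, so the cell dies below the normal division length), an
`elongated` death extends the terminal segment to 3.3–5 mean doubling
times without division. Phenotype, last-sibling fate and
segregation-defect draws are independent of replicative age by
construction — the simulator's null is an age-independent death process,
which is exactly what the calibration tests need. Default frequencies:
short/elongated 72/28%, sibling fates 66/14/20% (never divided / once /
multiple), terminal segregation-defect rate 40% vs 7% across all
divisions.

Per-cell random streams are derived from the master seed by stable
hashing of the cell id, so any subset of a cohort reproduces identically.

## Synthetic kymograph stacks and their quantification

`render_kymograph_stack` draws the cell as a dark rod (intensity 0.3 on a
1.0 background) anchored at the channel notch, with a darker septum band
just inside the new pole for a few frames after each division. Three
rendering choices are deliberate:

* **Static device structure.** PDMS walls, channel-boundary ridges and
  the notch wall are drawn into every frame. Cross-correlation
  registration needs static structure to lock onto; with only the growing
  cell in frame the correlation peak tracks growth and registration is
  ill-posed. Real fields of view are dominated by device structure.
* **Optical blur.** A small Gaussian blur (σ = 0.7 px) emulates the
  deliberately out-of-focus acquisition used for septum-resolved
  contrast, and keeps edges band-limited so bilinear rotation round-trips
  without aliasing loss.
* **Nuisances in acquisition order.** Rotation (whole field), then
  per-frame integer stage jitter (recorded in the ground truth), then
  additive Gaussian sensor noise.

Quantification mirrors the two pre-processing/annotation stages of such
pipelines: rotate back by the measured angle (bilinear, EBImage), recover
integer shifts against the first frame by the FFT cross-correlation peak
(sub-pixel registration is not attempted — synthetic jitter is integer
and the noise floor does not justify it), take the centreline pixel row
from the notch outward as one kymograph row per frame, and trace the cell
edge as the last position whose lightly smoothed intensity falls below
0.65 (midway between cell and background). With a 5-pixel moving-average
profile smoother, a background pixel would need a ~7 σ noise excursion at
the default noise level to masquerade as cell, so edge tracing is stable.

### Division detection

Divisions are local minima of the moving-median-smoothed length trace
(window 5 timepoints = 10 min). Two screens make the raw minima usable:

* **Relative-drop screen.** A minimum counts only if the smoothed length
  fell by ≥ 25% from the running maximum of its segment
  (`min_drop_frac = 0.25`). Fission halves the length (~50% drop); noise
  wiggles on a rising segment do not come close. Without this screen any
  noisy monotone segment sprouts spurious minima.
* **Spacing merge.** Accepted minima closer than
  `min_generation_time = 0.5` h are merged, keeping the deepest. The
  value is half an earlier working default of 1.0 h (about half the mean
  doubling time): with the drop screen already suppressing noise minima,
  the tighter guard only needs to merge double-detections of the same
  reset, whereas a 1.0 h guard silently deletes genuine divisions whenever
  a drawn doubling time falls below an hour (~1% of generations at
  2.05 ± 0.45 h), which measurably breaks exact generation recovery.

A minimal plateau (several equal smoothed values after a reset) is
reported at its first index so division times align with the reset frame.
Division length is the raw maximum since the previous division;
inter-division intervals are the recovered doubling times.

### Ejection screening

A captured cell that is ejected and replaced produces an abrupt
between-frame length change. Any single-frame relative change above 35%
is flagged unless it is division-consistent: within ±2 frames of an
accepted division *and* leaving a post/pre ratio inside [0.41, 0.59]
(± 4.5 sd of the simulated fission asymmetry). The ratio condition is
what separates a 60% reload drop from a legitimate halving; flagged
traces are excluded downstream.

### NETO breakpoint

`detect_neto` fits a continuous two-segment piecewise-linear model by
profiling the breakpoint over a 0.10–0.90 grid (step 0.01) and solving
each conditional fit in closed form. If the two slopes differ by less
than 10% of the larger, the breakpoint is reported unidentifiable rather
than returning a meaningless location on a straight line.

## Death-aligned analyses

`post_synchronize_to_death` re-indexes each dying cell's completed
generations backwards from death (k = 1 is the last completed division).
Sequential bins are compared by two-sample Kolmogorov–Smirnov tests with
the conventional star annotation (* p < 0.05, ** p < 0.01) and no
multiplicity correction — mirroring common practice for these displays —
with a Holm-corrected column reported alongside for readers who want it.
Sibling-fate proportions are binned by quartiles of age at death by
default (any explicit breaks can be supplied), with cell-level bootstrap
SDs and a global chi-square independence check. Segregation-defect
enrichment is computed at event level (a cell contributes each scored
division), and per-class lethality carries exact binomial CIs.
`screen_normality` exposes an Anderson–Darling normality check for any of
these samples; it is reporting-only — nothing is gated on it
automatically, it simply records whether parametric summaries are
reasonable alongside the distribution-free KS comparisons.

## What the simulator does and does not emulate

It emulates the statistical structure the analyses consume: discrete
per-generation mortality, bilinear growth with realistic parameter
scatter, age-independent terminal phenotypes, imaging nuisances
(rotation, integer jitter, noise, blur). It does **not** model
fluid dynamics or device geometry, fluorescence photophysics,
continuous-time death within a generation, correlated measurement error,
sub-pixel stage drift, focus drift, or cell crowding. Passing tests
therefore demonstrate that the estimators are correct and calibrated
under the stated generative model — not that real microscopy meets that
model. The interactive annotation step of real pipelines is replaced by
programmatic edge detection validated against simulator ground truth.

## Problem sizes

The test suite and acceptance script use cohort sizes chosen to match the
study design while staying desk-scale: 440 cells per cohort for
model-selection and coverage calibration (200 Monte-Carlo replicates,
120-resample bootstrap per replicate), 10,000 cells for the
hazard-recovery fit, 1,000 trajectories for division-statistics recovery,
a 200-cell mixed-nuisance cohort for the image round trip, and 100,000
draws for survivor-function convergence checks.

## Known limitations

* The Gompertz fit near the $\beta = 0$ boundary is one-sided; its
  bootstrap $\beta$ CI is a boundary interval, which is why the aging
  classifier treats a lower limit at the boundary as "includes zero".
* Registration is integer-pixel by design; real stages drift
  sub-pixel.
* The empirical hazard at old ages is noisy (few cells at risk); fitted
  hazards are the stable summary, and both are labelled by source.
* Complete-data KM is exact because loss is excluded, not censored, the
  standard treatment when losses are rare; `km_estimate(censor_lost =
  TRUE)` switches to the product-limit estimator with lost cells
  right-censored at their last observed generation, for datasets where
  loss is not negligible.
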