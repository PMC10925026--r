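---
title: "Stress-time cell-death thresholds for ex vivo muscle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-time cell-death thresholds for ex vivo muscle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtithresh)
```

`dtithresh` analyses ex vivo indentation experiments on skeletal muscle: a
flat circular indenter compresses the tissue for a fixed duration, dead
fibers take up a membrane-impermeable dye, and the question is which
stress-time combinations kill fibers. This vignette is the package's own
account of the science behind each stage — the models, the tunables and
their defaults, the design decisions that were genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## From indenter load to internal compressive stress

The external direct stress under a flat circular indenter is the applied
force over the contact area, $\sigma_{ext} = F/(\pi r^2)$
(`external_stress_kpa()`; gravity defaults to 9.81 m/s²). An 11 g indenter
with r = 1 mm delivers 34.35 kPa.

The mean compressive stress *inside* the muscle layer is lower than the
interface pressure, because the load spreads through the tissue and into the
supporting substrate. Rather than re-solving the contact problem, the
package uses the linear structure of finite-element predictions for this
geometry: the difference between external and internal stress grows linearly
with the external stress,

$$\sigma_{ext} - \sigma_{int} = c_0 + c_1\,\sigma_{ext},$$

so two or more (external, internal) pairs calibrate the map by ordinary
least squares (`calibrate_stress_map()`, via `stats::lm`). The bundled
default calibration uses the two anchor pairs 5 → 3.4 kPa and
103 → 69.1 kPa, which gives $c_1 \approx 0.3296$, $c_0 \approx -0.048$ and a
32.0% relative reduction at the 5 kPa anchor. Predictions are clamped into
$[0, \sigma_{ext}]$: physically the internal mean stress cannot be negative
nor exceed the interface pressure, and near $\sigma_{ext} = 0$ the fitted
intercept would otherwise push the raw prediction slightly outside that
range. With only two bundled pairs the calibration $R^2$ is trivially 1;
users with their own FE point sets can pass them to
`calibrate_stress_map()` and obtain a meaningful $R^2$.

The hyperelastic/viscoelastic FE model itself (Ogden and Prony parameters,
indenter-edge stress concentrations) is out of scope by design: the linear
difference map is what the downstream analysis actually consumes.

## The Boltzmann stress-time threshold

Cell-death tolerance to sustained compression is modelled by a decreasing
four-parameter Boltzmann sigmoid

$$\sigma(t) = \frac{K}{1 + e^{\alpha (t - t_0)}} + C$$

with $K$ (kPa) the range, $\alpha$ (1/min) the slope coefficient, $t_0$
(min) the time at midrange and $C$ (kPa) the minimum compressive stress
asymptote. The curve falls from $K + C$ (short loading) to $C$ (long
loading) and passes through $K/2 + C$ at $t_0$. Two canonical curves are
built in: `cell_death_threshold()` (K = 16.2, α = 0.5, t0 = 90, C = 5.5) and
`no_damage_threshold()` (K = 13.1, α = 0.5, t0 = 90, C = 4.2), bounding a
transition zone where a fiber's fate is not clearly destined, plus
`in_vivo_reference_threshold()` (K = 23.0, α = 0.15, t0 = 90, C = 8.6), the
in vivo comparison curve reconstructed from the reported parameter
reductions (K lower by 6.8 kPa, C by 3.1 kPa ex vivo). Published parameter
sets for these curves are not fully consistent with each other (fitted
slopes near 0.54–0.57/min and midrange times of 87.8–89.5 min appear
alongside the rounded 0.5/min and 90 min used here); the package adopts the
closed-form curves above as canonical and makes no claim about which report
is authoritative.

### Fitting

`fit_threshold()` minimises the sum of squared *vertical* residuals (stress,
kPa²) — the model predicts stress as a function of time — over box-bounded
parameters. Constraints follow the conservative convention that the
cell-death curve must stay below all cell-death points
($C < 6$ kPa) and the no-damage curve above all no-damage points
($C > 3.7$ kPa); the remaining bounds ($K \le 50$ kPa, $\alpha \le 5$/min,
$t_0$ within the observed time range) are sanity boxes, not scientific
claims. Because the solver landscape has local minima (the sigmoid can
trade α against t0), the fit is multi-start: 16 Latin-hypercube points over
the feasible box plus one data-driven start (K from the observed stress
range, C from the observed floor), each refined by `L-BFGS-B` with an
analytic gradient (`factr = 1e3`, then a `factr = 10` polish of the winner;
the logistic is evaluated through `plogis` so large $\alpha(t-t_0)$ cannot
overflow). Parameters can be fixed (e.g. `fixed = c(alpha = 0.15, t0 = 90)`)
to express the workflow where slope and midrange time are adopted from a
reference study and only K and C are estimated.

Numerical behaviour worth knowing: on noiseless points the fit recovers
generating parameters to ~1e-6 relative error; with 15-min time grids only
one grid point sits on the sigmoid's step, so α is weakly identified and
noisy fits may push it to a bound while K and C remain accurate — the
recovery guarantees the tests enforce are therefore stated for K, C and
(noiseless) t0, not for α on sparse grids. No confidence intervals are
computed (deliberately out of scope).

## Image quantification

Sections are two-channel grayscale matrices: autofluorescence (viable-fiber
signal, used for segmentation) and dye (dead-fiber marker, used for
scoring). All pixel coordinates are 1-based (row, col) from the top-left,
the R convention.

- **Preprocessing** (`preprocess_channel()`): optional 8-bit quantisation,
  background estimation by grayscale morphological opening with a disc
  (default radius 50 px — anything much larger than a fiber is background),
  subtraction, then percentile rescaling (0.1–99.9) to [0, 1]. Robust
  percentiles, not min/max, so single hot pixels cannot set the scale.
- **Control threshold** (`control_intensity_threshold()`): the pooled mean
  dye intensity over the tissue foreground of a sample's control sections,
  i.e. pixels are pooled across sections rather than averaging per-section
  means (the two agree for equal-area sections). Foreground comes from Otsu
  thresholding of the autofluorescence channel with a small closing so the
  interstitial space between fibers counts as tissue. Whether such a
  "combined average" should pool pixels or per-section means, and whether it
  is computed on 8-bit or raw intensities, is genuinely underdetermined;
  both knobs are exposed and the defaults documented here.
- **Segmentation** (`segment_fibers()`): Otsu foreground, then watershed on
  the distance transform to split touching fibers, then removal of labels
  below `min_area` (default 40 px²) and dense relabelling. This is a
  bespoke, pluggable segmenter: any external instance segmenter (e.g. a
  trained neural model) can be substituted by providing its label matrix,
  since all downstream steps consume the `fiber_map` structure. A blank
  image is a valid input with zero fibers, not an error.
- **Scoring** (`score_dye_positive()`): a fiber is dead when its *mean* dye
  intensity strictly exceeds the control threshold — the simplest faithful
  reading of masking unlabelled fibers; a per-pixel-fraction rule was the
  alternative and is intentionally not the default. Counting is therefore
  monotone non-increasing in the threshold.
- **Indented area** (`restrict_to_indented_area()`): a disc ROI around a
  user-supplied indent centre; the default radius is infinite (whole
  section) because the indent position is often unknown on cross-sections.
  Per-sample means are taken over six sections (`quantify_sample()` warns,
  not errors, on other counts).

## Damage classification

Mechanically caused death shows a centralised pattern around the indentation
site; background death (handling, storage hypoxia) is scattered. The
original call was made by eye; the package replaces it with a reproducible
surrogate (`localization_statistic()`): the statistic is the mean pairwise
distance among positive-fiber centroids, and the null distribution comes
from 999 equal-size subsets drawn uniformly from all fiber centroids. Small
p means clustering. Fewer than three positives carry no spatial evidence and
return `NA` (never localized).

A sample is localized when at least one of its sections is
(`is_sample_localized()`, minimum p against `alpha_loc = 0.05`). In the
study-level pipeline the per-section level is Šidák-adjusted,
$1 - (1-\alpha)^{1/n_{sections}}$ (≈ 0.0085 for six sections), so that
`alpha_loc` is the *sample-level* false-localization rate. This adjustment
matters: with six sections at a raw 0.05 each, about one in four undamaged
samples would be falsely called localized, and because the count baseline is
the *minimum* mean count among localized samples, a single false call drags
the baseline down and misclassifies every undamaged sample above it. With
the adjustment, permutation resolution must satisfy
$1/(n_{null}+1) < \alpha_{section}$; `classify_study()` enforces this.

The baseline (`derive_baseline()`) is the lowest mean count among localized
samples; classification (`classify_sample()`) is inclusive at the boundary
(a mean equal to the baseline is "cell death", since the baseline-defining
sample is itself damaged — the published convention leaves strict-vs-inclusive
open, and this is the choice made here). Exclusions are always explicit user
inputs with a recorded reason (the archetype being a sample with a known
staining deviation), never automatic outlier rejection.

## The synthetic-data generator

The generator exists so that every stage has ground truth. It emulates, at
two levels:

- **Sections** (`simulate_scene()`): fibers as a jittered hexagonal grid of
  truncated-Voronoi cells (the polygonal, densely packed appearance of a
  muscle cross-section; ~800 fibers on 400×400 px by default), separated by
  interstitial boundaries. Dead fibers are planted exactly
  (`round(dead_fraction * n_fibers)`), either uniformly ("scattered") or
  with probability proportional to a Gaussian kernel at the indent centre
  ("localized", kernel sd defaulting to 10% of the section radius).
  Rendering: per-fiber lognormal autofluorescence (median 0.55, dead fibers
  ×0.85), low dye baseline in viable fibers (0.06), strong dye gain in dead
  ones (+0.5), and — deliberately — brighter dye in the interstitial space
  (0.28) than inside viable fibers, because soak staining pools dye in the
  extracellular matrix. That last choice is what makes the control-mean
  threshold workable at all: the pooled tissue mean sits with a margin above
  every viable fiber's mean, so viable fibers are not coin-flip positives.
  Noise is additive Gaussian (sd 0.02) plus a signal-dependent term
  (0.05·√I). Everything is bit-reproducible under a seed.
- **Studies** (`simulate_study()`): the default design crosses durations
  {30, 60, 90, 120} min with three internal-stress levels per duration —
  the protocol's extremes 3.4 and 69 kPa plus a middle level halfway between
  the two canonical curves (the transition zone). Conditions above the
  cell-death curve are labelled `cell_death`, below the no-damage curve
  `no_damage`, and in between stochastically with probability interpolated
  between the curves. Per-section counts are negative binomial (damaged mean
  180, size 40; undamaged mean 70, size 50), chosen so damaged sample means
  fall within the observed 110–254 range and undamaged ones below it — an
  emulation of the reported count regime, not a reproduction of it. Sections
  are point patterns (centroids plus the dead subset); full images can be
  rendered on request but are not needed for classification.

What the generator does *not* emulate: optics (PSF, chromatic effects),
tiling/stitching artefacts, illumination gradients beyond what background
subtraction removes, histology appearance, and ischaemia/reperfusion time
courses. Passing tests on synthetic sections therefore demonstrates that the
algorithms are correct on images matching the stated intensity model, not
that the pipeline is robust to every real microscope's artefacts; on real
data the preprocessing defaults (background radius, percentile clip) are the
knobs to revisit first.

## Validation summary and problem sizes

The test suite validates, among others: exact stress-map anchors (3.4 and
69.1 kPa, 32.0% reduction); noiseless parameter recovery to 1e-4 across 20
random truth models; noisy K/C recovery within 10% at noise sd 0.3 kPa with
35 points; constraint activation when the truth lies beyond the C bounds;
counting within ±5% of 150 planted dead fibers over 20 rendered sections
with ≤1% false positives on controls; localization type-I error within
[0.02, 0.08] over 500 null replicates and power ≥ 90% on localized patterns;
and mean classification agreement ≥ 11/12 with the generating truth over 10
simulated studies. These sizes (800 fibers, 400×400 px, 199–999 permutation
draws, 10–20 replicates) are the package's chosen validation scale — large
enough for stable statistics, small enough to run routinely.

## Known limitations

- With one sample per stress-duration combination, a three-level design
  validates *classification*, but the per-category point sets it yields are
  poor inputs for curve fitting (e.g. a constant 69 kPa across durations
  carries no information about the sigmoid's shape, and the bundled
  pipeline's illustrative fits can land on their sanity bounds). Threshold
  *recovery* is validated separately on points simulated near the curve,
  which is also how the published curves relate to their boundary-adjacent
  datapoints.
- The min-p localization rule, even Šidák-adjusted, occasionally
  (≈ α per sample) produces a false localized call whose low count then
  lowers the baseline; across simulated studies this costs about 0.2
  samples of accuracy on average. A robust quantile baseline would resist
  this but would change the published rule, so it is not the default.
- The real study's observed counts (53–254), baseline (110) and fit SSEs
  are not reproducible without the raw images and exact datapoints; all
  quantitative guarantees here are therefore stated against synthetic
  ground truth.
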