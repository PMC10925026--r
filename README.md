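# dtithresh

Deep tissue injury (DTI) is a pressure injury that starts in skeletal muscle
under a bony prominence while the skin still looks intact. Ex vivo indentation
experiments probe when sustained compression kills muscle fibers: a flat
circular indenter loads a freshly excised muscle for a set duration, dead
fibers are revealed by a membrane-impermeable dye (Procion Yellow) against the
green autofluorescence of viable fibers, and the dead-fiber counts across many
stress-time combinations are condensed into a stress-time cell-death
threshold.

`dtithresh` implements that whole analysis as a reusable, testable R pipeline
for researchers running (or simulating) such indentation studies:

- **Stress mapping** — converts indenter loads to external direct stress
  (sigma = F / (pi r^2)) and maps external to *internal* compressive stress
  through a linear model of the FE-predicted difference,
  `sigma_ext - sigma_int = c0 + c1 * sigma_ext`, calibrated by default from
  the bundled finite-element anchor pairs (5 -> 3.4 kPa, 103 -> 69.1 kPa,
  a ~32% reduction).
- **Image quantification** — background subtraction and normalisation of
  two-channel sections, a control-derived dye intensity threshold (pooled
  mean over control tissue), watershed fiber segmentation, and dye-positive
  counting in the indented area, averaged over six sections per sample.
- **Damage classification** — a permutation test for centralised
  (indentation-focused) damage patterns, the count baseline (lowest mean
  count among pattern-positive samples), and "cell death" / "no damage"
  labelling.
- **Threshold fitting** — constrained multi-start least squares for the
  four-parameter decreasing Boltzmann sigmoid

  sigma(t) = K / (1 + exp(alpha (t - t0))) + C

  with K the stress range (kPa), alpha the slope coefficient (1/min), t0 the
  time at midrange (min) and C the minimum compressive stress asymptote
  (kPa), under the conservative constraints C < 6 kPa (cell death) and
  C > 3.7 kPa (no damage).
- **Synthetic data** — ground-truthed generators for rendered two-channel
  sections (polygonal fiber tessellations with planted dead fibers) and for
  whole stress-time studies, so every stage is testable without microscope
  data.

Everything is tidyverse-native: tabular inputs and outputs are tibbles, fit
objects have `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Map indenter loads to stresses:

```r
library(dtithresh)

loading <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                          mass_g = c(11, 33, 90), radius_mm = 1,
                          duration_min = c(30, 60, 90))
add_stress_columns(loading)
#> # A tibble: 3 x 6
#>   sample_id mass_g radius_mm duration_min sigma_ext_kpa sigma_int_kpa
#>   <chr>      <dbl>     <dbl>        <dbl>         <dbl>         <dbl>
#> 1 S1            11         1           30          34.3          23.1
#> 2 S2            33         1           60         103.           69.1
#> 3 S3            90         1           90         281.          188.
```

An 11 g indenter of radius 1 mm delivers 34.3 kPa externally, of which
23.1 kPa arrives as mean compressive stress inside the muscle layer.

Recover a known threshold curve from noisy stress-time points:

```r
pts <- simulate_fit_points(cell_death_threshold(), seq(30, 120, by = 5),
                           noise_sd = 0.3, replicates = 2, seed = 1)
fit <- fit_threshold(pts, category = "cell_death", seed = 2)
fit
#> Boltzmann stress-time threshold [cell_death]
#>   sigma(t) = 16.317 / (1 + exp(0.490 (t - 89.97))) + 5.442  [kPa, t in min]
#>   SSE 2.5189 kPa^2 on 38 points
```

The generating curve had K = 16.2, alpha = 0.5, t0 = 90, C = 5.5; the
constrained fit recovers all four, and the fitted C respects the C < 6 kPa
cap. `compare_thresholds(fit, in_vivo_reference_threshold())` then gives the
parameter deltas against the in vivo reference curve (delta K ~ 6.7 kPa,
delta C ~ 3.2 kPa: the ex vivo threshold sits lower).

Run a full synthetic study end to end:

```r
run <- run_study_pipeline(seed = 42, n_null = 199)
run
#> Stress-time study analysis
#>   12 samples, baseline 162.5 dead fibers
#>   labels: cell_death=6, no_damage=6
#>   cell_death fit: K=50.00 alpha=0.050 t0=120.0 C=6.00 (SSE 4237.019)
#>   no_damage fit: K=7.75 alpha=2.345 t0=75.4 C=3.70 (SSE 259.390)
```

Twelve samples (4 durations x 3 stress levels) are simulated, sections are
tested for centralised damage, the count baseline (here 162.5) splits the
samples into six "cell death" and six "no damage", and threshold curves are
fitted to each side. `render_report(run)` emits the Markdown report with the
classification table and parameter comparisons; `autoplot(run)` draws the
stress-time scatter with the fitted curves. (On this three-level design the
category fits are illustrative — see the methods vignette; curve *recovery*
is validated with `simulate_fit_points()` as above.)

## Documentation

The methods vignette (`vignettes/stress-time-thresholds.Rmd`) describes the
model and its assumptions, every tunable with units and defaults, what the
synthetic generator does and does not emulate, and known limitations.
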