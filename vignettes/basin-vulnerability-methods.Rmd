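---
title: "Methods: basin-scale social-ecological vulnerability to freshwater stress and storage loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: basin-scale social-ecological vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basinvuln)
```

## The model

`basinvuln` quantifies, per river basin, the likelihood of social and
ecological harm from the co-occurrence of freshwater stress and freshwater
storage loss. The pipeline compresses gridded hydrological and
socio-economic inputs into five basin indicators and one product:

* **Freshwater stress** `F = min(W / (0.4 Q), 1)` — annual withdrawal `W`
  over annual streamflow `Q` (both mm/yr), normalized by 0.4 Q, the
  conventional "high stress" level, and capped at 1.
* **Storage trend** `T = -clamp(dTWS/dt / (0.4 Q), -1, 1)` — the
  total-water-storage trend under the same normalization, clamped to
  [-1, 1] and sign-flipped so drying scores positive, aligned with `F`.
* **Basin freshwater status** `B = max((F + T) / 2, 0)` — the arithmetic
  mean, floored at 0 because wetting can offset stress but status is never
  negative. Basins whose satellite storage-trend record is contaminated by
  a large earthquake are flagged, and for them `B = F` exactly: the trend
  carries no information there.
* **Ecological sensitivity** `E` — two gridded ecohydrological proxies
  (an environmental-flow head-decline field and a vegetation
  water-sensitivity field) are each converted to area-weighted percentile
  scores, averaged per basin, averaged across the two datasets, and
  normalized by the global maximum basin so the most sensitive basin
  scores exactly 1.
* **Social-ecological sensitivity** `S = 1 - (1 - E)(1 - (1 - A))` — the
  fuzzy sum of `E` with inverted adaptive capacity `A`. The fuzzy sum is
  commutative, bounded by 1, never below its largest input, and avoids
  subjective weights; `A = 0` (no adaptability) is absorbing.
* **Vulnerability** `V = S * B`.

Basins are classified with **Head/Tail Breaks** (three iterations, four
classes): the first break is the mean of all values, the "head" the
values strictly above it, and each further break the mean of the current
head. Classes are labelled low / transitional / high / very high, and
*hotspots* are the high and very-high basins. The method suits the
heavy-tailed vulnerability distributions this pipeline produces; a fixed
iteration count (rather than a skewness stopping rule) keeps the class
structure comparable across the social, ecological and combined variants.

## Geospatial conventions

All gridded operations live on regular latitude-longitude grids with
cells owned whole by one basin (no sub-cell apportioning). Cell areas use
the closed-form authalic-sphere formula
`R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with R = 6371.0088 km;
the deviation from ellipsoidal areas is below 0.3% and immaterial to area
weights. Intensive fields aggregate as area-weighted basin means with
masked cells excluded from numerator and denominator alike; extensive
fields as plain within-basin sums. Cell ownership for point overlays is
half-open (west and south edges inclusive).

The area-weighted percentile transform sorts valid cells by value, splits
the cumulative area into 100 equal-area bins, and scores each cell by the
bin containing the midpoint of its cumulative-area span. Tied values
share the percentile of the midpoint of their combined span — this
preserves the equal-area semantics and gives a defined result (0.5) for a
constant field. The transform is invariant under strictly monotone
transformations of the input, which is the property that lets two
datasets with incommensurable units be combined.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `norm_factor` | 0.4 | Fraction of Q normalizing both F and T |
| `stress_thresholds` | 0.10, 0.40 | Stressed / highly stressed cut-offs on W/Q (inclusive by default; `stress_strict` switches to `>`) |
| `trend_threshold` | 3 mm/yr | Clear-trend level for the *categorical* stress-by-trend labels only; it never enters B, which is enforced by keeping it out of the indicator code path |
| `percentile_bins` | 100 | Granularity of the percentile transform |
| `eco_pairwise` | TRUE | Basins covered by only one ecological dataset are scored from it alone (the head-decline proxy only exists where groundwater is pumped); `FALSE` = strict intersection |
| `rescale_A` | FALSE | Min-max rescale adaptive capacity before inversion — needed when A arrives on a native, non-unit scale |
| `htb_iterations` | 3 | Head/Tail Breaks depth (4 classes) |
| `include_zero_v` | TRUE | Zero-vulnerability basins enter the break computation (they simply populate the low class); the exclusion variant is available because either reading of the classification is defensible |

Boundary conventions that the data could not decide were fixed once:
stress thresholds are inclusive (the definitional reading of
"W/Q >= 10%"), and values exactly at the +/-3 mm/yr trend level count as
"no clear trend" because that figure is an observational error bar —
a value *at* it is not a clear trend.

## The synthetic-world generator

Because the pipeline's real inputs are a dozen published geospatial
datasets, testing uses self-contained synthetic worlds with the same
statistical structure:

* **Basins** are grown by seeded random dilation on the grid — compact,
  contiguous regions emulating a large-basin tessellation (default 200
  basins on a 120 x 80 half-degree grid) without hydrological routing.
  A contiguous blob of cells can be masked to emulate data-sparse regions.
* **Fields** are Gaussian random fields (kernel-smoothed white noise with
  a controllable correlation length in cells) pushed through marginal
  transforms: lognormal for W, Q, the sensitivity proxies and the
  extensive socio-economic fields; signed Gaussian for the storage trend;
  beta via a Gaussian copula for adaptive capacity. Default parameters
  were chosen once to be hydrologically plausible: W/Q spans [0, >1] with
  roughly 40% of basins above the 0.10 stress threshold, storage trends
  are of order +/-10 mm/yr against a 3 mm/yr detection level, and the
  sensitivity proxies are heavy-tailed.
* **Nations** are an independent contiguous tessellation, so basins
  naturally straddle borders; national IWRM scores are uniform on
  [0, 100].
* **Planted hotspots** are ground-truth guarantees, not additive shifts:
  a plant raises withdrawal to `multiplier` times the 0.10 stress
  threshold of local streamflow (or `multiplier` times its own level if
  larger), makes the basin lose storage at least `|trend_offset|` mm/yr,
  caps adaptive capacity and floors both sensitivity fields at a chosen
  quantile. Guarantee semantics make recovery tests meaningful
  independent of the basin's random base state.

What the generator does *not* emulate: hydrological routing and
upstream-downstream water sharing, observational error structure of the
satellite storage record, sub-grid heterogeneity, and the empirical
marginals of any specific published dataset. Passing tests therefore
demonstrate the correctness and robustness of the *method* — aggregation,
indicator algebra, classification, uncertainty propagation — not the
reproduction of real-world basin values, which require the real inputs.

## Uncertainty and sensitivity machinery

Two Monte-Carlo perturbation modes mirror the two uncertainty analyses of
the method: *uniform* (one multiplicative factor per input dataset and
realization, drawn from U[1-m, 1+m] — systematic over/under-estimation)
and *spatial* (a correlated per-cell factor field with the same marginal —
heterogeneous error). The magnitude `m` must always be stated explicitly;
it is a configuration, not a default. Bounded inputs stay valid under
perturbation (A re-clipped to [0, 1], factors floored to keep Q positive,
with the event recorded). Per-realization random streams are derived from
the master seed by counter-based splitting, so any realization can be
reproduced in isolation and results are independent of execution order.

The retention metric is the fraction of realizations in which a basin
keeps an at-least-transitional class; the summary is the share of
baseline transitional-plus-hotspot basins retained in more than half of
the realizations. The methodological sweep re-classifies one world under
a grid of configurations (normalization factor, threshold strictness,
percentile bins, zero-V handling, ...) and reports pairwise label
agreement and the consistently identified set — the analysis pattern of a
subjectivity audit, with the axes fully user-configurable.

Problem sizes used in the shipped tests and acceptance script — 200-basin
worlds (9,600 cells), up to 10,000 realizations on a 50-basin world
(400 cells), and 500/200 realizations on the 200-basin world — were chosen
as the smallest sizes at which the distributional properties under test
(heavy-tailed V, stable retention fractions) are comfortably resolved.

## Numerical choices and degenerate inputs

* Basins with `Q <= 0` are unscorable: every indicator returns `NA` and
  downstream tables flag rather than drop them. Division by zero never
  occurs silently.
* Head/Tail Breaks uses strict head membership (`v > mean`), which
  guarantees head shrinkage and termination; a head with fewer than two
  members or zero variance stops the recursion and the remaining members
  form the top class, so constant or near-constant inputs yield fewer
  classes, never an error.
* The E normalization maps the argmax basin to exactly 1; ties all attain 1.
* Fixture bundles serialize rasters at full double precision
  (`%.17g` ASCII grids), so a write-read round trip is numerically exact,
  and a JSON manifest with md5 checksums makes tampering detectable.
  Plain-text formats were chosen so bundles are portable, diffable and
  free of binary-format dependencies.
* A fixed master seed makes the whole pipeline bit-reproducible, including
  byte-identical CSV exports.

## Known limitations

The stress ratio treats within-basin withdrawal against within-basin
streamflow only — no upstream-downstream sharing rules and no special
handling of hyper-arid basins. Ecological sensitivity inherits the
coverage and biases of its two input proxies; the combination is
statistical (percentile-based), not process-based. Adaptive capacity is a
single generic national-development composite. The basin IWRM score is an
overlap-area-weighted mean of national scores — a population-weighted
alternative would change transboundary contrasts. None of the synthetic
defaults should be mistaken for calibrated reproductions of any real
dataset.
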