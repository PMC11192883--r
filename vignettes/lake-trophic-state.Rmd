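---
title: "Retrieving lake trophic state from multispectral reflectance: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving lake trophic state from multispectral reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeTSI)
```

## The problem and the model

Lake eutrophication is conventionally summarized by the Carlson trophic
state index, a 0–100 scale on which every 10-unit step corresponds roughly
to a doubling of algal biomass. Field measurement of the underlying
chlorophyll-a is sparse in space and time; multispectral satellites with
~30 m pixels can fill that gap, provided three problems are solved per
scene: finding the water, recognising which *optical type* of water each
pixel is, and inverting reflectance to TSI with a model appropriate to that
type. lakeTSI implements that chain.

The chlorophyll form of the index is

$$\mathrm{TSI} = 10\,(2.5 + 1.086 \ln \mathrm{Chla}),$$

with Chla in µg/L, and the five standard levels are oligotrophic [0, 30),
mesotrophic [30, 50), light eutrophic [50, 60), moderate eutrophic [60, 70)
and hyper eutrophic [70, 100]. The level boundaries are quoted in the
literature with shared endpoints ("0–30", "30–50"); we resolve the overlap
as half-open intervals with the boundary belonging to the upper level and
the final bin closed at 100 (`trophic_level()`).

The retrieval itself does not estimate chlorophyll. It uses the **algal
biomass index** (ABI): the difference between two linear spectral baselines
evaluated at the green wavelength, one drawn from blue to red, the other
from blue to near-infrared,

$$\mathrm{ABI} = (R - B)\,\frac{\lambda_G - \lambda_B}{\lambda_R - \lambda_B}
              - (NIR - B)\,\frac{\lambda_G - \lambda_B}{\lambda_{NIR} - \lambda_B}.$$

Note that the green reflectance itself cancels in this expression — ABI as
implemented is the difference of the two baseline *heights* at $\lambda_G$,
which is how the operational formula is printed. The original index
concept is described as a green-band height above a baseline; we implement
the printed formula verbatim and note the discrepancy rather than
second-guessing it. TSI follows from ABI by a per-type straight line,
`TSI = slope × ABI + intercept`, with the operational coefficients

```{r}
default_tsi_coefficients()
```

These coefficients are treated as data: `fit_type_model()` refits lines of
the same form from any matchup table, and `run_config()` lets a user swap
in their own.

## Water extraction and the decision tree

Water is found per lake: NDWI (`G − NIR`, the difference form — the
conventional normalized ratio is available behind the `ndwi_form` switch
but the difference form is the default because it is what the operational
chain prints) is thresholded by maximizing the between-class variance of a
256-bin histogram over the cloud-free pixels inside the lake outline
(`bimodal_threshold()`, Otsu's criterion; the specific bimodal method is
not specified in the method literature, and Otsu is the standard choice). The
resulting mask is eroded by 3 pixels (~100 m at 30 m resolution) with a
square structuring element to suppress mixed land–water boundary pixels;
the square element is our choice, since the printed "three-pixel buffer"
does not specify connectivity.

Water pixels then pass a fixed decision tree, in this order:

1. `FAI > 0.02` — floating algal scum, excluded from retrieval;
2. `−0.004 < FAI ≤ 0.02` — aquatic vegetation, excluded;
3. `G < 0.11` **or** `B > G` — clear water (type 3);
4. `TWI ≥ 0.076` — turbid water (type 2);
5. otherwise — algae-dominated water (type 1).

The *order* is a design decision: exclusions must precede typing, and the
clear-water test must precede the turbidity split because a clear pixel
also has small TWI and would otherwise be claimed by the algae-dominated
branch. The clear-water green threshold 0.11 is the rounded value of
μ + 2σ of surveyed oligotrophic-lake green reflectance (μ = 0.065,
σ = 0.021; `clear_threshold()` reproduces this arithmetic). The source
material also mentions removing "high suspended" pixels with `FAI < −0.01`,
which conflicts with typing turbid water via TWI (almost all turbid pixels
have strongly negative FAI). We resolve the conflict by keeping those
pixels as water by default and exposing a `strict_fai` mode that flags them
invalid, off by default.

Cloud handling follows the QA layer: medium and high cloud confidence are
masked, clear and low confidence are kept. For real Collection-1 `pixel_qa`
rasters the cloud-confidence bits must be decoded to these four categories
by the reader; the package's own scene format stores the category codes
directly.

Sensor wavelengths are registered per instrument (OLI green/red/NIR/SWIR at
563/665/865/1609 nm; TM and ETM+ at 560/660/835/1650 nm). Blue band
centres are not part of the printed operational constants, so we default to
the nominal centres (482 nm OLI, 485 nm TM/ETM+), overridable in
`sensor_spec()`. Cross-sensor harmonization is exposed as a per-band linear
hook (`harmonize_scene()`), defaulting to the identity.

## Inversion, aggregation and trends

Per-pixel TSI is the type's line applied to the pixel's ABI, clamped to
[0, 100]: the Carlson scale is defined on 0–100 and out-of-scale retrievals
carry no extra information; clamping events are counted and reported
(`n_clamped`) rather than silently discarded, since whether the published
records clamped or dropped such values is unstated.

Per-scene lake summaries are arithmetic means over retrieved pixels with a
coverage percentage (retrieved / total outline pixels). Annual records
average per-scene means with equal weight per observation date — not pooled
pixels — so that a single well-covered scene cannot dominate a year; the
annual pixel count is the rounded mean of per-scene counts (the published
column description is ambiguous between mean and maximum; we chose the
mean as consistent with the equal-weight rule). The long-term average is
the unweighted mean over non-missing years.

Trends use the Mann–Kendall test with the tie-corrected variance
$n(n-1)(2n+5)/18 - \sum_t t(t-1)(2t+5)/18$, a continuity-corrected normal
deviate, and the Sen slope as the median of pairwise slopes over the
*actual* year spacing, so gap years neither break the test nor distort the
slope. The significance level defaults to α = 0.05 (the published trend
maps are ambiguous between 0.05 and 0.01; 0.05 is the level stated with
the released records, and α is configurable). Series with fewer than four
values return "no trend" with a warning rather than an unreliable normal
approximation.

## The synthetic generator: what it emulates and what it does not

`simulate_scene()` is a forward model of exactly the statistical structure
the pipeline assumes: a land background with NDWI well below zero,
elliptical lakes whose vector outline includes a small land collar (so the
in-outline NDWI histogram really is bimodal, as it is for real outlines
that bound the water), per-class pixel fractions realized by
largest-remainder integer allocation (exact to one pixel), a true TSI
field that varies as a smooth gradient within each type's range, floating
scum and vegetation pixels with diagnostic FAI signatures, cloud blobs
grown by seeded random walks, and optional Gaussian band noise added last.

Water spectra are constructed by `solve_bands_for_abi()`: given a target
ABI, it fixes blue/green anchors and FAI/TWI operating points from a
feasibility ladder and solves the red/NIR/SWIR bands in closed form, so the
generated pixel evaluates to the target ABI at machine precision *and*
classifies back to the intended type. Spectra are confined to [0, 0.6]
reflectance for physical plausibility. A consequence worth knowing: under
the clear-water constraint set, no admissible spectrum yields ABI below
about −0.165, so clear-water (type 3) pixels cannot represent TSI above
roughly 35. That is consistent with the limnology the classifier encodes —
clear pixels are oligo/mesotrophic — and the default recipes assign type-3
TSI in [22, 33]. Default ranges for the other types are type 1 (algae
dominated) [58, 72] and type 2 (turbid) [45, 60], spanning the eutrophic
levels where those optical types occur.

Matchup simulation draws chlorophyll lognormal (meanlog 2, sdlog 1 on the
log scale, spreading TSI across all five levels), clips the trophic signal
to the observed [20, 90] range, derives ABI exactly from the type model and
adds Gaussian noise to the *measured TSI*. Putting the noise on the
response rather than on ABI is deliberate: with noisy ABI and exact TSI the
refit would be an errors-in-variables problem whose OLS slope attenuates by
the factor R², and coefficient-recovery checks against the generating
values would be structurally impossible. With response noise, the refit is
the standard OLS model and 95% confidence intervals cover the generating
coefficients at their nominal rate. `noise_sd_for_r2()` converts a target
fit strength (e.g. R² ≈ 0.66 at n = 310) into the implied noise level.

What the generator does **not** emulate: radiative transfer, sun glint,
atmospheric residuals, sensor noise spectra, SLC-off striping, mixed
pixels, or real lake morphometry. Passing the round-trip tests therefore
demonstrates the internal consistency and exactness of the implementation
(masking, thresholding, erosion geometry, classification logic, inversion
algebra), not retrieval accuracy on real imagery — that is what the matchup
validation metrics (`score()`) are for, on real matchup data.

## Numerical choices and degenerate inputs

- **Thresholding** needs at least two distinct values; constant samples
  raise a degenerate-histogram error. Where the between-class variance is
  flat (an empty gap between modes) any maximizing cut is acceptable; the
  implementation is deterministic for fixed input.
- **Reflectance validity**: values outside [0, 1] are accepted (surface
  reflectance products can exceed the physical range) but counted on the
  scene object (`n_out_of_range`).
- **Integer-scaled inputs** (the ×10000 surface-reflectance dialect) are
  rescaled by the reader when the value range implies it — never by index
  code.
- **Raster storage** uses 32-bit float TIFF plus a JSON sidecar for
  georeferencing and sensor metadata, with an explicit validity page for
  missing TSI values; round trips are exact to single precision.
- **Ties and gaps** in trend series are handled by the tie-corrected
  variance and by dropping missing years (with true year spacing in the
  Sen slope); `Z` is 0 when the variance degenerates.
- **OLS fits** require ≥ 3 matchups and non-constant ABI; exact fits are
  legitimate (noise-free case) and reported with R² = 1.

## Problem sizes used by the test suite

The acceptance checks run a 256 × 256 scene with three lakes covering all
five water-surface classes plus cloud; 20 random scenes against a naive
per-pixel classifier oracle; 500 random series against a brute-force
Mann–Kendall oracle; 200 seeded replicates of the coefficient-recovery
experiment at the training sample sizes (n = 310, 272, 71 with fit
strengths R² ≈ 0.66, 0.67, 0.66); and 200 replicates each of the trend
power (slope 0.3 TSI/yr, σ = 2, 40 years) and type-I error (slope 0)
experiments. These sizes give stable Monte-Carlo estimates (binomial
standard errors under 2 percentage points) while keeping the whole suite
fast.

## Known limitations

- The published national-scale coefficients ship as defaults, but their
  training matchups are not public; nothing in this package can reproduce
  the original coefficient table from raw data, only refit models of
  the same form.
- The regression R² reported by `score()` for a simple straight-line fit
  equals the squared Pearson correlation and is therefore symmetric in its
  arguments; asymmetric alternatives (R² about the 1:1 line) were
  considered and rejected as the primary metric because the operational
  validation quotes the regression-line R².
- GeoTIFF georeferencing is carried in a JSON sidecar rather than embedded
  TIFF tags; GIS tools will read the rasters but not their CRS without the
  sidecar.
- Shapefile outlines are not read; use GeoJSON.
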