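---
title: "Models and methods behind waterscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind waterscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterscape)
```

## The problem

Urban waterfront green spaces are graded on how well three things line up:
the measurable quality of the **space** itself, the **psychological**
response of visitors, and visitors' actual **behavior**. waterscape
implements that three-dimensional evaluation as a reusable pipeline: twelve
formula-defined spatial indicators, composite scores and natural-breaks
grades, sentiment-derived relative emotional statistics, heat and
kernel-density behavioral metrics, and a coupling–coordination model that
quantifies how balanced the three subsystems are. A synthetic-scene
generator replaces field data so that every stage is testable end to end.

## The spatial model

The space aesthetic value index groups twelve indicators into three
criterion blocks:

* **Horizontal space** (land-cover structure): C1 Shannon–Wiener diversity
  $H = -\sum_i p_i \ln p_i$ over the nine vegetation-structure classes; C2
  Pielou evenness $J = H/\ln S$; C3 hemeroby
  $HI = \sum_i i\,S_i / (h\,S_A)$, the area-weighted human-disturbance
  degree scaled by the number of degrees $h$; C4 fragmentation $N/A$,
  8-connected patches per hectare (the Fragstats default connectivity).
* **Vertical space** (scene structure): C5 layer superposition
  $PA = T/F$, the trace over the total of a layer-transition tally; C6
  opponent-channel colorfulness
  $C = \sigma_{rgyb} + 0.3\,\mu_{rgyb}$ with $rg = R-G$,
  $yb = (R+G)/2 - B$; C7 terrain position $P = H_g - \bar H_i$ (centre
  minus 8-neighbour mean); C8 profile curvature
  $K_p = -(rp^2 + 2spq + tq^2)\,/\,[(p^2+q^2)(p^2+q^2+1)^{3/2}]$.
* **Three-dimensional space** (volume and openness): C9 sky fraction
  (sky pixels / all pixels, averaged over a park's panoramas); C10
  tridimensional green biomass
  $V = \sum \Delta d^2\,|h_{ij} - H_{ij}|$ over vegetated cells; C11
  canopy density $A_{canopy}/A_{plot}$; C12 relief amplitude
  $E_{\max} - E_{\min}$.

Raw indicators are min–max normalized with **config-supplied bounds**: the
published scheme cannot be a cross-park min–max (no indicator column
attains both 0 and 1, and one park's C7 is negative), so bounds are an
explicit input and identity bounds `(0, 1)` consume already-normalized
tables unchanged.

**Arithmetic, not geometric, composites.** The published methodology text
says a geometric average, but the printed composite values are reproduced
exactly by arithmetic block means and are impossible under geometric
aggregation (terrain-position values near zero would collapse any
product). We treat the wording as a terminology slip; both aggregators are
implemented and arithmetic is the default.

**Rounding.** Reported values use R's `round()` (half-even) at the
published precisions: 4 decimals for indices and thermal/density values, 1
for emotional values and rates, 3 for coupling quantities. Five published
composite values sit on exact `.00005` ties which the source resolved
inconsistently (four up, one down — evidence it rounded unrounded inputs);
the acceptance tests therefore allow one printed ulp on those tie rows and
demand exact agreement everywhere else.

**Grading** uses exact Jenks natural breaks: the Fisher dynamic program
that provably minimizes the within-class sum of squared deviations, not
the common iterative heuristic — determinism matters more than speed at
n = 12. Class 1 is the highest-value block. Four-class membership of the
published overall column ships as a labeled fixture (`levels.csv`) rather
than being asserted as algorithm output, because the published grade
boundaries are not recoverable exactly from the printed values.

### Numerical choices

* Finite differences for C7/C8 are central differences on a
  replicate-padded grid; cells whose squared gradient falls below
  $10^{-6}$ get $K_p = 0$ (the formula's denominator vanishes on flats).
* Park-level C7 and C8 are plain means of per-cell values — the only
  aggregation consistent with a negative published park value.
* C5's transition matrix is built by splitting each panorama into six
  equal vertical bands, taking the modal layer label per band and column,
  and tallying consecutive band pairs. The construction is this package's
  own (no published recipe exists) and is flagged as such in run logs.
* The colorfulness statistics use the full pixel population (population
  variance), in double precision.

## The psychological model

Review records carry a park id, a target (`landscape` for reviews
addressing the landscape itself, `park` for general park evaluations —
two disjoint row sets) and text. A pluggable scorer maps text to the 0–10
emotional-value scale; the default is a transparent lexicon scorer,
$5 + 5(\mathrm{pos}-\mathrm{neg})/(\mathrm{pos}+\mathrm{neg})$, neutral 5
with no hits. It stands in for the original (untranslatable,
engine-specific) Chinese sentiment pipeline, whose published contract is
only the scale and the positive threshold at 5.

Per park we report the landscape relative evaluation rate
$100\,n_{ls}/n_{park}$, both emotional values (means by target, 1
decimal), and the relative emotional value — the ratio of landscape to
park emotional value, computed on unrounded means and then rounded
(7.8/4.5 = 1.73 → 1.7). A value above 1 means the landscape itself
attracts perception beyond the park baseline. An OLS regression of
relative emotional value on relative evaluation rate (with the two-sided
slope p-value) tests whether landscape experience predicts emotional
perception. The originally reported fit (R² = 0.398, p = 0.028) is *not*
recoverable from the rounded published columns — the package reports its
own fit instead of targeting those numbers.

## The behavioral model

Heat snapshots are grids on a 1–8 crowd-presence scale; the thermal value
is the mean over all masked cells of all snapshots, graded with
upper-inclusive thresholds `[1,2] → low`, `(2,5] → sub`, `(5,8] → high`
(the printed interval labels put 2.0 and 5.0 in the lower grade).
Visitor points get a Gaussian kernel density scaled so the surface
integrates to the person count (persons/m²); the bandwidth comes from
config, defaulting to Silverman's two-dimensional rule
$\sigma\,n^{-1/6}$. The default evaluation grid extends five bandwidths
past the points so mass conservation is testable to 1%; a park-bounded
grid truncates boundary mass rather than silently renormalizing.
Density grades use 3-class natural breaks across parks. Behavior
observations map recorded activities to five recreation-purpose
categories through a config map and report the frequency ranking and mean
recreation time.

## The coupling–coordination model

Each park's three subsystem scores (spatial overall composite, relative
emotional value, and a behavioral composite — the mean of min–max scaled
thermal and density values) are min–max scaled across parks to
$[0.01, 1]$; the 0.01 floor keeps the coupling product away from an
annihilating zero. Then

$$C = \left[\frac{\prod_i u_i}{\left(\bar u\right)^k}\right]^{1/k},
\qquad T = \sum_i w_i u_i, \qquad D = \sqrt{C\,T},$$

with equal weights by default and $k = 2$ or $3$ subsystems. $C$ is the
geometric-to-arithmetic mean ratio: 1 exactly when the subsystems are
equal ("high coupling"), small when they diverge. $D$ is graded on a
ten-level ladder with upper-inclusive 0.1-wide bins, from extreme
maladjustment (level 1) through excellent coordination (level 10). The
published three-subsystem formula is never printed; this standard form
satisfies every printed $(C, T, D)$ consistency check across all 48
reference rows within 0.001. Reference label columns of the
two-subsystem tables are internally inconsistent, so only the
three-subsystem table's labels are treated as authoritative for the
ladder.

## What the synthetic generator emulates — and what it does not

`scene_spec()` fixes a park's world: class proportions realized *exactly*
(rank thresholding of a smoothed Gaussian field, so patches are contiguous
while counts match to integer rounding), relief hit exactly by rescaling,
canopy heights with chosen mean/spread, banded panoramas whose sky share
is exact to one pixel row with ground-truth masks and layer labels,
token-sequence reviews whose expected emotional value is
$10 \times$ the positive fraction, Gaussian-bump heat fields clipped to
[1, 8], and visitor points drawn from the same bumps so heat and density
agree spatially. Every generator is a pure function of the spec and seed.

Defaults state the emulated world once: 100×100 cells of 10 m (the
land-use product's accuracy), patchiness radius 3 cells, 7 m relief, 6 m
mean canopy, 30% sky, review and visitor volumes typical of a mid-sized
riverside park. They are documented here and not tuned against tests.

A green test on synthetic scenes establishes that the *computations* are
correct against known truth. It does not establish that real land-cover
products, photography, social-media text, or heat-map snapshots behave
like the generator: synthetic reviews are token sequences, not language;
heat bumps have none of the temporal structure of real crowd data; and
panoramas have no lens distortion or mixed pixels.

## Design choices made where the design was open

* **Fixture-driven reproduction.** Raw field data are not available, so
  the published per-park tables ship as CSV fixtures and the headline
  checks run the package's own operators over them (identity
  normalization bounds make that exact).
* **Raster and image formats.** No GeoTIFF/PNG reader exists in the
  target environment, so rasters travel as Esri ASCII grids and images as
  ASCII netpbm (PPM/PGM) — both plain text, both round-tripping exactly.
* **Green volume normalization.** C10 is reported as volume *density*
  (m³ of canopy per m² of park) in the indicator table so parks of
  different sizes share one normalization bound; `green_volume()` itself
  returns m³ as defined.
* **Hemeroby degrees** are configuration (default: a 7-degree ladder with
  water 1, forests 2, shrubs 3, grass 4, hardscape 7) because the source
  never prints its assignment; making it explicit config restores
  reproducibility.
* **Sky segmentation** for real photos is a documented HSV-style
  threshold rule, not a learned model; synthetic scenes carry truth masks.

## Known limitations

* The rate–emotion regression on the rounded fixture differs materially
  from the originally reported fit; the package documents its own fit.
* Per-park kernel-density magnitudes depend on bandwidth and grid choice;
  only mass conservation and limiting behavior are guaranteed, and no
  published density value is asserted.
* The four-level Jenks grading of the overall column does not exactly
  reproduce the published level membership (shipped as a fixture instead).
* CJK text needs a caller-supplied segmenter; the default tokenizer is
  whitespace-based.
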