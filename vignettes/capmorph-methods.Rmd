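---
title: "capmorph: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capmorph: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmorph)
```

## The measurement problem

Reperfusing an occluded coronary artery saves myocardium but can injure the
microcirculation it feeds: capillary walls thin and rupture, endothelial
nuclei condense their chromatin as they die, inter-endothelial junctions
disappear, and tracer particles extravasate — most severely in an infarct
core that becomes inaccessible to flow altogether (no-reflow). These injuries
are read out on three modalities with very different geometry: single-capillary
transmission electron micrographs that are delineated by hand, stained
sections on which capillaries are counted in fixed frames, and two-channel
fluorescence images of tracer and endothelium. `capmorph` implements the
quantitative layer for all three, and a synthetic generator that makes every
estimator testable by round-trip recovery.

## Per-capillary morphometry

A capillary annotation consists of simple polygons (outer vessel boundary,
lumen, zero or more nuclei) in 0-based pixel-centre coordinates, plus point
marks for caveolae (with a diameter in nm) and junctions. All areas are
shoelace areas scaled by the per-image calibration (nm/pixel, always supplied
by the user — magnification varies between acquisitions and embedded
resolution tags are not trusted). Cytoplasm area is defined as
`total - lumen - sum(nuclei)`, so the conservation identity is exact for
every measured capillary and a negative value is an annotation error, not a
number.

**Wall thickness.** "Cytoplasm area divided by cytoplasm perimeter" is
ambiguous for an annulus, which has two boundaries. We divide by the
*midline* perimeter, the mean of the outer and luminal boundary lengths: for
any convex lumen with perimeter $P$ offset outward by a constant width $w$,
the wall area is exactly $w\,(P + \pi w)$, which is $w$ times the midline
perimeter — so the estimator returns the true width in the constant-width
limit. Dividing by the *sum* of the two boundaries (a plausible alternative
reading) would systematically halve the thickness; both alternatives remain
available via `convention = "outer"` / `"summed"` for sensitivity analysis.
Nucleus boundaries never enter the perimeter: nuclei sit inside the wall and
do not bound the lumen.

**Chromatin density variation.** CDV is the sample standard deviation
(n − 1) of grey values of pixels whose centres fall inside the nucleus
polygon. Pixel membership uses the even-odd rule with half-open edges
(`ymin <= y < ymax`, `x < x_cross`), which is deterministic,
orientation-independent, and makes adjacent polygons partition pixels without
overlap. CDV magnitudes of 20–50 presuppose an 8-bit intensity scale, which
the generator adopts for TEM scenes. CDV is invariant to adding a constant to
all intensities and scales linearly with intensity gain, so it should only be
compared within a fixed acquisition protocol.

**Multiple nuclei.** The per-capillary CDV is computed on the largest
nucleus; `nucleus_area_um2` sums all nuclei. The source data report a single
CDV per capillary without a pooling rule, and the largest nucleus is the most
robust single choice (most interior pixels).

## Capillary density

Per-frame density is count / frame area; the estimate across frames is the
mean and SD of per-frame densities, which is unbiased for a homogeneous
Poisson field and invariant to subdividing frames. The counting frame is
200×200 µm (the printed "200x200 mm²" is a unit slip — a 4 cm frame cannot
fit a rodent heart section). TEM-based density divides visible capillary
counts by section area; the surveyed section area is not stated in the source,
so the presets fix it at 0.04 mm² (a 200×200 µm montage), which gives the
20-section acceptance recovery a standard error of about 2.8%. The edge rule
for synthetic counting is centroid-inside (counts are Poisson draws at
intensity × area, the distribution this rule induces under translation
invariance).

## Leakage metrics

Zone MFI is the arithmetic mean intensity under a boolean mask; leakage is
the infarct/control MFI ratio (infarct = core ∪ border unless a single
infarct mask is supplied), with border/control and core/control reported
separately because their divergence — tracer crowded into the border, absent
from the core — is the no-reflow signature. The colocalisation fraction is
computed over *sphere-positive* pixels: binarise both channels, return
|spheres⁺ ∩ CD31⁺| / |spheres⁺|. The source does not state its binarisation;
the default is Otsu per channel, fixed cut-offs are available, and the
thresholds used are always attached to the result. Note that Otsu on a
strongly zone-heterogeneous sphere channel can place its cut between diffuse
zone levels rather than between diffuse signal and sphere dots; for
quantitative comparisons with the generator's ground truth, use the fixed
thresholds it records. Background subtraction is off by default (none is
described in the source protocol).

## The synthetic generator

The generator produces geometric phantoms, not photorealistic micrographs:
enough structure for every measurement operator, with exact ground truth.

**Capillary scenes.** The lumen is an ellipse (aspect ratio uniform on
[1, 1.6]); the outer boundary is its outward parallel curve at a distance
solved per draw so that the *measured* thickness (cytoplasm area over midline
perimeter, nucleus excluded) equals the drawn wall thickness; the nucleus is
a crescent lodged in the wall between 5% and 95% of the wall depth, its
angular span solved so its polygon area matches the drawn nucleus area. Wall
thickness, lumen area, nucleus area and chromatin SD are truncated-normal
draws from the preset; caveola and junction counts are Poisson draws; caveola
diameters are truncated normal. Draws whose nucleus cannot fit in the wall
annulus (angular fraction > 0.92) are redrawn — this consistency enforcement
truncates only the extreme joint tail. The rendered 8-bit raster uses a
bright lumen (230), dark wall (90), noisy background (200), and i.i.d.
Gaussian chromatin texture of the drawn SD centred at mid-grey.

Because the printed group values are mutually inconsistent with the
geometric identities (the published areas imply a ~645 nm wall for the
30-minute group where 407.8 nm is printed), the generator *drives* geometry
with lumen area, nucleus area and wall thickness and lets cytoplasm and total
area follow from the constructed contours. Total vessel area in the preset is
kept as documentation; all other preset parameters are recovered by the
pipeline within sampling error.

**Chromatin clipping.** An 8-bit Gaussian texture at σ = 50.5 centred at
127.5 cannot clip less than ≈1.2% of its mass, so for the widest preset the
clipping fraction slightly exceeds the 1% design goal; censoring shaves the
realized SD by ≈1% there (recorded per scene in the ground truth as
`realized$cdv_grey` next to the drawn σ, together with the clipping
fraction). The CDV acceptance checks use `generate_nucleus_texture()`, which
pins σ at the preset value: the 3% recovery tolerance is an estimator
tolerance, and drawing σ per capillary (between-capillary SD 3.8) would
inflate the 20-nucleus sampling error past it by itself.

**Fluorescence fields.** Three vertical zone bands (core, border, control)
separated by small gaps. The sphere channel is zone-scaled diffuse signal
plus bright dots whose per-zone expected count also scales with the zone
ratio, so the expected MFI ratio equals the preset ratio exactly. For the
reperfusion preset the headline infarct/control ratio of 3 is split with a
border:core weighting of 29 (border ≈ 5.8×, core ≈ 0.2× control) — tracer
crowding the border of an inaccessible core; the pure-ischemia presets are
homogeneous. Each dot lands on a CD31-positive pixel with probability equal
to the colocalisation target (25%), independently — binomial placement — and
the generator records its fixed separation thresholds (dots at +40 000 on a
16-bit scale, diffuse signal well below the 30 000 cut).

**Cohorts.** Per animal, Gaussian parameters are drawn in two levels: an
animal-level mean from the group distribution scaled by √ICC (default
ICC = 0.3, configurable), capillary draws around it scaled by √(1−ICC). The
source's "±" dispersions are treated as between-subject SDs by default; a
`dispersion = "sem"` preset flag rescales by √n if they were standard errors.
Poisson mark counts use fixed group rates (their between-animal variation is
not separately printed). Counting frames and one fluorescence field per
animal complete the tree, which the CLI consumes unchanged; a master seed
fully determines every artefact, including the manifest hash.

**Preset values chosen, not transcribed.** Caveolae per capillary are shown
only graphically in the source; the presets use 4 (30-min), 8 (90-min,
endothelial activation increases caveolae), 2 (reperfusion, significantly
fewer than 90-min), reproducing the reported ordering. Control-zone wall
thickness (400 nm) and CDV (45 ± 8) reflect "no difference between groups in
the control zone" and the statement that the reperfusion-group CDV fell
significantly below control; control lumen areas derive from the printed
within-group mean differences. These are fixed once and not tuned.

## Statistics

The experimental unit is the animal: per-animal means over ~20 capillaries
enter the tests, not per-capillary values, to avoid pseudo-replication.
One-way ANOVA is computed from sums of squares with $F = \mathrm{MS}_B /
\mathrm{MS}_W$ on $(k-1, N-k)$ degrees of freedom. Tukey HSD uses the
Tukey-Kramer standard error for unbalanced groups and the studentized-range
distribution implemented here by 2-D Gauss-Legendre quadrature (240 nodes per
axis) of

$$P(Q \le q) = \int_0^\infty g_\nu(s)\; k \int_{-\infty}^{\infty}
\varphi(z)\,[\Phi(z) - \Phi(z - qs)]^{k-1}\, dz\, ds,$$

with $g_\nu$ the scaled-chi density of the root-mean-square error estimate.
The implementation matches the exact $k=2$ closed form
$2\,T_\nu(q/\sqrt2) - 1$ and adaptive quadrature of the defining integral to
about 1e-8; base R's `ptukey` agrees to 1e-6 for ν ≥ 6 and is itself the
less accurate party at ν ≤ 3. The quantile function inverts the CDF by
bisection. t-tests are pooled-variance by default (the source does not state
the variant) with Welch as a flag; two constant identical samples give p = 1
by convention. No normality or variance-homogeneity gating is applied, since
none is described in the source protocol. A permutation oracle
(`anova_permutation_p`) validates the parametric ANOVA on small fixtures;
note the parametric and permutation p-values agree only up to the intrinsic
small-sample gap between the two distributions, which can exceed the Monte
Carlo standard error for some datasets.

## What a green test establishes — and what it does not

The generator emulates: annular cross-section geometry with group-specific
wall thickness, controlled chromatin grey-value dispersion, Poisson
mark counts and frame counts, and zone-structured two-channel fluorescence
with exact colocalisation placement. It does **not** emulate: membrane and
organelle texture, annotation error (polygons are the exact generating
contours), partial-volume and focus effects, stain variability, spatial
clustering of capillaries, or detection loss in either modality (the
IHC < TEM density gap is represented only by different preset intensities).
Green round-trip tests therefore establish that the *estimators* are correct
and calibrated on their stated models — not that the upstream imaging and
annotation process is unbiased.

## Numerical choices and degenerate inputs

- Polygons: implicit closure; repeated closing vertices deduplicated;
  simplicity validated by pairwise segment tests on load; < 3 distinct
  vertices is an error.
- Rasterization: vectorized even-odd scanline fill, identical by
  construction to the pixel-centre point-in-polygon rule.
- Zero-width annulus gives thickness 0; zero perimeter errors; empty zone
  masks and zero control MFI error rather than return NaN; a colocalisation
  denominator of zero sphere pixels errors ("undefined fraction").
- Truncated-normal draws use rejection sampling with bounds far from preset
  means; Poisson and binomial draws use base R generators under a private
  RNG stream that restores the caller's `.Random.seed`.
- File formats: uncompressed baseline greyscale TIFF (8/16-bit) and
  non-interlaced greyscale PNG, both read and written in pure R (zlib via
  `memCompress`); multi-channel or palette images are rejected with an error
  naming the file. Calibration is never read from image metadata.

## Known limitations

- The morphometry operates on manual (or generated) annotations; there is no
  automatic segmentation, by design.
- The CDV statistic depends on acquisition settings (gain, exposure); only
  within-protocol comparisons are meaningful.
- Preset dispersions conflate between-animal and within-animal variance; the
  two-level ICC split is an explicit modelling choice (default 0.3), not an
  estimate from data.
- The studentized-range quadrature covers the parameter ranges of routine
  group comparison (k ≤ ~20, any ν ≥ 2); extreme tail probabilities beyond
  |1 − p| < 1e-10 are not resolved.
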