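---
title: "Quantifying subcellular immunogold labelling with goldmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular immunogold labelling with goldmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldmap)
```

## The measurement problem

Pre-embedding immunogold electron microscopy marks an antibody-bound
epitope with a silver-enhanced gold particle. Because the particle is
electron dense and essentially point-like at the magnifications used for
synaptic ultrastructure, counting particles against annotated membranes
yields quantitative estimates of where a membrane protein — here the
A-type potassium channel subunits Kv4.2 and Kv4.3 in hippocampal
neurons — actually sits: on the plasma membrane or at intracellular
sites, in postsynaptic spines and shafts or presynaptic terminals, near
to or far from the postsynaptic density (PSD), and at what density on
each somato-dendritic compartment.

goldmap implements that quantification as a reusable pipeline over
annotated "scenes": membrane contours (2-D polylines in nm, image
convention with y increasing downward), synaptic specialisations stored
as arc-length intervals on their parent contour, compartment profiles
(spine, dendritic shaft, main dendrite, spiny branchlet, soma, axon
terminal), and gold-particle coordinates. Scenes are serialised in a
versioned JSON schema (`goldmap-scene/1`) with a plain CSV dialect for
particle tables, so annotations from any tool can be converted in.

## The three quantification schemes

**Compartment percentages.** Each particle is assigned to the profile
whose closed contour contains it; particles contained in no contour
(e.g. annotations on partial profiles at the micrograph border) are
attached to the nearest membrane if that membrane is within the
membrane threshold, and otherwise excluded with a logged count. A
particle is *membrane-associated* iff its projection distance onto its
profile's membrane is at most `membrane_threshold_nm`. Percentages use
two denominators, stated explicitly in the output metadata: membrane vs
intracellular over all assigned particles, and post- vs presynaptic over
membrane particles only. This matches how such results are convention-
ally reported, and the two conventions are not interchangeable — the
package records both denominators rather than leaving them implicit.

**PSD-distance binning.** For membrane particles on spines bearing an
asymmetric (excitatory) synapse, the arc distance from the particle's
projected membrane position to the nearest lateral edge of the PSD is
computed and binned into half-open 60-nm membrane segments
`[0, 60), [60, 120), ...` starting at the PSD edge. Distance is measured
*along the membrane* (arc length), not as a straight line: the
measurement protocol this emulates traces the spine membrane from the
edge of the synaptic junction, and on a closed spine outline the shorter
way around is taken. Particles projecting inside the PSD interval are
retained at distance 0 with a synaptic flag rather than excluded,
because labelling does occur along the main body of the synaptic
specialisation. The summary statistic `fraction_within` sums the first
`proximity_radius_nm / bin_width_nm` bins; under half-open bins this is
identical to directly counting distances strictly below the radius, so a
distance of exactly 300 nm falls outside the 300-nm annulus. That
equivalence is asserted by a test.

**Somato-dendritic density gradient.** Membrane particles are pooled per
domain — soma, main dendrite, spiny branchlets and spines split into
inner-third and outer-two-thirds molecular layer — and divided by the
pooled profile cross-section area (areal density, particles/µm²) and by
the pooled membrane length (linear density, particles/µm). Source
reports of such gradients are ambiguous between the two units, so both
are always computed and the areal one is the default report; the
discrepancy is surfaced, not resolved. Between-block variability is the
SEM of per-block densities with the animal as the block unit.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `membrane_threshold_nm` | 25 | max projection distance to call a particle membrane-associated; reflects the localisation accuracy of silver-enhanced 1.4-nm gold with pre-embedding labelling (particle sits on the cytoplasmic face, displaced by the antibody bridge) |
| `bin_width_nm` | 60 | PSD-distance bin width (membrane segments) |
| `proximity_radius_nm` | 300 | near-PSD annulus; must be an integer multiple of the bin width |
| `density_mode` | `"areal"` | which domain density to headline; both are computed |
| pooling `alpha` | 0.05 | pairwise-KS threshold below which pooling across blocks is refused |

The 25-nm membrane threshold deserves a note: annotation conventions
rarely define "attached to the plasma membrane" numerically, so the
threshold is exposed in `quant_config()` rather than hard-coded, and the
synthetic generator places membrane particles 2–20 nm inside the
membrane and intracellular particles at least 30 nm deep, so that every
generated label is at least 5 nm from the decision boundary and label
recovery can be asserted at 100%.

## Statistics

Two nonparametric procedures accompany the pipeline, matching standard
practice for this kind of morphometric data:

- `ks_two_sample()` computes the exact supremum of the ECDF difference
  (ties handled exactly) with the asymptotic Kolmogorov p-value at the
  effective sample size, switching to the exact small-sample p-value
  when both n ≤ 10. `pooling_check()` applies the block-pooling rule:
  distance samples from different animals are merged only when the
  smallest pairwise KS p-value is at least `alpha` (0.05 — pooling
  reports in the literature state only the observed p, not the
  threshold, so the conventional 0.05 is used and recorded).
- `kruskal_dunn()` wraps the tie-corrected Kruskal–Wallis test
  (`stats::kruskal.test`) and adds Dunn's z post hoc comparisons for all
  pairs from pooled mid-ranks, with Bonferroni adjustment by default.
  The adjustment is configurable; Bonferroni is the conservative and
  most common choice where the post hoc method is otherwise
  unspecified.

## Histoblot densitometry

`measure_roi()` averages the pixels whose centers fall strictly inside
an open circular cursor of physical diameter 0.10 mm (pixel-center
membership is deterministic and standard; a cursor clipped by the image
border is an error naming the ROI). `background_correct()` subtracts the
mean of eight background determinations taken near the tissue and floors
the result at zero, since densities are reported in non-negative
arbitrary units. `developmental_profile()` averages corrected densities
with each animal's regional mean as one observation and normalises each
region's curve to its maximum. No flat-field or gamma correction is
applied: the module assumes all images were acquired and processed
identically, and documents that assumption rather than modelling
acquisition differences. Whether darker or brighter pixels mean more
signal depends on the scanner; the reader treats higher values as more
signal and offers `invert` for the opposite convention.

## What the synthetic generator emulates

`build_preset_scene()` produces fully annotated scenes whose ground
truth carries frozen reference parameters, so every pipeline stage can
be tested end to end without image data:

- **Spine-field presets** (`ca1-kv42`, `ca3-kv42`, `dg-kv42`,
  `ca3-kv43`, `dg-kv43`) build 93 roughly elliptical spines (perimeter
  1.5–3 µm, one asymmetric synapse of 150–300 nm each, an apposed axon
  terminal across a 30-nm cleft) plus dendritic shafts, split across
  three synthetic animals to exercise the pooling rule. Particle counts
  are deterministic transforms of the frozen totals and percentages
  (membrane count from the membrane fraction; presynaptic count from
  the postsynaptic-of-membrane fraction; the reported spine-analysis n
  taken as the membrane-spine subset, with the remaining postsynaptic
  membrane particles on shafts), so count contracts hold exactly at
  every seed, while placement is stochastic: each spine membrane
  particle is within 300 nm of the PSD edge with the preset probability,
  uniform within `[0, 300)` nm and uniform beyond up to half the
  extrasynaptic membrane length. Uniform placement profiles are the
  deliberate default because aggregate reports print only the 300-nm
  fraction, not the full bin profile.
- **Granule-cell presets** (`dg-granule-kv42`, `dg-granule-kv43`) build
  the six somato-dendritic domains (about 100 µm² of soma, 22 µm² of
  main dendrite, 12 µm² per branchlet class and 23–25 µm² per spine
  class per seed) and draw each profile's membrane-particle count as
  Poisson with the frozen areal intensity. Only membrane particles are
  simulated here, since the gradient analysis counts nothing else.
- **Histoblot phantoms** place rectangular regions of known grey level
  on a uniform background with optional Gaussian pixel noise and emit a
  matching cursor set, so the corrected densities have closed-form
  ground truth.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: membrane tracing and synapse identification
errors, section-thickness and labelling-efficiency effects, profile
shapes beyond ellipses and rectangles, spatial clustering of channels
beyond the two-zone PSD-distance model, and optical artefacts in
histoblot scans. Recovery tests certify the *quantification*, not the
annotation.

## Numerical choices and degenerate inputs

- Projection returns the global minimum over all segments with ties
  broken towards the smallest arc coordinate, making results
  deterministic; the projection distance is 1-Lipschitz in the query
  point (asserted by a property test).
- Closed-contour arc distances take the shorter direction and never
  exceed half the contour length.
- Wrapping synapse intervals on closed contours carry an explicit
  `wraps` flag instead of an ambiguous `s_end < s_start` encoding.
- Scene JSON is written at full floating precision, so round trips are
  bit-exact; derived classification travels under a separate `derived`
  key and is always recomputed, never trusted.
- Degenerate inputs fail loudly and specifically: empty scene
  directories, empty distance vectors, all-intracellular scenes (the
  pre/post table gets an explicit zero-denominator flag), domains with
  zero area (excluded with a warning), identical samples in the
  Kruskal–Wallis test (H = 0, p = 1, no post hoc).

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
scenes at the scale of the emulated study: 93 spines and 1355–3075
particles per spine-field dataset, 87 profiles and ~190 particles per
granule-cell dataset, 20 replicate seeds for stochastic recovery checks
(pooling ≥ 2000 µm² of soma area for the lowest-density domain), 100
random contours for the geometry oracle, and 2000 null replicates for
the type-I-error check of the omnibus test. These sizes give 3-SE
recovery bands of a few percent while keeping a full run within a few
minutes on one CPU.

## Known limitations

- Geometry is per-section 2-D; no serial-section reconstruction.
- No image segmentation: contours and synapses arrive as annotations.
- No correction for labelling efficiency or section thickness; raw
  particle statistics only.
- The micrograph pixel size at typical EM magnifications is not
  modelled; the schema stores physical nm only.
- `pooling_check()` tests all pairwise block comparisons at the
  unadjusted `alpha`; with many blocks this is conservative in its
  refusal behaviour (any single significant pair refuses pooling).
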