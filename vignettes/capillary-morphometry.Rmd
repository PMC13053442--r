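---
title: "3D capillary network and muscle fibre morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D capillary network and muscle fibre morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myocap3d)
```

## The measurement problem

Two-dimensional capillary counts on thin muscle sections are biased by
section orientation and fibre size. The alternative implemented here is
fully three-dimensional: confocal z-stacks of thick (about 100 µm)
sections are segmented, thinned to centrelines, vectorised into a spatial
graph, and measured in world coordinates. The graph supports a compact
set of network parameters:

* **LVm** — capillary centreline length per tissue volume (µm⁻²),
  and its fibre-normalised companions **LVf** (per fibre volume),
  **LSf** (per fibre lateral surface) and **LL** (per fibre axial
  length);
* **Br_dens** — branch points (graph nodes of degree ≥ 3) per volume;
* **MeanCap** — mean capillary length, computed as
  \( \mathrm{MeanCap} = \tfrac{2}{3}\, L_V / N_V \), where \(L_V\) is the
  length density and \(N_V\) the branch-point density. The 2/3 factor
  reflects that each interior branch point terminates three capillary
  segments, two ends per capillary. The reference volume cancels, so the
  same value is obtained from raw field totals;
* **tortuosity** — the sum of exterior (turning) angles along all
  vectorised polylines divided by total length (rad µm⁻¹). Exterior
  angle means the angle between consecutive segment directions, so a
  straight path scores exactly zero and coordinate scaling by \(s\)
  multiplies the value by \(1/s\);
* **anisotropy** — an eigenvalue ratio of the length-weighted
  orientation tensor \(T = \sum_i \ell_i u_i u_i^{\mathsf T} / \sum_i
  \ell_i\) over unit segment directions \(u_i\) (orientation-symmetric,
  \(u \equiv -u\)).

Because the human autopsy material behind these methods is not publicly
deposited, the package validates every stage against synthetic phantoms
with exactly known vector ground truth, generated by the package itself.

## Reconstruction chain

`reconstruct_capillaries()` runs, in order:

1. **Segmentation.** A global Otsu threshold on the volume histogram
   (256 bins), or a fixed threshold. A morphological closing with the
   radius-1 Euclidean ball fills single-voxel gaps, then connected
   components (26-connectivity) smaller than `min_object_volume`
   (default 100 µm³) are removed. An all-background result raises a
   dedicated condition class rather than returning an empty volume
   silently. The global Otsu function is implemented in the package
   because the imaging packages available compute per-slice thresholds,
   which is the wrong model for a 3D stack with depth-uniform signal.
2. **Curve thinning.** Six directional subiterations (one per face
   direction); in each, border voxels that are *simple points* in the
   (26, 6) digital topology — one 26-connected foreground component in
   the 26-neighbourhood, one 6-connected background component in the
   18-neighbourhood — and are not curve endpoints are deleted, with the
   simplicity test re-evaluated sequentially at deletion time. This
   preserves components and loops by construction; the contract (subset
   property, component-count preservation, unit width) is what the test
   suite asserts, independent of the particular deletion order. Tube
   ends erode by roughly one tube radius, a known property of curve
   thinning.
3. **Graph extraction.** Nodes at skeleton voxels with a neighbour count
   different from two; clusters of mutually 26-adjacent junction voxels
   merge into one node at their centroid (no distance-based merging —
   the simplest rule with a testable contract). Edges are voxel-centre
   chains converted to µm using the voxel size and the volume's axial
   calibration factor.
4. **Spur pruning and junction consolidation.** Terminal edges below
   the spur threshold (default 5 µm, one segment length) are removed
   iteratively and junctions reduced to degree 2 are dissolved; then
   pairs of degree-≥3 nodes joined by an edge shorter than 3 µm — a
   junction blob that thinning split in two, since two genuine branch
   points closer than a tube diameter are not resolvable in the image —
   are contracted into one node. Together these replace the interactive
   manual cleanup used in practice with deterministic, parameterised
   rules.
5. **Centreline smoothing** (moving average, default window 8 µm).
   Voxel centrelines carry sub-voxel jitter; at a 5 µm vectorisation
   step that jitter contributes turning angles of the same order as real
   capillary curvature and would dominate the tortuosity estimate. A
   moving-average window \(W\) attenuates a sinusoidal undulation of
   wavelength \(\lambda\) by \(\mathrm{sinc}(\pi W/\lambda)\): at
   \(W = 8\) µm and \(\lambda = 50\) µm the true signal loses about 4%,
   while the voxel-scale noise (wavelength ≈ 2 voxels) is suppressed
   almost entirely. On straight-tube phantoms the residual tortuosity
   floor drops from ≈ 12 × 10⁻³ (no smoothing) to ≈ 8 × 10⁻³ rad µm⁻¹,
   and because noise and signal angles add near-quadratically per
   vertex, recovered tortuosity lands within a few percent of truth at
   both low (≈ 23 × 10⁻³) and high (≈ 42 × 10⁻³ rad µm⁻¹) setpoints.
6. **Arc-length resampling** into 5 µm segments (interior vertices at
   multiples of the step along the curve, endpoints preserved, final
   segment possibly shorter). Resampling by chord positions on the
   arc-length parameterisation; at a 5 µm step the chord-vs-arc
   difference is far below metric tolerance.

**Axial calibration.** Thick sections shrink along z. The correction is a
multiplicative factor on z world coordinates, carried by the
`voxel_volume` and applied when the skeleton is vectorised
(`apply_axial_calibration()`). The round trip — compress z by 0.5 at
rasterisation, calibrate by 2.0 at reconstruction — recovers length
density within a few percent; the residual comes from the halved axial
sampling of the shrunk stack.

**Border handling.** All skeleton length inside the imaged box counts;
no guard-zone correction is applied, since the densities are reported per
whole-field volume. This is a small, known bias source at field borders.

## The capillary phantom generator

`generate_capillary_network()` grows a network whose ground-truth metrics
are controlled *exactly*, not just in expectation:

* **Trunks.** Polylines with orientations drawn from a von Mises–Fisher
  distribution about the fibre (z) axis with concentration
  `orientation_kappa` (default 6, which yields orientation anisotropy in
  the 2–3.5 range typical of limb and trunk muscle). Each trunk carries
  a transverse sinusoidal undulation (wavelength 50 µm — the scale of
  capillary meander between fibres; amplitude is the tortuosity knob)
  and is sampled at ≈ 1 µm arc steps.
* **Branch points.** `round(target_NV × volume)` degree-3 nodes are
  created by transverse connectors: a full connector joins interior
  vertices of two trunks (two branch points), an odd remainder is a
  half connector with a free end (one). Attachments keep at least 9 µm
  from trunk ends — a shorter terminal stub would be spur-pruned
  downstream, dissolving the junction — and at least 7 µm from each
  other, so junction clusters remain resolvable.
* **Exact length fill.** Straight filler trunks are added until total
  centreline length equals `target_LVm × volume`, the last one truncated
  at the exact arc length. The realised LVm therefore matches the
  setpoint to floating-point precision, and the branch count matches the
  rounded setpoint exactly.
* **Clearance.** Polylines keep a minimum separation of one tube
  diameter plus a 3.5 µm guard band except where a branch is intended.
  Real capillaries do not interpenetrate, and the guard additionally
  covers voxelisation overshoot (about half a voxel diagonal per tube
  surface) and the 1-voxel morphological closing, which bridges surface
  gaps of up to two voxels: without the guard, tubes whose centrelines
  respect a bare two-radius separation still weld at segmentation and
  create branch points absent from the ground truth (in early
  development such welds tripled the apparent branch density). Connector
  interiors are checked against every tube except the two they join, and
  against those two only within 12 µm of the attachment itself. In dense
  fields the separation is relaxed gradually rather than failing
  outright; genuinely infeasible requests (e.g.
  `target_NV × volume < 1`, or connector length exceeding the length
  budget) raise explicit errors.
* **Tortuosity calibration.** When `target_tortuosity` is set, the
  undulation amplitude is found by root-finding against the *exact*
  exterior-angle tortuosity of the generated graph (monotone in the
  amplitude at fixed seed). Because the amplitude also enters the
  clearance geometry, the layout can rearrange slightly between
  candidate amplitudes; the calibrated graph lands within 1–3% of the
  setpoint, well inside measurement tolerance.

The stored ground truth is computed by the same metric functions the
pipeline uses (`total_length()`, `branching_density()`, `tortuosity()`,
`anisotropy()`, `mean_capillary_length()`) applied to the exact vector
graph, so truth and measurement are comparable by construction, and the
oracle identity is asserted bit-for-bit in the tests.

`rasterise_network()` turns the graph into the synthetic stand-in for a
confocal stack: voxels within `capillary_radius` of any polyline are
foreground (255), the rest background (0), at 0.76 × 0.76 × 1 µm voxels
over a 387.5 × 387.5 × 100 µm field by default. The capillary radius
(default 2.5 µm, a typical muscle capillary calibre) and the optional
Gaussian intensity noise (default off, keeping phantom runs
deterministic) are free parameters: neither is constrained by the
published imaging protocol, and both are exposed in the spec.

### What the phantoms do and do not emulate

They emulate: field geometry and voxel anisotropy, axial dominance and
orientation concentration of muscle capillaries, branch-point density,
smooth tube meander, axial shrinkage, inter-section misalignment (2D
arm), and exactly bookkept lipid area fractions. They do **not**
emulate: the confocal point-spread function, depth-dependent
attenuation, staining heterogeneity, vessel calibre variation, true DAB
colour chemistry, or anastomosing loop-rich topologies. Passing the
recovery suite therefore demonstrates that the *measurement chain* is
unbiased at realistic geometry and sampling, not that segmentation of
real, noisy confocal data is solved — on real stacks the segmentation
step carries most of the uncertainty.

## Fibre phantoms and the 2D serial-section arm

Fibre territories are prism-like: jittered hexagonal cross-sections on a
lattice whose spacing is tightened until the requested fibre count fits,
with a lognormal minimal-Feret diameter distribution, extruded through
the field depth. Ground truth contours are the exact polygons; derived
diameter, lateral surface (end caps excluded — the fibres continue
beyond the slab) and volume come from `fibre_geometry()`, which
integrates polygon areas and perimeters trapezoidally over the traced
planes and extends the first/last plane values to the stack bounds.
Gaps between jittered hexagons play the role of interstitium.

The serial-section generator assigns each fibre a MyHC type drawn from
supplied probabilities and renders three pseudo-stained sections
following the standard antibody panel convention (BA-D5 = MyHC-1,
SC-71 = MyHC-2a, 6H1 = MyHC-2x; pure types positive on one antibody,
hybrids 1/2a and 2a/2x concomitantly positive on two). Lipid droplets
are placed as 2 × 2 pixel blocks with single-pixel top-up so each
fibre's Sudan-positive area fraction equals its drawn value *exactly*.
Sections 2–4 are shifted by a small integer jitter to exercise
registration.

Analysis mirrors a practical workflow: translation-only registration by
centroid-cloud alignment (serial cryosections do not rotate
appreciably), mutual-nearest-centroid matching with a gate of half the
median equivalent diameter, per-channel positivity by an Otsu-style
two-class split of the per-fibre mean intensities (deterministic,
shift-invariant; degenerate channels are called all-negative with a
warning), the five-pattern truth table for typing (the three patterns
outside the convention are flagged `unclassified`, never guessed),
rotating-calipers minimal Feret on pixel-corner hulls (so a w-pixel-wide
rectangle measures exactly w pixels; an exhaustive angular sweep serves
as oracle), and exact lipid-pixel bookkeeping for the IMCL index.
Border-touching fibres are flagged and excluded from summaries by
default, since their width is biased low.

## Cohort models

`simulate_cohort()` draws a hierarchical two-group design: 24 + 24 male
subjects, four muscles each, five fields per subject × muscle, a
per-subject random intercept, field-level noise, and demographics
matching an older autopsy cohort (age ≈ N(70, 10) in both groups; BMI
N(24.8, 2.7) vs N(31.9, 4.7); HbA1c normal vs N(6.9, 1.1)).

`fit_group_model()` fits `value ~ group + age + BMI + (1 | subject)` by
REML with Satterthwaite-type degrees of freedom for the group test (the
fitting criterion and df method are the package's own choices — fixed
for reproducibility — with a normal approximation as fallback when the
Satterthwaite machinery fails). Optional sensitivity terms add centred
quadratic age, group × age, or a fibre-diameter covariate. Singular
fits are flagged but returned. Over 1000 null cohorts at the study
design size the empirical type-I error sits within [0.035, 0.065] at
nominal 0.05, and an injected group effect is covered by its own 95% CI
in at least 93 of 100 replicates — both asserted in the test suite.

Companion analyses follow the conventional repertoire: two-way ANOVA
(group × fibre type) with Tukey post hoc tests on subject-level means;
within-subject muscle hierarchy by all pairwise paired t-tests plus a
repeated-measures model `value ~ group * muscle + age + BMI +
(1 | subject)` (subjects with incomplete muscle sets are excluded
listwise from the paired analyses only); and linear models of
subject-level outcomes on HbA1c adjusted for age and BMI within the
disease subgroup. No multiplicity correction is applied across muscles
or outcomes — unadjusted two-sided p at α = 0.05 is reported, and users
should interpret accordingly.

## Numerical choices and degenerate inputs

* Zero-length segments (duplicated vertices, length < 1 nm) carry no
  direction and are excluded from angle and tensor sums.
* `MeanCap` with zero branch density is undefined and returns `NA` with
  a warning — never 0 or `Inf`.
* Anisotropy of a perfectly parallel segment set is flagged as `Inf`
  with a warning. The eigenvalue-ratio convention is configurable
  (`max_over_mean`, `max_over_min`, `max_over_mid`); the default
  `max_over_mean` equals 1 for isotropy and matches the 1.6–2.8
  magnitude range reported for muscle. Which ratio the original
  analysis software used is not documented, so the default is a
  convention, not a fact.
* Mean ± SD summaries of field-level metrics can be taken over fields
  or over subjects; the cohort table keeps field-level rows so either
  aggregation is available, and the mixed models handle the nesting
  explicitly.

## Problem sizes used by the tests

Unit tests run on 120 × 120 × 60 µm fields (≈ 1.5 million voxels) where
a reconstruction takes about a second; the end-to-end recovery tests use
the full 387.5 × 387.5 × 100 µm field at 0.76 × 0.76 × 1 µm voxels
(≈ 26 million voxels, ≈ 10 s per field), with five-field averages in the
acceptance script mirroring the five fields of view per muscle of the
sampling design. Statistical calibration uses 1000 null cohorts. These
sizes were chosen so the complete suite documents full-scale behaviour
while remaining quick enough to run routinely.

## Known limitations

* Curve thinning erodes tube ends by about one radius, biasing total
  length low by ≈ 1% at the default geometry; after junction
  consolidation the residual branch-point error is typically 0–1 in
  ≈ 20 per field.
* No guard-zone correction at field borders.
* The segmentation defaults are tuned for the noiseless and
  lightly-noised phantoms; real confocal stacks will need
  problem-specific thresholds and size filters.
* Registration is translation-only; rotated or sheared serial sections
  are out of scope.
* The generator's network topology (trunks + transverse connectors) is
  a stylised model of muscle capillarity, not a vascular growth model;
  loop-rich arcade topologies are under-represented.
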