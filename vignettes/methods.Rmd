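---
title: "Automated tract reconstruction with fibreflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tract reconstruction with fibreflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fibreflow)
```

# What the package computes

`fibreflow` is a desk-scale implementation of an automated white-matter
tractography pipeline and of the statistical framework used to judge whether
such a pipeline is *robust* (it finds every clinically relevant tract in a
healthy brain, with group results stable under resampling of subjects) and
*reliable* (repeating the processing, or rescanning the subject, reproduces
the same tract). The pipeline stages are:

1. **ROI construction** — seed, target, exclusion and inclusion masks are
   built from a labelled parcellation by a declarative recipe per tract
   (label selection, bounding-box splits, axial slabs, Gaussian dilation,
   landmark planes, an inter-structure sphere).
2. **Probabilistic tracking** — streamlines grow unidirectionally on a
   fibre-orientation-distribution (fODF) field under a fixed step length,
   curvature bound and amplitude cutoff, from random seed-voxel positions
   until a target is reached.
3. **Fibre-to-bundle coherence (FBC) filtering** — each streamline is scored
   by a kernel density over positions *and* orientations of all other
   streamlines; streamlines whose weakest stretch is a too-small fraction of
   the set average (low RFBC) are removed as spurious.
4. **Density and probability maps** — per-subject tract density images are
   binarised (`K >= 1`) and averaged across subjects into tractogram
   probability maps.
5. **Evaluation** — Dice overlap, hold-out cross-validation over subjects,
   repeated-processing comparison, and test–retest comparison.

Everything runs on synthetic phantoms shipped with the package, so the whole
pipeline is testable with no external imaging data.

# The six tract protocols

The shipped protocol file (`inst/protocols/default_six_tracts.yaml`) encodes
six clinically relevant tracts. Streamline counts: 5000 (FAT), 15000 (IFOF),
7000 (SLF III), 7500 (AF, CST, OR). fODF amplitude cutoffs, expressed as a
fraction of the field's global maximum amplitude: OR 10%, IFOF and CST 7%,
AF 7.5%, SLF III 8%, FAT 9%. All tracts use a step of 0.2 mm, a minimum
radius of curvature of 1 mm, and an attempt budget of 10,000 per seed voxel.

Geometric readings that the anatomical definitions leave open were fixed
once and made configurable:

* **"Anterior part" of the brainstem** (CST seed): the plane is placed at
  the anterior–posterior midpoint of the brainstem's bounding box (one
  global plane, not per-slice).
* **"Middle and posterior part" of the temporal gyri** (AF target): the
  posterior two thirds of the AP bounding extent (`split_axis` with
  fraction 1/3).
* **"Ventral and inferior part" of the precentral gyrus** (AF/SLF III
  seeds): the inferior half of the IS extent.
* **The 24 mm³ white-matter sphere** (IFOF include region) is implemented
  literally as a ball of volume 24 mm³ (radius ≈ 1.79 mm), centred at the
  midpoint of the posterior-insula and putamen centroids and snapped to the
  nearest white-matter voxel (ties broken at the lowest linear index, for
  determinism). The volume is a protocol parameter in case a diameter
  reading is preferred.
* **Gaussian dilation sizes** (1.5 mm for the OR seed, 3.0 mm for the SLF
  III superior-temporal exclusion) are taken as the kernel's standard
  deviation; both are configurable.
* **The pre-SMA anterior boundary** (FAT seed) is a coronal plane at the
  anterior-most y of a user-provided genu-of-corpus-callosum landmark mask.
* The RFBC filter strength is `1e-3` (medium) for all six tracts by
  default; the published protocol mixes medium and high settings per tract
  but does not tabulate the assignment, so the conservative common setting
  is shipped and the value is per-protocol configurable.

## Gaussian "dilation" semantics

`gaussian_dilate()` correlates the mask indicator with an *unnormalised*
isotropic Gaussian (value 1 at distance 0) and keeps voxels above 0.3; the
result is the original mask plus a shell of width
`sigma * sqrt(2 log(1/0.3)) ≈ 1.55 sigma`. A sum-normalised convolution was
rejected: its peak value shrinks as `sigma` grows, so a single-voxel mask
would stop dilating (and eventually vanish) at larger bandwidths, and
monotonicity in `sigma` — which the dilation operator should obviously have
— would fail. With the unnormalised kernel the operator is a grayscale
dilation with a Gaussian structuring element: monotone in `sigma`,
idempotent at `sigma -> 0`, and exactly characterised by a Euclidean
distance threshold (the property the unit tests assert).

# The tracker

The tracker is a first-order per-step sampler: at each step it
rejection-samples a unit direction with probability proportional to the fODF
amplitude, restricted to the curvature cone around the previous direction.
(The published pipeline uses a second-order path-integral sampler; the
evaluation framework is agnostic to the integrator, and the contract
surface — step, curvature, cutoff, seed cone, stopping rules — is the
same.)

* **Curvature bound.** A fixed-step polyline inscribed in a circle of
  radius `R` turns by at most `2 asin(step / 2R)` per step — 11.478° for
  0.2 mm steps and `R = 1` mm. Every sampled direction lies inside this
  cone by construction, so the bound holds exactly on every accepted
  streamline.
* **Amplitude cutoff.** "x% of the maximum amplitude" is referenced to the
  global maximum amplitude of the field (evaluated on a 100-direction
  spherical lattice over all voxels, cached). Directions below the cutoff
  are never accepted; a voxel whose coefficient vector cannot reach the
  cutoff (by a per-degree Cauchy–Schwarz bound with the SH addition
  theorem) fails without sampling at all, which is what terminates
  propagation outside supported tissue.
* **Seeding.** A seed voxel is drawn uniformly among seed-mask voxels and
  the position uniformly within its 2 mm cell. The OR protocol restricts
  the first direction to a 45°-half-angle cone (a "90° cone") pointing
  laterally; `"lateral"` resolves to +x or −x with the hemisphere.
* **Stopping.** Acceptance on entering any target; rejection on entering
  any exclusion region, leaving the field domain, exhausting the
  per-step trial budget (300 trials), or exceeding the length budget.
  Include regions are checked after acceptance: an accepted streamline
  must intersect all of them. The attempt budget is pooled:
  10,000 × (number of seed voxels) attempts for the whole tractogram.
* **"8 spherical harmonic coefficients"** is read as maximum even order 8
  (45 real coefficients), the conventional CSD setting; the order is
  configurable and any even order is accepted on input.
* The maximum streamline length defaults to 250 mm; the shipped protocols
  use 150 mm, ample for every phantom tract.

A noteworthy empirical property: the *streamline-level* acceptance rate is
not monotone in the amplitude cutoff. A moderately higher cutoff prunes
directions that lead into weakly supported fringe regions, so a larger
fraction of attempts reaches the target; only when the cutoff approaches
the lobe peak does acceptance collapse to zero. The monotone statement that
does hold — and is tested — is at the direction level: raising the cutoff
shrinks the acceptable direction set, hence the per-trial success
probability.

# FBC filtering

The cited coherence measures are defined through hypo-elliptic diffusion
kernels on the rigid-motion group; no closed formulas are given in the text
this package follows. `fibreflow` therefore implements a documented
separable surrogate with the same defining structure — a density in
positions and orientations:

* streamlines are lifted to (position, unit tangent) pairs, tangents by
  central differences with endpoints dropped;
* the local coherence (LFBC) of a lifted point is the mean over all lifted
  points of all *other* streamlines of
  `exp(-d² / 2σ_s²) · exp(κ((t·u)² − 1))`, a spatial Gaussian times an
  antipodally symmetric orientation concentration kernel, normalised to 1
  at zero distance and perfect alignment;
* the relative coherence (RFBC) of a streamline is the minimum sliding
  `W`-point-window mean of its LFBC profile divided by the mean LFBC over
  all points of all streamlines (0/0 defined as 0).

Defaults: `σ_s = 2` mm, `κ = 10`, `W = 7` points. Normalising by the
set-wide mean makes the filter thresholds scale-free — absolute densities
depend on streamline count and bandwidth — so `RFBC = 1e-3` (medium) and
`1e-1` (high) are meaningful across tractograms. Whether these two values
are numerically comparable to thresholds under the exact group-convolution
kernels cannot be established from the text; they are protocol-level
parameters. The production implementation is a vectorised block
computation; the unit tests pin it to a literal all-pairs double loop to
1e-8 on small sets.

# Density and probability maps

`tract_density()` counts, per voxel, distinct streamlines with at least one
point or segment crossing in it (at most one count per streamline per
voxel). Segments are supersampled at a quarter of the smallest voxel edge
so no traversed voxel can be skipped; the tests assert that halving that
spacing changes nothing on the phantom. Binarisation is the `K >= 1`
indicator. Group probability maps are voxelwise means of binarised maps
after nearest-neighbour resampling to the group grid — nearest-neighbour so
binarity survives normalisation — giving values in {0, 1/n, …, 1}: the
fraction of subjects with at least one streamline in the voxel. Confidence
thresholding at 5%, 50%, 90% produces nested masks.

# Evaluation framework

* **Dice**: `2 N(A∩B) / (N(A) + N(B))` over nonzero voxel counts; two empty
  masks give 1 with a degenerate flag so batch phantom runs do not crash.
* **Hold-out cross-validation**: each iteration draws a small group of
  `round(ratio · n)` subjects (complement rule for the large group), builds
  both groups' probability maps, thresholds at the minimal confidence
  level, and records the Dice overlap; defaults are a 10% ratio, 300
  iterations and a 5% confidence level. Note `round(0.10 × 136) = 14`,
  whereas the published split is stated as 13/129 for n = 136 — which is
  internally inconsistent (13 + 129 ≠ 136); the complement rule is used
  here and the small-group size is reported in the result object.
  Box-whisker summaries use Tukey 1.5·IQR whiskers.
* **Repeated processing**: R identical-settings runs give all
  `choose(R, 2)` pairwise Dice values (45 for R = 10), reported per
  filtering strength (none, medium, high).
* **Test–retest**: the session-2 map is brought to session-1 space with a
  supplied transform (the known inverse jitter for phantoms) before Dice;
  seed/target ROI overlap is tabulated per tract, ROI type and hemisphere
  as mean ± sample sd.

# The synthetic phantoms

Phantom anatomy is deliberately schematic — axis-aligned boxes in
anatomically plausible relative positions on a 40×48×40 grid of 2 mm
voxels — because the tests target the computation, not anatomy. The default
phantom contains every structure the six protocols reference, mirrored
across the midline, plus a white-matter complement label; analytic
centerlines connect each tract's seed to its target through plausible
waypoints (the corticospinal line rises from the anterior brainstem through
the corona radiata; the optic radiation leaves the LGN laterally before
sweeping back to the calcarine cortex; the IFOF trunk runs through the
external-capsule gap between insula and putamen and fans frontally). The
fODF generator places antipodal orientation lobes `exp(κ((d·t)² − 1))`
(κ = 12) along the centerlines with a Gaussian radial falloff inside a 3 mm
tube, superposing lobes where bundles cross, over a small isotropic
background; the spherical function is projected onto the order-8 real SH
basis by least squares on a 100-direction lattice. Order-8 truncation of a
κ = 12 lobe leaves ~4% ringing, which is why amplitude assertions in tests
use tolerances rather than exact values.

Cohorts apply small rigid-plus-scale affines per subject (the anatomical
jitter) and regenerate each subject's fODF from the transformed
centerlines; the exact inverse affine ships as the subject's normalisation
transform, so the "registration" consumed by the evaluation experiments is
ground truth by construction. Rotating SH coefficient fields directly would
require Wigner rotations and would still be exact only for the synthetic
model; regenerating from centerlines is exact and simpler.

Two mechanisms inject spurious structure:

* `inject_spurious()` adds straight streamlines orthogonal to a bundle at
  ≥ 10 mm offset (≥ 5σ_s), carrying ground-truth labels — used to verify
  that an RFBC sweep separates classes perfectly.
* For the repeated-processing experiment, the straight-bundle phantom
  raises its isotropic background *above* the amplitude cutoff, so
  rejection-sampled strays occasionally wander to the (full cross-section)
  target at random, run-varying positions. These accepted strays are
  spatially isolated (RFBC ≈ 0) and differ between runs, which is exactly
  the character of the spurious streamlines that post-tractography
  filtering exists to remove — and why pairwise Dice across repeated runs
  increases from no filtering through medium to high. Deterministic
  "distractor corridor" noise was evaluated and rejected for this purpose:
  corridors are reconstructed identically by every run, so removing them
  cannot improve (and in practice degrades) run-to-run overlap. Random
  per-voxel orientation noise was also insufficient, because isolated noise
  lobes never chain into an accepted path under the curvature and cutoff
  contract.

## What passing tests do and do not show

The phantoms exercise the full computational contract: geometry operators,
sampler constraints, stopping rules, kernel scores, map algebra and the
evaluation statistics. They do not emulate partial-volume effects, fibre
fanning/kissing configurations, susceptibility distortion, imperfect
registration, or realistic SNR; a pipeline that passes here is
computationally correct, not clinically validated.

## Problem sizes in the shipped tests

Test and acceptance runs scale the production streamline counts down to
3–50 streamlines per tractogram, 10 repeated runs, 8–20 synthetic subjects
and 300 hold-out iterations; these sizes were chosen so the full suite
exercises every stage end-to-end while remaining comfortable on a single
CPU. The production counts in the protocol file remain the published
settings.

# Numerical choices

* World coordinates are mm in RAS+; volumes are reoriented to RAS on load.
  Voxel indices are 0-based with half-open cells, the voxel centre at the
  integer index.
* Coefficient interpolation is trilinear; label/binary resampling is
  nearest-neighbour; probability/density resampling is trilinear with
  clamping to [0, 1].
* The sphere-centre snap and all set operations break ties at the lowest
  linear index; every ROI primitive is deterministic, so identical inputs
  give bit-identical masks.
* All stochastic stages consume seeds derived from one run seed through a
  counter scheme (`seed * 1009 + stage * 9973 mod 2^31 − 1`), so any stage
  can be reproduced in isolation and a full pipeline run is bit-identical
  under a fixed seed (the manifest records md5 checksums to make this
  checkable).
* TCK files are written as Float32LE with the self-referential `file: .`
  offset fixed-width-padded; TRK coordinates are converted through the
  corner-origin voxel-mm convention with the half-voxel shift.

# Known limitations

* The per-step sampler is first-order; tract shapes in strongly curved,
  low-SNR regions will differ from a path-integral sampler even under the
  same contract.
* The FBC kernel is a separable surrogate, not the exact SE(3)
  hypo-elliptic kernel; filter thresholds are calibrated within this
  package's scores only.
* Streamline-level acceptance is not monotone in the amplitude cutoff (see
  the tracker section).
* The phantom's "registration" is ground truth; the framework consumes
  transforms and never estimates them, so registration error is outside
  the tested scope.
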