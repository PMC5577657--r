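---
title: "Quantifying seed-soil contact and the iceberg effect from CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed-soil contact and the iceberg effect from CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcontact)
```

## The measurement problem

Germination begins with imbibition: the dry seed must draw water from the
soil it touches. How much of a seed's surface actually touches soil is
therefore an agronomically important quantity, but soil is opaque and the
interface microscopic, so historically "good seed-soil contact" was judged
qualitatively. X-ray computed tomography resolves the interface in situ:
a reconstructed volume of a soil core at around 20 µm voxel size shows air,
soil aggregates and the seed as three grey-level populations, and the
contact area can be measured rather than estimated.

This package implements that measurement for volumes of sugar beet (or any
similarly sized) seeds in soil, together with a synthetic phantom generator
used to validate every step against known ground truth, because public CT
scans of seeds in soil with reference measurements do not exist at the time
of writing.

## The contact measurement

The pipeline is:

1. **Phase segmentation** (`segment_phases()`). Two grey-level cut points
   split the histogram into air, seed and soil. With clean contrast the two
   cuts are estimated automatically by a three-class Otsu criterion
   (exhaustive maximisation of between-class variance on a 256-bin
   histogram); noisy or overlapping distributions should be cut manually via
   `thresholds`. By default the middle band is the seed — organic material
   attenuates between air and mineral grains — but the band-to-phase mapping
   is an argument, because pelleting material is not guaranteed to follow
   that ordering.

2. **Seed closing** (`select_seed()`, `close_seed()`). A germinating seed
   opens and develops internal air space, so its raw segmentation is a
   shell, not a solid. The physically meaningful denominator for contact is
   the *closed* surface. We close with a Euclidean ball (default radius 3
   voxels) to seal narrow openings, then fill every background component not
   connected to the grid boundary. Both steps are implemented by exact
   Euclidean distance transforms, so the ball is a true sphere and the
   operation is idempotent. Hole filling uses 6-connected background against
   26-connected foreground, the standard duality that prevents
   "tunnelling" through diagonal voxel chains. Voxels added by closing and
   by filling are reported separately; nothing is filled silently.

3. **Contact classification** (`compute_contact()`). The soil mask is
   dilated by one step so that it overlaps the unmoved seed wherever a grain
   touches it. Every exposed voxel face of the closed seed whose voxel falls
   inside the dilated soil is a contact face, and

   contact % = 100 · (contact faces) / (total boundary faces).

   Numerator and denominator share one discretisation, so the percentage is
   unaffected by the absolute-area estimator's bias. The default dilation
   element is the full 3×3×3 cube (26-connectivity): at 20 µm a grain
   diagonally adjacent to the seed is physically touching it; 6- and
   18-neighbourhoods are selectable, and contact grows monotonically with
   the neighbourhood.

4. **Ring-shell ("iceberg") metrics** (`ring_shell()`,
   `compute_iceberg()`). A visible contact patch is typically the tip of a
   much larger aggregate, so water access exceeds what the contact area
   suggests. Two shells are built around the closed seed — by default 5 and
   15 voxels wide, i.e. 100 µm and 300 µm at 20 µm voxels — and within each
   the *volume effect* (soil / (soil + air), in %), the soil boundary-face
   surface and the *surface effect* (contact area / soil surface within the
   ring) are computed. The *change in soil mass* is 100 · short/long for
   each effect: 100 means soil density is uniform with distance; above 100,
   soil is concentrated against the seed.

## Resolved ambiguities and numerical choices

Several details of the original workflow are underdetermined; the choices
made here, and why:

* **Shell geometry.** "5 voxels" is measured in Chebyshev distance, so that
  a width-5 shell is exactly five applications of the same +1-voxel
  dilation used for contact; an exact-Euclidean variant is available. The
  long-range shell spans distances 1–15 and therefore *contains* the short
  shell's region: the change-in-soil-mass ratio compares two measurements
  that both start at the seed surface. The 6–15 annulus is available via
  `annulus = TRUE`.

* **Volume effect definition.** The effect is the soil fraction of the
  shell, 100·soil/(soil+air), not a contact-to-volume ratio; degenerate
  shells with no soil surface return an explicit undefined flag instead of
  dividing by zero.

* **Surface-area estimators.** `face_count` multiplies exposed voxel faces
  by the face area; it is exactly consistent with the contact
  discretisation but overestimates smooth surfaces by a stable factor
  (≈1.5, the orientation average of |n_x|+|n_y|+|n_z|). `mesh` triangulates
  the 0.5 iso-surface of a Gaussian-smoothed (σ = 1 voxel) copy of the mask
  with marching tetrahedra; smoothing first is what makes the vertex
  interpolation sub-voxel accurate (marching directly on the 0/1 grid pins
  all vertices to edge midpoints and carries a ~27% orientation-dependent
  bias; with smoothing a radius-25 digitised sphere is recovered to well
  under 1%). Percentages are always face-based; mm² values are reported by
  whichever estimator is configured.

* **Contact-line bias.** The +1-voxel dilation marks roughly one extra face
  ring along the line where soil, air and seed meet. For a spherical-cap
  scene this inflates contact by ~3.5 percentage points at a sphere radius
  of 25 voxels and ~1.4 at 50, scaling as 1/r. It is a property of the
  overlap construction itself (shared with the original workflow), which is
  why validation against the analytic cap fraction is run at radius 50
  (a 4 mm seed at 40 µm voxels).

* **I/O.** TIFF spacing tags are treated as untrustworthy; the voxel size
  comes from an explicit argument or the package's own sidecar, and a
  conflict between argument and stored value is resolved in favour of the
  argument with a warning. Anisotropic spacings are rejected outright —
  every conversion in the package assumes one edge length. Integer volumes
  round-trip bit-exactly through 8/16-bit TIFF; arbitrary (floating-point)
  volumes use raw NRRD, which stores doubles losslessly.

## What the phantoms emulate — and what they do not

`phantom_spec()`/`generate_phantom()` produce scenes whose defaults are the
imaged system: 20 µm isotropic voxels, a 4 mm sphere ("pelleted and
coated") or a 4×3×3 mm five-lobed star prism ("naked" seed), soil grains
sieved below 1 mm, the seed placed centrally, greyscale means 10/120/220
(air/seed/soil) with SD 8 noise and optional Gaussian partial-volume blur.
Ground truth — label map, analytic contact fraction, per-distance shell
composition — is recorded before degradation.

Soil models, in increasing realism:

* `solid` and `half_space`/`spherical_cap(θ)` have closed-form truth: a
  sphere whose contact cap subtends polar angle θ has contact fraction
  (1 − cos θ)/2. These drive the recovery tests at θ ∈ {30°, 60°, 90°,
  120°}.
* `grain_packing` lays spherical grains (default radii 250–500 µm, i.e.
  diameters up to the 1 mm sieve cap) by random sequential addition to a
  target solid fraction (default 0.35, a partially packed seedbed), with a
  25% centre-distance overlap tolerance that merges grains into aggregate
  clusters. Around a rigid seed, placement runs in two phases: tangent
  ("settled") placements against the seed surface first — soil poured into
  a column comes to rest against the seed, and a grain lands only where it
  fits, so concavities narrower than a grain stay empty — then bulk
  placements. This two-phase rule is what reproduces the qualitative shape
  effect: the smallest default grain (500 µm diameter) cannot enter the
  ~400 µm notches between the star's lobes, so the star's contact
  percentage falls below the sphere's under matched packing parameters and
  random streams.

The phantoms deliberately do **not** emulate: real aggregate morphology
(grains are spheres), gravity or mechanical compaction (placement is
random, not settled physics), water films (unsegmentable at this
resolution even in real scans), X-ray physics (beam hardening, scatter,
ring artefacts), or seed swelling over time. Passing the phantom suite
therefore demonstrates that the *measurement chain* is correct and robust
to noise and partial-volume blur at realistic contrast — not that
segmentation of difficult real scans is solved; for scans where pellet
material overlaps soil intensities, thresholds and band mapping must come
from the user.

## Validation problem sizes

The test and acceptance runs keep the real physical dimensions (4 mm
seeds, sub-millimetre grains) on desk-scale grids by coarsening the voxel
size, so every scene stays faithful in millimetres while grid sides stay
near 150 voxels:
cap-recovery phantoms run a 4 mm seed at 40 µm voxels (sphere radius 50
voxels), shape-effect packings at 50 µm, and kernel-vs-brute-force checks
on random scenes up to 20³. Exact oracle equivalence (dilation, boundary
faces, contact classification, Chebyshev shells), analytic cap recovery
within 3 points (5 under noise), mesh-area convergence within 3%,
face-count bias stability, shell conservation/nesting, and the
sphere-above-star direction over five packing streams are all asserted in
`tests/testthat/`, and `scripts/acceptance.R` recomputes the headline
quantities from scratch.

## Replicate summaries and radicle length

`summarize_replicates()` reports mean ± standard error of the mean
(SD/√n); the captioned "standard error deviation" of the source figures is
interpreted as the SEM, which recomputation confirms: the three field-core
contact percentages 4.79%, 31.96% and 17.89% summarise to 18.21% ± 7.84%.
`polyline_length()` converts a user-traced point chain to mm — automated
radicle tracing is out of scope, matching the manual polyline tool used in
practice. No significance testing is bundled: the underlying replicate
scans are unavailable and the original test is unnamed, so inferential
statistics are left to the user.

## Known limitations

* Contact is defined through one dilation step, so its absolute value
  carries the 1/r contact-line bias described above; comparisons between
  treatments measured identically are unaffected.
* Chebyshev shells make "width" direction-dependent (a 5-voxel shell
  reaches 5√3 voxels diagonally in Euclidean terms); the Euclidean metric
  is available when isotropy of the shell matters more than consistency
  with the dilation operator.
* The closing radius bounds the width of openings that can be sealed; an
  opening wider than twice the radius leaves the cavity connected to the
  exterior, and those voxels are (by design) not filled.
* Grain packing by random sequential addition jams near 38% solid fraction
  for narrow radius ranges; targets above that are refused or reported as
  unreached rather than silently approximated.
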