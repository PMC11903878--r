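---
title: "Quantifying gamma-TuRC organization at centrosomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma-TuRC organization at centrosomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turcorg)
```

## Scope

The gamma-tubulin ring complex (gamma-TuRC) is the 14-spoke template that
nucleates microtubules. At human centrosomes it occupies two compartments:
a broad pool in the pericentriolar material and a condensed cluster inside
the centriole lumen, tethered near the wall of nine microtubule triplets
(MTTs). `turcorg` implements the quantitative analyses used to characterize
this organization from oriented particle tables (subtomogram-averaging
output) and MINFLUX localization recordings:

1. **Distance-pool statistics** — signed center-to-center distances from
   each particle to the nearest MTT B-tubule centerline, split into
   lumenal (negative) and pericentriolar (positive) pools, summarized with
   median-unbiased percentiles.
2. **Pair-configuration clustering** — each gamma-TuRC paired with its
   nearest MTT segment, reduced to a 7D feature (local-frame shift +
   relative orientation quaternion), clustered by k-means to find the
   preferred arrangement and its wall-facing spoke sector.
3. **MINFLUX post-processing** — iteration/EFO/trace-length filtering,
   axial rescaling, trace aggregation, per-structure cylinder-axis fitting
   and radial profiling.
4. **Ring-geometry deviation** — per-spoke gamma-tubulin-center deviations
   of a conformational model from a closed microtubule-capping reference
   after superposition on a spoke subset.

Because the raw tomographic particle coordinates and MINFLUX tables behind
the published organization of centrosomal gamma-TuRCs are not available in
reusable form, every stage is validated against synthetic data with
planted, recoverable geometry; the generators are first-class, tested
package code.

## Conventions

* **Units.** Nanometers in all spatial modules; Angstrom in the ring
  (conformation) module. Readers convert at the boundary.
* **Rotations.** Scalar-first unit quaternions mapping local frames to
  world frames (`v_world = R(q) v_local`). The q/-q double cover is
  resolved by canonicalization to `w >= 0` (ties at `w = 0` broken by the
  first nonzero vector component); without this, one pose population
  would split into two antipodal clusters in quaternion space.
* **Angles** are degrees at every interface, radians internally.
* **STAR Euler angles** are read as intrinsic ZYZ (rot, tilt, psi) with
  `(0, 0, 0)` the identity; the convention is pinned by a round-trip test
  fixture rather than assumed.
* **gamma-TuRC local frame.** +z along the ring's helical axis from the
  base toward the gamma-tubulin face; +x toward spoke 1's azimuth; spoke k
  sits at azimuth `(k - 1) * 360 / 13` degrees (13 spoke positions per
  helical turn, 14 spokes). Generator and analyzer share this convention;
  any fixed choice would do, but it must be single.

## Median-unbiased percentiles

All distribution summaries use the Hyndman–Fan type-8 estimator: the
plotting position is `h = p (n + 1/3) + 1/3`, linearly interpolated
between order statistics and clamped to `[1, n]`. This estimator is
approximately median-unbiased regardless of the underlying distribution,
which matters for the skewed, truncated distance laws that arise here. The
implementation is a direct transcription of the closed form and is tested
for exact agreement with an independent reference implementation.

## Pool classification and signed distances

The published pool split was visual. `classify_pools()` substitutes a
deterministic rule: a particle is lumenal iff its radial coordinate about
the centriole axis is below `wall_radius - margin` **and** its axial
coordinate lies within the centriole extent (margin 10 nm by default, an
allowance for axis-fit and wall-position uncertainty). Distance magnitudes
are minima of point-to-polyline distances over the nine B-tubule
centerlines; the sign encodes the pool (lumenal negative). Distances are
computed per tomogram and pooled only at the summary stage, mirroring the
per-centriole structure of the data.

## Pair-configuration analysis

MTT segments whose refined orientation deviates from the locally
interpolated MTT axis by more than 30 degrees are rejected before pairing
(orientation-consistency rule); each gamma-TuRC then pairs with its
nearest accepted segment, and pairs are kept when the center-of-mass
distance lies in the inclusive 60–120 nm window.

The 7D feature is `(shift_local / s, q_rel)` where `shift_local` is the
segment-minus-particle shift rotated into the gamma-TuRC frame and `q_rel`
the canonicalized relative orientation. Two choices deserve comment:

* **Local-frame shifts.** World-frame shifts are meaningless across
  tomograms; expressing the shift in the particle frame makes the feature
  exactly invariant under any global rigid motion of all inputs — the
  property that makes a "preferred relative arrangement" well defined.
  This invariance is asserted to 1e-9 in the tests.
* **Shift scaling** `s = 60` nm (half the upper distance cutoff) brings
  positional coordinates to the same order as quaternion components. The
  scaling is the dominant free choice of the method and is exposed in the
  configuration.

**Choice of k.** Clustering uses Lloyd's algorithm with seeded k-means++
initialization and 20 restarts; initialization runs over a
deterministically ordered copy of the features, so results are invariant
to input row order. With a diffuse orientation-random background at
fraction *b*, the main (largest) cluster collects essentially all
preferred-configuration pairs plus about one k-th of the background — the
main-cluster fraction estimator therefore carries an upward bias of about
`b / k`. Resolving a fraction to better than ±0.07 with `b` near 0.6
requires `k >= 9`; the package default is `k = 10`. Smaller k (e.g. 5)
systematically overstates the main cluster's share; users can set any k
in the configuration, and the bias formula above tells them what to
expect. The mean configuration of the main cluster combines the
arithmetic mean of member shifts with the antipode-aware eigenvector mean
of member quaternions (the rotation minimizing summed squared chordal
distance).

The **wall-facing angle** quantifies "spokes 9–12 face the wall": it is
the in-plane angle between the sector's mean-azimuth direction in the
gamma-TuRC frame and the projection of the local shift onto the local
xy-plane; 0 means the sector points at the MTT.

## MINFLUX post-processing

`filter_localizations()` applies, in fixed order: keep rows of the valid
acquisition iteration (9); rescale z by 0.7 (the refractive-index axial
correction); drop rows with EFO >= 100 kHz (strict `<` keeps); drop
traces left with fewer than 4 localizations. Only the EFO/trace-length
interaction is order-sensitive; the chosen order drops traces that lose
rows to the EFO cut — the stricter reading of keeping traces "for further
analysis". The filter marks its output so a second pass does not rescale
z again (idempotence).

Traces aggregate to emitter centers by the arithmetic mean, with per-axis
sample standard deviations as the per-trace precision estimate; the
precision summary is the per-structure type-8 median of those standard
deviations, averaged across structures, with a single lateral value
`sigma_xy = (sigma_x + sigma_y) / 2`.

**Axis fitting.** The per-structure axis starts from the total-least-
squares line through the collective centroid (dominant scatter direction,
`fit_axis_tls()`). For points on a cylindrical shell this is exact only
under perfectly uniform angular coverage: at finite sampling the
covariance between azimuth and height tilts the principal direction by
order one degree for a few hundred traces on a 35 x 450 nm cylinder.
`fit_structure_axis()` therefore refines the TLS axis by minimizing the
variance of the radial distances over axis tilt and transverse offset
(a cylinder fit, Nelder-Mead); on a shell this criterion is exact at any
finite sampling, and residual direction errors on synthetic data are a
few tenths of a degree. The refinement can be disabled
(`refine = FALSE`) to obtain the plain TLS axis.

## Ring-geometry deviations

`ring_deviation_profile()` superposes a query ring model onto a reference
over a spoke subset using Kabsch superposition (proper rotations only —
the determinant correction forbids reflections, as physical rigid bodies
require) and reports per-spoke Euclidean deviations of the gamma-tubulin
centers. The default superposition subset is spokes 2–8, with 3–8
available by argument: both subsets are in circulation for this analysis
and the package surfaces the choice instead of silently resolving it.
Centroids of PDB selections (for deriving centers from atomic models) are
unweighted coordinate means — reproducible without element tables; whether
a mass-weighted center was intended upstream is not determinable, so the
simpler definition is used and documented.

`align_ring_to_z()` orients a ring by its normal — the *minor* scatter
direction of the selected centers (the ring plane carries the two large
eigenvalues) — and fixes handedness so spoke indices increase
counter-clockwise viewed from +z.

## Synthetic data: what is emulated, what is not

The generators (`sim_config()` defaults in parentheses) emulate:

* a nine-fold centriole wall — 9 straight (optionally twisted) B-tubule
  centerlines at wall radius (115 nm) over the centriole length (450 nm);
* a condensed lumenal cluster — nearest-B-tubule distances Gaussian
  (75 ± 6 nm), axial positions in the central third, ~17 nm minimum
  packing separation via rejection sampling, a planted preferred
  orientation relative to the nearest MTT frame (perturbed up to 10
  degrees) for a fraction 1 − 0.37 of particles and uniform SO(3)
  orientations for the rest;
* a broad pericentriolar pool — lower-truncated Gaussian distances
  (85 ± 26 nm, minimum 30 nm), uniform orientations;
* MINFLUX recordings — 17 structures x 200 traces on cylinders of radius
  35 nm, lateral noise 6 nm and axial noise 5 nm applied before the 0.7
  axial distortion (so the pipeline's correction recovers true geometry),
  an EFO mixture with 10% above 100 kHz, 5% short traces, and decoy rows
  from earlier iterations.

Totals (300 lumenal + 500 pericentriolar) are distributed over 15
tomograms: a single centriole lumen cannot hold 300 particles at the
packing separation, and the per-tomogram structure matches how such data
are collected. The background fraction 0.37 makes the planted
configuration span about 63% of the lumenal pool. Noise amplitudes are
applied along the world axes (the instrument frame), while structures are
randomly posed, so axis fitting is exercised under the realistic
anisotropy.

Not emulated: image formation (densities, missing wedge), photophysics
(blinking, bleaching), upstream alignment errors correlated between
particles, or any biology beyond geometry. Passing recovery tests
therefore shows the *analysis chain* is correct and unbiased under the
stated generative model — not that the model captures every property of
real recordings.

Pair-set backgrounds are uniform on SO(3) and uniform over the admissible
60–120 nm shift shell (uniform over the set of vectors, i.e. density
proportional to r^2 in magnitude).

## Numerical choices

* Unit-norm and identity checks at 1e-9; degeneracy detection (eigenvalue
  ties, collinearity) at 1e-6 relative — double-precision headroom on
  both sides.
* Axis direction signs follow a positive-z (then y, then x) cascade so
  fixture outputs are deterministic.
* k-means restarts derive their streams from the user seed; one global
  seeded stream per generator call; identical configuration and seed give
  bit-identical tables and reports (asserted byte-for-byte in the tests).
* Writers use fixed 6-decimal formatting, making files byte-deterministic
  and round-trips accurate to 1e-6.
* Degenerate inputs error early and descriptively: zero-norm quaternions,
  antipodal orientation means, collinear superposition subsets, isotropic
  axis fits, zero in-plane shifts in the wall-facing angle.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the study scales: 300 + 500 particles over 15 tomograms, 232 particle
pairs (42% planted), 17 structures x 200 traces (about 36,000 localization
rows), and 13/14-spoke ring models. A full synthetic pipeline run
completes in well under a minute on one CPU.

## Known limitations

* The pool split is geometric; particles hugging the wall within the
  margin are assigned pericentriolar by construction.
* The main-cluster fraction estimator retains the `b / k` background bias
  discussed above; it is reported, not corrected.
* `quat_mean()` is the chordal (eigenvector) mean — adequate for
  concentrated orientation clusters, not a general SO(3) Fréchet mean.
* STAR input supports the particles-loop dialect with ZYZ Euler angles;
  other dialects need pre-conversion.
* The closed-reference ring is accepted as a pre-reduced center table
  (13 or 14 centers); full-atom model preparation is out of scope.
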