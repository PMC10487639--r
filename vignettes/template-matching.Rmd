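---
title: "Locating macromolecules in tomograms by masked local correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating macromolecules in tomograms by masked local correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
score, the sampling theory behind the orientation search, the model of
the data the synthetic generator emulates, the numerical choices, and
the limits of what passing tests demonstrate.

## The scoring model

Template matching treats detection as a hypothesis test at every voxel:
does the neighborhood of position x, viewed under a mask M, look like
the reference T rotated to some orientation υ? The statistic is the
local correlation coefficient (LCC) — a normalized cross-correlation in
which both the mean and the standard deviation of the search volume are
computed *locally*, under the mask footprint placed at x. Local
normalization is what makes the score comparable between a particle
sitting on a carbon edge and one floating in ice: global normalization
would let background intensity gradients dominate.

Two physical modulations enter the template before correlation:

* **CTF and low-pass.** The reference map is multiplied in Fourier
  space by a weak-phase contrast transfer function
  `-(sqrt(1-A^2) sin chi + A cos chi)`, `chi(k) = pi*lambda*dz*k^2 -
  (pi/2)*Cs*lambda^3*k^4`, truncated to zero beyond its first zero
  crossing, and by a soft low-pass at the resolution the data actually
  support (40 Å for typical in-situ tomograms). Filtering happens at
  the fine input voxel size; only afterwards is the template
  Fourier-cropped to the tomogram's voxel size, which is alias-free —
  the reason we resample in Fourier space rather than by real-space
  decimation.
* **Missing wedge.** A tilt series limited to ±t degrees leaves a
  double wedge of half-angle 90°−t unmeasured in Fourier space. The
  tomogram has no power there, so the rotated template is multiplied by
  the binary wedge mask *in the tomogram frame* (the wedge belongs to
  the tomogram's Fourier coverage, not to the particle, so it is not
  rotated with the template). A perfect planted copy then scores
  exactly 1 — the Cauchy–Schwarz bound — which the tests verify.

At each voxel the maximum score over the orientation set and the index
of the achieving orientation are retained. Ties go to the lowest index,
which makes the result independent of how the search is partitioned.

## Orientation sampling

The increment follows the Crowther criterion Δα = 1/(r·d): at
resolution r, rotating a particle of diameter d by Δα moves its rim by
one resolution element, so finer sampling cannot be resolved and
coarser sampling loses signal. For a 300 Å ribosome at (40 Å)⁻¹ this
gives 0.13 rad ≈ 7.6°.

The set itself is generated deterministically: a Fibonacci (spiral)
lattice places `round(4π/Δα²)` points on the sphere for the first two
Euler angles, and the in-plane angle is a uniform ring at the
increment, giving `round(360/Δα)` values. The construction is one of
several reasonable quasi-uniform covers; its counts agree with the
reference list sizes used in the field (about 7000 at 13°, about
45,000 at 7°, about 550,000 at 3°) to within a few percent, and a
Monte-Carlo test checks that no rotation lies farther than 1.5
increments from the set under the bi-invariant geodesic metric
`2·acos(|q₁·q₂|)`.

Orientation search cost scales as Δα⁻³, which is why the scoring loop
lives in compiled code: rotation by prefiltered cubic b-splines
(interpolating at the grid points to ~1e-12, the accuracy reference for
non-smooth densities), wedge filtering in the small template box, and
the large-volume correlation via FFTW real-to-complex transforms, with
the tomogram spectrum and — for spherical masks — the local standard
deviation computed once and reused for every orientation. That
spherical-mask shortcut is the single biggest saving: a rotationally
symmetric mask makes σ_MV(x) orientation-independent.

## Splitting

Large volumes are processed as subvolumes extended by one full template
box on shared faces; interiors are cropped back and concatenated.
Because scores further than half a box from a face are unaffected by
wrap-around, the assembled result equals the serial one to FFT rounding
(< 1e-6; the exactness test asserts this). The angular search can
instead be partitioned into chunks merged by pointwise maximum — with
the lowest-index tie-break this is *exactly* the serial result,
bit for bit. Wrap-around contaminates a margin of half a template box
at the volume faces; those scores are set to −1 and flagged invalid,
and extraction refuses to pick there. Correctness over coverage.

## Extraction and classification

Candidates are taken greedily: the global maximum of the LCCmax volume
is recorded, a sphere of the masking radius around it is invalidated
(set to −1, so a previously masked region can never resurface as a
fake candidate), and the process repeats. Ties break lexicographically
in (z, y, x). No sub-voxel interpolation is applied — coordinates are
voxel-precision by design; refinement belongs to subtomogram averaging
downstream.

The score histogram of the extracted candidates (bin width 0.015) is
modeled as two Gaussians: background and true positives. The
background component is initialized at the mean and standard deviation
of the full score volume, with its mean constrained to ±2 volume
standard deviations and its width to [0.5×, 2×] of the volume value —
the "initialized and bound by" idea made concrete; the peak height
starts at N/(w·σ·√2π). The fit is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) on the binned counts; using the optimizer
directly (rather than an `nls` wrapper) matters because a legitimate
fit outcome is a zero particle amplitude, which makes the `nls` model
matrix singular even though the answer is fine. Components are
reordered after fitting so the particle mean exceeds the background
mean.

From the fit, upper-tail masses give TP(c) and FP(c) at any cutoff c,
hence sensitivity TP/(TP+FN) and FDR FP/(FP+TP). The package evaluates
these on 500 evenly spaced cutoffs spanning the observed score range —
dense enough for about 1e-3 accuracy in the operating point — and
reports the cutoff maximizing sensitivity × (1 − FDR), the largest
rectangle under the sensitivity/FDR curve (RUC). The two verbal
definitions of this point in circulation ("largest rectangle under the
curve" versus "smallest rectangle with the corner") disagree; we
implement the maximum-rectangle form because it is the one that
reproduces both published calibration anchors: 1 for a perfect
classifier and 0.25 for the diagonal (random) reference. Note the
diagonal value is attained at sensitivity = FDR = 0.5 exactly; a
500-point grid brackets it to within ~1e-6.

## Spatial statistics

For polysome geometry, each particle's vectors to its n = 4 nearest
neighbors beyond a 100 Å exclusion radius (clash removal) are rotated
by the inverse of the particle's orientation into the reference frame
and histogrammed in (20 Å)³ voxels over ±1000 Å — wide enough for the
(i±2) neighbor shells. Counting is directional: an unordered pair
contributes once per member, matching the per-particle definition.
Normalization divides by the neighbors actually binned, so the map is
a probability and sums to 1. An optional principal-axis alignment
(PCA of the accumulated vectors; the smallest-variance axis goes to z,
with a sign flip to keep the rotation proper) puts a membrane in the
xy-plane. The plane fit and the "direction of least variation" are the
same operation and are implemented once.

For lamella damage, particle coordinates are PCA-aligned the same way,
the median z is subtracted to center the ice layer at z = 0, and one
(z, score) pair per particle is returned. Depressed LCCmax toward
|z| → surface is the damage signature.

## The phantom generator

The synthetic module is the package's ground truth. It emulates the
data regime the method is designed for: a tomogram-voxel-size template
(default: an asymmetric sum of Gaussian lobes, ~300 Å across with
25–40 Å features, windowed to its nominal diameter — a synthetic
stand-in for a ribosome map), planted at seeded rejection-sampled
positions (pairwise separation ≥ 350 Å, clear of the invalid margin)
with orientations drawn as uniform random quaternions — independent of
the orientation-set generator under test. The summed volume is then
wedge-filtered (binary 39° wedge by default) and degraded with white
Gaussian noise calibrated so that signal variance / noise variance
equals the requested SNR (0.5 at study conditions, measurable and
unambiguous).

What it deliberately does not model: structured background (membranes,
crowding), per-tilt CTF and dose weighting, correlated reconstruction
noise, alignment errors. Passing the recovery tests therefore
demonstrates the correctness of the scoring, search and extraction
machinery under the stated degradations — not detection performance on
real cellular tomograms, where background structure dominates the
false-positive budget.

## Problem sizes and numerical choices

The validation suite runs matching end to end at a 128³ phantom with 25
particles, SNR 0.5, a 39° wedge and a 15° search (~4400 orientations),
and compares planted-particle LCCmax medians against a 7° search
(~43,000 orientations) evaluated at the planted positions only — the
median is a property of those voxels, so the full 7° score volume is
not needed. Module tests use 16³–96³ volumes. Other choices, made once:

* Rotation center is `floor(n/2)` on each axis; voxels mapped from
  outside the box are zero; the mask, when not spherical, is rotated
  with linear interpolation and clamped to [0, 1].
* Positions whose local standard deviation falls below 1e-8 × the
  global volume standard deviation score 0 (flat-region guard against
  division blow-up).
* The low-pass edge is a raised cosine two Fourier voxels wide; the
  wedge mask is sharp binary with an optional angular smoothing width.
* The soft spherical mask has σ = 1.5 voxels by default and is exactly
  zero beyond radius + 3σ, keeping the stated support.
* The CTF truncation acts on the zero of the full
  amplitude-contrast-shifted curve, not the pure phase term.
* MRC voxel sizes are float32 in the file format, so a 13.8 Å voxel
  round-trips to ~1e-8 relative precision, not exactly.
* Gimbal-lock decompositions (middle angle within ~1e-8° of 0 or 180)
  put the whole in-plane rotation on the third angle.

## Known limitations

The engine is single-threaded CPU code; a GPU or multi-process backend
would change speed, not results (the split/merge contract pins the
numbers). Only spherical-mask searches enjoy the reused-denominator
shortcut; arbitrary masks pay three extra large FFTs per orientation.
Scores other than the LCC (e.g. constrained correlation), symmetry-
reduced orientation sets, hierarchical coarse-to-fine search, per-tilt
3D CTF modeling and polysome chain tracing are out of scope.
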