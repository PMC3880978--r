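---
title: "How rigid coregistration perturbs PET quantification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How rigid coregistration perturbs PET quantification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcoreg)
```

## The problem

Quantitative FDG-PET reads -- SUVmax, metabolic tumor volume (MTV, ml) and
total lesion glycolysis (TLG = MTV x SUVmean) -- are routinely taken not
from the PET reconstruction grid but from the PET volume *after* rigid
coregistration to a CT, i.e. after the PET has been resampled onto the CT
voxel lattice by trilinear interpolation. Even a perfectly rigid transform
therefore changes every voxel value these reads are computed from. This
package provides an in-silico replication of that pipeline on digital
phantoms with analytic ground truth, so that each stage (interpolation,
registration, segmentation, quantification, statistics) is separately
verifiable.

The mechanism is elementary but easy to underestimate:

* a translation by an exact multiple of the voxel size incurs **no
  interpolation at all** -- the resampled volume is an index-shifted copy;
* a translation by half a voxel (plus any integer part) maximizes the
  interpolation: each output voxel is the average of two neighbours;
* trilinear interpolation is a convex combination, so the resampled
  maximum can never exceed the source maximum -- SUVmax can only drop
  under noise-free pure resampling;
* everything is worse on a coarse grid (5 mm CT slices) than on a fine
  one (1 mm slices).

## Geometry and transforms

An `image_geometry` maps a 0-based continuous voxel index $v$ to world
coordinates $x = o + R\,(v \circ s)$ with spacing $s$ (mm), origin $o$
(the *center* of voxel $(0,0,0)$) and an orthonormal direction matrix
$R$ with $\det R = +1$. All resampling evaluates the source at target
voxel centers; together with the voxel-center origin convention this
makes the "integer shift = no interpolation" property exact (continuous
indices within $10^{-9}$ of a grid node are snapped onto it so the
property survives floating-point round trips through world
coordinates). Grid presets reproduce the simulated acquisition: PET
4.1 x 4.1 x 5.0 mm, diagnostic CT ("ct1") 1.4 x 1.4 x 1.0 mm, low-dose
CT ("ct5") 1.4 x 1.4 x 5.0 mm. The field of view is configurable and
defaults to a lesion-centered thoracic sub-volume (about 131 x 131 x
100 mm) rather than the full scanner matrix; voxel sizes, which drive
all interpolation effects, are never changed.

Rigid transforms use intrinsic Z-Y-X Euler angles in degrees
($R = R_z R_y R_x$), a translation in mm and an explicit rotation center
(the commercial software being emulated does not document its
parameterization; any proper rigid parameterization is equivalent, and
ours is round-trip tested: compose/invert map 100 random points back to
within $10^{-9}$ mm).

## The synthetic data

`phantom_spec()` describes an idealized solid lung lesion: a sphere or
ellipsoid of uptake `suv_lesion` in a homogeneous background, optionally
with a concentric cold core (fraction of the radii, default core uptake =
background: central necrosis). Phantom generation voxelizes by
center-inclusion, convolves with an isotropic Gaussian of 5 mm FWHM
(the reconstruction filter; $\sigma =$ FWHM/2.3548, kernel truncated at
$4\sigma$ and renormalized -- the blur is applied to the
background-subtracted map so a constant background is preserved
exactly), then adds i.i.d. Gaussian noise clipped at 0 SUV. The true
volume is carried analytically ($\tfrac43\pi r_1 r_2 r_3$; a necrotic
core remains part of the lesion support). Clipping at zero is the only
deviation from strict Gaussianity and only matters in air.

`cohort_spec()` emulates the lesion population of a 28-lesion clinical
lung cohort: true volumes log-uniform over 1.1-27.2 ml, uptake uniform
over SUV 1.6-30.9 (the printed cohort ranges), lung background 0.5 SUV,
25% of lesions necrotic, mild random ellipticity (volume-preserving,
axis ratios within about +/-20%) and sub-voxel random placement. Noise
defaults to 0.15 SUV -- moderate for a modern reconstruction; the paper
does not quantify its image noise, so the property tests are also run
at 0. Per-lesion seeds are `master seed + lesion index`.

`body_model()` adds a simple torso when a scene needs whole-field
structure: an eccentric elliptic cylinder of soft tissue (mild uptake
1.0 SUV / about +30 HU) around a lung compartment, tapered along the
axis so that axial position and out-of-plane rotations are identifiable.
`generate_pseudo_ct()` renders the same (optionally displaced) anatomy
in HU-like units, with a seeded smooth parenchymal texture and voxel
noise in the lung. The intensity mapping is deliberately not monotone
in the PET values -- chest wall and lesion share soft-tissue density
while their uptake differs by an order of magnitude -- so registration
must rely on mutual information rather than any linear intensity
relationship (the aligned PET/CT voxel correlation is kept below |r| =
0.9 by construction).

What the generator does **not** emulate: projection-space physics (no
OSEM, attenuation, scatter), respiratory motion, irregular lesion
shapes, heterogeneous background uptake. Passing tests therefore show
that the *resampling arithmetic, registration machinery and threshold
segmentation* behave as claimed -- not that clinical deviations will
numerically equal the phantom ones.

## Mutual-information rigid registration

`register_rigid()` maximizes the mutual information (in bits, from a
64 x 64 equal-width joint histogram) between the fixed CT and the PET
sampled through the candidate transform, over 6 rigid parameters from an
identity start, with a derivative-free direction-set search (cyclic
bracketed golden-section line searches, translations before rotations,
two rounds with shrinking steps; convergence at $10^{-3}$ mm / $10^{-3}$
degrees). The `fast` and `slow` modes differ only in the fraction of the
fixed grid sampled for the similarity (5% vs 50%), mirroring commercial
fast/slow variants that differ in the number of samples.

Two estimator details matter far more than the optimizer and are worth
recording:

* **Off-grid sampling.** Sampling the similarity at voxel centers makes
  MI systematically higher for transforms that align the two voxel
  lattices (interpolation then smooths less), biasing recovered
  transforms by up to about a degree. Sample positions are therefore
  drawn at random *continuous* positions, frozen per registration
  (seeded).
* **Constant sample population.** If samples that map outside the
  moving volume are dropped, MI can rise simply because boring border
  samples leave the pool -- self-registration then drifts away from the
  identity. If they are instead read as the out-of-field value, MI is
  biased toward transforms that keep everything in view. The sampling
  region is therefore eroded by the worst-case displacement of the
  search range (+/-10 mm, +/-4 degrees by default), so the same samples
  stay in bounds for every candidate.

Registration accuracy is characterized by `registration_experiment()`:
random known 6-DOF misalignments (+/-6 mm, +/-2 degrees) of a torso
scene with two lung lesions and a cardiac-like organ, recovered on the
1 mm diagnostic CT grid. Slow mode recovers translations to about
0.1-0.4 mm and rotations to about 0.2 degrees on average, and is
consistently more accurate than fast mode. Rotation recovery is
information-limited by the 5 mm PET resolution: a 0.5 degree rotation
displaces even the chest wall by well under a voxel, and roughly one
random draw in twenty lands on a coupled rotation-translation ridge of
the MI surface where the estimator's peak sits about 0.6 degrees from
the truth (we verified the displaced peak is a property of the surface,
not of the optimizer, and is insensitive to bin count and CT
smoothing). The package therefore states per-draw guarantees for
translation and mean-level guarantees for rotation.

## Segmentation

Four delineation methods, each confined to a per-lesion VOI box with the
seed at the VOI maximum ("measured maximum activity" is always the VOI
maximum of the image being segmented, never carried over from another
image):

* **T40 / T50 / T60**: all voxels with at least 40/50/60% of the VOI
  maximum (inclusive `>=`), reduced to the 26-connected component
  containing the seed. Nested by construction: T60 within T50 within T40.
* **AT** (background-adapted, volume-reproducing): fixed-point
  iteration from the T40 mask; each step estimates the local background
  $B$ as the mean over a shell 1-3 dilation steps (26-connectivity)
  outside the current mask inside the VOI, thresholds at
  $T = B + f\,(\max - B)$, and re-segments; stops when the mask repeats
  (a 2-cycle returns the last mask flagged non-converged). Adding a
  constant to the whole volume leaves the AT mask unchanged -- the
  defining contrast with the fixed thresholds. The commercial tool's
  exact update rule and calibration are not published; this scheme is a
  documented, testable stand-in that honours "volume-reproducing
  threshold after subtraction of local background".
* `calibrate_volume_reproducing_fraction()` fits $f$ by minimizing the
  mean squared relative volume error on noise-free blurred spheres
  spanning over a decade of volume (interior minimizer required in
  (0.2, 0.8)). The package default $f = 0.41$; calibration on 1.2/4/14 ml
  spheres on the 5 mm CT grid gives $f \approx 0.42$ and reproduces
  held-out sphere volumes within 15%.

Ties for the VOI maximum break to the lowest linear index; VOI bounds
are 1-based R array indices while geometry index space is 0-based
continuous (the NIfTI convention).

## Quantification and statistics

`quantify_lesion()` reports SUVmax as the VOI maximum (independent of
segmentation method, as the study design implies), MTV as voxel count
times exact voxel volume, SUVmean over the mask, and TLG = MTV x
SUVmean (exact product in every emitted record). Deviations are always
coregistered minus original, in percent of the original.

`wilcoxon_signed_rank()` drops zero differences, uses average ranks for
ties, enumerates all $2^n$ sign patterns exactly for $n \le 12$ and
switches to a tie-corrected normal approximation with continuity
correction above. `bland_altman()` reports the mean difference, the
sample SD, 95% limits of agreement (mean +/- 1.96 SD) and the +/- 2 SD
lines often drawn on agreement plots -- both are emitted, labeled
distinctly, mirroring the mixed usage in the literature. Quantiles are
linear-interpolation order statistics (R type 7). Lesions are treated
as independent even when a clinical cohort would nest them in patients;
the replicated study design does the same.

## The study pipeline

`run_study()` executes the full design per lesion: generate the PET
phantom inside a FOV-scaled torso; draw a true misalignment (translation
uniform within +/-1.5 PET voxels per axis, rotation within +/-2 degrees
-- the source study reports only that large deviations came from shifts
far from voxel multiples, not its actual transform magnitudes); resample
the aligned PET onto each target CT grid with the identity transform
(the "original", OR, arm -- so OR and coregistered data live on the same
grid and differ only by the transform's interpolation); resample through
the true transform (`truth` mode) or a transform estimated by MI
registration (`rf`/`rs`); segment both arms independently with all four
methods; quantify; summarize. Everything is seeded and deterministic;
per-lesion failures are tabulated without aborting.

`truth` mode is the default: it isolates the pure interpolation effect
that the study is about, with no registration error mixed in, and is
what the cohort-level tests use; `rf`/`rs` add the estimated-transform
realism at registration cost and are validated separately by
`registration_experiment()`.

Two mechanistic experiments complete the picture. `shift_sweep()`
translates a noise-free phantom along one grid axis by a fraction of
the voxel size: deviations vanish at fractions 0 and 1 and peak near
0.5. The sweep phantom is a *prolate* necrotic ellipsoid (long axis
along the shift): for an in-plane symmetric lesion the blurred maximum
is a spherical ridge that the 1.4 mm in-plane grid re-captures at any
axial offset, leaving SUVmax exactly unchanged -- the elongated shape
gives the maximum a point-like neighborhood so the sweep actually
probes it. `heterogeneity_contrast()` compares volume-matched necrotic
and homogeneous twins at a half-voxel shift on the 5 mm grid. The
necrosis effect is regime-dependent: it requires a large lesion with a
thin viable rim (defaults 15 ml, core fraction 0.65, elongation 1.4),
where axial smoothing depresses the rim maximum, the adaptive threshold
drops with it and the mask inflates (about +20% MTV and -9% SUVmax at
default settings, versus about -4% and 0% for the homogeneous twin).
For mid-size necrotic spheres the contrast can invert, because the
homogeneous twin's MTV jumps by whole axial cap layers while the ridge
maximum never moves -- a genuine limitation worth knowing when reading
single-lesion anecdotes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 28-lesion cohorts
(5 seed replicates for the grid-coarseness comparison), 20-seed
registration recovery, 11-point shift sweeps, 3-sphere calibration with
held-out evaluation, and a 4-lesion two-mode study for byte-level
determinism of the CSV outputs. These sizes were chosen to exercise
every code path at full fidelity on a single CPU; all of them scale up
by changing one argument.

Degenerate inputs are errors, not warnings: empty VOIs, non-positive
VOI maxima, empty background shells, zero-valued original quantities in
relative differences, non-overlapping volumes in the joint histogram,
calibration sets without a decade of volume span. Out-of-field sampling
returns 0 SUV (air) by design, not an error.

## Known limitations

* Phantoms are ellipsoids with at most one concentric core; real
  lesions are irregular and textured.
* No projection-space simulation: blur + additive noise stands in for
  reconstruction; noise correlations of iterative reconstruction are
  absent.
* The AT method is a faithful-in-spirit stand-in for the unpublished
  commercial algorithm.
* Registration rotation recovery is mean-accurate but has heavy-tailed
  per-draw errors at the 0.5 degree scale, as discussed above.
* Cohort-scale numbers from any specific clinical population are
  reproduced qualitatively (coarse grid worse than fine, SUVmax biased
  down, MTV inflated for rim lesions), not numerically -- they depend
  on patient data this package does not model.
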