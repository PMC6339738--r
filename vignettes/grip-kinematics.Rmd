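---
title: "Bone-model measurement of finger flexion during cylinder gripping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-model measurement of finger flexion during cylinder gripping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripangle)
```

This vignette explains what `gripangle` computes, the assumptions behind its
synthetic data generator, the numerical choices made where the measurement
protocol leaves room, and what the test suite does and does not establish
about real data.

## 1. The measurement model

The hand coordinate frame has its origin at the dorsal concavity of the
capitate; the y axis runs along the long axis of the third metacarpal
(proximal positive), the x axis is palmar-dorsal (palm positive), and the z
axis radioulnar, completing the right-handed triad.  `build_hand_frame()`
constructs it from four reference points; because no algorithmic rule exists
for locating the capitate landmark on an arbitrary mesh, the origin is an
input, not something the package detects.

For each of the 16 bones (4 fingers × metacarpal, proximal, middle, distal
phalanx), the two end centers are estimated from eight surface points placed
at approximately 45° intervals around the end's outer circumference.  The
estimator is the **arithmetic centroid** of the eight points.  The protocol
only says the center is "determined from" the points; the centroid is the
simplest faithful reading, is exact for evenly spaced points on a circle,
and is permutation- and rigid-motion-equivariant.  A least-squares 3D circle
fit (`fit_ring_circle()`: total-least-squares plane by SVD, Kasa
initialization, Gauss–Newton refinement of geometric distances) is available
via `estimate_center(ring, "circle")` and serves as the independent
cross-check: under the default landmark noise the two estimators agree to a
mean gap of ~0.17 mm (500-seed Monte Carlo).

Bone axes are unit vectors from base center to head center; a joint's
flexion angle is `acos` of the clipped dot product of its two bone axes,
unsigned in `[0°, 180°]`.  Hyperextension is therefore not distinguished
from flexion — the protocol reports positive flexion only.  All interfaces
speak degrees and millimetres; radians appear only inside function bodies.
Dot products are clipped to `[-1, 1]` before `acos` to absorb floating-point
drift.

Missing bones do not vanish silently: `measure_hand()` always emits 12
records per hand, with explicit `missing-data` markers that downstream
summaries and ANOVAs refuse, because every statistic here assumes a balanced
design.

## 2. The synthetic hand

Real CT segmentations of gripping hands are not publicly available, so the
package generates its own geometry with known ground truth.

**Bone proxies.** Each bone is a watertight capsule: a cylindrical shaft
joined to spherical head/base caps (`make_phalanx_mesh()`).  The measurement
procedure only relies on near-circular end circumferences, which real
condyles approximate.  Mesh volume agrees with the closed-form
segment+cylinder+segment volume within 2% at resolution 64.

**Anthropometry.** `default_hand_specs()` scales segment lengths from a
185.8 mm hand (the mean hand length of the reference cohort of ten adult
men) using standard phalangeal proportions; e.g. the middle finger ray is
65/42/26/17 mm for metacarpal through distal phalanx, with shaft radii of
3.5–4.2 mm and cap radii of 4–7 mm.

**Forward kinematics.** Flexion is planar per finger about a z-parallel
axis: the metacarpal points distally and each joint rotates the next bone
toward the palm by its flexion angle.  Abduction/adduction is not modelled —
only flexion angles are analyzed.  Per-joint angles recovered from the true
centers equal the posed angles to 1e-9°, which is the foundation the
measurement tests stand on.

**Grip solver.** `solve_grip_pose()` replaces a human subject with a
closed-form wrap model.  The joint positions are treated as chords of a
circle of radius `diameter/2 + shaft_radius + 3 mm` (the 3 mm being a soft
tissue pad between bone surface and cylinder); each joint's turn angle is
the sum of the half-arc angles `asin(L/(2ρ))` of its two adjacent chords,
with the distal half of the metacarpal contributing the palm-cupping share
of the MP angle.  Beyond the chord-feasible regime (`L > 2ρ·sin 60°`) the
half-arc is extended linearly (C¹) so the wrap measure stays defined and
strictly increasing for arbitrarily tight cylinders, and each joint is
hard-capped at normative range-of-motion values per finger (e.g. 70°/107°/85°
for the middle finger's DIP/PIP/MP).  The solver is deliberately a
direction-of-effect stand-in, not a biomechanical contact simulation: what
the pipeline validates is that every joint angle decreases strictly from
10 to 60 to 120 mm, never increases along a fine diameter sweep, and
vanishes in the locally-flat limit.  In the wrap regime the bone-surface
contact residuals stay within the 4 mm scenario tolerance (3 mm pad plus
half the sagitta of the longest phalanx chord at the 60 mm grip, the
physical analogue of pulp compression).  A cylinder thinner than the gap the
fully flexed fingertip leaves against the palm cannot be pinned at all; that
diameter is reported in the `infeasible-grip` error.

**Landmark noise.** Manual point picking is emulated by uniform angular
jitter of ±10° about the nominal 45° spacing plus isotropic Gaussian
positional noise with 0.2 mm SD (plausible sub-voxel picking error for
0.5 mm CT slices).  Under this model a single ring centroid errs by
~0.2 mm, but it is unbiased: the mean centroid over 1000 rings lands well
under 0.1 mm from the true center.  End-to-end, noiseless rings reproduce
posed grips to better than 0.5° and the default noise gives a mean absolute
angle error well under 2°.

**Cohort simulator.** `simulate_cohort()` draws balanced
subjects × diameters × fingers × joints records as

```
angle = cell_mean + f·cell_sd·z_subject + sqrt(1 − f²)·cell_sd·ε
```

with `z_subject` shared across all of a subject's cells, so that the
marginal per-cell SD equals the stated cell SD regardless of the split
`f = subject_sd_fraction`.  The published tables report only total cell SDs;
the between-/within-subject split is unknowable from them, so `f` defaults
to 0.5 and is surfaced in the configuration rather than hidden.  Angles are
clipped to `[0°, 180°)`; for wide low-mean cells this occasionally produces
an exact 0° PIP, whose coupling ratio is then flagged `undefined-ratio`
rather than silently dropped.  The default cell parameters are the published
per-cell means and SDs (`grip_cell_parameters()`), i.e. the simulator
reproduces the study conditions: 10 subjects, cylinders of 10/60/120 mm.

What the generator does **not** emulate: biofidelic bone shape, tendon or
contact mechanics, thumb kinematics, hyperextension, or any non-normal or
skewed angle distribution.  Green tests demonstrate that the measurement and
statistics recover what this generator encodes — they do not certify
segmentation quality or landmark reproducibility on real CT data.

## 3. The statistics

`rm_anova()` implements the balanced, fully-within-subject factorial ANOVA
from scratch.  In a balanced crossed design Type III sums of squares
coincide with sequential sums of squares, and every effect's SS follows from
marginal means by inclusion–exclusion; each within effect is tested against
its own effect×subject interaction.  The implementation is verified to 1e-8
(observed: ~1e-14) against `aov()` with `Error()` strata on seeded datasets,
and the full decomposition (subject + effects + error terms = corrected
total) closes to 1e-8 relative.

Sphericity is assessed per effect with Mauchly's test on the orthonormal
contrast covariance (Kronecker products of per-factor Helmert contrasts for
interactions), using the standard two-term chi-square expansion; the
implementation matches `stats::mauchly.test()` to machine precision.  When
the test rejects at α = 0.05 — the package-wide α, since no separate gate
level is conventional — both df of that effect's F test are multiplied by
the Greenhouse–Geisser ε (trace form, clamped to `[1/df, 1]`); mean squares
are recomputed on the corrected df so `MS = SS/df` always holds in the
output.  Greenhouse–Geisser is used whenever correction is applied; the
Huynh–Feldt alternative is intentionally not offered.  Two-level effects are
vacuously spherical (ε = 1).  With 10 subjects the three-way interaction's
contrast covariance (12 dimensions vs 9 error df) is singular; it is
reported as the `W = 0` boundary case with a warning and left uncorrected,
which mirrors how such designs are reported in practice.  Applying ε ≤ 1
never decreases a p-value, and under a null simulation each effect's
rejection rate at α = 0.05 stays within [0.03, 0.07].

`simple_main_effects()` runs the one-way repeated-measures ANOVA of one
factor inside each combination of the others, each on its own
within-combination error term — numerically identical to `rm_anova()` on the
subset.  `bonferroni_pairwise()` uses paired t tests (the common post-hoc
for within-subject factors when the software is unspecified) with the family
defined as the `k(k−1)/2` comparisons within one fixed combination — m = 3
for diameters and joints, m = 6 for fingers — matching how the published
comparison tables are organized; a `family = "global"` switch widens the
family if desired.  `p_adj = min(1, m·p)` and the direction string (e.g.
`"10 > 60"`) is emitted only below α.  p-values under 5·10⁻⁴ render as
`<0.0005` in the formatted tables.

The coupling ratio is computed **per subject first** and only then averaged
(mean of ratios); on heterogeneous subjects this differs from the ratio of
means, and the tests pin the convention.  Marginal "All" entries of the CR
table are equal-weight means of the collapsed cells, which on balanced data
equal the pooled means — the published marginals are consistent with this
reading (0.80 for the 60 mm row, 0.88 for 120 mm, 0.75 grand), and the
pipeline enforces balance so the ambiguity never bites.  Rounding happens
only at presentation: one decimal for angles, two for CRs.

## 4. Numerical and design choices

* Sample SDs use the n−1 denominator throughout (subject samples).
* Dot products are clipped before `acos`; frames must be orthonormal to
  1e-9; unit-vector inputs to `flexion_angle()` are checked to 1e-6.
* All randomness flows through explicit integer seeds (`with_seed`
  internally saves and restores the caller's RNG state); no call site draws
  from ambient entropy.
* Interchange formats: CSV (comma, UTF-8, `.` decimal, mandatory header
  `subject,diameter_mm,finger,joint,angle_deg`), YAML configuration with an
  exact load–save round trip, JSON manifests recording the seed, and
  PLY/STL meshes in ASCII and binary dialects.  PLY is written at double
  precision so round trips are lossless; binary STL is float32 by the format
  definition, and its round trip is exact only to that precision.
* The mesh landmark picker (`pick_end_rings()`) finds each cap circumference
  by a fixed-point search on the radial profile and prefers a single
  latitude ring when the mesh exposes one; base/head ends are disambiguated
  afterwards by chain proximity (`grip_measure()`), since a principal axis
  has no intrinsic sign.
* Simulation sizes in the tests are chosen to keep the default suite under
  about a minute: 1000 null replicates for type-I error, 200 cohort seeds
  for the power check, 100 seeds for the noisy-recovery error, n = 10000
  for generator-honesty checks.

## 5. Known limitations

* The grip solver is phenomenological; its angles at intermediate diameters
  track the published magnitudes only loosely, and only its monotone
  structure is load-bearing.
* Power of the 10 vs 120 mm Bonferroni comparison under the published cell
  statistics is ~0.85 for the index DIP at n = 10 (the published index-DIP
  contrast was itself the weakest, p = 0.011); expectations of near-certain
  replication for that one cell are not supported by the cell statistics
  themselves.
* Unbalanced or mixed between/within designs, non-parametric alternatives,
  thumb kinematics and articular-surface-based joint centers are out of
  scope; the statistics refuse unbalanced input rather than approximating.
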