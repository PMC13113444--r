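---
title: "Estimating lower-limb muscle forces from slow-gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-limb muscle forces from slow-gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmuscle)
```

## The problem

Estimating the forces that individual lower-limb muscles produce during
walking normally requires either surface electromyography (sEMG) or a full
musculoskeletal simulation with static optimization. Both are poorly suited
to elderly and post-stroke populations walking slowly: sEMG of weak, slow
contractions is noisy and hard to obtain from deep muscles, activation
patterns after stroke no longer map cleanly onto force, and full
simulation pipelines are computationally heavy and demand specialist setup.

`gaitmuscle` implements a simplified, kinematics-only alternative. During
slow walking the dominant determinant of a muscle's force is its
instantaneous fiber length; segment accelerations and activation dynamics
contribute comparatively little. The package therefore estimates
*normalized* active and passive force profiles — shapes over the gait
cycle, not newtons — from three ingredients:

1. a subject-scaled skeletal geometry (a "digital twin"),
2. time-varying muscle-tendon lengths computed from gait kinematics, and
3. a Hill-type force-length relation parameterized by a muscle
   architecture index.

This restricts the model's validity to slow gait: as walking speed grows,
inertial and activation effects the model omits become material, and
agreement with reference simulations is expected to degrade. That is a
scope statement, not a defect.

## Subject scaling

Cadaver reference geometries tabulate lower-limb dimensions but usually
lack trunk data. The missing sternum-head distance $y$ (mm) is regressed
on standing height $x_h$ (mm):

$$y = 0.3674\,x_h - 297.0699, \qquad r^2 = 0.97.$$

Alternative branches on body mass ($y = 2.1135\,x_w - 188.2610$,
$r^2 = 0.52$, $x_w$ in kg) and sitting height ($y = 0.7111\,x_s -
310.3478$, $r^2 = 0.94$) exist; height is the default because its fit is
the best of the three. The mass branch's input unit is not stated by its
source; this package interprets it as kilograms and documents that choice
here.

Every body segment then receives a dimensionless scale factor — the ratio
of the subject's segment length to the generic model's — applied
isotropically to that segment's muscle attachment coordinates and to
generic optimal fiber lengths (`compute_scale_factors()`,
`scale_body_model()`). Per-axis scaling is deliberately not modelled:
only segment lengths are measured, so an anisotropic factor would be
unidentifiable. Segment masses come from total body mass times the
packaged Dempster proportional coefficients
(`segment_mass_fractions()`).

## Frames and transition matrices

Muscle attachment coordinates are published in per-segment *anatomical*
frames; gait kinematics live in *kinematic* frames. For the pelvis, the
anatomical frame sits at the pubic-symphysis midpoint with its y axis
toward the inter-ASIS midpoint; the kinematic frame sits at the
inter-ASIS midpoint with its z axis from left to right ASIS
(`build_pelvic_frames()`). The published axis conventions are internally
inconsistent about the sign of the lateral axis; this package fixes
x anterior, y superior, z to the subject's right, a right-handed triad,
for every frame.

The transition matrix between paired point sets is the closed-form rigid
Procrustes solution (SVD-based, rotation + translation, no scaling),
exact to machine precision on noiseless rigid pairs
(`estimate_transition_matrix()`). All transforms use the row-vector
homogeneous convention — a point $(x, y, z, 1)$ multiplies the $4\times4$
matrix on the right — matching how the reference pelvic matrix is
printed; `transform_parts()` converts to the column convention at the
boundary.

## Muscle model

Nine representative muscles span the lower limb: Glut_Max1, TFL, Iliacus,
Pectineus, Vas_Int, Med_Gas, Tib_Ant, Tib_Post and Soleus. Each is a
straight line from origin to insertion, each attachment fixed in its
segment's kinematic frame. No wrapping surfaces or via points are
modelled — a stated simplification; for muscles that wrap strongly
(Med_Gas at the knee, Tib_Post at the malleolus) the straight-line length
underestimates true excursion.

The instantaneous length ratio $L/L_0$ drives the normalized forces:

$$
f_l = \begin{cases}
\exp\!\left(-\left(\dfrac{(L/L_0)^{0.9631} - 1}{0.3531\,(1 - I_a)}\right)^2\right), & I_a < 1,\\[2ex]
\exp\!\left(-2.727\,\big(\ln(L/L_0)\big)^2\right), & I_a = 1,
\end{cases}
\qquad
f_p = 0.0195\, e^{(2.933 + 4.911 I_a)(L/L_0 - 1)}.
$$

Both active branches are unimodal with maximum 1 at $L = L_0$; the
passive force grows exponentially with stretch and is only prominent
beyond the optimal length. Two typographic ambiguities in the printed
source of these relations were resolved as follows and are isolated
behind `active_force()` / `passive_force()` so either could be swapped
without touching callers:

* the pennate ($I_a < 1$) active branch is reconstructed to preserve the
  printed constants 0.9631 and 0.3531 and the $(1 - I_a)$ width term
  while honouring the unimodal, max-1-at-$L_0$ contract that every
  caller and test relies on;
* the passive stiffness $(2.933 + 4.911 I_a)$ multiplies the relative
  stretch *inside* the exponential; the alternative parse puts part of
  it outside and would make $f_p$ negative for $L < L_0$, which a
  passive elastic element cannot be.

The model identifies the normalized length with muscle-tendon length over
an optimal *operating* length ($L/L_0$ straight into the force-length
relation, no tendon-slack or pennation projection), because the force
relations consume only that ratio.

### Architecture index

The architecture index $I_a \in (0, 1]$ summarizes pennation angle $x$
(degrees) and optimal fiber length $y$:

$$I_a = 0.1546 - 5.7662\times10^{-5}x + 6.6753\times10^{-4}xy
 - 2.0563\times10^{-4}x^2 - 1.3233\times10^{-3}y
 + 7.6327\times10^{-4}y^2, \qquad r^2 = 0.98.$$

Muscles with pennation below 5° are treated as parallel-fibered,
$I_a = 1$ exactly. This creates a genuine discontinuity at 5°, which the
package documents rather than smooths (`architecture_index()` jumps from
1 to the polynomial value). The regression's source tables hold pennation
between 5° and 25°; larger angles are evaluated with a warning rather
than refused, since the model is merely "best suited" in range. Raw
polynomial values outside $(0, 1]$ are clamped with a warning, because
the force relations require $I_a \le 1$ and positive.

The fiber-length unit of the regression is not stated by its source; the
anatomical tables it derives from are tabulated in centimetres, so this
package evaluates $y$ in cm (`fiber_length_cm` in `muscle_path()`). The
operating length `L0` used for $L/L_0$ normalization and the anatomical
fiber length feeding the regression are kept as separate fields: a
muscle-tendon operating length (hundreds of mm) fed into a
fiber-length regression would always clamp, collapsing every pennate
muscle to $I_a = 1$.

## Cycle-offset compensation

A muscle stretches before it contracts, so the peak of a purely
length-driven force estimate leads the peak of the actual force by a
roughly condition-stable fraction of the gait cycle (electromechanical
delay plus phase shift). The packaged table `cycle_offset_table()` holds
the empirical per-muscle offsets for five conditions; estimation applies
them as a circular forward shift of the *active* waveform only
(`apply_cycle_offset()`), quantized to the nearest sample of the
101-point grid — sub-sample interpolation is deliberately out of scope.
Passive force is never shifted, since it depends only on instantaneous
length. `estimate_cycle_offset()` recovers an offset from data as the
argmax of circular cross-correlation, ties broken toward the smallest
lag; the empirical procedure behind the packaged values is not published,
so the estimator is the package's own, validated by planted-shift
recovery.

## Gait-cycle grid and validation

All waveforms live on a fixed 101-point grid (0–100% inclusive, foot
strike to ipsilateral foot strike). `resample_to_cycle()` linearly
interpolates between consecutive foot strikes and averages multiple
cycles pointwise. Agreement with reference waveforms uses Pearson
correlation for non-pathological gait and Spearman for stroke gait
(extreme values after stroke make a linear measure unstable);
`classify_strength()` bands $|r|$ at 0.5 and 0.8 by default —
configurable, since the banding convention is not universal; a
coefficient exactly at a cut takes the higher band.

## The synthetic generator and what it does (not) show

No public mocap data accompany this model, so the package ships a
deterministic synthetic generator (`generate_gait_trial()`) and a
versioned synthetic body model (`generic_body_model()`, md5-checked).
Design choices:

* Sagittal hip/knee/ankle angles are 3-harmonic Fourier series — the
  simplest family giving smooth, realistic cyclic kinematics; the
  coefficients live in the model file.
* Four speed conditions (X-slow 0.61, slow 0.80, free 1.17, R-fast
  1.64 m/s) with realistic default stride lengths (0.90–1.45 m); cycle
  duration is stride/speed, so it decreases monotonically with speed and
  the mean forward speed is exactly nominal. Joint-angle amplitudes are
  shared across speeds — a simplification; real kinematic waveforms
  change shape with speed.
* The marker set is reduced to what the four segment frames need
  (ASIS pair, pubic point, joint centers, heel and toe) rather than a
  full 39-marker protocol.
* Muscle attachments are plausible synthetic coordinates, not cadaver
  data. Operating lengths `L0` were fixed once from the generated length
  ranges: the stretch-prone muscles TFL, Iliacus and Vas_Int get
  $L_0 = 0.95 \times$ their peak cycle length, so a cycle stretches them
  past optimum and produces visible passive force; the others get
  $L_0 =$ peak length, just reaching optimum.
* Hemiplegic gait (`generate_hemiplegic_trial()`) scales the affected
  side's harmonic amplitudes by a weakness factor and warps phase so the
  unaffected side's stance lengthens — the standard compensatory
  asymmetry — with a weakness of 1 reducing exactly to symmetric gait.
* All randomness (optional marker jitter) flows through one seed,
  default 20260326; trials are bitwise reproducible.

Passing tests on this generator demonstrate internal consistency of the
pipeline — frames, lengths, forces, offsets, resampling — under known
ground truth. They do not demonstrate accuracy on real subjects: the
generator has no soft-tissue artifact, no marker occlusion, no
inter-subject anatomical variability, and its reference "truth" is its
own forward kinematics. Subject-level correlation studies against
independent musculoskeletal simulations require mocap data that is not
publicly deposited, and are therefore outside what this package can
verify; the hemiplegic asymmetry check (affected-side hip-muscle force
peaks below unaffected-side peaks) is the qualitative stand-in.

## Numerical choices

* Procrustes fits refuse fewer than 3 points or collinear sets (singular
  value ratio below $10^{-9}$); the proper-rotation branch of the SVD
  solution is always taken, so reflections cannot leak in.
* Constructed transforms must be orthonormal to $10^{-6}$; transforms
  transcribed from printed sources carry their own looser tolerance
  (printed 4-decimal entries are orthonormal only to about $10^{-4}$),
  which propagates through inversion and composition.
* Degenerate landmark geometry (coincident or collinear pelvic points)
  raises an error rather than producing a NaN frame.
* Normalization refuses all-zero or negative-maximum series; correlation
  refuses constant series — both are undefined, not zero.
* Cycle offsets are validated to $[0, 100)$; shifts are circular with
  period 100 samples and the duplicated 100% sample is rewritten to
  match 0%.
* Internal units are millimetres (marker files are read in mm); the
  architecture regression input is centimetres; masses are kilograms.

## Problem sizes

The test suite and the acceptance script run the generator at 100 Hz
with 3 gait cycles (a few hundred frames), 100 planted rigid transforms
on 4-point sets, and 50 planted cycle offsets at two noise levels —
sizes chosen so the whole verification completes in seconds on a laptop
while still exercising every code path at realistic sampling densities.

## Known limitations

* Normalized forces only: no maximum isometric force, no PCSA, so no
  newtons. Peak-to-peak *shape* comparison is the intended use.
* No activation dynamics and no velocity dependence — the model is for
  slow gait and degrades as speed rises.
* Straight-line paths bias lengths for strongly wrapping muscles.
* The parallel-muscle rule makes $I_a$ discontinuous at 5° pennation.
* The synthetic generator is a pipeline test-bed, not a gait simulator
  of record.
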