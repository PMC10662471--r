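---
title: "Center-of-mass estimation with statically equivalent serial chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-of-mass estimation with statically equivalent serial chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sescom)
```

## The problem

The three-dimensional center of mass (CoM) of a standing human is a
workhorse quantity in balance assessment, rehabilitation and sports
science, but it cannot be observed directly. The classical segmental
route — divide the body into rigid segments, attach tabulated
anthropometric masses and segment-CoM offsets, and compute the weighted
mean

$$\vec{CoM} = \frac{\sum_i m_i \, \vec{C}^G_i}{M}$$

— inherits the biases of population tables. The statically equivalent
serial chain (SESC) sidesteps the tables: for **any** branched rigid-body
chain the same CoM can be rewritten as the end effector of a virtual
serial chain,

$$\vec{CoM} = \vec{d}_1 + [R_1 \cdots R_n]
  \begin{bmatrix} \vec{v}_1 \\ \vdots \\ \vec{v}_n \end{bmatrix}
  = \vec{d}_1 + B\vec{V},$$

where $\vec{d}_1$ is the root-joint (L5/S1) position, $R_j$ is the global
rotation of joint $j$'s frame, and $\vec{V}$ is a constant $3n$-vector
absorbing every mass, offset and segment-CoM term. $\vec{V}$ is
*subject-specific but posture-invariant*, so it can be identified once per
person by least squares from a set of static calibration postures — and
in static postures the force-plate center of pressure (CoP) is the
horizontal projection of the CoM, so a force plate supplies the reference
without any anthropometry. After identification, the full 3D CoM follows
from joint angles alone.

This package implements the full workflow — kinematic body models of
graded complexity, identification, CoM estimation, raw-signal
preprocessing, and agreement evaluation — together with a synthetic-data
generator that provides ground truth for every stage.

## Body models and conventions

Four preset branched structures of increasing complexity are provided,
all rooted at L5/S1:

| model | joints | DoF | joint types |
|---|---|---|---|
| a | 7 | 7  | all hinge (flexion/extension) |
| b | 9 | 13 | hinge trunk/knees/ankles, universal shoulders/hips |
| c | 7 | 17 | spherical trunk/shoulders/hips, hinge knees |
| d | 9 | 19 | as (b) with spherical trunk/shoulders/hips |

Conventions, fixed once and used everywhere:

* Global frame: X anteroposterior (anterior positive), Y mediolateral,
  Z vertical up. Flexion/extension is rotation about Y, so a Y-only
  model generates **no** mediolateral motion — this drives the model-(a)
  degeneracy below.
* Joint rotations compose in the fixed-axis order
  $R = R_y(\alpha) R_x(\beta) R_z(\gamma)$ (the ZXY convention of
  IMU motion-capture exports); hinge and universal joints use the
  leading one or two factors. The same convention is applied to both
  body sides; side-specific sign conventions, if present in a vendor
  export, must be resolved upstream.
* Units: radians and meters internally; degrees and millimeters at every
  file boundary (matching the 1.5° and 6 mm static criteria).
* Transforms are stored as rotation+translation pairs; composition is
  identical to chained 4×4 homogeneous matrices.

The simplest preset deserves a note: the canonical 7-joint set of model
(a) is L5/S1, both shoulders, both hips and both ankles, with the
thigh+shank lumped into one segment between hip and ankle. A prose
listing of only "L5/S1, shoulders and ankles" would give 5 joints; the
7-joint, 7-segment structure with two 3-deep leg chains forces the hips
to be included, and that is the unique reading consistent with the
companion model (c) ("a knee joint instead of the ankle joint").
Arms are single segments in every preset (no elbows), and the head is
lumped with the trunk.

`project_posture()` maps recordings made under a rich model onto a
simpler one by decomposing each joint rotation in the ZXY sequence and
*retaining exactly* the components the target joint names. Because the
presets' DoF sequences are nested prefixes (y; y,x; y,x,z), this is a
component selection. It is deliberately **not** the best low-DoF
approximation of the rotation in the Frobenius sense — the dropped-angle
truncation can be beaten by a joint re-optimization of the retained
angles — but it is what an angle-export pipeline actually does: each
reported angle component is kept or ignored, never re-fitted.
Decompositions at gimbal lock ($|\cos\beta|<10^{-9}$) are flagged rather
than silently resolved.

## Identification

Stacking $B$ over $k$ postures gives a linear system for $\vec{V}$.
With full 3D CoM observations (possible only synthetically) the system
uses all three rows per posture; with CoP observations the vertical row
is dropped and the $2k \times 3n$ system

$$\vec{V} = \begin{bmatrix}B_{x} \\ B_{y}\end{bmatrix}^{\dagger}
  \begin{bmatrix}CoP_x - d_{1,x} \\ CoP_y - d_{1,y}\end{bmatrix}$$

is solved, requiring $k \ge \lceil 3n/2 \rceil$ distinct postures
(enforced as an error, overridable). The root position $d_1$ is
subtracted per posture (floating-base form), consistent with unifying
all frames at the L5 origin.

Numerical choices:

* The pseudoinverse is computed by SVD with a relative singular-value
  cutoff of $10^{-10}$, not by the normal equations
  $(B^TB)^{-1}B^T$ — the normal-equations form squares the condition
  number. On well-conditioned systems the two agree.
* Rank deficiency is intrinsic here, not an accident: every chain of
  Y-only joints (hip → knee → ankle) shares its mediolateral $B$ column
  with its parent, because $R_y$ fixes the global Y axis. Model (d)
  therefore has rank 23 of 27 even with perfectly diverse postures, and
  the flexion-only model (a) couples *all* mediolateral columns (rank
  15 of 21). The fit reports the unidentifiable columns and returns the
  minimum-norm solution; predictions are unaffected because the null
  space is posture-invariant — the same column coincidences hold at
  estimation time.
* With 3D observations, rank deficiency is treated as an error instead
  (the idealized identification has no business being degenerate).

For a subject with known parameters the true vector has the closed form

$$\vec{v}_j = \frac{1}{M}\Big(m_j \vec{c}_j +
  \sum_{q \in \mathrm{children}(j)} M_{\mathrm{subtree}(q)}\,
  \vec{o}_q\Big),$$

(each joint carries its own segment's first moment plus the moments of
the subtrees hanging from it), and `estimate_com(model, sesc_true_vector(...), ...)`
reproduces `com_weighted_sum()` to floating-point accuracy. This
identity is the package's central oracle and is asserted across all
presets in the test suite.

## Preprocessing

Raw sessions arrive as joint-angle series (60 Hz, degrees) and CoP
series (1000 Hz, mm). The pipeline is: 4th-order zero-phase Butterworth
low-pass at 10 Hz for the CoP; resampling to 60 Hz (zero-phase
anti-alias filter at 45% of the target rate, then spline interpolation);
frame unification by subtracting the L5 horizontal position; static
detection; 75/25 identification/testing split.

* Zero-phase (forward–backward) filtering is used because a static
  analysis must not phase-shift CoP relative to angles. Edges are
  handled by removing the line through the record's endpoints,
  odd-reflection padding, and re-adding the line; this keeps constants
  exact and passband tones within a fraction of a percent over the whole
  record.
* A posture is static when, within a sliding 1 s window, every angle
  channel's SD is below 1.5° and each CoP axis' SD is below 6 mm
  (per-axis reading of the criterion; configurable). Overlapping
  passing windows are merged; merged runs shorter than the 5 s minimum
  hold are discarded; the posture value is the channel mean over the
  run's central 1 s window. The window slides sample-by-sample rather
  than tiling, and the central-window mean is used because the hold's
  middle is farthest from the entry/exit ramps.
* The identification/testing split is random with a caller-supplied
  seed (a chronological split is available by flag); the train size is
  `round(0.75 k)`, e.g. 74/24 at the typical 98 postures.

## Synthetic study conditions

The generator emulates the study design the estimator is meant for: a
cohort of 18 adults, ~98 static postures each, truth body of model (d)
topology, CoP equal to the true horizontal CoM plus noise. Defaults,
chosen once:

* Noise is Gaussian with SDs at half the static criteria — 3 mm CoP,
  0.75° angles — so generated holds pass detection with margin.
* Segment mass fractions follow standard adult proportions
  (trunk+head+pelvis 0.578, whole arm 0.050, thigh 0.100, shank 0.0465,
  foot 0.0145), jittered ±10% per subject and renormalized; stature
  scales all offsets by ±8%; total mass is uniform on 55–95 kg.
* Posture ranges are conservative healthy range-of-motion subsets per
  joint (e.g. hip flexion −20° to 80°, knee 0–90°); all configurable.
  An optional stratified mode guarantees every DoF is excited across
  its range.
* Raw sessions are built as noisy holds joined by smooth cosine ramps,
  angles at 60 Hz and CoP at 1000 Hz, with the schedule recorded for
  round-trip tests.

What the generator does *not* emulate: physiological sway dynamics,
soft-tissue artifact, IMU bias/drift, or inter-joint coordination
(angles are drawn independently). Passing tests therefore demonstrate
correctness of the estimator and pipeline under the stated noise model,
not performance on any particular human dataset; the study's
subject-specific millimeter values depend on its raw recordings and are
not reproduction targets.

## Evaluation

Estimates are scored against held-out CoP per axis (AP, ML):

* RMS error, Pearson and Spearman correlations (two-sided).
* Bland–Altman: bias = mean difference, 95% limits of agreement =
  bias ± 1.96·SD of differences, and proportional bias by regressing
  differences on pairwise means. The proportional-bias model is pooled
  OLS plus per-subject slopes summarized by mean and between-subject SD
  — a deliberate two-stage stand-in for a likelihood-based mixed-effects
  regression, noted in reports. The hypothesis-test battery
  (Shapiro–Wilk, RM-ANOVA, Friedman, and post hocs) is standard
  off-the-shelf machinery; `compare_models()` exposes the paired
  per-subject RMS values needed to run it externally.
* A structurally degenerate estimator makes the Bland–Altman geometry
  exact: if the ML estimate is a constant $e$ per subject, then
  $d = 2e - 2m$ identically and the per-subject slope is −2 to machine
  precision. Fitting model (a) to any subject recorded under a richer
  truth body reproduces this analytically — a useful canary that the
  degeneracy reporting and the agreement layer are wired correctly.

On synthetic cohorts at the default conditions the evaluation ranks the
presets as expected: model (a) is clearly worst on both axes (its AP
error reflects the missing knees/DoFs, its ML error is the degeneracy),
and models (b)–(d) improve with diminishing returns.

## Problem sizes and determinism

All simulations in the test suite and the acceptance script are sized to
the study conditions themselves: single-subject checks use 40–98
postures; the oracle sweep uses 10 subjects × 100 postures × 4 presets;
the complexity-ordering property uses 20 replicate cohorts of
18 subjects × 98 postures. Every random draw flows through explicit
seeds (cohort seeds derive from one master seed), so any reported number
is reproducible bit-for-bit.

## Limitations

* Static postures only; no dynamic (Kalman-style) identification.
* No symmetry-reduced or node-based SESC variants.
* The preprocessing assumes gap-free, uniformly sampled inputs; no
  sensor-fusion or drift correction.
* The mediolateral components of Y-only chains are unidentifiable in
  principle (see above); the package reports rather than regularizes
  this.
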