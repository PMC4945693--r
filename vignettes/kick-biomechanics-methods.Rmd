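---
title: "Methods: from synthetic kick sequences to intramuscular forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synthetic kick sequences to intramuscular forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fetalkick` estimates the mechanical environment of a fetal kick in utero
from 2D image sequences, in four chained stages: (1) a ground-truthed
synthetic generator of cine-MRI-like kick sequences, (2) a constrained
template-matching joint tracker, (3) a plane-stress finite-element (FE)
model of the uterine wall indented by the foot, and (4) a planar
musculoskeletal model resolving the kick into per-muscle forces.  This
vignette documents the models, their assumptions, the tunable parameters,
and the numerical choices, in enough detail to judge what a passing test
suite does and does not establish.

## 1. Synthetic kick sequences

Real kick recordings of this kind are thick-slice (30-40 mm) dynamic MR
acquisitions with 2.2 x 2.2 mm pixels and one frame per 0.303 s; the raw
scans are not publicly available.  The generator therefore *defines* the
study conditions: a `kick_scenario` holds the per-fetus femur and tibia
lengths, the outer uterine ellipse axes, the maximal wall deflection, the
kick duration, and the imaging parameters.  `reference_scenarios()` returns
the three study fetuses (gestational ages 20-22 weeks, kick durations
3.0/2.0/3.3 s).

The kick itself is a simple in-plane extension: the hip stays
quasi-stationary (a smooth drift of amplitude `hip_drift_mm`, default
0.5 mm -- the residual motion is not quantified anywhere, so it is exposed
as a parameter rather than fixed), while the ankle travels along a straight
workspace path from a retracted pose to the cavity surface with a cubic
ease-in-out time profile, and then outward along the local wall normal,
ramping smoothly to the scenario's `max_deflection` at the final frame.
Knee positions come from exact two-link inverse kinematics, so
|knee - hip| and |ankle - knee| equal the scenario segment lengths to
machine precision at every frame -- the property the tracker's length
constraint is later tested against.  Frames are counted as
`floor(duration / interval) + 1` (one at t = 0 plus one per completed
interval).  First wall contact happens at 60% of the kick by default
(`contact_fraction`); the contact site is the arc midpoint of the upper
half-ellipse (`contact_angle = pi/2`), for the reasons given in section 3.

Rendering draws the wall as a bright elliptical band (membrane + muscle,
6.6 mm total) whose cavity boundary bulges outward under the ankle by the
current deflection (a Gaussian bump of half-width set by the foot width --
purely visual; the mechanics live in the FE stage), the femur and tibia as
capsules, and the joints as compact Gaussian blobs that dominate the local
contrast.  A Gaussian point-spread blur (`blur_sigma`, default 1.5 mm) and
additive Gaussian noise (`noise_sd`, default 0.05 of the dynamic range)
emulate the acquisition; both defaults were chosen once so that the
tracker operates in a realistic "mostly but not always easy" regime.
Rendering is seeded and bit-reproducible.

What the generator does *not* emulate: MR contrast physics, out-of-plane
motion, the fetal torso and arms, amniotic-fluid texture, or intensity
inhomogeneity.  Tracker results on these sequences therefore demonstrate
correctness of the algorithm under controlled appearance change and noise,
not clinical performance.

## 2. Joint tracking

The tracker follows the hip, knee and ankle with zero-normalised
cross-correlation (ZNCC) template matching.  Templates are accumulated
over frames into a per-joint ensemble scored as a weight-normalised
average of per-template ZNCC, with geometric recency weights
(`recency_decay^age`, default 0.8) so recent appearance counts most; the
frame-0 template -- the operator's manual selection -- keeps a guaranteed
weight share (`anchor_weight`, default 0.1) to bound template-update
drift.  Matching is kinematically constrained: the hip is matched within a
disc of `search_radius` (default 8 px) around its previous position; knee
candidates must lie both within that disc of the previous knee and within
+/-10% (`length_tolerance`) of the running femur length from the new hip;
the ankle likewise against the running tibia length.  Running lengths are
initialised from the seeds and updated by an exponential moving average
(rate 0.3).  The best admissible integer candidate is refined to subpixel
by separable quadratic interpolation of the correlation surface; seeds are
first snapped to the local intensity peak and the residual fractional
offset is carried through every reported position.  Ties break toward the
smallest row-major candidate index; below `min_match_score` (default 0.4)
the track is declared lost with a classed error.

The wall deflection is the translational displacement of the ankle from
its position at first contact, over the frames where the ankle is within
half a pixel (1.1 mm) of the cavity surface or beyond it.  Cohort
summaries report the mean and the *population* standard deviation
(divisor n), the convention under which the three per-fetus deflections
6.40, 7.37 and 7.07 mm summarise to 6.95 +/- 0.41 mm.

## 3. Uterine-wall finite elements

The wall is a half-ellipse bilayer ring: a 0.6 mm fetal membrane
(E = 7.53 MPa) lining the cavity, backed by 6 mm of uterine muscle
(E = 0.586 MPa), both with Poisson ratio 0.4 and linear elastic isotropic.
A round-ended cartilage probe (E = 1.1 MPa, nu = 0.49, width 15 mm --
standing in for the fetal foot, whose diameter is not recorded) is driven
along the outward wall normal by the tracked deflection in ten equal
increments, with frictionless contact against the membrane.  Elements are
4-node bilinear plane-stress quadrilaterals with 2 x 2 Gauss quadrature
and total-Lagrangian Green-strain kinematics (a 7 mm deflection of a
6.6 mm wall involves finite rotation); a geometrically linear mode is
available (`model$nlgeom <- FALSE`).  The element passes the constant-
stress patch test exactly, has exactly three rigid-body modes, and matches
the Euler-Bernoulli cantilever within 5% on a slender benchmark.

Three modelling choices deserve explanation:

* **Contact site.**  The contact is placed at the arc midpoint of the
  half model (the apex), maximally far from both symmetry edges -- the
  natural reading of "the midpoint of the geometry, avoiding edge
  effects", and the only placement that reproduces the documented
  per-fetus compliance pattern: with apex contact the largest uterus
  (fetus B) is the softest and the force order is A > C > B, with an
  implied stiffness ratio A/B of about 2.6 against roughly 2.5 from the
  published forces and displacements.  Placing contact at the quarter-arc
  instead puts fetus B's site near a cut edge and inverts the order.
* **Out-of-plane depth.**  Plane-stress forces scale linearly with an
  arbitrary out-of-plane thickness (verified exactly by the homogeneity
  test).  The package uses 35 mm, the midpoint of the 30-40 mm imaging
  section thickness: the 2D model represents the slab of tissue the scan
  actually averages.  Under this convention the per-fetus reaction forces
  come out at 0.35/0.14/0.24 N against the published 0.72/0.33/0.51 N --
  the right order and pattern, about half the scale; an exact match would
  need an (unreported) depth near 78 mm.
* **Probe driving.**  The displacement is prescribed on the probe shank,
  leaving the round cap elastic.  Driving only the back edge lets the
  soft cartilage column buckle sideways under frictionless contact;
  driving the shank keeps the probe a blunt pushed body while preserving
  a small, realistic probe-modulus sensitivity through cap compliance
  (halving/doubling the modulus changes the reaction force by under
  0.5% at the study displacement).

Contact is node-to-segment with a penalty of 100x the softest adjacent
stiffness (E x depth), two-pass (probe-tip nodes against the wall and
wall nodes against the cap), with averaged nodal normals interpolated
within segments (a C0 normal field) and a C1-regularised penalty law
(quadratic up to 0.05 mm penetration, linear beyond) -- together these
keep penetrations below ~1% of the indentation while letting full Newton
iterations converge.  The solver adds residual-norm backtracking,
automatic substepping (bisection on failure), and, as a last resort,
grounding-spring stabilisation for genuine limit points.  Meshes grade
from ~2 mm elements near contact to ~8 mm far away, marched symmetrically
outward from the contact point, with 2 layers through the membrane and 6
through the muscle; refining the wall changes the total contact force by
under 5% between the two finest levels.

Known numerical limitations, stated rather than hidden: frictionless
contact leaves a nearly neutral tangential sliding mode, so the discrete
problem admits families of slid equilibria whose total force differs by a
few percent -- this bounds the symmetric-load lateral-force check (~10%),
explains occasional substepping, and sets a noise floor for parameter
studies (the probe-modulus sensitivity is therefore evaluated by
continuation from a common branch and at the nominal displacement).  Cap
node spacings much finer than ~2 mm destabilise the two-pass contact, so
refinement studies refine the wall with the probe mesh fixed.

The bench validation scenario (`run_validation_scenario`) reuses the same
machinery for a round-ended rigid-plastic probe (E = 2.6 GPa, nu = 0.3,
10 mm diameter) pressed 5 mm into a clamped silicone sheet (E = 10.3 MPa,
nu = 0.49).  The rig's clamp span and sheet thickness are not recorded, so
they must be supplied by the user and the published peak force is treated
as a qualitative reference only; the check asserted in tests is the
physics: zero force at zero displacement, monotone loading, and identical
loading/unloading curves (elastic, frictionless).

## 4. Planar musculoskeletal model

The leg is four planar segments -- pelvis (fixed to the tracked hip),
femur, tibia, and a lumped foot with the ankle locked plantargrade, heel
leading into the wall (the reaction is applied at the calcaneus, so the
lock sign is chosen so the heel is the wall-ward point; verified
geometrically at the contact frame).  Scaling is per-segment linear from
adult reference lengths (femur 396 mm, tibia 430 mm), pelvis and foot by
the mean factor, masses by factor cubed, maximum isometric forces
unchanged -- for a 20-22-week fetus the factors are ~0.13.

Eighteen muscles ship as a CSV of planar via-point paths (fraction along
the segment axis plus perpendicular offset) and adult maximum isometric
forces approximating published gait-model values; the file is a *synthetic
planar digitization* -- 3D wrapping surfaces are reduced to fixed via
points (condyle and malleolus points added so biarticular muscles cross
joints on the anatomically correct side), and hip-flexor moment arms use
flexed-posture values (psoas/iliacus arms exceeding the rectus femoris
hip arm, as published moment-arm curves show for flexed hips).  Swap the
file to use another source set.

The analysis chain is: per-frame least-squares inverse kinematics (exact
on forward-generated data), Newton-Euler inverse dynamics with gravity
neglected (fetus and amniotic fluid have nearly equal specific gravity)
and central-difference accelerations (one-sided at the ends), then
quadratic static optimization per frame:

minimise sum(a_j^2) + w * sum((res_i / ref)^2) subject to
sum_j r_ij Fmax_j a_j + res_i = M_i and 0 <= a_j <= 1,

with moment arms r_ij = -dL_j/dq_i computed numerically from the path
geometry.  One reserve acts on each of the three moment rows (hip, knee,
locked ankle; weight w = 1e3, reference 1 N mm) -- in this planar
reduction, with the pelvis pinned to the tracked hip, reserve *forces* on
the pelvis never enter the moment equations, so a reserve per equation is
what guarantees feasibility; frames where any reserve exceeds 1% of its
moment are flagged.  The bound-constrained QP is solved exactly by an
active-set method on the KKT system (well-conditioned for any reserve
weight) and is cross-checked in tests against closed forms and a
brute-force activation grid.  Keeping the locked ankle's moment row means
muscles spanning the ankle must balance the heel load -- a deliberate
design choice (a kinematic lock is not a moment sink).

**What this stage can and cannot reproduce.**  The qualitative structure
survives the planar reduction: the knee-surrounding musculature outworks
the hip-surrounding musculature in every fetus, forces ramp with wall
contact, and scaling the external force never lowers a group maximum.
The published per-muscle magnitudes (~8 N hip, ~21 N knee) do not: with a
~0.3 N contact force whose line of action passes close to all three
joints of an extended leg, planar statics yields moment demands of only a
few N mm and per-muscle forces of ~0.5-2 N, and the heel-applied load
selects dorsiflexors and extensors (tibialis anterior, vasti, gluteus
maximus) rather than the published plantarflexor-dominant pattern --
heel loading demanding dorsiflexors is correct planar statics (standing
on one's heels loads tibialis anterior).  Reproducing ~20 N plantarflexor
forces would require effects outside this model's declared scope: 3D
muscle paths and wrapping, force-length/velocity curves and passive fibre
forces after scaling, and the source tool's particular treatment of
locked coordinates.  The package reports its honestly computed values.

## 5. Problem sizes and reproducibility

Default problem sizes are chosen for interactive use: frames of roughly
80-100 px squared, 7-11 frames per kick, wall meshes of ~500-900 elements
solving in a few seconds per fetus, and 18-muscle QPs solving in
milliseconds.  Every stochastic step (rendering noise) is seeded through
the scenario, `run_pipeline()` derives per-scenario seeds from one global
seed, and identical runs produce byte-identical reports.
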