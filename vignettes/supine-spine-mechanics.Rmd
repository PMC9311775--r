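---
title: "Supine spinal curvature and mattress mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supine spinal curvature and mattress mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemat)
```

`spinemat` studies how mattress and pillow stiffness reshape the supine
sagittal spine. This vignette is the package's own account of its models:
what is computed, under which assumptions, with which defaults, and what
the synthetic experiments do and do not show about real data.

## 1. The tape measurement model

A flexible curvature-measurement tape lies along the back midline in the
sagittal plane. It is 870 mm long and carries 30 inclination sensors, so
it reports 29 segments of nominally 30 mm each; every segment is either a
circular arc or a straight line, encoded as three points (start, mid,
end; mm). Coordinates follow one fixed convention throughout the
package: **+x runs caudally along the mattress top, +y points vertically
away from the mattress**.

Reconstruction (`chain_elements()`) proceeds per element:

* classification (`classify_element()`): an element is a line iff the
  mid point lies within `tol_line` (default 0.05 mm — an order below
  plausible sensor resolution) of the start–end chord;
* arcs are the circumscribed circle through the three points
  (`fit_arc()`), with the swept angle chosen so the arc traverses the mid
  point;
* each element is sampled at 20 points (≈1.5 mm spacing) and the samples
  concatenated in tape order. The cumulative arclength `s` attached to
  the curve is the *analytic* per-element arclength (radius × swept
  angle), not a chord sum, so the total curve length equals the sum of
  element arclengths exactly.

If consecutive elements disagree about their shared joint point by more
than `gap_tol` (default 0.5 mm), the later element is rigidly translated —
never rotated — onto the junction, with a warning. Translation preserves
the inclinations the sensors actually measured; whether the device
reports elements in one global frame or per-element frames is not
observable from its output, and the translation repair covers both.

## 2. Spine parameters

Four standard supine alignment metrics are extracted from a back profile
(`extract_spine_params()`):

* **TI** (torso inclination): the angle, relative to the mattress top, of
  the common tangent line supporting the thoracic and sacral regions from
  the mattress side. Among all point pairs (one thoracic, one sacral),
  the supporting pair is the one whose connecting line leaves every point
  of both regions on or above it; it is found exactly as the spanning
  edge of the lower convex hull of the two regions, and an O(n²)
  exhaustive search serves as the test oracle.
* **HD**: perpendicular distance of the cranial curve endpoint to the TI
  line; **CLD** / **LLD**: the maximum perpendicular distance of the
  cervical / lumbar region to the TI line (the lordosis apex height).

Distances are *perpendicular*, not vertical: perpendicular distance is
invariant under rigid motions of the curve, which makes HD/CLD/LLD
device-orientation-free, while TI changes by exactly the applied rotation.
A head point below the support line is physically odd but can occur with
noisy tapes; it is clipped to 0 with a warning rather than an error.

Regions are arclength fractions of the curve (`region_partition()`):
head `[0, 0.10)`, cervical `[0.10, 0.20)`, thoracic `[0.20, 0.55)`,
lumbar `[0.55, 0.75)`, sacral `[0.75, 0.90]`. The tape cannot localise
vertebral levels, so these are anthropometric choices, exposed in the
API. The head region is one tenth of the tape (87 mm) because the
cranial contact arc from crown to occiput spans roughly that length, and
because the head-to-cervical height drop must be geometrically absorbed
inside this region: an arclength-parameterised profile can never be
steeper than |dh/ds| = 1, so a very short head region would make
realistic profiles with HD well above CLD unconstructible (§3).

## 3. The synthetic profile generator

`make_profile()` is the constructive inverse of the extraction: given
(TI, HD, CLD, LLD) it builds a height profile h(s) over arclength with

* the head point at height HD at s = 0;
* a cervical lobe peaking at CLD (apex at 60% of the cervical region);
* flat plateaus at height 0 inside the thoracic and sacral regions — the
  tangent support line is therefore realised *exactly*, and extraction
  recovers TI with no construction error;
* a lumbar lobe peaking at LLD;
* zero height from the sacral plateau to the tape end.

Between knots, h is a C1 "smoothed ramp": a linear segment with
quadratic ease-in/ease-out blends covering a fraction β = 0.3 of each
segment. Two properties motivated this shape over an ordinary cubic
smoothstep:

* its maximum slope is |Δh|/(w(1−β)) ≈ 1.43|Δh|/w versus 1.5|Δh|/w for a
  cubic — and, more importantly, the blend fraction spreads curvature
  over 30%-of-segment zones. With narrow blends the profile carries
  curvature radii below the 30 mm element length, which a three-point
  tape element cannot follow; with β = 0.3 the noise-free
  sample-then-chain loop is the identity to within 0.2 mm Hausdorff
  distance for cohort-scale profiles.
* the plateaus give the extraction bit-exact tangent points.

The planar curve is x(s) = ∫√(1−h′²) ds (trapezoid on a 0.5 mm grid), so
the arclength parameter is exact; the curve is then tilted by −TI. A
parameter set is *feasible* when every ramp stays below |dh/ds| = 0.95
(`profile_feasible()`); the binding case is a head far above the cervical
apex, which must descend within the head region.

`sample_tape()` cuts a curve into n equal-arclength pieces and emits the
start/mid/end points of each piece, adding isotropic Gaussian noise to
the 2n+1 sampled points *before* splitting, so adjacent elements share
their noisy joint sensor exactly as the physical tape does.

`generate_cohort()` draws per-participant, per-condition parameters from
truncated-at-zero normals with the per-mattress means and SDs of the
reference supine crossover experiment (soft/medium/hard, see
`default_conditions()`). Within-participant correlation across conditions
is induced by a shared participant random effect carrying ρ = 0.5 of the
variance; the marginal data give no information on the true
inter-parameter or inter-condition covariance, so ρ is an explicit knob,
not an estimate. Draws that are infeasible for the constructor are
re-sampled (up to 100×). Two small biases follow and are accepted:
truncation at zero inflates the mean of low-mean/high-SD parameters
(visible for TI in the soft condition, z ≈ −1.4), and feasibility
rejection trims the extreme HD−CLD tail (≲0.2% of soft-condition draws
with the 87 mm head region). Moment-recovery tests therefore check
parameters for which these effects are far below sampling error at
n = 2000.

## 4. Foam materials and foundation laws

Compressive stress–strain curves for the three mattresses and the pillow
are bundled as **synthetic** CSVs (`inst/extdata/materials/`, names say
`synthetic_*`): the reference foams' measured curves exist only as a
published figure, so the package constructs curves with the canonical
open-cell polyurethane shape — a stiff elastic toe, a long plateau to
about 0.6 strain, then a densification upturn — calibrated so that the
25% indentation-load-deflection surrogate reproduces the advertised
firmness grades 20 / 42 / 120 lbf (soft / medium / hard) on the standard
323 cm² indenter, with the pillow tracking the medium foam (5% stiffer).

`ild_25()` is a deliberately uniaxial surrogate (stress at 25% strain ×
indenter area): the standardised test uses a round indenter on a full
slab with preflex cycles, so only firmness *orderings* are asserted, not
the absolute pounds of a certified rig.

`fit_foam_law()` interpolates the data with a Hyman-filtered monotone
cubic spline (exact at the data, monotone between), extended linearly
beyond the last strain with the terminal slope.

A foam slab of thickness t acts as a **Winkler foundation**: independent
vertical columns with contact pressure `law(w/t)` at deflection w. The
foams' Poisson ratio is ≈0.01, so lateral coupling is genuinely
negligible and the columnar reduction is the appropriate limit. Stacked
slabs act as springs in series — equal stress, deflections add — solved
by monotone root finding (`foundation_pressure()`, tolerance 1e-6 kPa);
deflections beyond 95% of the stack thickness raise a densification
error.

One stack deserves care: a **stiff pillow on a soft mattress**. The
pillow diffuses the narrow craniocervical load over its much larger base
(a ~270 cm² contact spreading over a 55 × 35 cm footprint), so the
mattress below it sees only a fraction of the contact stress. A naive
equal-stress series would push the full head stress into the soft
mattress and sink the pillow with it — the opposite of what a stiff
pillow does. `support_surface()` therefore attenuates the stress reaching
the sub-pillow mattress layer by `pillow_spread` (default 0.15, the
contact-to-base footprint ratio). This is the load-spreading mechanism
by which the *same* pillow supports the head more strongly the softer
the mattress is.

## 5. The supine equilibrium model

`build_default_body()` reduces the body to a sagittal chain of 29 nodes —
head, C1–C7, T1–T12, L1–L5, sacrum/pelvis, thigh, shank, heel — placed
along a neutral rest back profile (mild cervical and lumbar lordosis,
scaled geometrically with stature; the spine occupies 49.4% of height,
the tape length for the 176 cm reference subject). Lumped masses follow
published segment fractions (head 8.1%, trunk 49.7% plus the arms folded
in, thighs 20%, shanks 9.3%, feet 2.9%), with the trunk split
anatomically: a neck sliver, the thorax (plus arms) over T1–T12, the
abdomen over L1–L5, the pelvis on the sacrum node. Each node carries an
effective contact width (head 120, thorax 280, sacrum 220, heel 40 mm,
…) converting the line model into tributary areas.

Joints between nodes carry axial stiffness and rotational stiffness
about the rest shape. The rotational values describe the bending
compliance of the dorsal *body surface* draping over a support — not the
ligamentous spine: a supine torso conforms to foam because its soft
envelope deforms, and a chain as stiff as the vertebral column would
bridge across a foam plateau like a beam. Two structural features carry
the physics: the rib-cage-backed thoracic section is an order of
magnitude stiffer than the cervical and lumbar junctions (1e4 vs
1e3/2e3 N·mm/rad), so sinking of the lower trunk rotates the thorax and
loads the neck; and the cervical pillow ends at the shoulder line
(`fit_pillow_extent()`), so the neck spans from pillow-held head to
mattress-level upper thorax. Ligament bridging springs (tension-only,
every second node) use the printed reference moduli as given, in kPa,
behind a `ligament_unit_scale` knob: literature ligament moduli are
MPa-scale, so as printed they are mechanically negligible, and the knob
documents rather than hides that discrepancy. Disc geometry (area,
half-depth, second moment per level, C2–C3 … L5–S1) follows typical
literature magnitudes and is override-able.

`solve_equilibrium()` minimises the total potential energy

E(y) = Σ mᵢ g yᵢ + Σ ½k_ax(L−L₀)² + Σ ½k_rot(θ−θ₀)² + Σ ½k_lig⟨L−L₀⟩₊²
      + Σ Aᵢ Φᵢ(Sᵢ−yᵢ)

over **vertical** nodal positions y (x frozen at rest): the body settles
onto the support. Freezing x removes the translational null space a
Winkler foundation cannot constrain, and matches the fixed initial guess
— the rest profile lowered (or raised) until first contact. Φ is the
integral of the (stacked) pressure–deflection law, tabulated per stack
on the union of the layers' strain grids so foam plateaus are resolved,
with a stiff linear barrier beyond densification; contact is unilateral.

Numerics: chunked L-BFGS-B with the analytic gradient, plus a
damped-Newton polish on the residual (finite-difference Hessian of the
analytic gradient, Levenberg damping, steps accepted only when the
residual norm falls) whenever the maximum nodal residual force exceeds
`tol_grad`. Convergence requires a relative energy decrease below 1e-8
per block *and* max residual below 1e-6 N; near the minimum the energy
itself changes below float resolution, which is why the polish phase
works on the residual. Very stiff foundations are reached through a
deterministic continuation ladder (scale 1, 10, 100, …), and the force
tolerance scales with √(stiffness scale) — a 1e6× stiffer foundation
shifts the attainable force resolution in double precision by the same
factor. The recorded energy trace collects the monotone checkpoints of
the final stage and is non-increasing by construction; everything is
deterministic (no randomness, fixed initial guess), so identical inputs
give bit-identical results.

At convergence the total contact force balances the body weight to
~1e-10 relative (the gradient components sum to gravity minus contact by
construction, so force balance is equivalent to stationarity).

Outputs: nodal pressures (kPa) and regional peaks (occiput, cervical,
scapula, buttock, calf, heel); contact area above a 1 kPa threshold
(tributary areas, split pillow vs mattress); per-disc loading proxies
|F|/A + |M|c/I from joint axial forces and bending moments, with the
disc moment taken as the mean of its two adjacent node moments; and the
deformed back-surface curve — the spine nodes joined by linear
interpolation (a spline would overshoot at contact kinks and contaminate
the tangent construction) and extended caudally towards the thigh so the
curve spans the same body fraction as the measurement tape, which keeps
the arclength region partition aligned.

## 6. Statistics and reporting

`paired_contrasts()` computes participant-wise paired differences per
parameter and condition pair, two-sided paired t tests, and Holm
adjustment over the three pairs within each parameter. The experiment
being emulated shows significance stars for a three-condition crossover
without naming its test; the paired t is the conventional choice at
n = 16, and zero-variance edge cases follow fixed conventions (identical
conditions: p = 1; constant non-zero differences: p = 0, infinite
statistic). `validate_correlation()` is a plain Pearson correlation with
the conventional "strong" label for r ∈ [0.7, 1]. `validation_sweep()`
pools all four spine parameters across scenarios into one
predicted-vs-truth correlation — the jitter-plot validation logic used
for body-model computations; pooling across parameters of different
magnitudes makes r dominated by between-parameter structure, which is
exactly what that validation style measures.

`run_pipeline()` chains everything: cohort → tape simulation →
reconstruction → extraction → contrasts (on the cohort parameter table,
so an SD-0 cohort reproduces mean-difference arithmetic exactly) →
per-condition mechanics → validation of predicted against measured
condition means; the output bundle is deterministic given the seed.

## 7. Problem sizes and runtimes

The test suite and the benchmark script run at desk scale by design:
cohorts of 16 participants (moment checks at n = 2000 draws without
curve construction), 29-element tapes, 100-profile round-trip checks, 20
seeded mattress-comparison scenarios and a 30-scenario validation sweep;
one equilibrium solve takes a fraction of a second, the whole suite
under a minute.

## 8. What the synthetic experiments do and do not show

The generator reproduces the *marginal* per-mattress distributions of
the four spine parameters and the tape's geometry and noise; it does not
know true inter-parameter covariances, participant anthropometry
coupling (taller people presumably have longer spines *and* different
parameter means), breathing or postural drift, or accelerometer error
structure. Passing round-trip and moment tests therefore shows the
pipeline is self-consistent and statistically faithful to the published
summary statistics — not that it would reproduce raw data from a new
device.

The mechanics model is a surrogate with honest, known distortions:

* contact areas move in node-sized quanta (a node's whole tributary area
  enters or leaves contact), so area comparisons are coarse;
* absolute pressures and disc stresses depend on the assumed contact
  widths and disc geometry; only orderings and mechanisms — soft
  mattress spreads load and eases the buttock, stiff craniocervical
  support loads the cervical discs, hard mattress flattens the torso —
  are claimed, and those are the properties the tests assert;
* on a *rigid* floor the draping chain flattens its unsupported arches
  (head falls, lumbar hollow collapses) — real behaviour for a relaxed
  body, but it means the rigid-foundation limit preserves the rest
  *shape* only for a stiffened body variant (tested as such); the
  penetration always vanishes;
* the head-height mechanism on the *soft* mattress is only partially
  expressed: the model holds the head up (pillow spreading) and tilts
  the torso, but its tangent line rises toward the head when the pelvis
  sinks much deeper than the thorax, so the extracted HD on the soft
  mattress comes out below, not above, the medium-mattress value — a
  direct consequence of the decoupled Winkler columns and the coarse
  thoracic discretisation. The cervical *loading* ordering
  (soft > medium > hard) is expressed correctly.

## 9. Defaults that matter

| Parameter | Default | Where | Why |
|---|---|---|---|
| `tol_line` | 0.05 mm | `classify_element` | an order below sensor resolution |
| `gap_tol` | 0.5 mm | `chain_elements` | device joints agree far tighter; beyond this is a data fault to repair |
| sampling | 20 pts/element | `chain_elements` | ≈1.5 mm, below all stated tolerances |
| partition | 0.10/0.20/0.55/0.75/0.90 | `region_partition` | §2; head region must absorb the HD drop |
| blend β | 0.3 | profile ramps | tape-resolvable curvature; §3 |
| ρ | 0.5 | `cohort_spec` | free knob; marginals carry no covariance information |
| noise | 0.5 mm | `cohort_spec` | plausible sensor noise at tape scale |
| ν | 0.01 | foam laws | open-cell foam; justifies Winkler columns |
| `pillow_spread` | 0.15 | `support_surface` | contact-to-base footprint ratio |
| k_rot | 1e3/1e4/2e3 N·mm/rad (cerv/thor/lumb) | body | surface draping with a stiff rib cage; §5 |
| tolerances | 1e-8 rel energy, 1e-6 N force | solver | §5 |
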