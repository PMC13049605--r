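---
title: "Robustness evaluation of reduced setup uncertainty in scanned proton therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness evaluation of reduced setup uncertainty in scanned proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protonrem)
```

# The question the package answers

Pencil-beam-scanning proton plans for mediastinal targets are robustly
optimized against setup and range uncertainty.  The setup uncertainty
parameter directly sets how far dose spills beyond the target: a smaller
value spares the heart, breasts, thyroid, lungs and esophagus, but too small
a value risks underdosing the target once real treatment errors — residual
setup error after image guidance, range uncertainty, breathing motion with
delivery interplay, and week-scale anatomical change — are taken into
account.  `protonrem` implements the full evaluation chain needed to ask,
on a synthetic but fully controlled 4D thorax, whether reducing the setup
uncertainty from 5 mm to 4 mm or 3 mm preserves delivered target coverage
while lowering organ-at-risk dose and the associated lifetime risk of acute
coronary events (ACE).

The pipeline mirrors clinical practice:

1. robustly optimize a reference plan at 5 mm / 3 % on the breathing-averaged
   anatomy (21-scenario worst-case optimization);
2. regenerate plans at 4 mm and 3 mm by voxel-based dose mimicking from the
   reference, so the only thing that changes is the setup-uncertainty demand;
3. verify planning robustness with a 3D evaluation: the voxel-wise minimum
   dose over 28 setup/range scenarios, gated at D98 > 95 % of prescription
   and V95 > 98 % on the internal target volume (ITV);
4. compare delivered-dose robustness with a 4D evaluation: 8 simulated
   fractions x 14 error scenarios with breathing interplay on weekly
   anatomies, warped to the end-of-exhale reference and accumulated;
   coverage on the clinical target volume (CTV), organ doses on the
   voxel-wise mean;
5. convert mean heart dose (MHD) to lifetime ACE risk with a linear
   relative-risk model and test paired differences across the three settings
   with the exact Wilcoxon signed-rank test at a Bonferroni-corrected
   threshold (0.05 / 3, displayed as 0.017).

# The synthetic 4D phantom

Clinical 4DCTs cannot be shipped, so every input is generated by
`generate_phantom()` from analytic geometry: a thorax-like body (elliptical
cylinder), two low-density lungs (relative stopping power 0.30), a heart, a
mediastinal CTV wrapping the anterior-superior aspect of the heart, left
and right breasts, thyroid and esophagus.  All masks are exact indicator
samples of the analytic shapes — no segmentation or resampling error.

Breathing is a single smooth displacement field: a dominant
superior-inferior direction with a smaller anterior-posterior component,
modulated by a Gaussian cranio-caudal envelope peaking in the caudal
mediastinum, times a sinusoidal phase factor sampled at 10 phases.  Phase 5
(0-based) is end-of-exhale and serves as the reference; the phase factor is
zero there and one at end-of-inhale.  The envelope is normalized so that
the realized point-max target motion (the maximum displacement of any
target voxel over the cycle) equals the configured amplitude.  Cohort
amplitudes are drawn uniformly from 5–20 mm, the range reported for
mediastinal lymphoma targets on planning 4DCTs; the envelope decay across
the target produces mean target motions of a few millimetres, again
matching the reported range.

Because the deformation model is analytic, every phase stores its exact
displacement field to the reference.  Phase anatomies are built by
inverting the forward map with a fixed-point iteration (8 iterations; the
fields have Jacobian perturbations well below 1, so the round-trip error is
far below 0.1 voxel, which the test suite verifies).  Deformable image
registration — a real and important error source clinically — is therefore
bypassed by construction, and dose warping in the 4D evaluation is exact up
to trilinear interpolation.  Passing tests consequently validate the
evaluation logic, not registration robustness on real images.

Weekly anatomical change is a small random smooth displacement (two seeded
Gaussian blobs, normalized to a 3 mm peak) composed with the breathing
model, one variant per treatment week.  What the generator does *not*
emulate: Hounsfield calibration, cardiac motion, irregular breathing or
baseline drift, density changes such as pleural effusion, and
patient-specific anatomy.  Conclusions from the synthetic cohort are about
the methodology's behavior, not about any patient population.

# The dose engine

The engine is a deterministic parallel-ray pencil-beam model on the 3 mm
dose grid used throughout (the clinical resolution for this indication).
Each spot deposits a lateral Gaussian (sigma 9 mm in the study
configuration, truncated at 3 sigma) times an analytic Bragg curve: a
power-law build-up from entrance dose 1 to a peak of 4 at the nominal
range, then a Gaussian distal falloff (sigma 3 mm) truncated continuously
to zero.  Water-equivalent depth is integrated along the beam direction
through the phase's density grid by an incremental shear sweep, so lung
heterogeneity shifts the peak as it should.  Physical dose is multiplied by
the constant proton RBE of 1.1; all doses are Gy(RBE) for the full course.

Scenario perturbations enter exactly as in scenario-based TPS evaluation:
a setup error translates the beam isocenter by the negative shift relative
to the anatomy, and a range/density error scales the water-equivalent depth
(3 % range uncertainty maps to scales 0.97/1.00/1.03).  Because rays are
parallel, a shift component along the beam axis does not change the dose in
the patient frame — physically sensible for protons, whose range is set by
tissue depth — so setup scenarios act through their lateral components;
with three beams at -30, 0 and +30 degrees every Cartesian shift direction
is lateral to at least two beams.  No Monte Carlo noise is simulated: the
1 % statistical noise of a clinical dose engine would only blur the exact
oracle tests that a deterministic engine makes possible.

Spot templates place spots on a 1-sigma lateral lattice with a placement
margin of the setup uncertainty plus 0.8 sigma, and energy layers every
7 mm of water-equivalent depth with a range-uncertainty-dependent depth
margin.  The margin's dependence on the setup uncertainty is the geometric
mechanism by which smaller settings spare organs at risk.

# Robust optimization and dose mimicking

`robust_optimize()` minimizes a composite objective over non-negative spot
weights.  Each of the 21 optimization scenarios (7 shifts x 3 density
scales) carries a convex target penalty: a one-sided quadratic below the
prescription plus a milder one-sided quadratic above 110 % of it
(weight 0.1).  The scenario with the largest penalty is the worst —
the scenario with the lowest coverage of the prescription.  A hard
worst-case selection by a coverage statistic such as D98 makes the
composite discontinuous and stalls first-order solvers at the minimax kink,
so the implementation aggregates the per-scenario penalties with a p-norm
(p = 12), which upper-bounds the maximum, tends to it as p grows, and keeps
the objective differentiable; the reported `worst_scenario_index` is still
the argmax penalty.  Organ-at-risk terms are quadratic penalties on the
nominal-scenario mean dose.  The default weights (target 10, each organ 1)
follow the clinical priority of coverage first; an internal scale of 0.02
on the organ terms calibrates a unit organ weight to a soft preference that
shapes dose without competing with coverage (without it, six organ terms
overwhelm the coverage term and the gate fails).

The solver is projected gradient descent with Barzilai–Borwein step
initialization and monotone Armijo backtracking: the objective trace is
non-increasing by construction (a test asserts this), weights stay
non-negative, and iteration stops at a cap (default 500; the cohort uses
150) or after three consecutive relative improvements below 1e-6 — the
patience matters because the active scenario can change between iterates.
The optimizer's internal linear algebra runs on a deterministic subsample
of target voxels (cap 2000; cohort 1000) and organ voxels (cap 600; cohort
400); all reported metrics are always computed on the full masks.

`dose_mimic()` regenerates a plan at a reduced setup uncertainty from the
reference plan's nominal dose: a one-sided quadratic penalty for organ
voxel doses exceeding the reference, plus the worst-scenario one-sided
under-dose penalty at the reduced scenarios, plus the same mild hot-spot
term — without the latter the coverage term can rescale the whole plan
upward, exceeding rather than reproducing the reference dose level.  The
reduced setting must be strictly smaller than the reference, matching the
study design.  The mimicking reference is the nominal-scenario dose; a
voxel-wise-minimum reference would also be defensible but couples the
mimic to the evaluation stage.

# 3D and 4D robustness evaluation

The 3D stage (`run_3drem()`) evaluates 28 scenarios on the planning
(average) anatomy: six axis shifts and eight body-diagonal shifts — all
normalized to the setup-uncertainty norm, keeping every scenario on the
same error sphere (a `component` convention is available) — times two
density scales.  The voxel-wise minimum over scenarios is gated on the ITV
at D98 > 95 % of prescription and V95 > 98 %, both strict, exactly as the
clinical criterion is phrased.  Any DVH metric of the voxel-wise minimum is
bounded above by the same metric of every single scenario; the acceptance
suite checks this dominance property explicitly.

The 4D stage (`run_4drem()`) simulates 8 fractions x 14 scenarios.  Each
scenario carries a systematic setup vector (fixed across its fractions), a
per-fraction random vector — both isotropic Gaussians with SDs from the
van Herk split of the 2 mm residual after daily image guidance,
Sigma = sigma = 2/3.2 = 0.625 mm — and a systematic range level from
{-3, 0, +3} %, assigned 5/4/5 across the 14 scenarios.  Delivery timing is
simulated (5 ms per spot, 1 s layer switch) instead of parsed from machine
log files, because the timing's only role is to place each spot in a
breathing phase of the 4.5 s cycle; each energy layer is painted five
times, and the starting phase of each fraction is drawn uniformly.  Each
spot's dose is computed on the phase anatomy of that week's 4DCT active at
its delivery time, pulled back to the planning end-of-exhale phase through
the ground-truth fields, and fraction doses are accumulated with equal
weights, scaled to the clinical course (11 or 15 fractions).  Coverage is
gated on the reference-phase CTV of the voxel-wise minimum across
scenarios (same thresholds as planning), and organ metrics are read from
the voxel-wise mean.  The key cross-module oracle: with zero motion, zero
errors and identical weeks, the accumulated course reproduces the static
dose to a relative maximum error below 1e-6.

# Outcome modelling and statistics

Lifetime ACE risk is the linear relative-risk form
`risk = baseline x (1 + c x MHD)`: the baseline lifetime risk (from age,
sex and risk factors, with patients under 40 evaluated at age 40) enters as
an input, and the default excess rate c = 0.074 per Gy(RBE) is the
epidemiological 7.4 %/Gy estimate for major coronary events per unit mean
heart dose.  The national selection rule is implemented as stated: a
patient qualifies for protons when the photon-minus-proton risk difference
is at least 2 %.  Under the linear model the risk reduction between two
proton settings is proportional to their MHD difference, which the tests
exploit.

Paired differences across the 5/4/3 mm settings use a two-sided Wilcoxon
signed-rank test implemented in-package: zeros dropped, average ranks for
ties, and an exact null distribution up to n = 25 computed by a
generating-function convolution over doubled ranks (exact even with ties,
which the normal-approximation fallback handles above n = 25 with tie and
continuity corrections).  The standard library test is used as an
independent cross-check where it is exact (tie-free), and an explicit
2^n enumeration is the oracle for small n.  Three pairwise comparisons give
the corrected threshold 0.05/3, displayed as 0.017 and applied unrounded.

# Numerical conventions

* D-at-volume uses the conservative no-interpolation convention: the
  ceiling(n x v/100)-th largest voxel sample, so D98 of 100 voxels dosed
  1..100 is 3.  Volume-at-dose is an exact count, reported in percent and
  cm^3 (lung V5 and breast V4 thresholds are percentages of the
  prescription dose; both unit variants are reported).
* Masks map through displacement fields by trilinear interpolation of the
  indicator with a 0.5 threshold, ties toward inclusion; the ITV is the
  union of the per-phase target masks and their tissue-mapped images, so
  voxelization can only grow, never erode, the envelope.
* The average anatomy warps each phase to the reference through the
  ground-truth field before averaging with equal phase weights; with exact
  fields this is essentially the reference density, which is the intended
  meaning of a motion-compensated average.
* All grids use voxel-center sampling on isotropic 3 mm lattices (unit
  tests use the same geometry at 6 mm), world coordinates in mm with the
  isocenter at the grid center, and shifts in patient space.
* Dose deposition has two mathematically equivalent code paths — per spot,
  and per energy layer on the regular spot lattice — that agree to 1e-7 and
  are cross-checked in the tests.

# The synthetic cohort

The shipped study (`run_study()`, also driving `scripts/acceptance.R`)
uses 10 patients on 48-cubed grids at 3 mm: per patient a sampled target
geometry (semi-axis scale 0.85–1.15, center jitter of a few mm), motion
amplitude 5–20 mm, fractionation 15 x 2.0 Gy(RBE) for seven patients and
11 x 1.8 Gy(RBE) for three, baseline ACE risk 8–12 %, and a photon
comparator MHD 2–6 Gy(RBE) above the proton value for the selection-gate
demonstration.  Optimizer caps (150 iterations, 1000 target voxels) and
the grid size are the package's trade-off between fidelity and a cohort
run of well under half an hour on a single core.  On this cohort all 30
plans pass their
3D gate, the mean heart dose falls monotonically from 5 to 4 to 3 mm for
every patient in both the nominal and the 4D-mean dose, all MHD
comparisons are significant at the corrected threshold, and the median 4D
ACE-risk reductions are a few tenths of a percent — the same order as the
clinical report this methodology targets.

# Known limitations

The dose engine is an analytic surrogate (no nuclear halo, no
multiple-Coulomb-scattering heterogeneity corrections, no variable RBE);
the phantom's deformations are smooth and exactly known, so registration
error is absent; rotational setup errors are not modelled (clinically
corrected by a 6-D couch); the junction technique for caudally extended
targets is not implemented; and the dose-mimicking objective is a
one-sided quadratic stand-in for the proprietary clinical formulation,
chosen to encode the same stated priorities (organ sparing first,
prescribed coverage preserved).
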