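---
title: "Methods: drop-jump analysis and PLS determinant modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drop-jump analysis and PLS determinant modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(djpls)
```

## The problem

A drop jump (DJ) is a stretch-shortening-cycle task: the athlete drops from
a box (here 0.3 m), lands on two force plates, and rebounds as high and as
fast as possible. Performance is summarized by three outcomes: ground
contact time CT (s), jump height Ht (m), and the reactive strength index
RSI = Ht/CT (m/s). The scientific question this package operationalizes is
which phase-specific kinetic and kinematic variables determine those
outcomes when the predictor set is large (44 variables) and heavily
collinear — a setting where partial least squares (PLS) regression with
variable-importance-in-projection (VIP) scores is the natural tool.

The pipeline has two halves: a signal half (markers + forces to a
participant-level feature table) and a statistical half (feature table to
three filtered, cross-validated PLS models). Both halves are exercised
against a synthetic-trial generator whose ground truth is known exactly.

## Signal half

**Filtering.** Marker trajectories (250 Hz) and force channels (1000 Hz)
are smoothed with a fourth-order zero-lag Butterworth low-pass filter,
implemented as a forward-backward pass of a second-order section with
odd-reflection padding of about one settling length. The default cutoff is
20 Hz; `residual_analysis_cutoff()` implements the classic residual
analysis (RMS residual vs cutoff; straight-line fit to the upper third of
the candidate range; lowest cutoff whose residual does not exceed the
zero-frequency intercept). "Fourth-order zero-lag" is read as dual-pass
second-order *without* the dual-pass cutoff correction; the corrected
variant (per-pass cutoff divided by 0.802) is available via
`correct_cutoff = TRUE`. Note that with a real fourth-order roll-off a
noiseless band-limited signal still leaves residual energy just above its
band, so the residual-analysis choice for such signals lands between the
band edge and ~20 Hz rather than exactly at the band edge.

**Events.** Ground contact, take-off and landing are threshold crossings
(default 20 N) of the summed vertical ground reaction force of both plates,
with a 5 ms dwell requirement to reject spikes. Events are detected on the
*raw* force by default: a zero-phase filter smears the sharp force onset
across the threshold and can move the crossing by several milliseconds,
while the unfiltered onset of a real (or generated) landing is steep enough
to locate the event to ~1 ms. Amplitude features always use the filtered
channels. The eccentric phase runs from contact to the vertical
centre-of-mass (COM) minimum, the concentric phase from that minimum to
take-off; COM-minimum ties break to the earliest sample.

**Body model.** A Dempster/Winter 15-segment inertial table is bundled
(`segment_parameter_table()`); because the protocol keeps hands on hips,
the reduced marker set lumps the upper body into a head-arms-trunk segment,
giving an 8-segment model whose mass fractions are exact sums of the
15-segment table. Joint centres: mid-malleolar, mid-epicondylar, and the
greater trochanter shifted medially by 0.11 x inter-ASIS width. Joint
angles are Cardan decompositions of the distal segment frame relative to
the proximal one, sequence flexion/extension - ab/adduction (or
valgus/varus, eversion/inversion) - axial rotation, unwrapped over time,
with signs fixed so hip and knee flexion are negative (a flexed landing
posture reads about -25 degrees) and dorsiflexion positive. Bilateral
averaging mirrors the right side's frontal and transverse channels so
symmetric excursions do not cancel.

**Kinetics.** Jump height is (take-off COM velocity)^2 / (2 g) with the COM
velocity from central differences of the (cubic-resampled, 1000 Hz) model
COM. Impulse is the trapezoidal integral of vertical force over each phase
per kilogram; the impulse ratio is eccentric/concentric. Vertical stiffness
is peak eccentric force over |eccentric COM displacement|. Two variables
have no published formula and are labelled interpretations, isolated behind
configuration: RFD defaults to peak eccentric force divided by time from
contact to that peak (`rfd_method = "max_slope"` is the alternative), and
Synchro is the |time of peak force - time of COM minimum| as a percentage
of contact time. Bottom-up Newton-Euler inverse dynamics (foot, shank,
thigh; one plate per foot) yields ankle/knee/hip moments, powers
(moment x relative angular velocity) and per-phase work, summed over sides
and normalized by body mass.

**The 44 predictors.** The feature table carries 3 outcomes + 44
predictors: 5 global kinetics (stiffness, RFD, Synchro, impulse ratio,
force at zero COM velocity), 9 contact angles, 2 x (phase duration,
impulse, mean and peak force), 2 x (COM displacement, COM work), and
2 x 9 ranges of motion. The six joint-work variables are computed but kept
as auxiliary columns (`include_joint_work = TRUE`) so the default predictor
inventory totals exactly 44; including them would make 50, which no
partitioning of the published variable list reconciles with a 44-predictor
table.

## Synthetic trials

The generator (`generate_trial()`) is built so the analyzer's every claim
can be checked against exact truth:

* The COM trajectory is prescribed analytically: ballistic drop from the
  box, a contact-phase acceleration pulse `a(t) = -g + K sin(pi t/T)^p`
  (default p = 1; K solves the impulse-momentum budget for the prescribed
  drop height, contact time and jump height), ballistic flight, a landing
  pulse, quiet stance. `Fz = m (a + g)` holds at every sample by
  construction, so impulse-momentum closure is exact up to quadrature.
* Posture is a one-parameter "crouch" family: shank, thigh and trunk
  inclinations grow as ~sqrt(crouch) so the COM drop (which scales with
  1 - cos of the inclinations) is near-linear in the parameter; crouch < 0
  smoothly switches to heel raise (the foot pivots about the toes), letting
  the take-off COM exceed the flat-foot standing height as in a real
  toe-off. During contact the crouch is solved frame-wise by inverting the
  posture-to-COM map, so the marker-derived model COM matches the
  prescribed COM to under a millimetre; in the air the posture continues
  with matched velocity and zero curvature (`u exp(-(u/tau)^2)`, soft
  clamping), because any velocity corner near take-off rings through the
  zero-phase filter back into the contact window and biases the
  concentric ranges of motion.
* Small frontal/transverse excursions (lateral knee deviation, axial
  rotations of the marker clusters, trunk sway) are windowed inside
  contact; constant participant-level baselines keep the contact-instant
  angles non-degenerate across a cohort.
* Truth includes contact time, jump height, RSI, phase boundaries, COM
  works and impulses per phase, sagittal joint-angle profiles and ROMs,
  and the quasi-static ankle moment implied by the generated centre of
  pressure (the foot is at rest during contact, so this truth is exact).

Documented recovery tolerances on the default noiseless trial: jump height
5 mm, events 2 ms, knee concentric flexion ROM 1 degree and all sagittal
ROMs 1.5 degrees (the residue is the unavoidable 20 Hz filter bias at the
posture's extension end), ankle moment 12% of its peak, and limb joint work
vs COM work within 40% (the lumbar joint is not modelled, so trunk work is
missing from the limb total). What a green test establishes is
generator/analyzer consistency under the stated noise model (i.i.d.
Gaussian marker and force noise); it does not establish robustness to soft
tissue artefact, marker mislabeling, or non-stationary force-plate drift,
none of which are emulated.

The cohort generator draws participant parameters from the target
population (height 1.74 +/- 0.07 m, mass 79 +/- 12 kg, contact time
0.22 +/- 0.04 s in [0.16, 0.38], jump height 0.33 +/- 0.05 m in
[0.25, 0.51]); the published mass SD (23.4 kg) is implausibly large next
to the height SD and is moderated to 12 kg.

## Statistical half

All predictors are z-scored (n - 1 denominator). Collinearity is reduced in
two passes: (1) while any pair of retained predictors has |r| > 0.95, drop
the member of the worst pair with the larger mean absolute correlation with
all other retained predictors (deterministic; ties by column order);
(2) iteratively remove the predictor with the largest variance inflation
factor until all VIF <= 10, with exact collinearity recorded as infinite
VIF.

The PLS fit is single-response NIPALS with X- and y-deflation. The number
of latent variables is chosen by 10-fold cross-validation (seeded shuffle,
near-equal folds) minimizing RMSECV = sqrt(PRESS/n) in standardized-y
units; Q2 = 1 - PRESS/TSS is reported from the same partition. Two filter
modes exist: `"paper_faithful"` applies the filters once before
cross-validation (the mode used for reproducing printed model metrics) and
`"leak_free"` refits standardization and both filters inside every training
fold. The published analysis is silent on this point; both are exposed and
the default for reproduction is paper-faithful.

VIP follows the standard formula
`VIP_j = sqrt(p * sum_a SS_a (w_ja/||w_a||)^2 / sum_a SS_a)`, which
guarantees mean(VIP^2) = 1; the threshold VIP > 1 flags influential
predictors. "Weight" in reports is the unit-norm X-weight of the variable
on its assigned component; each variable is assigned to the component where
its |weight| is maximal (the assignment rule behind the published tables is
not stated; this is a documented interpretation, with the transformed
weights w* available as an alternative).

Model p-values approximate the PLS model by an ordinary regression of the
response on the first c score vectors (overall F-test, df1 = c,
df2 = n - c - 1). One caution, verified by simulation: if the scores were
selected using the same response, this test is strongly anticonservative
(under a null response the p-values pile up near zero because the first
weight vector is X'y itself). The calibration test therefore regresses
fresh null responses on scores from an independent fit, which is the sense
in which the F-machinery is uniform; p-values reported for a fitted model
share the optimism of the published approach and should be read
accordingly.

The a-priori power computation uses the noncentral-F power of the R2 = 0
test with noncentrality f2 x N (the G*Power convention), df1 = number of
predictors, df2 = N - predictors - 1; with f2 = 0.43, alpha = 0.05, power
0.80 and 4 predictors the smallest adequate N is 33.

## The tabular generator and identifiability

`latent_truth()` / `generate_pls_dataset()` build X = T P' + E,
y = T q + f with stored truth. The response noise defaults to the level
making the population R2 of y on the latent scores exactly 0.9. The default
loading matrix uses unequal block sizes (14, 7, 3 of 44) with decaying
scale (1, 0.675, 0.35) and alternating response signs (1, -1, 1): with
symmetric blocks and equal coefficients a single X-direction would carry
the whole response and no cross-validation could (or should) recover
"3 components", so the identifiable design is part of the stated world,
chosen once. Under it, RMSECV selects 3 components and the truly loading
predictors fill the top VIP ranks in a clear majority of seeds.

## Numerical choices and degenerate inputs

* Filter edges: odd-reflection padding, DC-steady-state initial
  conditions; edge effects are excluded from frequency-response tests.
* Resampling: cubic splines, exact at the original sample instants.
* Derivatives: central differences (one-sided at record ends); angular
  velocity from `Rdot R'` of the segment frames.
* Cardan decomposition warns within 1 degree of gimbal lock; frames are
  validated orthonormal to 1e-6.
* Zero-variance columns abort standardization with the column named;
  all-zero force traces raise "incomplete trial" errors naming the missing
  event; a monotone COM over contact yields a boundary minimum with a
  warning.
* Segment inertia uses the transverse radius of gyration isotropically;
  axial asymmetry is ignored (adequate for near-planar motion).

## Known limitations

The generator's motion is sagittal-dominant with parameterized lateral
excursions; it does not emulate muscle dynamics, soft-tissue artefact, or
asymmetric landings beyond a fixed 52/48 plate split. The energy
bookkeeping between limb joint work and COM work is loose (no lumbar
joint). Reproduction of the published model tables requires the original
participant-level dataset, which cannot be redistributed with the package;
the reproduction test and a column-name dictionary
(`inst/extdata/column_map.yaml`) ship ready to run once that file is placed
under `inst/extdata/`.
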