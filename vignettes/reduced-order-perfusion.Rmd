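---
title: "A reduced-order model of perfusion impairment in a Murray-law microvascular tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of perfusion impairment in a Murray-law microvascular tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murraynet)
```

## Motivation

Coronary microvascular dysfunction impairs myocardial perfusion at the
level of the pre-arterioles and arterioles, where neither flow nor wall
shear stress (WSS) can be measured in vivo. A practical way to study the
hemodynamic consequences of such impairment is to perfuse an idealized
microvascular network — physically, as a microfluidic chip, or numerically
— while blocking subsets of its outlets, and to ask how flow and WSS
redistribute over the remaining branches. `murraynet` implements that
study as a lumped-parameter (0D) pipeline: tree construction, steady flow
solution, WSS estimation, and scenario comparison, plus a synthetic
measurement generator so the whole chain can be exercised and validated
without any laboratory data.

This vignette is the package's own account of the model: its assumptions,
its tunable parameters, the numerical and design choices made where the
problem left them open, and what the validation does and does not show.

## The idealized tree

The network is a rooted symmetric binary tree. Channel generation $g$
holds $2^{g-1}$ branches labeled `Cg-Bk` left to right; with the default
three bifurcation levels the tree has 15 segments and 8 outlets
`O1`–`O8`, terminal branch `Bk` draining outlet `Ok`. Three parameter
groups fix the geometry (`geometry_config()`):

* **Radii.** A generalized Murray rule at every bifurcation,
  $r_p^m = \sum_c r_c^m$, i.e. $r_c = r_p\,2^{-1/m}$ for equal children.
  The classical exponent $m = 3$ makes fully developed laminar WSS
  invariant across generations under equal flow splits. The default
  endpoint diameters (1 mm inlet, 0.4 mm outlets) are *not* consistent
  with $m = 3$ over three generations (which would give 0.5 mm), so by
  default the package infers the exponent that honours both printed
  endpoints, $m = n\ln 2 / \ln(d_{in}/d_{out}) \approx 2.2694$. Strict
  Murray behaviour is available via
  `geometry_config(murray_exponent = 3)`, under which the terminal
  diameter becomes nominal. Both modes are provided deliberately: the
  fabricated-device dimensions and the Murray statement cannot both be
  exact, and neither reading is guessed to be "the intent".
* **Lengths.** Only the 1 cm root-to-outlet path length is specified by
  the reference geometry; per-generation lengths are not. The default
  assigns equal fractions of the path to each channel generation
  (`length_fractions = rep(1/4, 4)`), configurable. Device images show no
  strong length grading, and the flow solution depends on lengths only
  through the per-segment resistances, so this choice is mild.
* **Angle.** The bifurcation half-angle (default 30°) is stored for
  planar layout and export only. A resistance network is
  angle-independent, and no angle is specified for the reference device.

The branch↔outlet topology (left-to-right `B` numbering, terminal `Bk`
↔ `Ok`) is an assumption reconstructed from the reference tables' zero
patterns; the test suite asserts its consistency with both the
measurement table (zero out-splits) and the WSS table (zero entries).

## Flow: two solution modes

Fluid is Newtonian with water properties (ρ = 1000 kg/m³,
μ = 10⁻³ Pa·s, 20 °C nominal; configurable) — the perfusion experiments
the model mirrors use water rather than blood. Flow is steady and
laminar; at the default inlet condition (0.012 m/s mean velocity in a
1 mm channel) the Reynolds number is 12, far below transition, and
pulsatility is neglected as it is largely damped before the arteriolar
level.

**Resistance (predictive) mode.** Each segment is a Hagen–Poiseuille
resistor $R = 8\mu L/(\pi r^4)$. `solve_network()` assembles the nodal
conductance (Laplacian) system with: mass conservation at every junction,
a prescribed inlet flow (velocity × root area when the inlet is given as
a velocity), one common reference pressure (0 Pa) at all open outlets,
and occlusion as an *exact zero-flow constraint* — occluded terminal
segments are removed from the conductance graph and their dangling nodes
take the stagnant upstream pressure. The zero-flow reading matches the
experimental design (outlets sealed with closed syringes, i.e.
effectively infinite outlet resistance) and keeps the system symmetric
positive definite and well conditioned, unlike a large-but-finite
penalty resistance.

**Splits (coupling) mode.** When measured outlet out-splits exist,
`flows_from_splits()` imposes them directly:
$Q(b) = Q_{in} \sum_{k \in \mathrm{down}(b)} s_k$. Conservation holds by
construction. Printed split tables can sum to 0.99–1.01 because of
rounding; they are used **raw** by default (a `renormalize` flag exists
but is off), because the raw values are exactly what the reference CFD
consumed and they reproduce its WSS table best. Consequently the root
"fraction" equals the split total, which may differ from 1 by the
table's rounding.

The two modes agree: feeding resistance-mode outlet fractions back
through the splits mode reproduces the segment flows to 10⁻¹⁰ relative,
for every occlusion pattern — a property the tests check against an
independent series–parallel reduction of the resistor ladder over all
255 feasible patterns.

One documented inconsistency in the reference conditions is retained
rather than resolved: the printed inlet velocity (0.012 m/s ≈ 565 µL/min
through a 1 mm circle) and the printed pump rate (195 µL/min) disagree,
and the printed "maximum Reynolds number 0.018" is irreconcilable with
either (water at 0.012 m/s in a 1 mm channel gives Re = 12). Both inlet
constants are kept as independent configuration (`flow_bc()`), and
`solve_network()` reports the Reynolds numbers it actually computes.

## Wall shear stress

Per branch, the fully developed laminar closure
$\tau = 4\mu Q/(\pi r^3)$ (`poiseuille_wss()`). This is exact for long
straight tubes but underestimates *area-averaged* WSS in a short
bifurcating network fed by a flat velocity profile: the 3D CFD reference
for the control scenario reports 0.36 Pa in the root channel where the
closure gives 0.096 Pa (factor ≈ 3.75; entrance-region and junction
effects are the plausible cause). The package therefore treats absolute
Poiseuille levels as indicative and validates the *ratio* form instead:

$$\tau_s(b) = \tau_{ref}(b)\,\frac{f_s(b)}{f_{ref}(b)},$$

where $f$ is the branch flow fraction (`branch_fractions()`,
`rescale_wss()`). At fixed inlet flow and geometry, area-averaged WSS
scales with the flow the branch carries, so a single reference column
predicts every other scenario. Rescaling against the packaged control
CFD column with the packaged measured splits reproduces the reference
CFD WSS table across all three occluded scenarios to within ±0.02 Pa in
every branch — i.e. to the table's printed precision — and exactly at
two decimals for the representative shared and terminal branches the
acceptance suite pins. The reference fractions default to the *measured*
control splits (not the idealized 0.125), because the reference CFD was
itself driven by the measured splits.

Near-zero entries (0.01–0.02 Pa) appear in the reference table for fully
occluded branches where the model predicts exactly zero; these are CFD
discretization artifacts, and a 0.05 Pa threshold is used wherever
"zero-WSS" branches are counted (`wss_summary()`). Printed-table
reproduction uses round-half-away-from-zero at two decimals
(`round_half_up()`), matching the tables' formatting; base `round()`
rounds half to even and would differ on exact halves.

## Scenarios and comparison

`builtin_scenarios()` returns the four study conditions: `control` (all
outlets open) and `case_1/8`, `case_3/8`, `case_5/8` with 1, 3 and 5
outlets blocked. The occlusion sets ({O3}, {O1–O3}, {O1–O3, O5, O8}) are
not stated explicitly anywhere; they are reconstructed from the
exact-zero rows of the measurement table and cross-validated in the
tests against the zero-WSS entries of the reference table. Each scenario
carries its measured splits, so the default pipeline runs in splits
mode.

`run_pipeline()` builds the tree once, computes each scenario's flows
and both WSS variants (Poiseuille `model` values alongside `rescaled`
ones — the rescaled values are the validated output, the absolute ones
are emitted for transparency), and assembles per-branch and per-outlet
ratios against control. Zero-flow branch counts — segments whose entire
downstream outlet set is occluded, a pure function of topology and the
occlusion set — come out as 0/1/4/6 for the four scenarios.
`compensation_index()` summarizes redistribution as the largest
open-outlet ratio of scenario split to control split: 1.27 for
`case_1/8`, 2.82 for `case_5/8` — the few unobstructed vessels carry up
to nearly three times their control share, the compensatory behaviour
expected of a real microcirculation. Reports round flows to 3
significant figures and WSS to 2 decimals (`write_comparison()`), and
identical inputs yield identical outputs.

## The synthetic measurement generator

`simulate_measurements()` emulates one outlet volume-collection run: the
resistance network is solved at the pump rate (default 195 µL/min),
open-outlet flows become collected volumes over the run duration
(default 60 s; 24.375 µL per outlet in the symmetric noiseless case),
multiplicative noise is applied per outlet, occluded outlets collect
exactly zero (sealed blocks, no leak term), and out-splits are
normalized by the measured total so they sum to 1 exactly.

* **Noise.** Multiplicative on volume, because reading a collected
  volume scales with the amount collected. The default relative SD 0.03
  is calibrated once to the spread of the reference control out-splits
  (0.121–0.129 around 0.125, a ~3% scatter). Default distribution is
  Gaussian truncated at zero; a unit-mean lognormal is available. The
  true error structure of the underlying experiment is not reported
  anywhere; this model is an exposed assumption, not an inference.
* **Fabrication jitter.** `perturb_geometry()` perturbs each radius by
  half an independent Gaussian *width* (diameter) deviation, with
  `width_sd` defaulting to 20 µm / qnorm(0.995) ≈ 7.8 µm so that 99% of
  width deviations fall inside the 20 µm envelope reported for the
  fabricated channels. Draws producing non-positive radii raise an
  error rather than being silently clamped.
* **Seeding.** One global seed with per-outlet (and per-segment)
  substreams derived by counter, so adding outlets or segments never
  reshuffles earlier draws, and the caller's RNG state is restored
  afterwards.

`detect_occlusions()` closes the loop: outlets with out-split at or
below a threshold (default 0.01) are flagged. Because blocked outlets
are exactly zero while open ones stay well above any plausible noise
floor, recovery of all four built-in patterns is error-free across the
whole 0.005–0.05 threshold range, and replicate means recover the true
splits to ±0.005 with 60–200 replicates.

What the generator does *not* emulate: leakage past a blocked outlet,
drift or pressure-dependence of the pump, inter-device geometric
correlation (each segment is jittered independently), and any imaging or
cell-culture observable. Passing the synthetic-recovery tests therefore
shows the estimator chain is consistent under the stated noise model —
not that real measurements obey that model.

## Numerical choices

* The nodal system is solved dense (`solve()`): the default tree has at
  most 9 unknown pressures, where sparse machinery would add overhead
  without benefit. The formulation stays SPD for any occlusion pattern
  with at least one open outlet; occluding everything is rejected as
  infeasible up front.
* Exact zeros are preserved deliberately: occluded outlets and fully
  starved branches carry flow 0.0, not 1e-17, so downstream logic
  (zero-flow counts, WSS zero-propagation, ratio bookkeeping) can test
  equality. Roundoff negatives in stagnant branches are clipped to zero
  after asserting they are below 10⁻⁹ of the inlet flow.
* Ratios against control record 0 (not NaN) for branches with zero flow.
* Tolerances: Murray conservation and path-length conservation hold to
  10⁻¹² relative by construction; solver-vs-oracle and mode-equivalence
  checks run at 10⁻¹⁰ relative.
* JSON tree export writes full-precision doubles and round-trips
  losslessly; the VTK polyline export is legacy ASCII with one point per
  node and a `radius_m` point array.

## Validation scope and problem sizes

The test suite exercises: closed-form geometry identities; the linear
solver against an independent series–parallel reduction over all 255
occlusion patterns of the default tree; conservation, mirror-symmetry
and monotonicity properties on randomized patterns; exact reproduction
of the packaged measurement and WSS reference tables through the splits
and rescaling paths; and Monte-Carlo recovery on synthetic data (200
replicate tables for split recovery, 400 jitter draws for the 20 µm
envelope, 20 replicates × 3 thresholds × 4 patterns for occlusion
detection). These sizes keep the full suite under ten seconds while
leaving Monte-Carlo standard errors well inside the asserted margins.

## Limitations

The model is 0D: it resolves no velocity profiles, no secondary flows,
no entrance regions — hence the documented factor between Poiseuille and
area-averaged CFD WSS, and the restriction of quantitative WSS claims to
the rescaling form. Vessel compliance, non-Newtonian rheology and
pulsatility are all neglected, consistently with the steady
water-perfused reference setup it mirrors. The symmetric binary topology
with equal-length generations is an idealization; asymmetric or
measured geometries would require generalizing the tree builder, though
the solver itself is topology-agnostic within rooted trees.
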