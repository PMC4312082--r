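---
title: "Methods: shear-stress quartiles and plaque association in parametric vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shear-stress quartiles and plaque association in parametric vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coroshear)
```

## The scientific question

Atherosclerotic plaque does not form uniformly along a coronary artery: it
concentrates where the endothelial shear stress (ESS) — the tangential
frictional force the flowing blood exerts on the wall, in pascal — is low,
and to a lesser degree where it is very high. `coroshear` implements the
full in-silico counterpart of an in-vivo analysis of that association:
parametric coronary-like geometries stand in for image-derived lumens, a
steady laminar flow solve yields the wall shear stress field, the wall is
stratified into four equal-area ESS quartiles, and a synthetic intravascular
ultrasound (IVUS) pullback provides wall-thickness and tissue-composition
measurements whose statistical structure mirrors the published per-quartile
tables. The association statistics (prevalence table + chi-square, ANOVA
with Duncan's multiple range test, cluster-robust GEE) operate on that
measurement table exactly as they would on real pullback data.

Because no patient imaging is available (or needed) here, the geometry and
measurement generators *are* the study conditions: every downstream claim a
test makes is a claim about this synthetic population, not about patients.
What carries over to real data is the machinery — the solver contracts, the
equal-area stratification, the estimators and their calibration — which is
what the test suite pins down.

## Geometry and meshing

Vessels are single-inlet/single-outlet conduits defined by a centerline
(straight, planar bend, or helix), a base lumen radius (default 1.5 mm,
a typical coronary), and optional cosine-tapered stenoses parameterised by
diameter-severity (a 0.3 severity narrows the diameter 30% and the area
51%). Frames are transported along the centerline by the double-reflection
(rotation-minimizing) method so the swept section does not twist at bends.

The volume mesh is a structured hexahedral O-grid sweep: a square core
block mapped onto the disk plus `n_radial` quad rings, the outermost three
rings graded geometrically (growth ratio 1.3, first-layer thickness 5% of
the local radius by default) to resolve the near-wall gradient that the
wall-shear evaluation needs. These boundary-layer defaults are this
package's choice; only the *presence* of three thin wall layers is taken
from the reference setup, which does not state its grading.

Two numerical choices matter downstream:

* **Equal-area section calibration.** A polygonal cross-section inscribed
  in the circle has both a smaller area and a smaller effective radius, and
  both biases push flux-derived quantities (mean velocity, wall shear) up
  by several percent at the resolutions used here. The section template is
  therefore scaled so its *discrete* area equals the circle's. Wall area
  and enclosed volume still converge to the analytic cylinder values under
  refinement (a test asserts the error decreases over three levels).
* **Cell counts.** Reference-scale meshes (hundreds of thousands of
  polyhedra) are unnecessary for the desk-scale validation this package
  targets; defaults give O(10^3–10^4) hexahedra, and resolution is a
  config knob. The acceptance checks run the straight-tube ladder at
  (n_circ, n_radial, n_axial, first-layer) = (8, 4, 10, 0.10),
  (12, 5, 14, 0.07) and (16, 6, 20, 0.05), i.e. 360 to 2240 cells.

## Flow model and solver

Blood is Newtonian (viscosity 3.7 mPa s, density 1060 kg/m³) and the flow
steady, incompressible and laminar — Reynolds number about 300 for a
6.2 mm vessel at the constant 0.17 m/s inlet speed, and about 146 for the
default 3 mm tube. Walls are rigid with no slip; the single outlet is
traction-free (reference pressure zero); the inlet is a plug profile by
default, with a parabolic option used for analytic validation (a plug
inlet needs ~0.06·Re·D of entrance length to develop, which exceeds the
default tube length).

The solver is a colocated cell-centred finite-volume scheme in which each
Picard iteration assembles and direct-solves one coupled sparse system in
(u, v, w, p):

* convection: implicit blend of first-order upwind and central
  interpolation (`conv_blend`, default 0.5; the blend can be implicit
  because the coupled system is solved by sparse LU, which does not need
  diagonal dominance);
* diffusion: over-relaxed orthogonal part implicit, non-orthogonal
  correction explicit from Green–Gauss gradients;
* continuity: face fluxes with Rhie–Chow pressure dissipation, which
  suppresses pressure checkerboarding on the colocated grid.

Because the continuity rows are solved exactly (direct solver), the
reported face fluxes satisfy per-cell mass balance to machine precision at
every iteration — the global inlet/outlet imbalance in converged runs is
~1e-15 relative, far inside the 1e-6 contract. The coupled matrix mixes
rows in newtons with rows in m³/s, so it is 1-norm row/column equilibrated
before factorization; without this the LU pivoting can fail. High central
blends (≳0.9) can still produce fragile pivot sequences — the error message
says so, and the default 0.5 is both stable and accurate enough that the
straight-tube results are indistinguishable from pure upwind (the
convective term vanishes identically in fully developed Poiseuille flow).

Convergence is declared when the scaled momentum and continuity residuals
(normalised by the inlet momentum flux and inlet volume flux) drop below
`tol` = 1e-6; "fully converged" is not quantified in the reference
description, so this tolerance is the package's own contract. Runs that do
not converge abort with the residual history attached.

Wall shear stress is evaluated per wall face as
τ = μ‖u_t‖ / d_n from the wall-adjacent cell's tangential velocity and its
wall-normal distance — a one-sided gradient whose leading error for a
parabolic profile is d_n/2R ≈ 1–3% with the default boundary layers.
Measured against the Poiseuille value 4μV/R = 1.677 Pa (R = 1.5 mm,
parabolic inlet, mid-tube), the ladder above gives errors of roughly
7.9%, 3.2% and 1.7% — strictly decreasing, with the finest level well
inside the 5% acceptance band.

## Equal-area quartile stratification

Wall faces are sorted by τ ascending and the cumulative face area is cut at
25/50/75% of the total. Faces are atomic: one that straddles a cut goes
entirely to the lower quartile, so each quartile's area deviates from a
quarter of the wall by at most one face area (asserted against a
brute-force enumeration oracle on 10-face instances). Ties in τ are broken
by the stable face index; permuting face storage changes no areas or
summaries. Only *relative* (quartile) ESS is used downstream — absolute
thresholds would inherit every segmentation and inflow assumption, which is
exactly why the reference analysis avoided them.

Per-quartile summaries are per-face (unweighted) by default, mirroring a
point-sampled IVUS comparison; area-weighted variants are reported in
separate, explicitly named columns.

## The synthetic IVUS generator

The generator reproduces the *statistical structure* of the published
per-quartile tables, not ultrasound physics:

* **Thickness.** Per quartile, a truncated lognormal on the published
  [min, max] range. Thickness is positive and right-skewed (the published
  maxima sit far above mean + 2 SD), which motivates the family. The two
  free parameters are fitted so the **truncated** mean and SD equal the
  published mean and SD. Fitting the untruncated moments instead (and then
  truncating) biases the quartile-1 mean down by ~0.006 mm — comparable to
  the 2-standard-error recovery band at n = 10⁴ — and the published
  statistics describe range-limited data in the first place, so the
  truncated-moment fit is both the more faithful and the more robust
  choice.
* **Composition.** A Dirichlet model per quartile over (fibrous,
  fibrofatty, necrotic, calcified). The quartile means place the
  fibrofatty excess in quartile 1 (≈33.5% vs ≈21% elsewhere) while keeping
  the prevalence-weighted pooled means near the published overall
  composition (56.3/24.7/11.9/7.1%). The concentration parameter 2.1 is a
  one-time least-squares calibration of the four marginal SDs against the
  published 41.7/22.3/7.8/5.6 percentage points; the four-class closure
  constraint makes an exact match impossible, so it is not attempted.
  Composition is only generated for plaque cross-sections, and the thinnest
  19% of those are flagged "not analyzable" and excluded from composition
  analysis, mirroring the published failure rate of radiofrequency tissue
  classification on very small plaques. Flagging the *thinnest* plaques
  (rather than a random subset) encodes the stated failure mechanism.
* **Clustering.** A vessel-level additive random effect on thickness
  (SD 0.05 mm) gives the cluster-robust machinery real correlation to
  detect; it is a config knob.
* **Sampling.** 25 points per quartile per vessel (100 per vessel),
  area-weighted without replacement over the quartile's wall faces. How
  the original random points were drawn is not stated; area-weighting is
  this package's choice and is recorded here.
* **Registration.** Pullback time maps to centerline arclength through a
  monotone piecewise-linear interpolant anchored at landmarks, with the
  nominal 0.5 mm/s motorized speed extrapolating outside the anchored
  range; the map is exactly invertible there. Rotational (angular)
  registration of IVUS frames is deliberately not modelled.

### What the generator does and does not establish

A known tension, documented rather than hidden: the published thickness
table and the published prevalence table are mutually inconsistent under
*any* two-parameter right-skewed thickness family. Matching the quartile
mean/SD/range exactly gives 0.3 mm-exceedance probabilities of
54.0/27.8/33.0/46.4% — correctly ordered (Q1 > Q4 > Q3 > Q2) but with a
Q1–Q4 gap of 7.5 points where the prevalence table prints 14.8. At 250
points per quartile that gap has z ≈ 1.7, so a single synthetic study
reproduces the full sample ordering with probability ≈ 0.95, and a
199-in-200-replicates style bar on that event is a coin flip by
construction. The test suite states the check at its face value and the
package does not tune the generator to pass it: the generator's fidelity
target is the thickness table, and the prevalence *ordering* holds in
expectation.

## Statistics

* `prevalence_table()` reproduces published-style tables exactly
  (percentages printed to one decimal); `chi_square()` is the 3-df Pearson
  test without continuity correction.
* `anova_duncan()` follows the classical multiple range test: ordered
  means, critical ranges from studentized-range quantiles at Duncan's
  protection levels α_p = 1 − (1 − α)^(p−1), harmonic-mean n for unequal
  groups, stepwise testing with containment, and a letter display of
  homogeneous subsets. Critical values come from `qtukey()`, so any number
  of groups and error df work without tables. At k = 2 the test reduces to
  the pooled two-sample t decision (verified).
* `fit_clustered_binary()` is a logistic marginal model fitted by
  generalized estimating equations with an exchangeable working
  correlation (moment estimator) and robust sandwich covariance. Link and
  correlation structure are not stated in the reference analysis; logit +
  exchangeable is the standard choice for clustered binary outcomes, with
  the vessel as the default cluster. With singleton clusters it coincides
  with `glm()` to 1e-6 (verified); constant outcomes and separation abort
  with an explicit error instead of a silent fix.
* The naive (independence) ANOVA/Duncan results and the cluster-adjusted
  GEE are reported side by side in the study report; the reference analysis
  used both without stating how they were combined.

## End-to-end study

`run_study()` chains geometry → flow → WSS → stratification → sampling →
measurement synthesis → statistics for a configurable vessel set (default:
a stenosed straight tube, a 180° bend, and a helical segment), writes every
intermediate artifact (STL walls, VTK fields, per-quartile surfaces,
CSV tables, residual histories, the YAML config with seed and config hash),
and is deterministic given the config seed. Per-vessel quartiles are
computed within each vessel and then pooled, matching the per-vessel
surface-model workflow of the reference analysis.

## Known limitations

* Steady flow only: no pulsatility, no wall motion or compliance, no
  non-Newtonian rheology — the same simplifications the reference analysis
  makes, and its stated ones.
* Single-inlet/single-outlet conduits: bifurcations are out of scope, so
  the "high ESS at flow dividers" pattern has no geometric substrate here;
  the bend and stenosis cases carry the qualitative ESS patterns instead.
* The coupled direct solve is O(10⁴) cells practical; larger meshes need a
  segregated or preconditioned iterative solver.
* Synthetic measurements share none of the device physics of IVUS
  (speckle, reader variability beyond one noise term, angular
  misregistration); conclusions from passing tests are about the
  generator's statistical structure.
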