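# coroshear

Endothelial shear stress (ESS) and atherosclerotic plaque association in
parametric coronary vessels.

Low wall shear stress marks where coronary plaque preferentially forms;
very high shear marks a second, smaller peak. Demonstrating that
association requires chaining a 3-D lumen geometry, a laminar
computational-fluid-dynamics solve, an equal-area stratification of the
wall by shear, co-registered intravascular-ultrasound (IVUS) wall
measurements, and clustered categorical statistics. `coroshear` implements
that whole chain in R for *parametric* vessels, so every stage is
reproducible, testable against analytic oracles, and free of patient data:

* **geometry** — straight / bent / helical conduits with cosine-tapered
  stenoses; structured hexahedral O-grid sweep meshes with three graded
  near-wall boundary layers; STL/PLY/VTK export.
* **cfd** — steady incompressible Navier–Stokes (Newtonian blood:
  μ = 3.7 mPa·s, ρ = 1060 kg/m³, 0.17 m/s inlet, no-slip walls,
  traction-free outlet) with a colocated finite-volume, Rhie–Chow
  stabilized, fully coupled velocity–pressure scheme; wall shear stress
  τ = μ‖u_t‖/d_n per wall face.
* **ess_analysis** — quartile stratification where each quartile covers
  25% of the wall *area* (quartile 1 = lowest ESS), per-quartile
  summaries, per-quartile surface export.
* **synthetic_ivus** — pullback measurement tables with the published
  per-quartile thickness distributions (truncated lognormals), four-class
  Dirichlet tissue composition with a fibrofatty excess at low ESS, 25
  points per quartile per vessel, vessel-level clustering, and
  landmark-based time↔arclength registration at 0.5 mm/s.
* **association** — the 0.3 mm plaque rule, prevalence tables with
  chi-square, one-way ANOVA with Duncan's multiple range test
  (studentized-range critical values, protection levels
  α_p = 1 − (1−α)^(p−1)), and a logistic GEE with exchangeable working
  correlation and sandwich standard errors for the clustered data.

## Worked example

Reproduce a published-style prevalence analysis from its counts, then run
a small flow benchmark:

```r
library(coroshear)

prev <- prevalence_from_counts(n_plaque    = c(124,  50,  60,  87),
                               n_no_plaque = c(126, 200, 190, 163))
prev
#> Plaque prevalence by ESS quartile
#>   Q1: plaque  124 (49.6%)   no plaque  126 (50.4%)
#>   Q2: plaque   50 (20.0%)   no plaque  200 (80.0%)
#>   Q3: plaque   60 (24.0%)   no plaque  190 (76.0%)
#>   Q4: plaque   87 (34.8%)   no plaque  163 (65.2%)
#>   overall: 321 of 1000 (32.1%)
chi_square(prev)
#> # A tibble: 1 × 4
#>   statistic    df  p.value method
#>       <dbl> <int>    <dbl> <chr>
#> 1      60.3     3 5.12e-13 Pearson chi-square
```

Plaque is commonest at the lowest shear (49.6%), second-commonest at the
highest (34.8%), rare in between; the chi-square test rejects homogeneity
decisively (p < 0.001).

The flow solver against the analytic Poiseuille solution
(τ = 4μV/R = 1.677 Pa at R = 1.5 mm, V = 0.17 m/s):

```r
sp  <- vessel_spec("straight", length = 20, radius = 1.5)
msh <- build_mesh(sp, n_circ = 12, n_axial = 14, n_radial = 5, first_layer = 0.07)
fw  <- solve_steady_flow(msh$volume, fluid_model(), inlet_profile = "parabolic")
fw
#> <flow_fields> 966 cells, Re = 146, 18 Picard iterations (converged: TRUE)
#>   inlet flux 1.238930e-06 m3/s, outlet flux 1.238930e-06 m3/s (imbalance 1.68e-14)
wss <- compute_wss(fw, msh$volume)
mean(wss$tau[wss$s_mm > 5 & wss$s_mm < 15])   # mid-tube mean wall shear, Pa
#> [1] 1.731353
```

1.7314 Pa against the analytic 1.677 Pa (3.2% discretization error at this
coarse resolution; the error falls below 2% one refinement level up), with
mass conserved to machine precision.

A full synthetic study — three vessels, flow solves, quartile maps, a
100-point pullback per vessel, and all association statistics — is one
call:

```r
report <- run_study(study_config(seed = 1))
report$prevalence      # 4-row plaque table from the synthetic pullback
report$thickness_anova # ANOVA + Duncan letters across ESS quartiles
tidy(report$gee)       # cluster-robust quartile contrasts
```

A thin command-line driver wraps the same functions
(`inst/cli/coroshear.R`; subcommands `geometry`, `solve`, `stratify`,
`simulate-ivus`, `associate`, `run-study`, `tables-from-counts`).

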