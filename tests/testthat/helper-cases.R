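# Shared fixtures: flow solutions are expensive, so each named case is
# solved once per test run and reused by unit and acceptance tests.

.case_cache <- new.env(parent = emptyenv())

cached_case <- function(key, expr) {
  if (!exists(key, envir = .case_cache))
    assign(key, expr, envir = .case_cache)
  get(key, envir = .case_cache)
}

# Poiseuille refinement ladder: circumferential, radial and first-layer
# resolution all refine together.
poiseuille_levels <- list(
  list(n_circ = 8,  n_radial = 4, n_axial = 10, first_layer = 0.10),
  list(n_circ = 12, n_radial = 5, n_axial = 14, first_layer = 0.07),
  list(n_circ = 16, n_radial = 6, n_axial = 20, first_layer = 0.05))

poiseuille_case <- function(level) {
  cached_case(paste0("poiseuille", level), {
    lv <- poiseuille_levels[[level]]
    sp <- vessel_spec("straight", length = 20, radius = 1.5)
    msh <- build_mesh(sp, n_circ = lv$n_circ, n_axial = lv$n_axial,
                      n_radial = lv$n_radial, first_layer = lv$first_layer)
    fw <- solve_steady_flow(msh$volume, fluid_model(), tol = 1e-6,
                            max_iter = 60, inlet_profile = "parabolic",
                            relax = 1, conv_blend = 0.5)
    list(mesh = msh, flow = fw, wss = compute_wss(fw, msh$volume))
  })
}

bend_case <- function() {
  cached_case("bend", {
    sp <- vessel_spec("bend", bend_radius = 10, sweep_deg = 180, radius = 1.5)
    msh <- build_mesh(sp, n_circ = 12, n_axial = 28, n_radial = 5,
                      first_layer = 0.07)
    fw <- solve_steady_flow(msh$volume, fluid_model(), tol = 1e-6,
                            max_iter = 60, inlet_profile = "parabolic",
                            relax = 1, conv_blend = 0.5)
    list(mesh = msh, flow = fw, wss = compute_wss(fw, msh$volume))
  })
}

stenosis_case <- function() {
  cached_case("stenosis", {
    sp <- vessel_spec("straight", length = 20,
                      radius = radius_profile(1.5,
                        data.frame(center = 10, length = 8, severity = 0.3)))
    msh <- build_mesh(sp, n_circ = 12, n_axial = 24, n_radial = 5,
                      first_layer = 0.07)
    fw <- solve_steady_flow(msh$volume, fluid_model(), tol = 1e-6,
                            max_iter = 60, inlet_profile = "plug",
                            relax = 1, conv_blend = 0.5)
    list(mesh = msh, flow = fw, wss = compute_wss(fw, msh$volume))
  })
}

stokes_case <- function(speed = 0.17) {
  cached_case(paste0("stokes", speed), {
    sp <- vessel_spec("straight", length = 20, radius = 1.5)
    msh <- build_mesh(sp, n_circ = 8, n_axial = 10, n_radial = 4,
                      first_layer = 0.10)
    fl <- fluid_model(density = 1060 * 1e-3, inlet_speed = speed)
    fw <- solve_steady_flow(msh$volume, fl, tol = 1e-6, max_iter = 40,
                            inlet_profile = "parabolic", relax = 1,
                            conv_blend = 0.5)
    list(mesh = msh, flow = fw, wss = compute_wss(fw, msh$volume))
  })
}

analytic_poiseuille_tau <- function(mu = 3.7e-3, V = 0.17, R_mm = 1.5) {
  4 * mu * V / (R_mm * 1e-3)
}

# independent sequential-scan oracle for the area-quartile rule
oracle_quartile_labels <- function(tau, area) {
  ord <- order(tau, seq_along(tau))
  total <- sum(area)
  cuts <- total * c(0.25, 0.5, 0.75)
  lab <- integer(length(tau))
  cum <- 0
  for (i in ord) {
    lab[i] <- 1L + sum(cum >= cuts - 1e-12 * total)
    cum <- cum + area[i]
  }
  lab
}

# all monotone 4-block partitions of n sorted faces (cut positions 0..n)
enumerate_partitions <- function(n) {
  out <- list()
  for (c1 in 0:n) for (c2 in c1:n) for (c3 in c2:n)
    out[[length(out) + 1L]] <- c(c1, c2, c3)
  out
}
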