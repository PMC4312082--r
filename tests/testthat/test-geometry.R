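test_that("centerlines have the analytic arclengths", {
  cl <- make_centerline(vessel_spec("straight", length = 20), n = 30)
  expect_equal(sqrt(sum((cl$points[30, ] - cl$points[1, ])^2)), 20)

  clb <- make_centerline(vessel_spec("bend", bend_radius = 10, sweep_deg = 90),
                         n = 100)
  expect_equal(max(clb$arclength), pi * 10 / 2, tolerance = 1e-8)

  # helix closed form, checked against dense numerical integration
  sph <- vessel_spec("helix", helix_radius = 5, pitch = 10, n_turns = 2)
  L_exact <- 2 * 2 * pi * sqrt(5^2 + (10 / (2 * pi))^2)
  expect_equal(vessel_length(sph), L_exact)
  th <- seq(0, 4 * pi, length.out = 20001)
  p <- cbind(5 * cos(th), 5 * sin(th), 10 * th / (2 * pi))
  num <- sum(sqrt(rowSums(diff(p)^2)))
  expect_equal(num, L_exact, tolerance = 1e-6)
  clh <- make_centerline(sph, n = 500)
  expect_equal(max(clh$arclength), L_exact, tolerance = 1e-9)
})

test_that("centerline invariants hold: monotone arclength, unit frames", {
  for (sp in list(vessel_spec("straight"), vessel_spec("bend", sweep_deg = 135),
                  vessel_spec("helix", n_turns = 1.5))) {
    cl <- make_centerline(sp, n = 40)
    expect_true(all(diff(cl$arclength) > 0))
    expect_equal(rowSums(cl$tangents^2), rep(1, 40), tolerance = 1e-12)
    expect_equal(rowSums(cl$e1^2), rep(1, 40), tolerance = 1e-12)
    expect_equal(rowSums(cl$e1 * cl$tangents), rep(0, 40), tolerance = 1e-12)
  }
})

test_that("radius profile evaluates base and stenosis values", {
  rp0 <- radius_profile(1.5)
  expect_equal(eval_radius(rp0, c(0, 7.3, 20)), rep(1.5, 3))

  rp <- radius_profile(1.5, data.frame(center = 10, length = 8, severity = 0.3))
  expect_equal(eval_radius(rp, 10), 1.05)          # 1.5 * (1 - 0.3)
  expect_equal(eval_radius(rp, c(5.99, 14.01)), c(1.5, 1.5))
  # throat area reduction = 1 - (1 - severity)^2 = 51%,
  # cross-checked against numerically integrated cross-section area
  r_throat <- eval_radius(rp, 10)
  expect_equal(1 - r_throat^2 / 1.5^2, 0.51, tolerance = 1e-12)
  a_num <- integrate(function(th) rep(r_throat^2 / 2, length(th)), 0, 2 * pi)$value
  expect_equal(1 - a_num / (pi * 1.5^2), 0.51, tolerance = 1e-9)

  expect_error(eval_radius(rp, 25, extent = 20), "extent")
  expect_error(radius_profile(-1), "positive")
  expect_error(radius_profile(1.5, data.frame(center = 1, length = 2, severity = 1)),
               "severity")
})

test_that("vessel spec rejects degenerate parameters", {
  expect_error(vessel_spec("straight", length = -5), "positive")
  expect_error(vessel_spec("bend", bend_radius = 1, radius = 1.5),
               "self-intersecting")
  expect_error(vessel_spec("helix", pitch = -1), "positive")
})

test_that("straight-tube mesh reproduces analytic wall area and volume", {
  sp <- vessel_spec("straight", length = 20, radius = 1.5)
  msh <- build_mesh(sp, n_circ = 64, n_axial = 40, n_radial = 8)
  expect_equal(sum(msh$wall$area), 2 * pi * 1.5 * 20, tolerance = 0.01)
  expect_equal(sum(msh$volume$cell_volume), pi * 1.5^2 * 20, tolerance = 0.01)
})

test_that("mesh area and volume errors decrease over 3 refinement levels", {
  sp <- vessel_spec("straight", length = 20, radius = 1.5)
  errs <- sapply(1:3, function(lv) {
    p <- poiseuille_levels[[lv]]
    m <- build_mesh(sp, n_circ = p$n_circ, n_axial = p$n_axial,
                    n_radial = p$n_radial, first_layer = p$first_layer)
    c(abs(sum(m$wall$area) - 2 * pi * 1.5 * 20) / (2 * pi * 1.5 * 20),
      abs(sum(m$volume$cell_volume) - pi * 45) / (pi * 45))
  })
  expect_true(all(diff(errs[1, ]) < 0))
  # cell volumes sum to the section-area-calibrated value at every level;
  # the wall-area error is the polygonal perimeter bias and must shrink
  expect_lt(errs[1, 3], 0.01)
})

test_that("every interior face is shared by exactly two cells", {
  msh <- build_mesh(vessel_spec("bend", sweep_deg = 120), n_circ = 8,
                    n_axial = 8, n_radial = 4)
  vm <- msh$volume
  n_int <- sum(!is.na(vm$neigh))
  n_bnd <- sum(is.na(vm$neigh))
  expect_equal(2L * n_int + n_bnd, 6L * nrow(vm$hexes))
  expect_true(all(vm$owner[!is.na(vm$neigh)] != vm$neigh[!is.na(vm$neigh)]))
  # boundary faces form the closed surface: inlet + outlet + wall
  expect_setequal(unique(vm$patch[is.na(vm$neigh)]), c("wall", "inlet", "outlet"))
})

test_that("boundary layers are graded: wall-adjacent shells thinner than interior", {
  msh <- build_mesh(vessel_spec("straight"), n_circ = 8, n_axial = 6,
                    n_radial = 5, bl_layers = 3, bl_growth = 1.3,
                    first_layer = 0.05)
  vm <- msh$volume
  # mean cell volume by distance-from-wall layer (annulus rings only)
  v_by_layer <- tapply(vm$cell_volume, vm$cell_layer, mean)
  expect_lt(v_by_layer[["1"]], v_by_layer[["2"]])
  expect_lt(v_by_layer[["2"]], v_by_layer[["3"]])
  expect_lt(v_by_layer[["3"]], v_by_layer[["4"]])
})

test_that("mesh generation is deterministic", {
  sp <- vessel_spec("helix", helix_radius = 5, pitch = 12, n_turns = 1)
  m1 <- build_mesh(sp, n_circ = 8, n_axial = 8, n_radial = 4)
  m2 <- build_mesh(sp, n_circ = 8, n_axial = 8, n_radial = 4)
  expect_identical(m1$volume$nodes, m2$volume$nodes)
  expect_identical(m1$volume$hexes, m2$volume$hexes)
})

test_that("mesh construction rejects invalid resolutions", {
  sp <- vessel_spec("straight")
  expect_error(build_mesh(sp, n_circ = 6), "multiple of 4")
  expect_error(build_mesh(sp, n_circ = 8, n_radial = 3, bl_layers = 3),
               "n_radial")
})
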