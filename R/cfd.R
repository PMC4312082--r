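# Steady incompressible laminar Navier-Stokes on the hex sweep mesh.
#
# Colocated cell-centred finite volumes with a coupled velocity-pressure
# linear system per Picard iteration: implicit upwind convection with
# deferred central correction, over-relaxed orthogonal diffusion with
# explicit non-orthogonal correction, an implicit pressure-gradient block,
# and a continuity block whose face fluxes carry Rhie-Chow pressure
# dissipation to suppress checkerboarding. Each Picard step is one sparse
# direct solve of the full (u, v, w, p) system, so the converged face fluxes
# satisfy per-cell continuity to direct-solver precision.

# Precompute SI-unit finite-volume geometry from a volume_mesh (mm).
fv_geometry <- function(mesh) {
  cc <- mesh$cell_centroid * MM_TO_M
  V <- mesh$cell_volume * MM_TO_M^3
  Sf <- mesh$Sf * MM_TO_M^2
  cf <- mesh$face_centroid * MM_TO_M
  o <- mesh$owner
  n <- mesh$neigh
  int <- which(!is.na(n))
  ni <- n[int]
  oi <- o[int]
  d <- cc[ni, , drop = FALSE] - cc[oi, , drop = FALSE]
  Sfi <- Sf[int, , drop = FALSE]
  Sfd <- rowSums(Sfi * d)
  Dgeo <- rowSums(Sfi^2) / Sfd
  # linear interpolation weight of the owner cell
  do_f <- sqrt(rowSums((cf[int, , drop = FALSE] - cc[oi, , drop = FALSE])^2))
  dn_f <- sqrt(rowSums((cf[int, , drop = FALSE] - cc[ni, , drop = FALSE])^2))
  w <- dn_f / (do_f + dn_f)
  tvec <- Sfi - Dgeo * d  # non-orthogonal remainder

  bnd <- which(is.na(n))
  ob <- o[bnd]
  db <- cf[bnd, , drop = FALSE] - cc[ob, , drop = FALSE]
  Dgeo_b <- rowSums(Sf[bnd, , drop = FALSE]^2) / rowSums(Sf[bnd, , drop = FALSE] * db)
  patch_b <- mesh$patch[bnd]

  list(cc = cc, V = V, Sf = Sf, cf = cf, o = o, n = n,
       int = int, oi = oi, ni = ni, d = d, Dgeo = Dgeo, w = w, tvec = tvec,
       bnd = bnd, ob = ob, Dgeo_b = Dgeo_b, patch_b = patch_b,
       inlet = bnd[patch_b == "inlet"], outlet = bnd[patch_b == "outlet"],
       wall = bnd[patch_b == "wall"], nc = length(V))
}

# Green-Gauss cell gradients of one scalar field given its face values.
gg_gradient <- function(geo, phi_f) {
  acc_idx <- c(geo$o, geo$ni)
  out <- matrix(0, geo$nc, 3)
  for (k in 1:3) {
    contrib <- c(geo$Sf[, k] * phi_f, -geo$Sf[geo$int, k] * phi_f[geo$int])
    g <- rowsum(contrib, acc_idx)
    out[as.integer(rownames(g)), k] <- g
  }
  out / geo$V
}

# face values of a cell field with given boundary values
face_values <- function(geo, phi, phi_bnd) {
  phi_f <- numeric(length(geo$o))
  phi_f[geo$int] <- geo$w * phi[geo$oi] + (1 - geo$w) * phi[geo$ni]
  phi_f[geo$bnd] <- phi_bnd
  phi_f
}

# inlet boundary velocity (rows match geo$inlet), m/s
inlet_velocity <- function(mesh, geo, fluid, inlet_profile) {
  cl <- mesh$centerline
  t0 <- cl$tangents[1, ]
  R_in <- eval_radius(mesh$spec$radius, 0, extent = max(cl$arclength)) * MM_TO_M
  cfb <- geo$cf[geo$inlet, , drop = FALSE]
  rel <- sweep(cfb, 2, cl$points[1, ] * MM_TO_M)
  rel <- rel - outer(as.vector(rel %*% t0), t0)
  r <- sqrt(rowSums(rel^2))
  speed <- if (inlet_profile == "plug") {
    rep(fluid$inlet_speed, length(r))
  } else {
    2 * fluid$inlet_speed * pmax(0, 1 - (r / R_in)^2)
  }
  outer(speed, t0)
}

#' Solve steady laminar flow through a vessel mesh
#'
#' Solves the steady incompressible Navier-Stokes equations on a
#' [build_mesh()] volume mesh with no-slip walls, a prescribed inlet velocity
#' (plug by default, parabolic for analytic validation) and a zero-pressure
#' outlet. Picard iterations couple velocity and pressure in a single sparse
#' direct solve per iteration; convergence is declared when the scaled
#' momentum and continuity residuals drop below `tol`.
#'
#' @param mesh A `volume_mesh` from [build_mesh()].
#' @param fluid A [fluid_model()].
#' @param tol Relative residual tolerance (default 1e-6).
#' @param max_iter Maximum Picard iterations.
#' @param inlet_profile `"plug"` (constant inlet velocity) or `"parabolic"`.
#' @param relax Picard under-relaxation factor in (0, 1].
#' @param conv_blend Deferred-correction blend towards central differencing
#'   of the convective term, in `[0, 1]` (0 = pure upwind).
#' @param quiet Suppress per-iteration residual output.
#' @return An object of class `flow_fields`: cell velocities (m/s), cell
#'   pressures (Pa), conservative face fluxes (m3/s), residual history, and
#'   inlet/outlet flux diagnostics.
#' @export
solve_steady_flow <- function(mesh, fluid = fluid_model(), tol = 1e-6,
                              max_iter = 80,
                              inlet_profile = c("plug", "parabolic"),
                              relax = 1, conv_blend = 0.5, quiet = TRUE) {
  stopifnot(inherits(mesh, "volume_mesh"))
  inlet_profile <- match.arg(inlet_profile)
  geo <- fv_geometry(mesh)
  mu <- fluid$dynamic_viscosity
  rho <- fluid$density
  nc <- geo$nc
  nfb <- length(geo$bnd)

  D_mean <- 2 * mesh$spec$radius$base_radius * MM_TO_M
  Re <- reynolds_number(fluid, D_mean)
  if (Re > 2000)
    warn(sprintf("Reynolds number %.0f exceeds the laminar range; results unreliable.", Re))

  u_in <- inlet_velocity(mesh, geo, fluid, inlet_profile)
  F_in <- rowSums(u_in * geo$Sf[geo$inlet, , drop = FALSE])  # negative (inflow)
  Q_in <- -sum(F_in)
  A_in <- sum(sqrt(rowSums(geo$Sf[geo$inlet, , drop = FALSE]^2)))

  # boundary velocity table (rows match geo$bnd): wall 0, inlet prescribed,
  # outlet zero-gradient (filled per iteration)
  bvel <- matrix(0, nfb, 3)
  i_in <- match(geo$inlet, geo$bnd)
  i_out <- match(geo$outlet, geo$bnd)
  i_wall <- match(geo$wall, geo$bnd)
  bvel[i_in, ] <- u_in

  # initial state: inlet speed rescaled by local lumen area, along the local
  # tangent; zero pressure
  cl <- mesh$centerline
  s_cells <- mesh$cell_s
  R_s <- eval_radius(mesh$spec$radius, s_cells, extent = max(cl$arclength))
  R0 <- eval_radius(mesh$spec$radius, 0, extent = max(cl$arclength))
  tang_idx <- pmax(1L, pmin(nrow(cl$points),
    round(stats::approx(cl$arclength, seq_along(cl$arclength), xout = s_cells,
                        rule = 2)$y)))
  shape <- if (inlet_profile == "parabolic") 2 * (1 - pmin(1, mesh$cell_rfrac)^2) else 1
  uvec <- cl$tangents[tang_idx, , drop = FALSE] *
          (fluid$inlet_speed * (R0 / R_s)^2 * shape)
  p <- numeric(nc)
  # initial face fluxes from the initial velocity field
  Ff <- numeric(length(geo$o))
  for (k in 1:3) Ff <- Ff + face_values(geo, uvec[, k], c(0)[rep(1, nfb)]) * geo$Sf[, k]
  Ff[geo$inlet] <- F_in
  Ff[geo$wall] <- 0

  iu <- seq_len(nc); iv <- iu + nc; iw <- iu + 2L * nc; ip <- iu + 3L * nc
  int <- geo$int; oi <- geo$oi; ni <- geo$ni; w <- geo$w
  scale_mom <- max(rho * fluid$inlet_speed^2 * A_in,
                   mu * fluid$inlet_speed * A_in / D_mean)
  hist <- vector("list", max_iter)
  converged <- FALSE
  x <- c(uvec[, 1], uvec[, 2], uvec[, 3], p)
  x_solved <- x
  F_solved <- Ff

  for (iter in seq_len(max_iter)) {
    mdot <- rho * Ff[int]
    up <- ifelse(mdot >= 0, oi, ni)

    ## --- momentum coefficient matrix (shared by u, v, w) -------------------
    # convection: implicit blend of upwind and central interpolation; the
    # coupled direct solve does not need diagonal dominance, so the blend can
    # be implicit and the Picard loop only lags the mass fluxes
    g <- conv_blend
    Ti <- c(oi, ni, oi, oi, ni, ni, oi, oi, ni, ni)
    Tj <- c(up, up, oi, ni, oi, ni, oi, ni, ni, oi)
    Tx <- c((1 - g) * mdot, -(1 - g) * mdot,
            g * mdot * w, g * mdot * (1 - w),
            -g * mdot * w, -g * mdot * (1 - w),
            mu * geo$Dgeo, -mu * geo$Dgeo, mu * geo$Dgeo, -mu * geo$Dgeo)
    # boundary diffusion (wall + inlet) and outlet convection
    wi_faces <- c(geo$wall, geo$inlet)
    wi_rows <- geo$ob[match(wi_faces, geo$bnd)]
    wi_D <- mu * geo$Dgeo_b[match(wi_faces, geo$bnd)]
    out_rows <- geo$ob[match(geo$outlet, geo$bnd)]
    mdot_out <- rho * Ff[geo$outlet]
    Ti <- c(Ti, wi_rows, out_rows)
    Tj <- c(Tj, wi_rows, out_rows)
    Tx <- c(Tx, wi_D, pmax(mdot_out, 0))
    Amom <- Matrix::sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(nc, nc))
    aP <- Matrix::diag(Amom)
    aP <- pmax(aP, 1e-300)

    ## --- explicit momentum sources ----------------------------------------
    bmom <- matrix(0, nc, 3)
    # inlet: diffusion to prescribed value and upwind convective inflow
    mdot_in <- rho * Ff[geo$inlet]
    in_rows <- geo$ob[match(geo$inlet, geo$bnd)]
    in_D <- mu * geo$Dgeo_b[match(geo$inlet, geo$bnd)]
    for (k in 1:3) {
      src <- in_D * u_in[, k] - mdot_in * u_in[, k]
      bmom[, k] <- bmom[, k] + unname_rowsum(src, in_rows, nc)
    }
    # explicit non-orthogonal diffusion correction
    bvel[i_out, ] <- uvec[geo$ob[match(geo$outlet, geo$bnd)], , drop = FALSE]
    for (k in 1:3) {
      gradk <- gg_gradient(geo, face_values(geo, uvec[, k], bvel[, k]))
      gf <- w * gradk[oi, , drop = FALSE] + (1 - w) * gradk[ni, , drop = FALSE]
      nonorth <- mu * rowSums(gf * geo$tvec)
      bmom[, k] <- bmom[, k] + unname_rowsum(nonorth, oi, nc) - unname_rowsum(nonorth, ni, nc)
    }

    ## --- pressure gradient block ------------------------------------------
    # + sum_f p_f Sf_k in each momentum row
    PGi <- PGj <- PGx <- list()
    for (k in 1:3) {
      off <- (k - 1L) * nc
      PGi[[length(PGi) + 1L]] <- c(oi + off, oi + off, ni + off, ni + off,
                                   wi_rows + off)
      PGj[[length(PGj) + 1L]] <- c(oi, ni, oi, ni, wi_rows) + 3L * nc
      PGx[[length(PGx) + 1L]] <- c(w * geo$Sf[int, k], (1 - w) * geo$Sf[int, k],
                                   -w * geo$Sf[int, k], -(1 - w) * geo$Sf[int, k],
                                   geo$Sf[wi_faces, k])
    }

    ## --- continuity block ---------------------------------------------------
    Vbar_aP <- geo$V / aP
    drc <- 0.5 * (Vbar_aP[oi] + Vbar_aP[ni]) * geo$Dgeo
    pb <- p[geo$ob]
    pb[i_out] <- 0
    gradp <- gg_gradient(geo, face_values(geo, p, pb))
    gpd <- rowSums((w * gradp[oi, , drop = FALSE] +
                    (1 - w) * gradp[ni, , drop = FALSE]) * geo$d)
    CTi <- CTj <- CTx <- list()
    for (k in 1:3) {
      off <- (k - 1L) * nc
      CTi[[length(CTi) + 1L]] <- c(oi, oi, ni, ni) + 3L * nc
      CTj[[length(CTj) + 1L]] <- c(oi, ni, oi, ni) + off
      CTx[[length(CTx) + 1L]] <- c(w * geo$Sf[int, k], (1 - w) * geo$Sf[int, k],
                                   -w * geo$Sf[int, k], -(1 - w) * geo$Sf[int, k])
    }
    CTi[[length(CTi) + 1L]] <- c(oi, oi, ni, ni) + 3L * nc
    CTj[[length(CTj) + 1L]] <- c(oi, ni, oi, ni) + 3L * nc
    CTx[[length(CTx) + 1L]] <- c(drc, -drc, -drc, drc)
    # outlet: F = u.Sf + drc_b * p_o  (p_b = 0)
    drc_b <- Vbar_aP[out_rows] * geo$Dgeo_b[match(geo$outlet, geo$bnd)]
    for (k in 1:3) {
      CTi[[length(CTi) + 1L]] <- out_rows + 3L * nc
      CTj[[length(CTj) + 1L]] <- out_rows + (k - 1L) * nc
      CTx[[length(CTx) + 1L]] <- geo$Sf[geo$outlet, k]
    }
    CTi[[length(CTi) + 1L]] <- out_rows + 3L * nc
    CTj[[length(CTj) + 1L]] <- out_rows + 3L * nc
    CTx[[length(CTx) + 1L]] <- drc_b
    bcont <- -unname_rowsum(F_in, in_rows, nc) - unname_rowsum(drc * gpd, oi, nc) +
             unname_rowsum(drc * gpd, ni, nc)

    ## --- assemble the coupled system ----------------------------------------
    Ai <- c(Ti, Ti + nc, Ti + 2L * nc, unlist(PGi), unlist(CTi))
    Aj <- c(Tj, Tj + nc, Tj + 2L * nc, unlist(PGj), unlist(CTj))
    Ax <- c(Tx, Tx, Tx, unlist(PGx), unlist(CTx))
    A <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Ax, dims = c(4L * nc, 4L * nc))
    b <- c(bmom[, 1], bmom[, 2], bmom[, 3], bcont)

    ## --- residuals of the nonlinear system at the current state -------------
    r <- as.vector(A %*% x - b)
    res <- c(u = sum(abs(r[iu])), v = sum(abs(r[iv])), w = sum(abs(r[iw])),
             continuity = sum(abs(r[ip])))
    res[1:3] <- res[1:3] / scale_mom
    res[4] <- res[4] / Q_in
    hist[[iter]] <- c(iter = iter, res)
    if (!quiet)
      cat(sprintf("iter %3d  res u %.3e v %.3e w %.3e cont %.3e\n",
                  iter, res[1], res[2], res[3], res[4]))
    if (max(res) < tol) { converged <- TRUE; break }

    # 1-norm row/column equilibration: momentum rows are in newtons and
    # continuity rows in m3/s, so the raw saddle-point system is badly scaled
    # for the sparse LU pivoting
    rsc <- 1 / Matrix::rowSums(abs(A))
    A <- Matrix::Diagonal(x = rsc) %*% A
    csc <- 1 / Matrix::colSums(abs(A))
    A <- A %*% Matrix::Diagonal(x = csc)
    xs <- tryCatch(csc * as.vector(Matrix::solve(A, rsc * b)),
      error = function(e) abort(paste0(
        "Sparse factorization of the coupled system failed (",
        conditionMessage(e),
        "). A lower `conv_blend` usually restores a stable pivot sequence."),
        class = "coroshear_linear_solve"))
    lam <- if (iter == 1) 1 else relax
    x <- x + lam * (xs - x)
    # keep the solver state on the solved manifold for flux evaluation
    uvec <- cbind(x[iu], x[iv], x[iw])
    p <- x[ip]
    # conservative face fluxes of the *solved* state (exact per-cell continuity)
    us <- cbind(xs[iu], xs[iv], xs[iw]); ps <- xs[ip]
    Fn <- numeric(length(geo$o))
    Fn[int] <- (w * us[oi, 1] + (1 - w) * us[ni, 1]) * geo$Sf[int, 1] +
               (w * us[oi, 2] + (1 - w) * us[ni, 2]) * geo$Sf[int, 2] +
               (w * us[oi, 3] + (1 - w) * us[ni, 3]) * geo$Sf[int, 3] -
               drc * (ps[ni] - ps[oi]) + drc * gpd
    Fn[geo$inlet] <- F_in
    Fn[geo$wall] <- 0
    Fn[geo$outlet] <- rowSums(us[out_rows, , drop = FALSE] *
                              geo$Sf[geo$outlet, , drop = FALSE]) + drc_b * ps[out_rows]
    F_solved <- Fn
    x_solved <- xs
    Ff <- Fn  # Picard-lagged fluxes for the next convection assembly
  }

  history <- as_tibble(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  if (!converged) {
    final <- unlist(utils::tail(history, 1))[-1]
    abort(c(sprintf("Flow solver did not converge in %d iterations (final residual %.3e, tol %g).",
                    max_iter, max(final), tol),
            i = "Residual history attached as `history` in the condition."),
          class = "coroshear_no_convergence", history = history)
  }
  # report the last *solved* state so face fluxes conserve mass exactly
  uvec <- cbind(x_solved[iu], x_solved[iv], x_solved[iw])
  p <- x_solved[ip]
  flux_in <- -sum(F_solved[geo$inlet])
  flux_out <- sum(F_solved[geo$outlet])

  structure(list(velocity = uvec, pressure = p, face_flux = F_solved,
                 residual_history = history, converged = converged,
                 iterations = max(history$iter),
                 flux_in = flux_in, flux_out = flux_out,
                 reynolds = Re, fluid = fluid,
                 inlet_profile = inlet_profile, geo = geo),
            class = "flow_fields")
}

unname_rowsum <- function(x, idx, n) {
  out <- numeric(n)
  g <- rowsum(x, idx)
  out[as.integer(rownames(g))] <- g
  out
}

#' @export
print.flow_fields <- function(x, ...) {
  cat(sprintf(paste0("<flow_fields> %d cells, Re = %.0f, %d Picard iterations",
                     " (converged: %s)\n"),
              nrow(x$velocity), x$reynolds, x$iterations, x$converged))
  cat(sprintf("  inlet flux %.6e m3/s, outlet flux %.6e m3/s (imbalance %.2e)\n",
              x$flux_in, x$flux_out,
              abs(x$flux_in - x$flux_out) / x$flux_in))
  invisible(x)
}

#' Wall shear stress from a converged flow solution
#'
#' Evaluates, on every wall face, the magnitude of the tangential viscous
#' traction \eqn{\tau = \mu \|u_t\| / d_n} from the wall-adjacent cell's
#' velocity (no-slip wall), where \eqn{d_n} is the wall-normal distance of
#' that cell centre. The graded boundary layers of [build_mesh()] keep
#' \eqn{d_n} small so this one-sided gradient is accurate.
#'
#' @param flow A `flow_fields` object from [solve_steady_flow()].
#' @param mesh The `volume_mesh` the flow was solved on.
#' @param mu Dynamic viscosity in Pa s (defaults to the fluid used).
#' @return A tibble, one row per wall face: `face`, `tau` (Pa), `area_mm2`,
#'   `s_mm`, `theta`, and wall-face centroid coordinates (mm).
#' @export
compute_wss <- function(flow, mesh, mu = flow$fluid$dynamic_viscosity) {
  stopifnot(inherits(flow, "flow_fields"), inherits(mesh, "volume_mesh"))
  if (!any(mesh$patch == "wall")) abort("Mesh has no wall faces.")
  wall <- make_wall_mesh(mesh)
  geo <- flow$geo
  iw <- match(wall$volume_face, geo$bnd)
  cells <- wall$cell
  nrm <- wall$normal
  uc <- flow$velocity[cells, , drop = FALSE]
  un <- rowSums(uc * nrm)
  ut <- uc - un * nrm
  dn <- rowSums((geo$cf[wall$volume_face, , drop = FALSE] -
                 geo$cc[cells, , drop = FALSE]) * nrm)
  tau <- mu * sqrt(rowSums(ut^2)) / dn
  tibble(face = seq_along(cells), tau = tau, area_mm2 = wall$area,
         s_mm = wall$s_mm, theta = wall$theta,
         x = wall$centroid[, 1], y = wall$centroid[, 2], z = wall$centroid[, 3])
}
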