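#' Parametric radius profile along a vessel
#'
#' Describes the lumen radius as a function of arclength: a constant base
#' radius, optionally narrowed by one or more smooth (cosine-tapered)
#' stenoses. Severity is expressed as a diameter-reduction fraction, so a
#' severity of 0.3 narrows the local diameter by 30% (and the lumen area by
#' \eqn{1 - 0.7^2 = 51\%} at the throat).
#'
#' @param base_radius Base lumen radius in mm (> 0).
#' @param stenoses A data frame (or tibble) with columns `center` (arclength
#'   of the throat, mm), `length` (axial extent of the narrowing, mm) and
#'   `severity` (diameter-reduction fraction in `[0, 1)`), one row per
#'   stenosis. `NULL` for a uniform vessel.
#' @return An object of class `radius_profile`.
#' @examples
#' rp <- radius_profile(1.5, stenoses = data.frame(center = 10, length = 8, severity = 0.3))
#' eval_radius(rp, c(0, 10)) # 1.50 at inlet, 1.05 at the throat
#' @export
radius_profile <- function(base_radius, stenoses = NULL) {
  if (!is.numeric(base_radius) || length(base_radius) != 1L || base_radius <= 0)
    abort("`base_radius` must be a single positive number (mm).")
  if (!is.null(stenoses)) {
    stenoses <- as_tibble(stenoses)
    req <- c("center", "length", "severity")
    if (!all(req %in% names(stenoses)))
      abort("`stenoses` needs columns center, length, severity.")
    if (any(stenoses$length <= 0)) abort("Stenosis `length` must be positive.")
    if (any(stenoses$severity < 0 | stenoses$severity >= 1))
      abort("Stenosis `severity` must lie in [0, 1).")
  }
  structure(list(base_radius = base_radius, stenoses = stenoses),
            class = "radius_profile")
}

#' Evaluate a radius profile at given arclengths
#'
#' Within each stenosis window the radius is reduced by a raised-cosine taper
#' that reaches `base_radius * (1 - severity)` at the throat and blends
#' smoothly (C1) into the base radius at the window edges.
#'
#' @param profile A [radius_profile()].
#' @param s Arclength position(s) in mm.
#' @param extent Optional vessel length (mm); positions outside `[0, extent]`
#'   are an error when supplied.
#' @return Numeric vector of radii (mm), one per element of `s`.
#' @export
eval_radius <- function(profile, s, extent = NULL) {
  stopifnot(inherits(profile, "radius_profile"))
  if (!is.null(extent) && any(s < -1e-9 | s > extent + 1e-9))
    abort("Arclength `s` outside the vessel extent.")
  r <- rep(profile$base_radius, length(s))
  st <- profile$stenoses
  if (!is.null(st)) {
    for (i in seq_len(nrow(st))) {
      x <- (s - st$center[i]) / st$length[i]          # -0.5 .. 0.5 inside
      inside <- abs(x) <= 0.5
      taper <- 0.5 * (1 + cos(2 * pi * x[inside]))    # 1 at throat, 0 at edges
      r[inside] <- r[inside] * (1 - st$severity[i] * taper)
    }
  }
  r
}

#' Define a parametric vessel
#'
#' A `vessel_spec` fixes the centerline shape (straight, planar bend or
#' helical), the lumen radius profile, and the discretization defaults used
#' by [build_mesh()]. It is a parametric stand-in for an image-derived
#' coronary lumen: single inlet, single outlet, no branches.
#'
#' @param kind One of `"straight"`, `"bend"`, `"helix"`.
#' @param length Vessel length in mm (straight vessels; ignored otherwise).
#' @param radius A [radius_profile()] or a single base radius in mm.
#' @param bend_radius Bend radius of curvature in mm (`kind = "bend"`).
#' @param sweep_deg Bend sweep angle in degrees (`kind = "bend"`).
#' @param helix_radius Helix radius in mm (`kind = "helix"`).
#' @param pitch Axial advance per helix turn in mm (`kind = "helix"`).
#' @param n_turns Number of helix turns (`kind = "helix"`).
#' @param id Optional vessel identifier used in downstream tables.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(kind = c("straight", "bend", "helix"),
                        length = 20,
                        radius = 1.5,
                        bend_radius = 10, sweep_deg = 90,
                        helix_radius = 5, pitch = 10, n_turns = 2,
                        id = NULL) {
  kind <- match.arg(kind)
  if (is.numeric(radius)) radius <- radius_profile(radius)
  stopifnot(inherits(radius, "radius_profile"))
  if (kind == "straight" && length <= 0) abort("Vessel `length` must be positive.")
  if (kind == "bend") {
    if (bend_radius <= 0 || sweep_deg <= 0) abort("Bend parameters must be positive.")
    if (bend_radius <= radius$base_radius)
      abort("`bend_radius` must exceed the tube radius (self-intersecting sweep).")
  }
  if (kind == "helix" && (helix_radius <= 0 || pitch <= 0 || n_turns <= 0))
    abort("Helix parameters must be positive.")
  structure(list(kind = kind, length = length, radius = radius,
                 bend_radius = bend_radius, sweep_deg = sweep_deg,
                 helix_radius = helix_radius, pitch = pitch, n_turns = n_turns,
                 id = id %||% kind),
            class = "vessel_spec")
}

#' Total arclength of a vessel specification
#' @param spec A [vessel_spec()].
#' @return Arclength in mm.
#' @export
vessel_length <- function(spec) {
  switch(spec$kind,
    straight = spec$length,
    bend     = spec$bend_radius * spec$sweep_deg * pi / 180,
    helix    = spec$n_turns * 2 * pi *
               sqrt(spec$helix_radius^2 + (spec$pitch / (2 * pi))^2))
}

#' Sample the centerline of a vessel
#'
#' Returns centerline points at (approximately) uniform arclength spacing,
#' with unit tangents and rotation-minimizing orthonormal frames. The frames
#' are transported by the double-reflection method so the swept cross-section
#' does not twist at bends.
#'
#' @param spec A [vessel_spec()].
#' @param n Number of sample points (>= 2).
#' @return An object of class `centerline`: list with `points` (n x 3, mm),
#'   `arclength` (cumulative, mm), `tangents`, `e1`, `e2` (n x 3 unit
#'   vectors; `e1`/`e2` span the cross-sectional plane).
#' @export
make_centerline <- function(spec, n = 50) {
  stopifnot(inherits(spec, "vessel_spec"), n >= 2)
  L <- vessel_length(spec)
  if (L <= 0) abort("Vessel length must be positive.")
  t <- seq(0, 1, length.out = n)
  pts <- switch(spec$kind,
    straight = cbind(0, 0, t * L),
    bend = {
      # arc in the x-z plane, starting at origin with tangent +z,
      # curving toward +x (bend centre at (Rb, 0, 0))
      Rb <- spec$bend_radius
      phi <- t * spec$sweep_deg * pi / 180
      cbind(Rb * (1 - cos(phi)), 0, Rb * sin(phi))
    },
    helix = {
      th <- t * spec$n_turns * 2 * pi
      rh <- spec$helix_radius
      cbind(rh * cos(th) - rh, rh * sin(th), spec$pitch * th / (2 * pi))
    })
  tang <- switch(spec$kind,
    straight = cbind(0, 0, rep(1, n)),
    bend = {
      phi <- t * spec$sweep_deg * pi / 180
      cbind(sin(phi), 0, cos(phi))
    },
    helix = {
      th <- t * spec$n_turns * 2 * pi
      rh <- spec$helix_radius
      v <- cbind(-rh * sin(th), rh * cos(th), rep(spec$pitch / (2 * pi), n))
      v / sqrt(rowSums(v^2))
    })
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  # chord-length accumulation underestimates the true arclength slightly;
  # rescale so the parametric positions carry the analytic arclength
  s <- s / s[n] * L
  fr <- rmf_frames(pts, tang)
  structure(list(points = pts, arclength = s, tangents = tang,
                 e1 = fr$e1, e2 = fr$e2, spec = spec),
            class = "centerline")
}

# Rotation-minimizing frames by the double-reflection method
# (Wang et al. 2008), given points and unit tangents.
rmf_frames <- function(pts, tang) {
  n <- nrow(pts)
  e1 <- matrix(0, n, 3)
  # initial normal: any unit vector orthogonal to t[1]
  t0 <- tang[1, ]
  ref <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * t0) * t0
  e1[1, ] <- v / sqrt(sum(v^2))
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    e1[i + 1, ] <- if (c2 < 1e-30) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthonormalize against the analytic tangent
    e <- e1[i + 1, ] - sum(e1[i + 1, ] * tang[i + 1, ]) * tang[i + 1, ]
    e1[i + 1, ] <- e / sqrt(sum(e^2))
  }
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf("<vessel_spec> %s '%s': length %.3f mm, base radius %.3f mm",
              x$kind, x$id, vessel_length(x), x$radius$base_radius))
  ns <- if (is.null(x$radius$stenoses)) 0L else nrow(x$radius$stenoses)
  if (ns > 0) cat(sprintf(", %d stenos%s", ns, if (ns == 1) "is" else "es"))
  cat("\n")
  invisible(x)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arclength %.3f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' @rdname make_centerline
#' @param x A `centerline`.
#' @param ... Unused.
#' @export
as_tibble.centerline <- function(x, ...) {
  tibble(s_mm = x$arclength,
         x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
         tx = x$tangents[, 1], ty = x$tangents[, 2], tz = x$tangents[, 3])
}
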