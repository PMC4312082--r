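# Structured O-grid cross-section template on the unit disk.
#
# A square core block (elliptical square-to-disk mapping) surrounded by
# n_radial quad rings; the outermost `bl_layers` rings are geometrically
# graded boundary layers (thinnest at the wall). Returns unit-disk node
# coordinates, quad connectivity (CCW), the distance-from-wall layer index
# per quad, and the ordered outer ring used to close the wall surface.
ogrid_section <- function(n_circ, n_radial, bl_layers = 3, bl_growth = 1.3,
                          first_layer = 0.05, core_frac = 0.5) {
  if (n_circ < 8 || n_circ %% 4 != 0)
    abort("`n_circ` must be a multiple of 4 and at least 8.")
  if (n_radial < bl_layers + 1)
    abort("`n_radial` must be at least `bl_layers` + 1.")
  m <- n_circ / 4L

  # core block: elliptical map of an (m+1)^2 grid onto the disk of radius core_frac
  ij <- expand.grid(i = 0:m, j = 0:m)
  xi <- 2 * ij$i / m - 1
  eta <- 2 * ij$j / m - 1
  core <- core_frac * cbind(xi * sqrt(1 - eta^2 / 2), eta * sqrt(1 - xi^2 / 2))
  gid <- function(i, j) j * (m + 1L) + i + 1L

  # CCW perimeter of the core grid (4m nodes), starting at corner (m, 0)
  perim <- c(gid(m, 0:m),                 # right edge, bottom to top
             gid((m - 1):0, m),           # top edge, right to left
             gid(0, (m - 1):0),           # left edge, top to bottom
             gid(1:(m - 1), 0))           # bottom edge, left to right
  stopifnot(length(perim) == n_circ)
  theta <- atan2(core[perim, 2], core[perim, 1])

  # radial spacing: interior uniform cells, then graded boundary layers
  # (first_layer at the wall, growing inward by bl_growth)
  t_bl <- first_layer * bl_growth^(seq_len(bl_layers) - 1)
  span <- 1 - core_frac
  if (sum(t_bl) >= span)
    abort("Boundary layers thicker than the annulus; reduce `first_layer` or `core_frac`.")
  n_int <- n_radial - bl_layers
  h <- (span - sum(t_bl)) / n_int
  spacing <- c(rep(h, n_int), rev(t_bl))  # inner to outer
  radii <- core_frac + cumsum(spacing)
  radii[n_radial] <- 1                     # guard against rounding

  rings <- lapply(radii, function(r) r * cbind(cos(theta), sin(theta)))
  xy <- rbind(core, do.call(rbind, rings))
  ring_id <- function(k, j) (m + 1L)^2 + (k - 1L) * n_circ + j  # k>=1, j in 1..n_circ

  # core quads
  cij <- expand.grid(i = 0:(m - 1), j = 0:(m - 1))
  core_q <- cbind(gid(cij$i, cij$j), gid(cij$i + 1, cij$j),
                  gid(cij$i + 1, cij$j + 1), gid(cij$i, cij$j + 1))
  # annulus quads ring by ring (ring 0 = core perimeter)
  jp <- c(2:n_circ, 1L)
  ann_q <- do.call(rbind, lapply(seq_len(n_radial), function(k) {
    inner <- if (k == 1) perim else ring_id(k - 1L, seq_len(n_circ))
    outer <- ring_id(k, seq_len(n_circ))
    cbind(inner, outer, outer[jp], inner[jp])
  }))
  quads <- rbind(core_q, ann_q)

  # signed area check (all CCW)
  a <- quad_signed_area(xy, quads)
  stopifnot(all(a > 0))
  # equal-area calibration: scale the polygonal section so its discrete
  # cross-sectional area equals the circle's, removing the leading-order
  # polygonal bias in flux-derived quantities (areas/volumes still converge
  # to the analytic values with refinement)
  xy <- xy * sqrt(pi / sum(a))

  layer <- c(rep(NA_integer_, nrow(core_q)),
             rep(n_radial:1, each = n_circ))  # 1 = wall-adjacent ring
  cx <- (xy[quads[, 1], 1] + xy[quads[, 2], 1] + xy[quads[, 3], 1] + xy[quads[, 4], 1]) / 4
  cy <- (xy[quads[, 1], 2] + xy[quads[, 2], 2] + xy[quads[, 3], 2] + xy[quads[, 4], 2]) / 4
  list(xy = xy, quads = quads, layer = layer, rfrac = sqrt(cx^2 + cy^2),
       outer_ring = ring_id(n_radial, seq_len(n_circ)), n_nodes = nrow(xy))
}

quad_signed_area <- function(xy, q) {
  x <- matrix(xy[q, 1], ncol = 4); y <- matrix(xy[q, 2], ncol = 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) + (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) + (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

# network sort of four id columns, for canonical face keys
sort4_key <- function(f) {
  a <- f[, 1]; b <- f[, 2]; c <- f[, 3]; d <- f[, 4]
  lo1 <- pmin(a, b); hi1 <- pmax(a, b)
  lo2 <- pmin(c, d); hi2 <- pmax(c, d)
  mn <- pmin(lo1, lo2); mx <- pmax(hi1, hi2)
  m1 <- pmax(lo1, lo2); m2 <- pmin(hi1, hi2)
  paste(mn, pmin(m1, m2), pmax(m1, m2), mx, sep = "_")
}

#' Build a structured hexahedral mesh for a vessel
#'
#' Sweeps an O-grid cross-section (square core plus quad rings, the outermost
#' `bl_layers` rings graded as thin near-wall boundary layers) along the
#' vessel centerline using rotation-minimizing frames, scaling each section by
#' the local lumen radius. Returns the volume mesh together with the tagged
#' wall surface.
#'
#' @param spec A [vessel_spec()].
#' @param n_circ Circumferential divisions (multiple of 4, >= 8).
#' @param n_axial Axial divisions along the centerline.
#' @param n_radial Radial quad rings outside the core (>= `bl_layers` + 1).
#' @param bl_layers Number of near-wall boundary layers (default 3).
#' @param bl_growth Geometric growth ratio of layer thickness away from the
#'   wall (default 1.3).
#' @param first_layer First (wall-adjacent) layer thickness as a fraction of
#'   the local radius (default 0.05).
#' @param core_frac Radius fraction occupied by the square core (default 0.5).
#' @return A list with components `volume` (class `volume_mesh`) and `wall`
#'   (class `wall_mesh`).
#' @examples
#' vm <- build_mesh(vessel_spec("straight", length = 20), n_circ = 8,
#'                  n_axial = 6, n_radial = 4)
#' sum(vm$wall$area)          # close to 2*pi*R*L
#' sum(vm$volume$cell_volume) # close to pi*R^2*L
#' @export
build_mesh <- function(spec, n_circ = 16, n_axial = 40, n_radial = 6,
                       bl_layers = 3, bl_growth = 1.3, first_layer = 0.05,
                       core_frac = 0.5) {
  stopifnot(inherits(spec, "vessel_spec"))
  sec <- ogrid_section(n_circ, n_radial, bl_layers, bl_growth, first_layer, core_frac)
  cl <- make_centerline(spec, n_axial + 1L)
  s <- cl$arclength
  R <- eval_radius(spec$radius, s, extent = max(s))
  ns <- sec$n_nodes

  # nodes: station-major layout
  nodes <- matrix(0, ns * (n_axial + 1L), 3)
  for (i in seq_len(n_axial + 1L)) {
    P <- cl$points[i, ]
    E <- rbind(cl$e1[i, ], cl$e2[i, ])        # 2 x 3
    nodes[(i - 1L) * ns + seq_len(ns), ] <-
      rep(P, each = ns) + (R[i] * sec$xy) %*% E
  }

  # hexes: bottom quad at station l, top at station l+1
  nq <- nrow(sec$quads)
  base <- rep((0:(n_axial - 1L)) * ns, each = nq)
  q <- sec$quads[rep(seq_len(nq), n_axial), , drop = FALSE]
  hexes <- cbind(q + base, q + base + ns)
  nc <- nrow(hexes)

  cell_layer <- rep(sec$layer, n_axial)
  cell_rfrac <- rep(sec$rfrac, n_axial)
  cell_s <- rep((s[-1] + s[-(n_axial + 1L)]) / 2, each = nq)
  cell_slab <- rep(seq_len(n_axial), each = nq)

  # faces of every hex (consistent local winding; orientation fixed later)
  loc <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
               c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  all_faces <- matrix(0L, nc * 6L, 4L)
  for (k in 1:6) all_faces[seq_len(nc) + (k - 1L) * nc, ] <- hexes[, loc[k, ]]
  face_cell <- rep(seq_len(nc), 6L)

  key <- sort4_key(all_faces)
  o <- order(key, method = "radix")
  dup <- key[o][-1] == key[o][-length(o)]
  if (any(dup & c(dup[-1], FALSE)))
    abort("Conforming-mesh violation: a face shared by more than two cells.")
  first <- o[c(!c(FALSE, dup))]              # first instance of each unique face
  pair_pos <- which(dup)
  owner_inst <- o[pair_pos]; neigh_inst <- o[pair_pos + 1L]

  interior_nodes <- all_faces[owner_inst, , drop = FALSE]
  interior_owner <- face_cell[owner_inst]
  interior_neigh <- face_cell[neigh_inst]
  bnd_inst <- setdiff(first, owner_inst)
  bnd_nodes <- all_faces[bnd_inst, , drop = FALSE]
  bnd_owner <- face_cell[bnd_inst]

  fnodes <- rbind(interior_nodes, bnd_nodes)
  owner <- c(interior_owner, bnd_owner)
  neigh <- c(interior_neigh, rep(NA_integer_, length(bnd_owner)))
  nf <- nrow(fnodes)

  # boundary patches: caps by node station, rest is wall
  station <- (fnodes - 1L) %/% ns           # station index per face node
  is_bnd <- is.na(neigh)
  all0 <- rowSums(station == 0L) == 4L
  allN <- rowSums(station == n_axial) == 4L
  patch <- rep("interior", nf)
  patch[is_bnd] <- "wall"
  patch[is_bnd & all0] <- "inlet"
  patch[is_bnd & allN] <- "outlet"

  # face geometry: area vector 0.5 (p3 - p1) x (p4 - p2), triangle-fan centroid
  p1 <- nodes[fnodes[, 1], , drop = FALSE]; p2 <- nodes[fnodes[, 2], , drop = FALSE]
  p3 <- nodes[fnodes[, 3], , drop = FALSE]; p4 <- nodes[fnodes[, 4], , drop = FALSE]
  Sf <- 0.5 * cross3(p3 - p1, p4 - p2)
  a1 <- 0.5 * row_norm(cross3(p2 - p1, p3 - p1))
  a2 <- 0.5 * row_norm(cross3(p3 - p1, p4 - p1))
  cf <- ((p1 + p2 + p3) / 3 * a1 + (p1 + p3 + p4) / 3 * a2) / pmax(a1 + a2, 1e-300)
  area <- row_norm(Sf)
  if (any(area <= 0)) abort("Degenerate face (zero area) in swept mesh.")

  # orient Sf from owner to neighbour (outward at boundaries)
  xm <- (nodes[hexes[, 1], ] + nodes[hexes[, 2], ] + nodes[hexes[, 3], ] +
         nodes[hexes[, 4], ] + nodes[hexes[, 5], ] + nodes[hexes[, 6], ] +
         nodes[hexes[, 7], ] + nodes[hexes[, 8], ]) / 8
  outv <- cf - xm[owner, , drop = FALSE]
  flip <- rowSums(Sf * outv) < 0
  Sf[flip, ] <- -Sf[flip, ]
  fnodes[flip, ] <- fnodes[flip, 4:1]

  # cell volumes/centroids from face pyramids (divergence theorem)
  vol_pyr_o <- rowSums((cf - xm[owner, , drop = FALSE]) * Sf) / 3
  c_pyr_o <- xm[owner, , drop = FALSE] + 0.75 * (cf - xm[owner, , drop = FALSE])
  ii <- which(!is.na(neigh))
  vol_pyr_n <- -rowSums((cf[ii, , drop = FALSE] - xm[neigh[ii], , drop = FALSE]) *
                        Sf[ii, , drop = FALSE]) / 3
  c_pyr_n <- xm[neigh[ii], , drop = FALSE] +
             0.75 * (cf[ii, , drop = FALSE] - xm[neigh[ii], , drop = FALSE])
  cell_idx <- c(owner, neigh[ii])
  vol_all <- c(vol_pyr_o, vol_pyr_n)
  if (any(vol_all <= 0))
    abort("Degenerate or inverted cell in swept mesh (bend too tight?).")
  V <- as.vector(rowsum(vol_all, cell_idx))
  cw <- rowsum(rbind(c_pyr_o, c_pyr_n) * vol_all, cell_idx)
  cc <- cw / V

  volume <- structure(list(
    nodes = nodes, hexes = hexes,
    face_nodes = fnodes, owner = owner, neigh = neigh,
    Sf = Sf, face_area = area, face_centroid = cf, patch = patch,
    cell_centroid = cc, cell_volume = V,
    cell_layer = cell_layer, cell_rfrac = cell_rfrac,
    cell_s = cell_s, cell_slab = cell_slab,
    centerline = cl, spec = spec,
    dims = list(n_circ = n_circ, n_axial = n_axial, n_radial = n_radial,
                bl_layers = bl_layers, bl_growth = bl_growth,
                first_layer = first_layer, core_frac = core_frac)),
    class = "volume_mesh")

  wall <- make_wall_mesh(volume)
  list(volume = volume, wall = wall)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
row_norm <- function(a) sqrt(rowSums(a^2))

# Wall surface view of a volume mesh: per-face areas, outward normals, and
# the cross-sectional coordinates (arclength s, angle theta) used downstream.
make_wall_mesh <- function(vm) {
  w <- which(vm$patch == "wall")
  Sf <- vm$Sf[w, , drop = FALSE]
  area <- vm$face_area[w]
  cf <- vm$face_centroid[w, , drop = FALSE]
  normal <- Sf / area
  cl <- vm$centerline
  # nearest centerline station by arclength of the owner cell
  s_mm <- vm$cell_s[vm$owner[w]]
  idx <- pmax(1L, pmin(nrow(cl$points),
                       round(stats::approx(cl$arclength, seq_along(cl$arclength),
                                           xout = s_mm, rule = 2)$y)))
  rel <- cf - cl$points[idx, , drop = FALSE]
  u <- rowSums(rel * cl$e1[idx, , drop = FALSE])
  v <- rowSums(rel * cl$e2[idx, , drop = FALSE])
  structure(list(
    vertices = vm$nodes, faces = vm$face_nodes[w, , drop = FALSE],
    area = area, normal = normal, centroid = cf,
    s_mm = s_mm, theta = atan2(v, u),
    cell = vm$owner[w], volume_face = w, spec = vm$spec),
    class = "wall_mesh")
}

#' Tabular view of a wall surface
#'
#' @param x A `wall_mesh`.
#' @param ... Unused.
#' @return A tibble with one row per wall face: `face` (index), `area_mm2`,
#'   centroid coordinates, arclength `s_mm` and cross-sectional angle `theta`.
#' @export
as_tibble.wall_mesh <- function(x, ...) {
  tibble(face = seq_along(x$area), area_mm2 = x$area,
         x = x$centroid[, 1], y = x$centroid[, 2], z = x$centroid[, 3],
         s_mm = x$s_mm, theta = x$theta)
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf(paste0("<volume_mesh> %d hex cells, %d nodes, %d faces ",
                     "(%d wall, %d inlet, %d outlet)\n"),
              nrow(x$hexes), nrow(x$nodes), length(x$owner),
              sum(x$patch == "wall"), sum(x$patch == "inlet"),
              sum(x$patch == "outlet")))
  cat(sprintf("  total volume %.4f mm^3, wall area %.4f mm^2\n",
              sum(x$cell_volume), sum(x$face_area[x$patch == "wall"])))
  invisible(x)
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat(sprintf("<wall_mesh> %d faces, total area %.4f mm^2\n",
              length(x$area), sum(x$area)))
  invisible(x)
}
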