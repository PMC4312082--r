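# Mesh and field export: ASCII STL / PLY for surfaces, legacy ASCII VTK for
# the volume mesh with cell data, CSV tables, YAML configs.

#' Write a wall surface to ASCII STL
#'
#' Quads are split into two triangles; facet normals are the stored outward
#' face normals.
#'
#' @param wall A `wall_mesh`.
#' @param path Output file path.
#' @param name Solid name embedded in the file.
#' @return The path, invisibly.
#' @export
write_stl <- function(wall, path, name = "wall") {
  stopifnot(inherits(wall, "wall_mesh"))
  f <- wall$faces
  v <- wall$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  tri <- rbind(f[, c(1, 2, 3), drop = FALSE], f[, c(1, 3, 4), drop = FALSE])
  nrm <- rbind(wall$normal, wall$normal)
  lines <- character(0)
  for (i in seq_len(nrow(tri))) {
    p <- v[tri[i, ], , drop = FALSE]
    lines <- c(lines,
      sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
      "    endloop", "  endfacet")
  }
  writeLines(lines, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a wall surface to ASCII PLY
#'
#' @param wall A `wall_mesh`.
#' @param path Output file path.
#' @param face_scalar Optional numeric per-face scalar stored as a `quality`
#'   property (e.g. wall shear stress).
#' @return The path, invisibly.
#' @export
write_ply <- function(wall, path, face_scalar = NULL) {
  stopifnot(inherits(wall, "wall_mesh"))
  used <- sort(unique(as.vector(wall$faces)))
  remap <- match(wall$faces, used)
  dim(remap) <- dim(wall$faces)
  v <- wall$vertices[used, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(remap)),
           "property list uchar int vertex_indices")
  if (!is.null(face_scalar)) hdr <- c(hdr, "property float quality")
  writeLines(c(hdr, "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  fl <- sprintf("4 %d %d %d %d", remap[, 1] - 1L, remap[, 2] - 1L,
                remap[, 3] - 1L, remap[, 4] - 1L)
  if (!is.null(face_scalar)) fl <- paste(fl, sprintf("%.9g", face_scalar))
  writeLines(fl, con)
  invisible(path)
}

#' Write the volume mesh (and optional fields) to legacy ASCII VTK
#'
#' Unstructured-grid format with hexahedral cells; cell data can include the
#' velocity vector, pressure, and any additional named scalars.
#'
#' @param mesh A `volume_mesh`.
#' @param path Output file path.
#' @param flow Optional `flow_fields` whose velocity/pressure become cell
#'   data.
#' @param cell_scalars Optional named list of per-cell numeric vectors.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, path, flow = NULL, cell_scalars = NULL) {
  stopifnot(inherits(mesh, "volume_mesh"))
  nn <- nrow(mesh$nodes); nc <- nrow(mesh$hexes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nc, nc * 9L), con)
  h <- mesh$hexes - 1L
  writeLines(sprintf("8 %d %d %d %d %d %d %d %d", h[, 1], h[, 2], h[, 3],
                     h[, 4], h[, 5], h[, 6], h[, 7], h[, 8]), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(rep("12", nc), con)  # VTK_HEXAHEDRON
  scalars <- cell_scalars %||% list()
  if (!is.null(flow)) scalars$pressure <- flow$pressure
  if (length(scalars) > 0 || !is.null(flow)) {
    writeLines(sprintf("CELL_DATA %d", nc), con)
    if (!is.null(flow)) {
      writeLines("VECTORS velocity double", con)
      writeLines(sprintf("%.9g %.9g %.9g", flow$velocity[, 1],
                         flow$velocity[, 2], flow$velocity[, 3]), con)
    }
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", scalars[[nm]]), con)
    }
  }
  invisible(path)
}

#' Export a quartile map as CSV
#'
#' One row per wall face: face id, area, tau, quartile.
#'
#' @param qmap A `quartile_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_quartile_csv <- function(qmap, path) {
  df <- as.data.frame(qmap[, intersect(c("face", "area_mm2", "tau", "quartile"),
                                       names(qmap))])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write study configurations as YAML
#'
#' A study configuration is a plain named list (see [study_config()]);
#' round-trips through YAML losslessly.
#'
#' @param path YAML file path.
#' @return `read_study_config()` returns the validated config list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  merged <- utils::modifyList(study_config(), cfg)
  # list-of-vessels replaces rather than merges with the default set
  if (!is.null(cfg$vessels)) merged$vessels <- cfg$vessels
  validate_study_config(merged)
}

#' @rdname read_study_config
#' @param config A study configuration list.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
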