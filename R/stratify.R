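#' Stratify wall faces into equal-area ESS quartiles
#'
#' Sorts wall faces by ascending shear stress and cuts the cumulative face
#' area at 25/50/75% of the total, so each quartile covers (up to one face)
#' a quarter of the wall surface: quartile 1 holds the lowest-ESS quarter of
#' the wall, quartile 4 the highest. Faces are atomic: a face straddling a
#' cut is assigned entirely to the lower quartile. Ties in tau are broken by
#' the stable original face index.
#'
#' @param wss A data frame with columns `tau` (Pa) and `area_mm2` (one row
#'   per wall face), as produced by [compute_wss()]. Extra columns are
#'   carried through.
#' @return The input tibble with an integer `quartile` column appended, of
#'   class `quartile_map`. Attributes `cuts` (the three tau cut values, Pa)
#'   and `quartile_area` (per-quartile total area, mm2) summarise the
#'   stratification.
#' @export
stratify_by_area_quartiles <- function(wss) {
  wss <- as_tibble(wss)
  if (!all(c("tau", "area_mm2") %in% names(wss)))
    abort("`wss` needs columns `tau` and `area_mm2`.")
  if (nrow(wss) == 0L) abort("Empty wall: no faces to stratify.")
  if (any(!is.finite(wss$tau))) abort("Non-finite tau values.")
  if (any(wss$area_mm2 <= 0)) abort("Face areas must be positive.")

  ord <- order(wss$tau, seq_len(nrow(wss)))
  a <- wss$area_mm2[ord]
  total <- sum(a)
  cum_before <- cumsum(a) - a
  cuts_area <- total * c(0.25, 0.5, 0.75)
  lab_sorted <- 1L + findInterval(cum_before, cuts_area)
  quartile <- integer(nrow(wss))
  quartile[ord] <- lab_sorted

  tau_cuts <- vapply(1:3, function(k) {
    hi <- suppressWarnings(min(wss$tau[quartile == k + 1L]))
    lo <- suppressWarnings(max(wss$tau[quartile == k]))
    if (!is.finite(hi)) lo else if (!is.finite(lo)) hi else (lo + hi) / 2
  }, numeric(1))
  out <- dplyr::mutate(wss, quartile = quartile)
  qa <- vapply(1:4, function(k) sum(out$area_mm2[out$quartile == k]), numeric(1))
  attr(out, "cuts") <- tau_cuts
  attr(out, "quartile_area") <- qa
  class(out) <- c("quartile_map", class(out))
  out
}

#' Per-quartile ESS summary statistics
#'
#' Mean, SD, min and max of the wall shear stress per quartile. Per-face
#' (unweighted) statistics mirror the point-sampled IVUS comparison and are
#' the default; area-weighted mean/SD are reported alongside, flagged by the
#' `weighted_*` columns. When a `vessel` column is present, per-vessel
#' summaries can be pooled with `by_vessel = TRUE`.
#'
#' @param qmap A `quartile_map` from [stratify_by_area_quartiles()] (or any
#'   data frame with `tau`, `area_mm2`, `quartile`).
#' @param by_vessel Summarise within each vessel first (requires a `vessel`
#'   column).
#' @return A tibble of class `quartile_summary`, one row per quartile (per
#'   vessel when `by_vessel`): `n_faces`, `mean`, `sd`, `min`, `max`,
#'   `weighted_mean`, `weighted_sd`, `area_mm2`.
#' @export
summarize_quartiles <- function(qmap, by_vessel = FALSE) {
  qmap <- as_tibble(qmap)
  if (!all(c("tau", "quartile", "area_mm2") %in% names(qmap)))
    abort("Need columns `tau`, `quartile`, `area_mm2`.")
  if (nrow(qmap) == 0L) abort("Empty quartile map.")
  grp <- if (by_vessel) {
    if (!"vessel" %in% names(qmap)) abort("`by_vessel = TRUE` needs a `vessel` column.")
    dplyr::group_by(qmap, .data$vessel, .data$quartile)
  } else {
    dplyr::group_by(qmap, .data$quartile)
  }
  out <- dplyr::summarise(grp,
    n_faces = dplyr::n(),
    mean = mean(.data$tau),
    sd = sd(.data$tau),
    min = min(.data$tau),
    max = max(.data$tau),
    weighted_mean = sum(.data$tau * .data$area_mm2) / sum(.data$area_mm2),
    weighted_sd = sqrt(pmax(0, sum(.data$area_mm2 * (.data$tau -
      sum(.data$tau * .data$area_mm2) / sum(.data$area_mm2))^2) /
      sum(.data$area_mm2))),
    area_mm2 = sum(.data$area_mm2),
    .groups = "drop")
  class(out) <- c("quartile_summary", class(out))
  out
}

#' Split a wall surface into per-quartile submeshes
#'
#' Partitions the wall faces of a `wall_mesh` by their ESS quartile label;
#' the four face-disjoint submeshes cover the wall exactly. Empty quartiles
#' (possible for degenerate maps) produce a warning.
#'
#' @param wall A `wall_mesh` from [build_mesh()].
#' @param qmap A `quartile_map` whose rows match the wall faces (same order).
#' @return A list of four `wall_mesh` objects named `Q1`..`Q4`.
#' @export
extract_quartile_surfaces <- function(wall, qmap) {
  stopifnot(inherits(wall, "wall_mesh"))
  if (nrow(qmap) != length(wall$area))
    abort("Quartile map and wall mesh have different face counts.")
  q <- qmap$quartile
  out <- lapply(1:4, function(k) {
    sel <- which(q == k)
    sub <- list(vertices = wall$vertices,
                faces = wall$faces[sel, , drop = FALSE],
                area = wall$area[sel], normal = wall$normal[sel, , drop = FALSE],
                centroid = wall$centroid[sel, , drop = FALSE],
                s_mm = wall$s_mm[sel], theta = wall$theta[sel],
                cell = wall$cell[sel], volume_face = wall$volume_face[sel],
                spec = wall$spec, quartile = k)
    class(sub) <- "wall_mesh"
    sub
  })
  names(out) <- paste0("Q", 1:4)
  empty <- vapply(out, function(m) length(m$area) == 0L, logical(1))
  if (any(empty))
    warn(sprintf("Empty quartile submesh(es): %s.",
                 paste(names(out)[empty], collapse = ", ")))
  out
}
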