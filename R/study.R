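# End-to-end study driver: geometry -> flow -> WSS quartiles -> synthetic
# IVUS -> association statistics, with all artifacts written to disk.

#' Default study configuration
#'
#' A named list of every tunable: vessel specifications, mesh resolution,
#' fluid model, solver options, measurement-generator models, statistical
#' options, and the output directory. All reference constants (inlet speed
#' 0.17 m/s, viscosity 3.7 mPa s, density 1060 kg/m3, plaque threshold
#' 0.3 mm, pullback speed 0.5 mm/s, 25 points per quartile) are named
#' defaults here, never magic numbers downstream. Serializes losslessly to
#' YAML via [write_study_config()].
#'
#' @param n_vessels Number of vessels in the default synthetic study.
#' @param seed Study master seed.
#' @param out_dir Output directory for artifacts.
#' @return A validated config list.
#' @export
study_config <- function(n_vessels = 3, seed = 1L, out_dir = tempfile("study")) {
  vessels <- list(
    list(kind = "straight", length = 20, base_radius = 1.5,
         stenoses = list(list(center = 10, length = 8, severity = 0.3))),
    list(kind = "bend", bend_radius = 10, sweep_deg = 180, base_radius = 1.5),
    list(kind = "helix", helix_radius = 5, pitch = 10, n_turns = 1.5,
         base_radius = 1.5))
  list(
    vessels = utils::head(vessels, n_vessels),
    mesh = list(n_circ = 12, n_axial = 24, n_radial = 5,
                bl_layers = 3, bl_growth = 1.3, first_layer = 0.07),
    fluid = list(dynamic_viscosity = 3.7e-3, density = 1060, inlet_speed = 0.17),
    solver = list(tol = 1e-6, max_iter = 60, inlet_profile = "plug",
                  relax = 1, conv_blend = 0.5),
    ivus = list(n_per_quartile = 25, vessel_sd = 0.05, pullback_speed = 0.5,
                p_not_analyzable = 0.19),
    stats = list(plaque_threshold = 0.3, alpha = 0.05),
    seed = seed,
    out_dir = out_dir)
}

validate_study_config <- function(cfg) {
  req <- c("vessels", "mesh", "fluid", "solver", "ivus", "stats", "seed", "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0)
    abort(sprintf("Config is missing fields: %s", paste(miss, collapse = ", ")))
  if (length(cfg$vessels) == 0) abort("Config has zero vessels.")
  for (v in cfg$vessels)
    if (is.null(v$kind) || is.null(v$base_radius))
      abort("Each vessel needs at least `kind` and `base_radius`.")
  with(cfg$fluid, {
    if (dynamic_viscosity <= 0 || density <= 0 || inlet_speed <= 0)
      abort("Fluid parameters must be positive.")
  })
  if (cfg$stats$plaque_threshold <= 0) abort("Plaque threshold must be positive.")
  cfg
}

vessel_from_config <- function(v, id = NULL) {
  st <- NULL
  if (!is.null(v$stenoses) && length(v$stenoses) > 0)
    st <- dplyr::bind_rows(lapply(v$stenoses, as_tibble))
  vessel_spec(kind = v$kind,
              length = v$length %||% 20,
              radius = radius_profile(v$base_radius, st),
              bend_radius = v$bend_radius %||% 10,
              sweep_deg = v$sweep_deg %||% 90,
              helix_radius = v$helix_radius %||% 5,
              pitch = v$pitch %||% 10,
              n_turns = v$n_turns %||% 2,
              id = id %||% v$id)
}

#' Run the full synthetic ESS-plaque study
#'
#' For each configured vessel: builds the mesh, solves the steady flow,
#' computes wall shear stress, stratifies the wall into equal-area ESS
#' quartiles and samples measurement points; then simulates the IVUS
#' measurements across vessels and runs the association analysis
#' (prevalence + chi-square, thickness ANOVA/Duncan, cluster-adjusted GEE,
#' composition ANOVA). All intermediate artifacts (meshes, fields, tables)
#' are written under `config$out_dir`; the run is deterministic given the
#' config seed.
#'
#' @param config A [study_config()] list.
#' @param write_artifacts Write STL/VTK/CSV artifacts (default TRUE).
#' @return An object of class `study_report`.
#' @export
run_study <- function(config = study_config(), write_artifacts = TRUE) {
  config <- validate_study_config(config)
  out_dir <- config$out_dir
  if (write_artifacts) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fl <- fluid_model(config$fluid$dynamic_viscosity, config$fluid$density,
                    config$fluid$inlet_speed)
  ess_all <- list()
  points_all <- list()
  summaries <- list()

  for (i in seq_along(config$vessels)) {
    vid <- config$vessels[[i]]$id %||% paste0("vessel", i)
    sp <- vessel_from_config(config$vessels[[i]], id = vid)
    msh <- do.call(build_mesh, c(list(spec = sp), config$mesh))
    fw <- tryCatch(
      do.call(solve_steady_flow,
              c(list(mesh = msh$volume, fluid = fl), config$solver)),
      error = function(e) abort(sprintf("[cfd:%s] %s", vid, conditionMessage(e))))
    wss <- compute_wss(fw, msh$volume)
    qmap <- stratify_by_area_quartiles(wss)
    qmap$vessel <- vid
    ess_all[[vid]] <- qmap
    summaries[[vid]] <- dplyr::mutate(summarize_quartiles(qmap), vessel = vid)
    pts <- sample_points(qmap, config$ivus$n_per_quartile,
                         seed = config$seed + i)
    pts$vessel <- vid
    pts$position_mm <- pts$s_mm
    pts$time_s <- pts$position_mm / config$ivus$pullback_speed
    points_all[[vid]] <- pts

    if (write_artifacts) {
      write_stl(msh$wall, file.path(out_dir, paste0(vid, "_wall.stl")), name = vid)
      write_vtk(msh$volume, file.path(out_dir, paste0(vid, "_fields.vtk")),
                flow = fw,
                cell_scalars = list(layer = ifelse(is.na(msh$volume$cell_layer),
                                                   0, msh$volume$cell_layer)))
      write_quartile_csv(qmap, file.path(out_dir, paste0(vid, "_quartiles.csv")))
      subs <- extract_quartile_surfaces(msh$wall, qmap)
      for (k in 1:4)
        if (length(subs[[k]]$area) > 0)
          write_stl(subs[[k]], file.path(out_dir, sprintf("%s_wall_q%d.stl", vid, k)),
                    name = sprintf("%s_q%d", vid, k))
      utils::write.csv(as.data.frame(fw$residual_history),
                       file.path(out_dir, paste0(vid, "_residuals.csv")),
                       row.names = FALSE)
    }
  }

  pts <- dplyr::bind_rows(points_all)
  pts <- simulate_thickness(pts, thickness_model(), seed = config$seed + 1000L,
                            vessel_sd = config$ivus$vessel_sd)
  pts$plaque <- call_plaque(pts$thickness_mm, config$stats$plaque_threshold)
  plq <- which(pts$plaque)
  comp <- simulate_composition(pts[plq, ], composition_model(),
                               seed = config$seed + 2000L,
                               p_not_analyzable = config$ivus$p_not_analyzable)
  for (cl in c("fibrous", "fibrofatty", "necrotic", "calcified"))
    pts[[cl]] <- NA_real_
  pts$analyzable <- FALSE
  pts[plq, c("fibrous", "fibrofatty", "necrotic", "calcified")] <-
    comp[, c("fibrous", "fibrofatty", "necrotic", "calcified")]
  pts$analyzable[plq] <- comp$analyzable

  prev <- prevalence_table(pts)
  chi <- chi_square(prev)
  thick <- anova_duncan(data.frame(value = pts$thickness_mm,
                                   group = pts$quartile),
                        alpha = config$stats$alpha)
  gee <- if (length(unique(pts$vessel)) >= 2 && var(as.numeric(pts$plaque)) > 0) {
    fit_clustered_binary(pts)
  } else NULL
  compo <- if (sum(pts$analyzable, na.rm = TRUE) > 8 &&
               length(unique(pts$quartile[pts$analyzable])) >= 2) {
    composition_anova(pts, alpha = config$stats$alpha)
  } else NULL

  thick_tab <- dplyr::summarise(dplyr::group_by(pts, .data$quartile),
    n = dplyr::n(), mean = mean(.data$thickness_mm), sd = sd(.data$thickness_mm),
    min = min(.data$thickness_mm), max = max(.data$thickness_mm),
    .groups = "drop")

  report <- structure(list(
    ess_summary = dplyr::bind_rows(summaries),
    pooled_ess = summarize_quartiles(dplyr::bind_rows(ess_all)),
    measurements = pts,
    prevalence = prev, chi_square = chi,
    thickness_table = thick_tab, thickness_anova = thick,
    gee = gee, composition = compo,
    config = config,
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("coroshear")))),
    class = "study_report")

  if (write_artifacts) {
    utils::write.csv(as.data.frame(pts), file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(prev), file.path(out_dir, "prevalence.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(thick_tab), file.path(out_dir, "thickness.csv"),
                     row.names = FALSE)
    write_study_config(config, file.path(out_dir, "config.yaml"))
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
  }
  report
}

config_hash <- function(config) {
  config$out_dir <- NULL
  s <- paste(deparse(config), collapse = "")
  # small stable FNV-1a-style hash; avoids a digest dependency.  Kept below
  # 2^31 so the double arithmetic stays exact and bitwXor stays integral.
  h <- 21661362
  for (ch in utf8ToInt(s)) h <- (bitwXor(h, ch) * 16777619) %% 2^31
  sprintf("%08x", h)
}

format_report <- function(x) {
  stopifnot(inherits(x, "study_report"))
  out <- c("Synthetic ESS / plaque association study",
           sprintf("seed %d, config %s, coroshear %s", x$provenance$seed,
                   x$provenance$config_hash, x$provenance$package_version), "",
           "Pooled ESS by quartile (Pa):")
  pe <- x$pooled_ess
  out <- c(out, sprintf("  Q%d: %.3f +/- %.3f (range %.3f-%.3f)",
                        pe$quartile, pe$mean, pe$sd, pe$min, pe$max), "")
  out <- c(out, "Wall thickness by quartile (mm):")
  tt <- x$thickness_table
  out <- c(out, sprintf("  Q%d: %.2f +/- %.2f (range %.2f-%.2f), n=%d",
                        tt$quartile, tt$mean, tt$sd, tt$min, tt$max, tt$n), "")
  pv <- x$prevalence
  out <- c(out, "Plaque prevalence:",
           sprintf("  Q%d: %d/%d (%.1f%%)", pv$quartile, pv$n_plaque, pv$n,
                   pv$pct_plaque),
           sprintf("  overall %.1f%%, chi-square p = %.3g",
                   attr(pv, "overall_pct"), x$chi_square$p.value), "")
  out <- c(out, sprintf("Thickness ANOVA: F = %.2f, p = %.3g (naive, independence)",
                        x$thickness_anova$anova$statistic,
                        x$thickness_anova$anova$p.value))
  if (!is.null(x$gee))
    out <- c(out, sprintf("GEE (cluster-adjusted): alpha-hat = %.3f, Wald p (Q4 vs Q1) = %.3g",
                          x$gee$alpha, x$gee$p.value[["q4"]]))
  if (!is.null(x$composition)) {
    co <- x$composition
    out <- c(out, "", "Composition ANOVA p-values:",
             sprintf("  %-10s p = %.3g", co$tissue, co$p.value))
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
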