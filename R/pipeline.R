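#' Pipeline configuration
#'
#' Bundles the per-stage options of the scan-to-mesh pipeline with their
#' defaults.
#'
#' @param crop a [crop_region()] or `NULL` (no crop).
#' @param palette fiducial [default_palette()].
#' @param manual_points path to a `label,x,y,z` CSV replacing automatic
#'   fiducial detection, or `NULL`.
#' @param fourier_order,n_centers surface-fit orders.
#' @param mesh a [mesh_config()].
#' @param n_shells shells for the tetrahedral extrusion (`NULL` = auto).
#' @param recon a [recon_config()].
#' @param seed global RNG seed.
#' @export
pipeline_config <- function(crop = NULL, palette = default_palette(),
                            manual_points = NULL, fourier_order = 12L,
                            n_centers = 7L, mesh = mesh_config(),
                            n_shells = NULL, recon = recon_config(),
                            seed = 1L) {
  structure(list(crop = crop, palette = palette,
                 manual_points = manual_points,
                 fourier_order = fourier_order, n_centers = n_centers,
                 mesh = mesh, n_shells = n_shells, recon = recon,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the scan-to-FEM pipeline
#'
#' Chains the stages: load/crop, electrode identification, leveling,
#' surface fit, electrode-encoded remesh, and tetrahedral mesh build,
#' recording per-stage wall time and mesh statistics. Any stage error
#' aborts with the stage name.
#'
#' @param input path to a PLY scan or a [colored_surface()].
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, artifacts (cropped PLY, electrode CSV,
#'   fit JSON, MSH mesh, report JSON) are written there.
#' @param build_mesh run the remesh/FEM stages (the slow part).
#' @param verbose print stage progress.
#' @return list with `surface`, `electrodes`, `transform`, `fit`, `belt`,
#'   `mesh`, and `report` (stage timings and counts).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         build_mesh = TRUE, verbose = TRUE) {
  report <- list(stages = list(), seed = config$seed)
  res <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    report$stages[[name]] <<- list(seconds = dt)
    if (verbose) message(sprintf("[%s] %.2f s", name, dt))
    out
  }
  set.seed(config$seed)

  surface <- stage("load_crop", {
    s <- if (inherits(input, "colored_surface")) input else read_scan(input)
    if (!is.null(config$crop)) s <- crop(s, config$crop) else s
  })
  report$stages$load_crop$n_vertices <- nrow(surface$vertices)

  ident <- stage("electrodes", {
    if (!is.null(config$manual_points)) {
      mp <- read_manual_points(config$manual_points)
      plane <- fit_plane(rbind(do.call(rbind, mp$anchors), mp$whites))
      list(electrodes = label_electrodes(mp$anchors, mp$whites, plane$normal,
                                         config$palette),
           plane = plane)
    } else {
      identify_electrodes(surface, config$palette)
    }
  })
  report$stages$electrodes$n_found <- length(ident$electrodes$labels)
  report$stages$electrodes$occluded <- ident$electrodes$occluded

  lev <- stage("leveling", apply_leveling(surface, ident$electrodes))
  fit <- stage("surface_fit",
               fit_surface(lev$surface, fourier_order = config$fourier_order,
                           n_centers = config$n_centers))
  report$stages$surface_fit$rms_mm <- fit$rms
  report$stages$surface_fit$n_params <- fit$n_params

  res <- list(surface = lev$surface, electrodes = lev$electrodes,
              transform = lev$transform, fit = fit, belt = NULL, mesh = NULL)

  if (build_mesh) {
    res$belt <- stage("remesh",
                      remesh_surface(fit, lev$electrodes, config$mesh))
    report$stages$remesh$n_faces <- nrow(res$belt$surface$faces)
    res$mesh <- stage("fem_mesh",
                      build_fem_mesh(res$belt, n_shells = config$n_shells))
    q <- mesh_quality(res$mesh)
    report$stages$fem_mesh$n_nodes <- q$n_nodes
    report$stages$fem_mesh$n_elements <- q$n_elements
    report$stages$fem_mesh$z_extent_mm <- q$z_extent_mm
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan(res$surface, file.path(out_dir, "leveled.ply"))
    write_electrodes(res$electrodes, file.path(out_dir, "electrodes.csv"))
    write_surface_fit(res$fit, file.path(out_dir, "surface_fit.json"))
    write_transform(res$transform, file.path(out_dir, "transform.json"))
    if (!is.null(res$mesh)) write_msh(res$mesh, file.path(out_dir, "mesh.msh"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res$report <- report
  res
}
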