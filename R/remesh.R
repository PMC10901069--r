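#' Meshing configuration
#'
#' Target edge lengths follow the belt-EIT meshing defaults: 0.5 mm near
#' the electrodes and 5 mm in the background of the domain, with
#' electrodes modeled as surface discs of 5 mm radius (1 cm electrodes).
#' Tests and examples typically scale these up for speed.
#'
#' @param h_electrode target edge length near electrodes, mm.
#' @param h_background target edge length elsewhere, mm.
#' @param electrode_radius electrode disc radius, mm.
#' @param z_extent mesh height, mm (`NULL`: the fitted z-range).
#' @param quality_floor minimum accepted triangle quality (0-1).
#' @param max_iter force-equilibrium iteration cap.
#' @return object of class `mesh_config`.
#' @export
mesh_config <- function(h_electrode = 0.5, h_background = 5,
                        electrode_radius = 5, z_extent = NULL,
                        quality_floor = 0.2, max_iter = 500L) {
  if (!(h_electrode > 0 && h_electrode <= h_background))
    stop("need 0 < h_electrode <= h_background")
  if (!(electrode_radius > h_electrode))
    stop("electrode_radius must exceed h_electrode")
  structure(list(h_electrode = h_electrode, h_background = h_background,
                 electrode_radius = electrode_radius, z_extent = z_extent,
                 quality_floor = quality_floor, max_iter = as.integer(max_iter)),
            class = "mesh_config")
}

#' Sizing field: ramps from h_electrode inside the disc to h_background
#' beyond 3x the disc radius. `d` = 3D distance to the nearest electrode.
#' @noRd
sizing_field <- function(d, config) {
  r <- config$electrode_radius
  t <- pmin(pmax((d - r) / (2 * r), 0), 1)
  config$h_electrode + t * (config$h_background - config$h_electrode)
}

#' Remesh the fitted surface with encoded electrodes
#'
#' Force-equilibrium (Persson-Strang) remeshing on the fitted r(theta, z)
#' surface: nodes repel along a truss of Delaunay edges until edge lengths
#' match the sizing field, each node being projected back to the surface
#' every step. Electrode disc rims are resolved by fixed nodes placed on
#' the rim, and the facets inside each rim are labeled with the electrode
#' number.
#'
#' @param model a `surface_fit`.
#' @param electrodes an [electrode_set()]; centers are projected onto the
#'   fitted surface (they must lie within 3 mm of it).
#' @param config a [mesh_config()].
#' @param verbose print iteration progress.
#' @return list of class `belt_surface`: `surface` (uncolored
#'   [colored_surface()]), `labels` (electrode number -> face indices),
#'   `electrode_uv` (projected electrode centers as theta/z),
#'   `iterations`, `converged`.
#' @export
remesh_surface <- function(model, electrodes, config = mesh_config(),
                           verbose = FALSE) {
  zr <- model$z_range
  if (!is.null(config$z_extent)) {
    zm <- mean(zr)
    zr <- zm + c(-0.5, 0.5) * config$z_extent
    zr[1L] <- max(zr[1L], model$z_range[1L])
    zr[2L] <- min(zr[2L], model$z_range[2L])
  }
  re <- config$electrode_radius
  ecen <- NULL; euv <- NULL
  if (!is.null(electrodes) && length(electrodes$labels) > 0L) {
    th_e <- atan2(electrodes$positions[, 2L], electrodes$positions[, 1L])
    z_e <- electrodes$positions[, 3L]
    off <- abs(signed_distance(model, electrodes$positions))
    if (any(off > 3))
      warning("electrode center(s) ", paste(which(off > 3), collapse = ","),
              " more than 3 mm from the fitted surface; projecting")
    euv <- cbind(theta = th_e, z = z_e)
    ecen <- evaluate_fit(model, th_e, z_e)
    dmat <- as.matrix(stats::dist(ecen))
    diag(dmat) <- Inf
    if (min(dmat) < 2 * re)
      stop(ply_err("electrode_overlap",
                   sprintf("electrode discs overlap (min center distance %.1f mm < %.1f)",
                           min(dmat), 2 * re)))
  }

  # --- fixed nodes: electrode centers and rim rings
  fix_uv <- matrix(numeric(), 0L, 2L)
  rim_of <- integer()   # electrode row index per fixed node (0 = none)
  if (!is.null(ecen)) {
    for (i in seq_len(nrow(euv))) {
      n_rim <- max(12L, ceiling(2 * pi * re / config$h_electrode))
      phi <- seq(0, 2 * pi, length.out = n_rim + 1L)[-(n_rim + 1L)]
      a_loc <- local_theta_scale(model, euv[i, 1L], euv[i, 2L])
      duv <- cbind(re * cos(phi) / a_loc, re * sin(phi))
      uv <- cbind(euv[i, 1L] + duv[, 1L], euv[i, 2L] + duv[, 2L])
      # one correction step: scale the offset so 3D distance equals re
      for (rep in 1:2) {
        p3 <- evaluate_fit(model, uv[, 1L], uv[, 2L])
        d3 <- sqrt(rowSums(sweep(p3, 2L, ecen[i, ])^2))
        fac <- re / d3
        uv <- cbind(euv[i, 1L] + (uv[, 1L] - euv[i, 1L]) * fac,
                    euv[i, 2L] + (uv[, 2L] - euv[i, 2L]) * fac)
      }
      fix_uv <- rbind(fix_uv, euv[i, , drop = FALSE], uv)
      rim_of <- c(rim_of, i, rep(i, n_rim))
    }
  }

  # --- initial points: density-graded rejection sampling on the strip
  abar <- mean(fit_radius(model, seq(0, 2 * pi, length.out = 64L),
                          rep(mean(zr), 64L)))
  h0 <- config$h_electrode
  nu <- max(8L, ceiling(2 * pi * abar / h0))
  nv <- max(4L, ceiling(diff(zr) / (h0 * sqrt(3) / 2)))
  gu <- seq(0, 2 * pi, length.out = nu + 1L)[-(nu + 1L)]
  gv <- seq(zr[1L], zr[2L], length.out = nv)
  g <- expand.grid(theta = gu, z = gv)
  g$theta <- g$theta + rep_len(c(0, pi / nu), nv)[as.integer(factor(g$z))] # stagger
  # slight jitter breaks the cocircular structure of the seed grid
  g$theta <- g$theta + stats::runif(nrow(g), -0.05, 0.05) * 2 * pi / nu
  inner <- g$z > gv[1L] & g$z < gv[nv]
  g$z[inner] <- g$z[inner] + stats::runif(sum(inner), -0.05, 0.05) * diff(zr) / nv
  p3 <- evaluate_fit(model, g$theta, g$z)
  dmin <- electrode_distance(p3, ecen)
  hloc <- sizing_field(dmin, config)
  keep <- stats::runif(nrow(g)) < (h0 / hloc)^2
  # keep boundary rows always
  keep[g$z %in% gv[c(1L, nv)] & stats::runif(nrow(g)) < (h0 / hloc)^1] <- TRUE
  pts <- as.matrix(g[keep, , drop = FALSE])
  # drop random points too close to fixed ones
  if (nrow(fix_uv) > 0L) {
    p3k <- evaluate_fit(model, pts[, 1L], pts[, 2L])
    f3 <- evaluate_fit(model, fix_uv[, 1L], fix_uv[, 2L])
    nnf <- FNN::get.knnx(f3, p3k, k = 1L)
    pts <- pts[nnf$nn.dist[, 1L] > 0.7 * config$h_electrode, , drop = FALSE]
    pts <- rbind(fix_uv, pts)
  }
  n_fix <- nrow(fix_uv)

  # --- force equilibrium loop
  Fscale <- 1.2; deltat <- 0.2
  ttol <- 0.1; dptol <- 1e-3
  pold <- NULL
  tri <- NULL
  iterations <- 0L; converged <- FALSE
  p3d <- evaluate_fit(model, pts[, 1L], pts[, 2L])
  for (it in seq_len(config$max_iter)) {
    iterations <- it
    if (is.null(pold) ||
        max(sqrt(rowSums((p3d - pold)^2))) > ttol * config$h_electrode) {
      tri <- periodic_delaunay(pts, abar, diff(zr))
      pold <- p3d
      incid <- Matrix::sparseMatrix(
        i = c(tri$edges[, 1L], tri$edges[, 2L]),
        j = rep(seq_len(nrow(tri$edges)), 2L),
        x = rep(c(1, -1), each = nrow(tri$edges)),
        dims = c(nrow(pts), nrow(tri$edges)))
    }
    bars <- tri$edges
    b1 <- p3d[bars[, 1L], , drop = FALSE]
    b2 <- p3d[bars[, 2L], , drop = FALSE]
    bvec <- b1 - b2
    L <- sqrt(rowSums(bvec^2))
    mid <- (b1 + b2) / 2
    hbars <- sizing_field(electrode_distance(mid, ecen), config)
    L0 <- hbars * Fscale * sqrt(sum(L^2) / sum(hbars^2))
    # density control: overly crowded points (strongly compressed trusses)
    # prevent equilibrium; remove them and retriangulate
    if (it %% 30L == 0L && it < 0.8 * config$max_iter) {
      crowded <- bars[L0 > 2 * L, , drop = FALSE]
      drop <- setdiff(unique(as.vector(crowded)), seq_len(n_fix))
      if (length(drop) > 0L) {
        keep <- setdiff(seq_len(nrow(pts)), drop)
        pts <- pts[keep, , drop = FALSE]
        p3d <- p3d[keep, , drop = FALSE]
        pold <- NULL
        next
      }
    }
    Fmag <- pmax(L0 - L, 0) / pmax(L, 1e-12)
    Fv <- bvec * Fmag
    Ftot <- as.matrix(incid %*% Fv)
    if (n_fix > 0L) Ftot[seq_len(n_fix), ] <- 0
    # cooling: on a closed periodic surface the Fscale pre-compression has
    # no open boundary to drain into, so a few nodes oscillate at fixed
    # step size; decaying steps let them settle
    dt_it <- if (it <= config$max_iter / 2) deltat
             else deltat * max(0.1, 1 - (it - config$max_iter / 2) /
                                      (0.55 * config$max_iter))
    p3new <- p3d + dt_it * Ftot
    # reparametrize (this projects back to the surface) and clamp z
    th_new <- atan2(p3new[, 2L], p3new[, 1L])
    z_new <- pmin(pmax(p3new[, 3L], zr[1L]), zr[2L])
    pts[, 1L] <- th_new; pts[, 2L] <- z_new
    if (n_fix > 0L) pts[seq_len(n_fix), ] <- fix_uv
    p3prev <- p3d
    p3d <- evaluate_fit(model, pts[, 1L], pts[, 2L])
    # convergence is judged on interior nodes; nodes sliding along the
    # z-boundary are projected and excluded, as in the original scheme
    interior <- p3new[, 3L] > zr[1L] + 1e-9 & p3new[, 3L] < zr[2L] - 1e-9
    mv <- sqrt(rowSums((p3d - p3prev)^2))
    move <- if (any(interior)) max(mv[interior]) else max(mv)
    if (verbose && it %% 25L == 0L)
      message(sprintf("  remesh iter %d: max move %.4g mm", it, move))
    if (move < dptol * config$h_background) { converged <- TRUE; break }
  }
  if (!converged) {
    lastmove <- move
    if (lastmove > 0.05 * config$h_background)
      stop(ply_err("remesh_no_converge",
                   sprintf("remeshing did not converge in %d iterations (last move %.3g mm)",
                           iterations, lastmove)))
    message("remeshing stopped at the iteration cap near equilibrium (move ",
            signif(lastmove, 3), " mm)")
  }

  # protection ring: free nodes that settled onto an electrode rim would
  # break the rim edge chain; drop them before the final triangulation
  if (!is.null(ecen) && nrow(pts) > n_fix) {
    dcen <- FNN::get.knnx(ecen, p3d, k = 1L)$nn.dist[, 1L]
    near_rim <- abs(dcen - re) < 0.5 * config$h_electrode
    near_rim[seq_len(n_fix)] <- FALSE
    if (any(near_rim)) {
      pts <- pts[!near_rim, , drop = FALSE]
      p3d <- p3d[!near_rim, , drop = FALSE]
    }
  }
  tri <- periodic_delaunay(pts, abar, diff(zr))
  faces <- tri$triangles
  surf <- colored_surface(p3d, orient_tube_faces(pts, faces), validate = FALSE)
  surf <- clean_surface(surf)

  labels <- list()
  if (!is.null(ecen)) {
    cent <- (surf$vertices[surf$faces[, 1L], , drop = FALSE] +
             surf$vertices[surf$faces[, 2L], , drop = FALSE] +
             surf$vertices[surf$faces[, 3L], , drop = FALSE]) / 3
    nnc <- FNN::get.knnx(ecen, cent, k = 1L)
    owner <- matrix(0L, nrow(surf$faces), 1L)
    inside <- nnc$nn.dist[, 1L] < re
    for (i in seq_len(nrow(ecen))) {
      fidx <- which(inside & nnc$nn.index[, 1L] == i)
      if (length(fidx) == 0L)
        stop(ply_err("label_transfer", paste0("no facets inside electrode ",
                                              electrodes$labels[i], " disc")))
      labels[[as.character(electrodes$labels[i])]] <- fidx
    }
  }
  structure(list(surface = surf, labels = labels, electrode_uv = euv,
                 electrode_centers = ecen, model = model, z_range = zr,
                 config = config, iterations = iterations,
                 converged = converged),
            class = "belt_surface")
}

electrode_distance <- function(p3, ecen) {
  if (is.null(ecen)) return(rep(Inf, nrow(p3)))
  FNN::get.knnx(ecen, p3, k = 1L)$nn.dist[, 1L]
}

#' |dp/dtheta| of the fitted surface, by central difference
#' @noRd
local_theta_scale <- function(model, theta, z) {
  eps <- 1e-4
  p1 <- evaluate_fit(model, theta + eps, z)
  p0 <- evaluate_fit(model, theta - eps, z)
  sqrt(sum((p1 - p0)^2)) / (2 * eps)
}

#' Delaunay triangulation of points on the periodic (theta, z) strip
#'
#' Ghost copies within an angular margin of the seam are added, the plane
#' strip (u = theta * abar, v = z) triangulated, triangles re-indexed to
#' original points, and duplicates removed.
#' @noRd
periodic_delaunay <- function(pts, abar, zspan) {
  th <- pts[, 1L] %% (2 * pi)
  u <- th * abar; v <- pts[, 2L]
  Pu <- 2 * pi * abar
  margin <- 0.12 * Pu
  left <- which(u < margin); right <- which(u > Pu - margin)
  ug <- c(u, u[right] - Pu, u[left] + Pu)
  vg <- c(v, v[right], v[left])
  idmap <- c(seq_len(nrow(pts)), right, left)
  dup <- duplicated(cbind(ug, vg))
  if (any(dup)) { ug <- ug[!dup]; vg <- vg[!dup]; idmap <- idmap[!dup] }
  tm <- suppressWarnings(interp::tri.mesh(ug, vg, duplicate = "error"))
  tr <- interp::triangles(tm)[, 1:3, drop = FALSE]
  # map interp's node ids back (duplicate removal keeps order for distinct pts)
  ti <- matrix(idmap[tr], ncol = 3L)
  cent_u <- (ug[tr[, 1L]] + ug[tr[, 2L]] + ug[tr[, 3L]]) / 3
  keep <- cent_u >= 0 & cent_u < Pu
  ti <- ti[keep, , drop = FALSE]
  # canonical form to drop duplicated wrapped triangles
  key <- apply(ti, 1L, function(r) paste(sort(r), collapse = "-"))
  ti <- ti[!duplicated(key), , drop = FALSE]
  e <- unique(rbind(ti[, c(1L, 2L)], ti[, c(2L, 3L)], ti[, c(3L, 1L)]))
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  list(triangles = ti, edges = e)
}

#' Orient tube faces counterclockwise in (theta, z), i.e. outward in 3D
#' @noRd
orient_tube_faces <- function(pts, faces) {
  u <- pts[, 1L]; v <- pts[, 2L]
  # unwrap triangle angles around their first vertex
  u1 <- u[faces[, 1L]]
  du2 <- wrap_pi(u[faces[, 2L]] - u1)
  du3 <- wrap_pi(u[faces[, 3L]] - u1)
  a <- du2 * (v[faces[, 3L]] - v[faces[, 1L]]) -
       du3 * (v[faces[, 2L]] - v[faces[, 1L]])
  flip <- a < 0
  faces[flip, c(2L, 3L)] <- faces[flip, c(3L, 2L)]
  faces
}

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi
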