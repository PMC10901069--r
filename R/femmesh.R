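#' Close a remeshed belt surface with flat caps
#'
#' The remeshed tube is closed by planar triangulated caps at both ends of
#' the z-range. Cap interiors are filled with a staggered grid at the
#' background edge length and triangulated against the rim nodes, which
#' are shared with the tube so the result is watertight.
#'
#' @param belt a `belt_surface` from [remesh_surface()].
#' @return list with `surface` (closed [colored_surface()], side faces
#'   first so the electrode face indices of `belt$labels` remain valid)
#'   and `labels`.
#' @export
close_belt_surface <- function(belt) {
  s <- belt$surface
  h <- belt$config$h_background
  eb <- boundary_edges(s$faces)
  if (nrow(eb) == 0L) stop("tube surface has no open rims to cap")
  zr <- belt$z_range
  verts <- s$vertices
  faces <- s$faces
  for (side in 1:2) {
    zcap <- zr[side]
    rim_nodes <- unique(as.vector(eb))
    rim_nodes <- rim_nodes[abs(verts[rim_nodes, 3L] - zcap) < 0.25 * h]
    if (length(rim_nodes) < 3L) stop("cap rim not found at z = ", zcap)
    rim_xy <- verts[rim_nodes, 1:2, drop = FALSE]
    o <- order(atan2(rim_xy[, 2L], rim_xy[, 1L]))
    rim_nodes <- rim_nodes[o]; rim_xy <- rim_xy[o, , drop = FALSE]
    # staggered interior grid
    bb <- apply(rim_xy, 2L, range)
    gx <- seq(bb[1L, 1L], bb[2L, 1L], by = h)
    gy <- seq(bb[1L, 2L], bb[2L, 2L], by = h * sqrt(3) / 2)
    gg <- expand.grid(x = gx, y = gy)
    stag <- rep_len(c(0, h / 2), length(gy))[as.integer(factor(gg$y))]
    gg$x <- gg$x + stag
    # break exact collinearity, which degrades the sweep-hull triangulation
    gg$x <- gg$x + stats::runif(nrow(gg), -0.05, 0.05) * h
    gg$y <- gg$y + stats::runif(nrow(gg), -0.05, 0.05) * h
    inside <- sp::point.in.polygon(gg$x, gg$y, rim_xy[, 1L], rim_xy[, 2L]) == 1L
    gg <- gg[inside, , drop = FALSE]
    if (nrow(gg) > 0L) {
      dr <- FNN::get.knnx(rim_xy, as.matrix(gg), k = 1L)$nn.dist[, 1L]
      gg <- gg[dr > 0.6 * h, , drop = FALSE]
    }
    np <- nrow(gg)
    ids <- c(rim_nodes, if (np > 0L) nrow(verts) + seq_len(np) else integer())
    px <- c(rim_xy[, 1L], gg$x); py <- c(rim_xy[, 2L], gg$y)
    tm <- suppressWarnings(interp::tri.mesh(px, py, duplicate = "error"))
    tr <- interp::triangles(tm)[, 1:3, drop = FALSE]
    if (anyNA(tr)) stop("cap triangulation failed")
    cx <- (px[tr[, 1L]] + px[tr[, 2L]] + px[tr[, 3L]]) / 3
    cy <- (py[tr[, 1L]] + py[tr[, 2L]] + py[tr[, 3L]]) / 3
    keep <- sp::point.in.polygon(cx, cy, rim_xy[, 1L], rim_xy[, 2L]) == 1L
    tr <- tr[keep, , drop = FALSE]
    # orient: bottom cap normal -z, top cap +z
    a2 <- (px[tr[, 2L]] - px[tr[, 1L]]) * (py[tr[, 3L]] - py[tr[, 1L]]) -
          (px[tr[, 3L]] - px[tr[, 1L]]) * (py[tr[, 2L]] - py[tr[, 1L]])
    want_ccw <- side == 2L
    flip <- if (want_ccw) a2 < 0 else a2 > 0
    tr[flip, c(2L, 3L)] <- tr[flip, c(3L, 2L)]
    if (np > 0L)
      verts <- rbind(verts, cbind(gg$x, gg$y, zcap))
    faces <- rbind(faces, matrix(ids[tr], ncol = 3L))
  }
  out <- colored_surface(verts, faces, validate = FALSE)
  be <- boundary_edges(out$faces)
  if (nrow(be) > 0L)
    stop("capped surface is not watertight (", nrow(be), " open edges)")
  list(surface = out, labels = belt$labels)
}

#' Edges incident to exactly one face
#' @noRd
boundary_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  open_keys <- names(tab)[tab == 1L]
  e[match(open_keys, key), , drop = FALSE]
}

#' Build the labeled tetrahedral FEM mesh
#'
#' Tetrahedralizes the volume enclosed by the electrode-encoded surface.
#' The default backend extrudes the closed boundary surface through
#' concentric shells toward the domain centroid (each boundary triangle
#' and its scaled copy forming a prism that is split into three
#' tetrahedra by a globally consistent min-index diagonal rule) and fans
#' the small core onto a center node; this is exact for the star-shaped
#' belt-band domains produced by the surface fit, and the outer boundary
#' of the result reproduces the input surface triangle-for-triangle, so
#' electrode facet labels transfer by identity.
#'
#' @param belt a `belt_surface` from [remesh_surface()] (or the output of
#'   [close_belt_surface()]).
#' @param config the [mesh_config()] (defaults to the one stored in
#'   `belt`).
#' @param backend `"shell"` (built-in) or `"gmsh"` (requires a `gmsh`
#'   executable on the PATH; raises a `backend-missing` error if absent).
#' @param n_shells number of extrusion shells (`NULL`: chosen from
#'   h_background).
#' @return object of class `fem_mesh`: `nodes` (mm), `tets` (1-based,
#'   positively oriented), `electrode_facets` (label -> node-triple
#'   matrix), `surface_tris`, `n_boundary_nodes`.
#' @export
build_fem_mesh <- function(belt, config = NULL, backend = c("shell", "gmsh"),
                           n_shells = NULL) {
  backend <- match.arg(backend)
  if (backend == "gmsh") {
    if (Sys.which("gmsh") == "")
      stop(ply_err("backend_missing",
                   "mesh backend 'gmsh' requires the gmsh executable on PATH"))
    stop(ply_err("backend_missing",
                 "gmsh backend not wired in this build; use backend = 'shell'"))
  }
  if (inherits(belt, "belt_surface")) {
    if (is.null(config)) config <- belt$config
    closed <- close_belt_surface(belt)
  } else {
    closed <- belt
    if (is.null(config)) stop("config required when passing a closed surface")
  }
  s <- closed$surface
  h <- config$h_background
  nb <- nrow(s$vertices)
  cen <- c(colMeans(s$vertices[, 1:2, drop = FALSE]), mean(range(s$vertices[, 3L])))
  rel <- sweep(s$vertices, 2L, cen)
  rbar <- mean(sqrt(rowSums(rel^2)))
  lam_core <- max(0.15, min(0.45, 2.5 * h / rbar))
  if (is.null(n_shells))
    n_shells <- max(2L, min(10L, round((1 - lam_core) * rbar / (1.6 * h))))
  L <- as.integer(n_shells)
  lam <- 1 - (1 - lam_core) * seq_len(L) / L

  nodes <- s$vertices
  for (l in seq_len(L))
    nodes <- rbind(nodes, sweep(rel * lam[l], 2L, -cen))
  cid <- nrow(nodes) + 1L
  nodes <- rbind(nodes, cen)

  nt <- nrow(s$faces)
  tets <- matrix(0L, nt * (3L * L + 1L), 4L)
  row <- 0L
  for (l in seq_len(L)) {
    bot <- s$faces + (l - 1L) * nb
    top <- s$faces + l * nb
    tets[row + seq_len(3L * nt), ] <- split_prisms(bot, top)
    row <- row + 3L * nt
  }
  inner <- s$faces + L * nb
  tets[row + seq_len(nt), ] <- cbind(inner, cid)

  # enforce positive orientation
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  v <- abs(v)
  if (any(v < 1e-12))
    warning(sum(v < 1e-12), " near-degenerate tetrahedra in shell mesh")

  facets <- lapply(closed$labels, function(fidx)
    s$faces[fidx, , drop = FALSE])
  structure(list(nodes = nodes, tets = tets,
                 electrode_facets = facets,
                 surface_tris = s$faces, n_boundary_nodes = nb,
                 n_shells = L, center = cen, config = config),
            class = "fem_mesh")
}

#' Split prisms (matched bottom/top triangle layers) into tetrahedra
#'
#' Quadrilateral side faces are cut by the diagonal leaving their
#' minimum-index corner; because shared faces see the same rule from both
#' sides the decomposition is globally conforming, and since bottom ids
#' are always lower than top ids the cyclic (untetrahedralizable)
#' configuration cannot occur.
#' @noRd
split_prisms <- function(bot, top) {
  n <- nrow(bot)
  # rotate so bottom vertex 1 is the smallest bottom index
  shift <- max.col(-bot, ties.method = "first")
  rot <- function(m, s3) {
    out <- m
    for (k in 2:3) {
      idx <- s3 == k
      out[idx, ] <- m[idx, c(k:3, seq_len(k - 1L)), drop = FALSE]
    }
    out
  }
  b <- rot(bot, shift); t2 <- rot(top, shift)
  res <- matrix(0L, 3L * n, 4L)
  c23 <- b[, 2L] < b[, 3L]  # diagonal b2-t3 if TRUE else b3-t2
  i <- which(c23)
  res[3L * (i - 1L) + 1L, ] <- cbind(b[i, 1L], b[i, 2L], b[i, 3L], t2[i, 3L])
  res[3L * (i - 1L) + 2L, ] <- cbind(b[i, 1L], b[i, 2L], t2[i, 3L], t2[i, 2L])
  res[3L * (i - 1L) + 3L, ] <- cbind(b[i, 1L], t2[i, 2L], t2[i, 3L], t2[i, 1L])
  j <- which(!c23)
  res[3L * (j - 1L) + 1L, ] <- cbind(b[j, 1L], b[j, 2L], b[j, 3L], t2[j, 2L])
  res[3L * (j - 1L) + 2L, ] <- cbind(b[j, 1L], t2[j, 2L], b[j, 3L], t2[j, 3L])
  res[3L * (j - 1L) + 3L, ] <- cbind(b[j, 1L], t2[j, 2L], t2[j, 3L], t2[j, 1L])
  res
}

#' Signed tetrahedron volumes (mm^3)
#' @noRd
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  u <- nodes[tets[, 2L], , drop = FALSE] - a
  v <- nodes[tets[, 3L], , drop = FALSE] - a
  w <- nodes[tets[, 4L], , drop = FALSE] - a
  (u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
   u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
   u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])) / 6
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat("<fem_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets, ",
      length(x$electrode_facets), " labeled electrodes\n", sep = "")
  invisible(x)
}

#' Boundary triangles of a tetrahedral mesh (faces used exactly once)
#' @noRd
tet_boundary_faces <- function(tets) {
  f <- rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)],
             tets[, c(1L, 2L, 4L)], tets[, c(1L, 3L, 2L)])
  key <- apply(f, 1L, function(r) paste(sort(r), collapse = "-"))
  f[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Mesh quality report
#'
#' Radius-ratio quality (3 r_in / r_circ, 1 for the regular tetrahedron),
#' node/element counts and z-extent.
#'
#' @param mesh a `fem_mesh`.
#' @return list with `n_nodes`, `n_elements`, `min_quality`,
#'   `mean_quality`, `z_extent_mm`, `total_volume_mm3`.
#' @export
mesh_quality <- function(mesh) {
  nodes <- mesh$nodes; tets <- mesh$tets
  v <- abs(tet_volumes(nodes, tets))
  # face areas of each tet
  farea <- function(i, j, k) {
    cr <- face_cross(nodes, cbind(tets[, i], tets[, j], tets[, k]))
    0.5 * sqrt(rowSums(cr^2))
  }
  Asum <- farea(2L, 3L, 4L) + farea(1L, 3L, 4L) + farea(1L, 2L, 4L) +
    farea(1L, 2L, 3L)
  r_in <- 3 * v / Asum
  # circumradius via the standard determinant-free formula
  a <- nodes[tets[, 1L], , drop = FALSE]
  ba <- nodes[tets[, 2L], , drop = FALSE] - a
  ca <- nodes[tets[, 3L], , drop = FALSE] - a
  da <- nodes[tets[, 4L], , drop = FALSE] - a
  l2b <- rowSums(ba^2); l2c <- rowSums(ca^2); l2d <- rowSums(da^2)
  cr_cd <- cbind(ca[, 2L] * da[, 3L] - ca[, 3L] * da[, 2L],
                 ca[, 3L] * da[, 1L] - ca[, 1L] * da[, 3L],
                 ca[, 1L] * da[, 2L] - ca[, 2L] * da[, 1L])
  cr_db <- cbind(da[, 2L] * ba[, 3L] - da[, 3L] * ba[, 2L],
                 da[, 3L] * ba[, 1L] - da[, 1L] * ba[, 3L],
                 da[, 1L] * ba[, 2L] - da[, 2L] * ba[, 1L])
  cr_bc <- cbind(ba[, 2L] * ca[, 3L] - ba[, 3L] * ca[, 2L],
                 ba[, 3L] * ca[, 1L] - ba[, 1L] * ca[, 3L],
                 ba[, 1L] * ca[, 2L] - ba[, 2L] * ca[, 1L])
  num <- l2b * cr_cd + l2c * cr_db + l2d * cr_bc
  r_circ <- sqrt(rowSums(num^2)) / (12 * v)
  q <- 3 * r_in / r_circ
  list(n_nodes = nrow(nodes), n_elements = nrow(tets),
       min_quality = min(q), mean_quality = mean(q),
       z_extent_mm = diff(range(nodes[, 3L])),
       total_volume_mm3 = sum(v))
}

#' Export a FEM mesh as Gmsh MSH 2.2 ASCII
#'
#' Electrode facets are written as surface elements with physical tag 100
#' + electrode number; tetrahedra carry physical tag 1.
#'
#' @param mesh a `fem_mesh`.
#' @param path output `.msh` path.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)), mesh$nodes[, 1L],
                   mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  writeLines("$EndNodes", con)
  n_fac <- sum(vapply(mesh$electrode_facets, nrow, 1L))
  writeLines(c("$Elements", as.character(n_fac + nrow(mesh$tets))), con)
  eid <- 0L
  for (lab in names(mesh$electrode_facets)) {
    f <- mesh$electrode_facets[[lab]]
    tag <- 100L + as.integer(lab)
    writeLines(paste(eid + seq_len(nrow(f)), 2L, 2L, tag, tag,
                     f[, 1L], f[, 2L], f[, 3L]), con)
    eid <- eid + nrow(f)
  }
  writeLines(paste(eid + seq_len(nrow(mesh$tets)), 4L, 2L, 1L, 1L,
                   mesh$tets[, 1L], mesh$tets[, 2L], mesh$tets[, 3L],
                   mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Export a FEM mesh (with an optional element field) as legacy VTK
#'
#' @param mesh a `fem_mesh`.
#' @param path output `.vtk` path.
#' @param cell_data optional numeric per-element field (e.g. a
#'   conductivity-change image), written as CELL_DATA.
#' @param field_name name of the cell field.
#' @export
write_vtk <- function(mesh, path, cell_data = NULL, field_name = "delta_sigma") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "scan2fem mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  writeLines(paste(mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  nt <- nrow(mesh$tets)
  writeLines(paste("CELLS", nt, 5L * nt), con)
  writeLines(paste(4L, mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
                   mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L), con)
  writeLines(paste("CELL_TYPES", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
  if (!is.null(cell_data)) {
    writeLines(c(paste("CELL_DATA", nt),
                 paste("SCALARS", field_name, "double", 1L),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(cell_data), con)
  }
  invisible(path)
}

#' Element centroids (mm)
#' @param mesh a `fem_mesh`.
#' @return n_elements x 3 matrix.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}
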