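#' Colored surface triangulation
#'
#' The in-memory form of a 3D scan: a triangulated surface with an optional
#' RGB color at every vertex. Coordinates are in millimetres; colors are
#' integers in \[0, 255\].
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices of each
#'   triangle.
#' @param colors optional integer matrix, n x 3, per-vertex RGB in
#'   \[0, 255\]. `NULL` marks an uncolored surface (e.g. a resampled fit).
#' @param validate check invariants (face indices in range, color length).
#' @return an object of class `colored_surface` with elements `vertices`,
#'   `faces`, `colors`.
#' @export
colored_surface <- function(vertices, faces, colors = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    if (ncol(colors) != 3L) stop("colors must be an n x 3 matrix")
  }
  s <- structure(list(vertices = vertices, faces = faces, colors = colors),
                 class = "colored_surface")
  if (validate) validate_surface(s)
  s
}

validate_surface <- function(s) {
  n <- nrow(s$vertices)
  if (nrow(s$faces) > 0L) {
    rng <- range(s$faces)
    if (rng[1L] < 1L || rng[2L] > n)
      stop("face index out of range: vertices ", n, ", index range ",
           rng[1L], "..", rng[2L])
  }
  if (!is.null(s$colors) && nrow(s$colors) != n)
    stop("colors length (", nrow(s$colors), ") != vertex count (", n, ")")
  invisible(s)
}

#' @export
print.colored_surface <- function(x, ...) {
  cat("<colored_surface> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces, ",
      if (is.null(x$colors)) "uncolored" else "RGB colored", "\n", sep = "")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x:[%.1f, %.1f] y:[%.1f, %.1f] z:[%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

n_vertices <- function(s) nrow(s$vertices)
n_faces <- function(s) nrow(s$faces)

#' Triangle areas and (unnormalized) face normals
#' @noRd
face_cross <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  u <- vertices[faces[, 2L], , drop = FALSE] - a
  v <- vertices[faces[, 3L], , drop = FALSE] - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Triangle areas of a surface (mm^2)
#' @param s a [colored_surface()].
#' @return numeric vector, one area per face.
#' @export
triangle_areas <- function(s) {
  cr <- face_cross(s$vertices, s$faces)
  0.5 * sqrt(rowSums(cr * cr))
}

#' Drop degenerate (zero-area) triangles and unreferenced vertices
#' @noRd
clean_surface <- function(s, area_tol = 1e-9) {
  f <- s$faces
  dup <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  keep_f <- !dup
  if (any(keep_f)) {
    ar <- triangle_areas(colored_surface(s$vertices, f[keep_f, , drop = FALSE],
                                         validate = FALSE))
    keep_f[keep_f] <- ar > area_tol
  }
  f <- f[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(s$vertices))
  remap[used] <- seq_along(used)
  colored_surface(s$vertices[used, , drop = FALSE],
                  matrix(remap[f], ncol = 3L),
                  if (is.null(s$colors)) NULL else s$colors[used, , drop = FALSE],
                  validate = FALSE)
}

#' Unique undirected edges of a triangulation
#' @noRd
surface_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Restrict a surface to its largest connected component
#' @noRd
largest_component <- function(s) {
  if (nrow(s$faces) == 0L) return(s)
  g <- igraph::graph_from_edgelist(surface_edges(s$faces), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(s$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  # pick the component holding most face-referenced vertices
  big <- which.max(tabulate(comp$membership, comp$no))
  keep_v <- comp$membership == big
  keep_f <- keep_v[s$faces[, 1L]] & keep_v[s$faces[, 2L]] & keep_v[s$faces[, 3L]]
  subset_surface(s, keep_f)
}

#' Keep a subset of faces, dropping unreferenced vertices and reindexing
#' @noRd
subset_surface <- function(s, keep_faces) {
  f <- s$faces[keep_faces, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(s$vertices))
  remap[used] <- seq_along(used)
  colored_surface(s$vertices[used, , drop = FALSE],
                  matrix(remap[f], ncol = 3L),
                  if (is.null(s$colors)) NULL else s$colors[used, , drop = FALSE],
                  validate = FALSE)
}

#' Nearest point on a triangulated surface
#'
#' Exact point-to-triangle distances, accelerated by a nearest-vertex
#' prefilter: only triangles incident to the `k` nearest vertices of each
#' query are examined, falling back to all triangles when that candidate
#' set cannot contain the minimizer.
#'
#' @param points q x 3 matrix of query points, mm.
#' @param surface a [colored_surface()].
#' @param k number of nearest vertices used to shortlist triangles.
#' @return list with `distance` (length q) and `closest` (q x 3 points).
#' @export
surface_distance <- function(points, surface, k = 8L) {
  points <- matrix(as.numeric(points), ncol = 3L)
  v <- surface$vertices
  f <- surface$faces
  if (nrow(f) == 0L) stop("empty surface")
  k <- min(k, nrow(v))
  nn <- FNN::get.knnx(v, points, k = k)
  # vertex -> incident faces
  vf <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  d <- numeric(nrow(points))
  cl <- matrix(0, nrow(points), 3L)
  for (i in seq_len(nrow(points))) {
    cand <- unique(unlist(vf[as.character(nn$nn.index[i, ])], use.names = FALSE))
    res <- point_tri_dist(points[i, ], v, f[cand, , drop = FALSE])
    # the true nearest triangle must be within reach of the k-th vertex bound
    if (res$distance > nn$nn.dist[i, k] && k < nrow(v)) {
      res <- point_tri_dist(points[i, ], v, f)
    }
    d[i] <- res$distance
    cl[i, ] <- res$closest
  }
  list(distance = d, closest = cl)
}

#' Exact distance from one point to a set of triangles
#' @noRd
point_tri_dist <- function(p, vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  ab <- b - a; ac <- c3 - a
  ap <- matrix(p, nrow(a), 3L, byrow = TRUE) - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(a), 3L, byrow = TRUE) - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(a), 3L, byrow = TRUE) - c3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  q <- matrix(NA_real_, nrow(a), 3L)
  done <- rep(FALSE, nrow(a))
  set_q <- function(idx, pts) {
    q[idx & !done, ] <<- pts[idx & !done, , drop = FALSE]
    done[idx] <<- TRUE
  }
  set_q(d1 <= 0 & d2 <= 0, a)
  set_q(d3 >= 0 & d4 <= d3, b)
  set_q(d6 >= 0 & d5 <= d6, c3)
  v_ab <- d1 / (d1 - d3)
  set_q(vc <= 0 & d1 >= 0 & d3 <= 0, a + v_ab * ab)
  w_ac <- d2 / (d2 - d6)
  set_q(vb <= 0 & d2 >= 0 & d6 <= 0, a + w_ac * ac)
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_q(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + w_bc * (c3 - b))
  denom <- va + vb + vc
  vv <- vb / denom; ww <- vc / denom
  set_q(rep(TRUE, nrow(a)), a + vv * ab + ww * ac)
  dd <- sqrt(rowSums((q - matrix(p, nrow(a), 3L, byrow = TRUE))^2))
  i <- which.min(dd)
  list(distance = dd[i], closest = q[i, ])
}

#' Merge two surfaces into one (disjoint union)
#' @noRd
merge_surfaces <- function(s1, s2) {
  off <- nrow(s1$vertices)
  cols <- NULL
  if (!is.null(s1$colors) && !is.null(s2$colors)) cols <- rbind(s1$colors, s2$colors)
  colored_surface(rbind(s1$vertices, s2$vertices),
                  rbind(s1$faces, s2$faces + off),
                  cols, validate = FALSE)
}

#' Seeded evaluation helper: runs `expr` under a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
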