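#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' points (smallest right singular vector of the centered point matrix).
#' The normal is oriented into the +z hemisphere of the input frame.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @return list with `centroid` (3-vector) and `normal` (unit 3-vector).
#' @export
fit_plane <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 3L)
    stop(ply_err("degenerate_plane", "plane fit needs >= 3 points"))
  cen <- colMeans(points)
  X <- sweep(points, 2L, cen)
  sv <- svd(X, nu = 0L)
  if (sv$d[2L] <= 1e-10 * max(sv$d[1L], 1e-300))
    stop(ply_err("degenerate_plane", "points are collinear or coincident"))
  nrm <- sv$v[, 3L]
  if (nrm[3L] < 0 || (nrm[3L] == 0 && (nrm[1L] < 0 || (nrm[1L] == 0 && nrm[2L] < 0))))
    nrm <- -nrm
  list(centroid = cen, normal = nrm)
}

#' Rigid transform (rotation + translation)
#'
#' Applies as `p' = R p + t`. Construct with [level_transform()] or
#' [rigid_align()].
#'
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param translation length-3 vector, mm.
#' @return object of class `level_transform`.
#' @export
level_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must have determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "level_transform")
}

#' Apply a rigid transform to points
#' @param transform a [level_transform()].
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  sweep(points %*% t(transform$rotation), 2L, -transform$translation)
}

#' Compose transforms: `b` after `a`
#' @noRd
compose_transform <- function(b, a) {
  level_transform(b$rotation %*% a$rotation,
                  as.vector(b$rotation %*% a$translation) + b$translation)
}

#' Minimal rotation taking unit vector `from` to unit vector `to`
#' @noRd
minimal_rotation <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2L] * to[3L] - from[3L] * to[2L],
         from[3L] * to[1L] - from[1L] * to[3L],
         from[1L] * to[2L] - from[2L] * to[1L])
  c2 <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-15) {
    if (c2 > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to `from`
    ax <- plane_basis(from)$e1
    K <- skew(ax)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew(v / s)
  diag(3) + sin(acos(max(-1, min(1, c2)))) * K +
    (1 - c2) * (K %*% K)
}

skew <- function(v) {
  matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
}

#' Level a scan to the electrode belt plane
#'
#' Fits the total-least-squares plane through the electrode centers and
#' applies the rigid map that takes the plane normal to +z and the
#' electrode centroid to the origin, to both the surface and the
#' electrodes. The rotation is the minimal one (no in-plane spin);
#' optionally the frame is additionally spun about z so electrode 1 lies at
#' azimuth 0.
#'
#' @param surface a [colored_surface()].
#' @param electrodes an [electrode_set()].
#' @param align_theta also rotate about z so electrode 1 (or the lowest
#'   present label) sits at azimuth theta = 0.
#' @return list with `surface`, `electrodes`, `transform`.
#' @export
apply_leveling <- function(surface, electrodes, align_theta = FALSE) {
  pl <- fit_plane(electrodes$positions)
  R <- minimal_rotation(pl$normal, c(0, 0, 1))
  tr <- level_transform(R, as.vector(-R %*% pl$centroid))
  if (align_theta) {
    p1 <- apply_transform(tr, electrodes$positions[1L, , drop = FALSE])
    th <- atan2(p1[1L, 2L], p1[1L, 1L])
    Rz <- matrix(c(cos(-th), sin(-th), 0, -sin(-th), cos(-th), 0, 0, 0, 1), 3L, 3L)
    tr <- compose_transform(level_transform(Rz), tr)
  }
  s2 <- surface
  s2$vertices <- apply_transform(tr, surface$vertices)
  e2 <- electrodes
  e2$positions <- apply_transform(tr, electrodes$positions)
  list(surface = s2, electrodes = e2, transform = tr)
}

#' Save / load a rigid transform as JSON
#' @param transform a [level_transform()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_transform` returns a [level_transform()].
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(rotation = transform$rotation,
                            translation = transform$translation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  level_transform(x$rotation, x$translation)
}
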