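#' Smooth boundary model: Fourier series in azimuth x RBFs in height
#'
#' The belt-band thorax boundary is modeled as a single-valued radius field
#' about the leveled z-axis,
#' \deqn{r(\theta, z) = \sum_{m=0}^{2N} \sum_{k=1}^{M} C_{mk}\,
#'   \psi_m(\theta)\, \phi_k(z),}
#' where \eqn{\psi} is the Fourier basis \{1, cos, sin, ..., cos N, sin N\}
#' and \eqn{\phi_k} are normalized Gaussian kernels (a partition of unity)
#' centered at M heights spanning the fitted z-range. The defaults N = 12,
#' M = 7 give (2N+1) x M = 175 free coefficients.
#'
#' @name surface_fit_model
NULL

#' Fit the boundary model to a leveled surface
#'
#' Converts vertices to cylindrical (theta, z, r) about the z-axis and
#' solves a ridge-regularized linear least-squares problem for the
#' coefficient matrix. The surface must be leveled (belt plane horizontal,
#' electrode centroid at the origin) and star-shaped about the axis at
#' every height — true of a thorax at belt level.
#'
#' @param surface a leveled [colored_surface()] (or an n x 3 point matrix).
#' @param fourier_order Fourier order N (default 12).
#' @param n_centers number of RBF height centers M (default 7).
#' @param width_factor RBF width as a multiple of the center spacing.
#' @param rbf_width absolute RBF width in mm, overriding `width_factor`.
#' @param ridge absolute ridge weight added to the normal equations
#'   (conditioning only; negligible against the data term).
#' @param z_range fitted height interval; defaults to the data range.
#' @param max_points fits on at most this many (evenly thinned) vertices.
#' @return object of class `surface_fit`: `fourier_order`, `centers`,
#'   `width`, `coeffs` ((2N+1) x M), `z_range`, `rms` (radial residual RMS
#'   over all vertices, mm), `n_params`.
#' @export
fit_surface <- function(surface, fourier_order = 12L, n_centers = 7L,
                        width_factor = 1.25, ridge = 1e-8, z_range = NULL,
                        rbf_width = NULL, max_points = 30000L) {
  pts <- if (inherits(surface, "colored_surface")) surface$vertices
         else matrix(as.numeric(surface), ncol = 3L)
  N <- as.integer(fourier_order); M <- as.integer(n_centers)
  p <- (2L * N + 1L) * M
  if (nrow(pts) < 10L * p)
    stop("need at least ", 10L * p, " vertices to fit ", p, " parameters")
  if (is.null(z_range)) z_range <- range(pts[, 3L])
  spacing <- diff(z_range) / (M - 1L)
  width <- if (is.null(rbf_width)) width_factor * spacing else rbf_width
  if (diff(z_range) < 2 * width || spacing <= 0)
    stop(ply_err("thin_band", "z-range shorter than two RBF kernel widths"))
  centers <- seq(z_range[1L], z_range[2L], length.out = M)

  theta <- atan2(pts[, 2L], pts[, 1L])
  rr <- sqrt(pts[, 1L]^2 + pts[, 2L]^2)
  zz <- pts[, 3L]
  idx <- seq_len(nrow(pts))
  if (nrow(pts) > max_points)
    idx <- unique(round(seq(1L, nrow(pts), length.out = max_points)))

  # QR on the ridge-augmented system: the overlapping Gaussian columns
  # make the normal equations ill-conditioned, QR keeps full accuracy
  A <- fit_design(theta[idx], zz[idx], N, centers, width)
  Aaug <- rbind(A, diag(sqrt(ridge), p))
  coef <- qr.coef(qr(Aaug, LAPACK = TRUE), c(rr[idx], rep(0, p)))
  C <- matrix(coef, nrow = 2L * N + 1L, ncol = M)
  model <- structure(list(fourier_order = N, centers = centers, width = width,
                          coeffs = C, z_range = z_range,
                          n_params = p, rms = NA_real_),
                     class = "surface_fit")
  model$rms <- sqrt(mean((rr - fit_radius(model, theta, zz))^2))
  model
}

fit_design <- function(theta, z, N, centers, width) {
  psi <- fourier_basis(theta, N)             # n x (2N+1)
  phi <- rbf_basis(z, centers, width)        # n x M
  n <- length(theta)
  A <- matrix(0, n, ncol(psi) * ncol(phi))
  for (k in seq_len(ncol(phi)))
    A[, (k - 1L) * ncol(psi) + seq_len(ncol(psi))] <- psi * phi[, k]
  A
}

fourier_basis <- function(theta, N) {
  out <- matrix(0, length(theta), 2L * N + 1L)
  out[, 1L] <- 1
  for (m in seq_len(N)) {
    out[, 2L * m] <- cos(m * theta)
    out[, 2L * m + 1L] <- sin(m * theta)
  }
  out
}

#' Normalized Gaussian kernels: partition of unity over the z-range
#' @noRd
rbf_basis <- function(z, centers, width) {
  zc <- pmin(pmax(z, centers[1L]), centers[length(centers)])
  G <- sapply(centers, function(c0) exp(-((zc - c0) / width)^2))
  G <- matrix(G, ncol = length(centers))
  G / rowSums(G)
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit> N=%d, M=%d (%d parameters), z in [%.1f, %.1f] mm, fit RMS %.3f mm\n",
              x$fourier_order, length(x$centers), x$n_params,
              x$z_range[1L], x$z_range[2L], x$rms))
  invisible(x)
}

#' Radius field of a fitted model
#' @param model a `surface_fit`.
#' @param theta,z azimuth (rad) and height (mm) vectors (recycled).
#' @return radius in mm. Heights outside `z_range` are flat-clamped.
#' @export
fit_radius <- function(model, theta, z) {
  n <- max(length(theta), length(z))
  theta <- rep_len(theta, n); z <- rep_len(z, n)
  psi <- fourier_basis(theta, model$fourier_order)
  phi <- rbf_basis(z, model$centers, model$width)
  rowSums((psi %*% model$coeffs) * phi)
}

#' Evaluate the fitted surface at (theta, z)
#' @inheritParams fit_radius
#' @return n x 3 matrix of 3D points, mm.
#' @export
evaluate_fit <- function(model, theta, z) {
  n <- max(length(theta), length(z))
  theta <- rep_len(theta, n); z <- rep_len(z, n)
  r <- fit_radius(model, theta, z)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Signed radial distance to the fitted surface
#'
#' Negative inside, zero on the surface, positive outside; measured along
#' the cylindrical radius at the point's azimuth with height flat-clamped
#' to the fitted range. For the near-cylindrical belt-band geometries the
#' radial distance closely tracks the Euclidean one.
#'
#' @param model a `surface_fit`.
#' @param points n x 3 matrix, mm.
#' @return signed distances, mm.
#' @export
signed_distance <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  theta <- atan2(points[, 2L], points[, 1L])
  rho <- sqrt(points[, 1L]^2 + points[, 2L]^2)
  rho - fit_radius(model, theta, points[, 3L])
}

#' Sample the fitted surface into a triangulated tube
#'
#' @param model a `surface_fit`.
#' @param n_theta,n_z grid resolution (azimuth is periodic; the tube is
#'   open-ended).
#' @param z_range height interval to sample; defaults to the fitted range.
#' @return an uncolored [colored_surface()] with `n_theta * n_z` vertices.
#' @export
sample_mesh <- function(model, n_theta, n_z, z_range = model$z_range) {
  stopifnot(n_theta >= 3L, n_z >= 2L)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(z_range[1L], z_range[2L], length.out = n_z)
  grid <- expand.grid(th = th, z = zs)
  verts <- evaluate_fit(model, grid$th, grid$z)
  faces <- tube_faces(n_theta, n_z)
  colored_surface(verts, faces, validate = TRUE)
}

#' Periodic tube triangulation of an n_theta x n_z vertex grid
#' (vertex id = (iz-1)*n_theta + itheta)
#' @noRd
tube_faces <- function(n_theta, n_z) {
  f <- matrix(0L, 2L * n_theta * (n_z - 1L), 3L)
  row <- 0L
  for (iz in seq_len(n_z - 1L)) {
    base <- (iz - 1L) * n_theta
    for (it in seq_len(n_theta)) {
      itn <- if (it == n_theta) 1L else it + 1L
      a <- base + it; b <- base + itn
      c3 <- base + n_theta + it; d <- base + n_theta + itn
      f[row + 1L, ] <- c(a, b, d)
      f[row + 2L, ] <- c(a, d, c3)
      row <- row + 2L
    }
  }
  f
}

#' Perimeter of a fitted cross-section
#' @param model a `surface_fit`.
#' @param z height of the slice, mm (default: mid-range).
#' @param n integration resolution.
#' @return arc length of the slice, mm.
#' @export
fit_perimeter <- function(model, z = mean(model$z_range), n = 2048L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  p <- evaluate_fit(model, th, rep(z, n + 1L))
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Serialize / load a surface fit as JSON
#' @param model a `surface_fit`.
#' @param path JSON path.
#' @export
write_surface_fit <- function(model, path) {
  jsonlite::write_json(unclass(model[c("fourier_order", "centers", "width",
                                       "coeffs", "z_range", "n_params", "rms")]),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_surface_fit
#' @export
read_surface_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fourier_order = as.integer(x$fourier_order),
                 centers = as.numeric(x$centers), width = as.numeric(x$width),
                 coeffs = matrix(as.numeric(x$coeffs),
                                 nrow = 2L * as.integer(x$fourier_order) + 1L),
                 z_range = as.numeric(x$z_range),
                 n_params = as.integer(x$n_params), rms = as.numeric(x$rms)),
            class = "surface_fit")
}
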