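#' Synthetic thorax phantom specification
#'
#' Defines an analytic thorax-like shape (ellipse cross-section modulated
#' by low-order cosine bumps and a mild vertical taper) wearing a
#' 32-sticker fiducial belt, from which scanner-like colored surfaces,
#' tracked ground-truth points, and simulated EIT recordings are generated.
#' Defaults emulate the study population: perimeters of roughly 77-105 cm
#' and axis ratios 1.1-1.5.
#'
#' @param perimeter belt-plane perimeter, mm (plausible band 600-1300).
#' @param axis_ratio ellipse major/minor axis ratio, in \[1, 2\].
#' @param z_extent height of the scanned band, mm.
#' @param bump_amplitude amplitude of the low-order shape bumps, mm.
#' @param taper relative radius change from bottom to top (star-shape
#'   preserving).
#' @param vertex_noise_sd scanner vertex noise SD, mm (per coordinate).
#' @param color_noise_sd scanner color noise SD, RGB units.
#' @param n_electrodes number of belt electrodes (32).
#' @param sticker_radius fiducial sticker radius, mm (12 mm stickers).
#' @param resolution target triangulation edge length, mm (the scanner
#'   records at ~1 mm; tests use coarser settings).
#' @param winding +1 (counterclockwise seen from above) or -1; electrode
#'   numbers increase along this direction.
#' @param seed RNG seed making the phantom deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(perimeter = 1048, axis_ratio = 1.1, z_extent = 120,
                         bump_amplitude = 4, taper = 0.04,
                         vertex_noise_sd = 0, color_noise_sd = 0,
                         n_electrodes = 32L, sticker_radius = 6,
                         resolution = 1, winding = 1L, seed = 1L) {
  if (perimeter < 600 || perimeter > 1300)
    stop("perimeter outside the plausible 600-1300 mm band")
  if (axis_ratio < 1 || axis_ratio > 2)
    stop("axis_ratio must be in [1, 2]")
  if (perimeter / n_electrodes < 2.2 * sticker_radius)
    stop("stickers would overlap: perimeter too small for ", n_electrodes,
         " electrodes of sticker radius ", sticker_radius)
  structure(as.list(environment()), class = "phantom_spec")
}

# fixed bump phases/weights: asymmetric enough to expose labeling bugs
phantom_r2d <- function(scale, axis_ratio, bump_amplitude, theta) {
  a <- 1; b <- 1 / axis_ratio
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  scale * r_ell + bump_amplitude * (0.6 * cos(2 * theta + 0.7) +
                                    0.4 * cos(3 * theta - 1.2))
}

phantom_radius <- function(par, theta, z) {
  phantom_r2d(par$scale, par$axis_ratio, par$bump_amplitude, theta) *
    (1 + par$taper * z / par$z_extent)
}

phantom_perimeter_at <- function(par, z = 0, n = 4096L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  r <- phantom_radius(par, th, z)
  p <- cbind(r * cos(th), r * sin(th))
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Generate a scanner-like colored surface from a phantom spec
#'
#' Builds the analytic surface triangulated at roughly the requested
#' resolution, paints skin color everywhere, stamps 32 sticker discs
#' equally spaced (in arc length) around the belt plane with the six
#' anchor colors at electrodes 7, 12, 17, 22, 27, 32 and white elsewhere,
#' then adds seeded Gaussian vertex and color noise. Deterministic per
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `surface` (a [colored_surface()]) and `truth`
#'   (electrode centers/labels on the analytic surface, the shape
#'   parameters, and two ellipsoidal lung regions for EIT simulation).
#' @export
make_scan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  par <- list(scale = 1, axis_ratio = spec$axis_ratio,
              bump_amplitude = spec$bump_amplitude, taper = spec$taper,
              z_extent = spec$z_extent)
  # calibrate the ellipse scale so the belt-plane perimeter matches
  f <- function(s) { par$scale <- s; phantom_perimeter_at(par) - spec$perimeter }
  par$scale <- stats::uniroot(f, c(spec$perimeter / 10, spec$perimeter),
                              tol = 1e-8)$root

  # electrode centers: equal arc-length spacing on the belt plane
  nfine <- 8192L
  thf <- seq(0, 2 * pi, length.out = nfine + 1L)
  rf <- phantom_radius(par, thf, 0)
  pf <- cbind(rf * cos(thf), rf * sin(thf))
  arc <- c(0, cumsum(sqrt(rowSums(diff(pf)^2))))
  P <- arc[nfine + 1L]
  s_i <- (seq_len(spec$n_electrodes) - 1L) / spec$n_electrodes * P
  if (spec$winding < 0) s_i <- (P - s_i) %% P
  th_e <- stats::approx(arc, thf, xout = s_i)$y
  re <- phantom_radius(par, th_e, 0)
  centers <- cbind(re * cos(th_e), re * sin(th_e), 0)

  # triangulated tube
  n_theta <- max(48L, round(spec$perimeter / spec$resolution))
  n_z <- max(8L, round(spec$z_extent / spec$resolution)) + 1L
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(-spec$z_extent / 2, spec$z_extent / 2, length.out = n_z)
  grid <- expand.grid(th = th, z = zs)
  rr <- phantom_radius(par, grid$th, grid$z)
  verts <- cbind(rr * cos(grid$th), rr * sin(grid$th), grid$z)
  faces <- tube_faces(n_theta, n_z)

  # colors: skin everywhere, then sticker discs
  pal <- default_palette()
  skin <- c(200L, 160L, 140L)
  cols <- matrix(rep(skin, each = nrow(verts)), ncol = 3L)
  sticker_cols <- matrix(rep(c(255L, 255L, 255L), each = spec$n_electrodes),
                         ncol = 3L)
  for (cname in names(pal$anchor_map))
    sticker_cols[pal$anchor_map[[cname]], ] <- pal$reference[cname, ]
  nn <- FNN::get.knnx(centers, verts, k = 1L)
  on_sticker <- nn$nn.dist[, 1L] <= spec$sticker_radius
  cols[on_sticker, ] <- sticker_cols[nn$nn.index[on_sticker, 1L], ]

  surface <- with_seed(spec$seed, {
    if (spec$vertex_noise_sd > 0)
      verts <- verts + matrix(stats::rnorm(length(verts), 0, spec$vertex_noise_sd),
                              ncol = 3L)
    if (spec$color_noise_sd > 0) {
      cols <- cols + matrix(round(stats::rnorm(length(cols), 0, spec$color_noise_sd)),
                            ncol = 3L)
      cols <- pmin(pmax(cols, 0L), 255L)
    }
    colored_surface(verts, faces, cols)
  })

  # lung regions: two ellipsoids left/right of the sternum axis
  rx <- phantom_radius(par, 0, 0); ry <- phantom_radius(par, pi / 2, 0)
  lungs <- list(
    left  = list(center = c(0.45 * rx, 0, 0),
                 semi = c(0.32 * rx, 0.5 * ry, spec$z_extent)),
    right = list(center = c(-0.45 * rx, 0, 0),
                 semi = c(0.32 * rx, 0.5 * ry, spec$z_extent)))

  truth <- list(centers = centers,
                labels = seq_len(spec$n_electrodes),
                shape = par, perimeter = P, z_extent = spec$z_extent,
                lungs = lungs, spec = spec)
  list(surface = surface, truth = truth)
}

#' Simulated tracked ground-truth points and contours
#'
#' Emulates an infrared-tracked pointer recording: the true electrode
#' centers plus isotropic Gaussian noise (with a chosen set of labels
#' occluded), and front/back contour polylines traced above the belt.
#'
#' @param truth `truth` element from [make_scan()].
#' @param noise_sd isotropic noise SD per coordinate, mm.
#' @param occlude integer labels to drop (e.g. hidden by the belt buckle).
#' @param seed RNG seed.
#' @param n_contour samples per contour.
#' @return list with `electrodes` (an [electrode_set()]) and `contours`
#'   (list of n x 3 polylines `front`, `back`).
#' @export
make_tracked_points <- function(truth, noise_sd = 0, occlude = integer(),
                                seed = 1L, n_contour = 100L) {
  keep <- setdiff(truth$labels, occlude)
  pos <- truth$centers[keep, , drop = FALSE]
  zc <- truth$z_extent * 0.3
  mk_contour <- function(th0) {
    th <- seq(th0 - 0.6, th0 + 0.6, length.out = n_contour)
    r <- phantom_radius(truth$shape, th, zc)
    cbind(r * cos(th), r * sin(th), zc)
  }
  with_seed(seed, {
    if (noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, noise_sd), ncol = 3L)
    front <- mk_contour(0); back <- mk_contour(pi)
    if (noise_sd > 0) {
      front <- front + matrix(stats::rnorm(length(front), 0, noise_sd), ncol = 3L)
      back <- back + matrix(stats::rnorm(length(back), 0, noise_sd), ncol = 3L)
    }
    list(electrodes = electrode_set(pos, keep),
         contours = list(front = front, back = back))
  })
}
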