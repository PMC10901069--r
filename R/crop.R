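#' Define a crop region
#'
#' A crop region mimics the manual step of boxing the belt in a projected
#' view of the scan: a simple polygon drawn in a 2D projection plus an
#' optional height interval.
#'
#' @param polygon numeric matrix (>= 3 x 2) of polygon vertices, mm, in the
#'   projected view.
#' @param view_axis projection axis: `"z"` (view from above, polygon in the
#'   x-y plane), `"x"` (polygon in y-z) or `"y"` (polygon in x-z).
#' @param z_bounds optional length-2 numeric, keep vertices with
#'   `z_bounds[1] <= z <= z_bounds[2]` (mm).
#' @return an object of class `crop_region`.
#' @export
crop_region <- function(polygon = NULL, view_axis = "z", z_bounds = NULL) {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L || ncol(polygon) != 2L)
      stop("polygon must have >= 3 points in 2 columns")
    if (polygon_self_intersects(polygon))
      stop("crop polygon is self-intersecting")
  }
  if (!view_axis %in% c("x", "y", "z")) stop("view_axis must be x, y or z")
  if (!is.null(z_bounds)) {
    if (length(z_bounds) != 2L || !(z_bounds[1] < z_bounds[2]))
      stop("z_bounds must satisfy lower < upper")
  }
  if (is.null(polygon) && is.null(z_bounds))
    stop("crop_region needs a polygon, z_bounds, or both")
  structure(list(polygon = polygon, view_axis = view_axis, z_bounds = z_bounds),
            class = "crop_region")
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # closing edge shares a vertex with edge 1
      if (segments_cross(p[seg[i, 1L], ], p[seg[i, 2L], ],
                         p[seg[j, 1L], ], p[seg[j, 2L], ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a, b, c3, d) {
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- orient(a, b, c3); o2 <- orient(a, b, d)
  o3 <- orient(c3, d, a); o4 <- orient(c3, d, b)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

#' Crop a scan to a region of interest
#'
#' Retains vertices whose projection lies inside the region's polygon and
#' whose height lies within `z_bounds`; drops every face touching a removed
#' vertex (faces are dropped, not clipped); then keeps only the largest
#' connected component, removing disconnected scan debris.
#'
#' @param surface a [colored_surface()].
#' @param region a [crop_region()].
#' @return the cropped [colored_surface()], reindexed.
#' @export
crop <- function(surface, region) {
  stopifnot(inherits(region, "crop_region"))
  v <- surface$vertices
  keep <- rep(TRUE, nrow(v))
  if (!is.null(region$polygon)) {
    uv <- switch(region$view_axis,
                 z = v[, c(1L, 2L), drop = FALSE],
                 x = v[, c(2L, 3L), drop = FALSE],
                 y = v[, c(1L, 3L), drop = FALSE])
    inside <- sp::point.in.polygon(uv[, 1L], uv[, 2L],
                                   region$polygon[, 1L], region$polygon[, 2L])
    keep <- keep & inside > 0L
  }
  if (!is.null(region$z_bounds)) {
    keep <- keep & v[, 3L] >= region$z_bounds[1L] & v[, 3L] <= region$z_bounds[2L]
  }
  keep_f <- keep[surface$faces[, 1L]] & keep[surface$faces[, 2L]] &
    keep[surface$faces[, 3L]]
  if (!any(keep_f))
    stop(ply_err("empty_crop", "crop region retains no faces"))
  largest_component(subset_surface(surface, keep_f))
}
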