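#' Default fiducial color palette
#'
#' The belt carries 32 fiducial stickers; six are printed in saturated
#' colors at fixed electrode numbers (cyan 7, orange 12, red 17, yellow 22,
#' green 27, pink 32) and the rest are white. These anchors make the
#' numbering of all 32 electrodes unambiguous.
#'
#' @param tolerance RGB Euclidean distance within which a vertex color
#'   matches a reference color. Scanner color is noisy and the sticker
#'   colors are saturated primaries, so the default is generous.
#' @return an object of class `color_palette`: `anchor_map` (color name ->
#'   electrode number), `reference` (color name -> RGB row), `tolerance`.
#' @export
default_palette <- function(tolerance = 60) {
  reference <- rbind(cyan   = c(0, 255, 255),
                     orange = c(255, 165, 0),
                     red    = c(255, 0, 0),
                     yellow = c(255, 255, 0),
                     green  = c(0, 200, 0),
                     pink   = c(255, 105, 180),
                     white  = c(255, 255, 255))
  structure(list(
    anchor_map = c(cyan = 7L, orange = 12L, red = 17L, yellow = 22L,
                   green = 27L, pink = 32L),
    reference = reference,
    tolerance = tolerance), class = "color_palette")
}

#' Labeled electrode positions
#'
#' @param positions k x 3 matrix of electrode centers, mm.
#' @param labels integer electrode numbers in 1..32, unique, one per row.
#' @param n_total total number of belt electrodes (32).
#' @return object of class `electrode_set` with `positions`, `labels`,
#'   `occluded` (the missing labels).
#' @export
electrode_set <- function(positions, labels, n_total = 32L) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  labels <- as.integer(labels)
  if (nrow(positions) != length(labels)) stop("positions/labels length mismatch")
  if (anyDuplicated(labels)) stop("duplicate electrode labels")
  if (any(labels < 1L | labels > n_total)) stop("labels must be in 1..", n_total)
  o <- order(labels)
  structure(list(positions = positions[o, , drop = FALSE], labels = labels[o],
                 occluded = setdiff(seq_len(n_total), labels),
                 n_total = n_total),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat("<electrode_set> ", length(x$labels), "/", x$n_total, " electrodes",
      sep = "")
  if (length(x$occluded))
    cat("; occluded:", paste(x$occluded, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Detect fiducial stickers by color
#'
#' Finds, for each palette color class (six anchors plus white), connected
#' clusters of surface vertices whose color is within tolerance of the
#' reference (and closer to it than to any other reference), and reduces
#' each cluster to its centroid projected back onto the surface. This is
#' the automated replacement for clicking fiducials by hand; manually
#' picked points can be supplied downstream instead.
#'
#' @param surface a colored [colored_surface()].
#' @param palette a [default_palette()].
#' @param min_cluster discard clusters with fewer vertices than this.
#' @return list with one entry per color class; each entry is a list of
#'   clusters sorted by decreasing size, each with `centroid` (3-vector, on
#'   the surface) and `size`. A named anchor color with no clusters raises
#'   a `missing-anchor` warning.
#' @export
detect_fiducials <- function(surface, palette = default_palette(),
                             min_cluster = 5L) {
  if (is.null(surface$colors)) stop(ply_err("no_color", "surface has no colors"))
  cols <- surface$colors
  refs <- palette$reference
  # squared distance of every vertex to every reference color
  d2 <- sapply(seq_len(nrow(refs)), function(j) {
    rowSums((cols - matrix(refs[j, ], nrow(cols), 3L, byrow = TRUE))^2)
  })
  nearest <- max.col(-d2)
  within <- d2[cbind(seq_len(nrow(cols)), nearest)] <= palette$tolerance^2
  edges <- surface_edges(surface$faces)
  out <- list()
  for (j in seq_len(nrow(refs))) {
    cname <- rownames(refs)[j]
    sel <- which(within & nearest == j)
    clusters <- list()
    if (length(sel) > 1L) {
      insel <- logical(nrow(cols)); insel[sel] <- TRUE
      e <- edges[insel[edges[, 1L]] & insel[edges[, 2L]], , drop = FALSE]
      map <- integer(nrow(cols)); map[sel] <- seq_along(sel)
      g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
      if (nrow(e)) g <- igraph::add_edges(g, t(matrix(map[e], ncol = 2L)))
      comp <- igraph::components(g)
      for (ci in seq_len(comp$no)) {
        idx <- sel[comp$membership == ci]
        if (length(idx) >= min_cluster) {
          cen <- colMeans(surface$vertices[idx, , drop = FALSE])
          proj <- surface_distance(rbind(cen), surface)$closest[1L, ]
          clusters[[length(clusters) + 1L]] <- list(centroid = proj,
                                                    size = length(idx))
        }
      }
      clusters <- clusters[order(-vapply(clusters, `[[`, 1L, "size"))]
    }
    if (length(clusters) == 0L && cname %in% names(palette$anchor_map))
      warning("missing-anchor: no cluster found for anchor color '", cname, "'",
              call. = FALSE)
    out[[cname]] <- clusters
  }
  out
}

#' Number the electrodes from anchor colors
#'
#' Sorts all fiducial points by azimuth about the belt centroid in the
#' leveled plane, picks the rotation direction along which the anchor
#' numbers (7, 12, 17, 22, 27, 32) increase cyclically, and assigns the
#' white stickers the in-between numbers. When fewer whites than slots lie
#' between two anchors (occlusion by the buckle), the assignment that best
#' matches uniform angular spacing is chosen by exhaustive search over the
#' slot subsets of that arc.
#'
#' @param anchors named list/matrix of anchor points: names are palette
#'   color names (or electrode numbers as characters), each a 3-vector.
#' @param whites matrix (w x 3) of unnumbered white-sticker points; may be
#'   empty.
#' @param level_normal unit normal of the belt plane (from [fit_plane()]).
#' @param palette palette giving the anchor color -> number map.
#' @return an [electrode_set()]; missing numbers appear in `$occluded`.
#' @export
label_electrodes <- function(anchors, whites, level_normal,
                             palette = default_palette()) {
  anum <- anchor_numbers(names(anchors), palette)
  apts <- do.call(rbind, lapply(anchors, function(p) as.numeric(p)))
  if (length(anum) < 2L) stop("need at least 2 anchors to orient the belt")
  whites <- if (is.null(whites) || length(whites) == 0L)
    matrix(numeric(), 0L, 3L) else matrix(as.numeric(whites), ncol = 3L)
  n_total <- 32L
  if (nrow(apts) + nrow(whites) > n_total)
    stop(ply_err("overfull_segment", "more fiducials than electrode slots"))

  pts <- rbind(apts, whites)
  is_anchor <- c(rep(TRUE, nrow(apts)), rep(FALSE, nrow(whites)))
  nrm <- level_normal / sqrt(sum(level_normal^2))
  basis <- plane_basis(nrm)
  cen <- colMeans(pts)
  rel <- sweep(pts, 2L, cen)
  ang <- atan2(rel %*% basis$e2, rel %*% basis$e1)[, 1L]

  o <- order(ang)
  anchors_sorted <- function(ordering) {
    idx <- ordering[is_anchor[ordering]]
    anum[match(idx, which(is_anchor))]
  }
  if (is_cyclic_increasing(anchors_sorted(o))) {
    direction <- 1
  } else {
    o <- rev(o)
    if (!is_cyclic_increasing(anchors_sorted(o)))
      stop(ply_err("anchor_order",
                   "anchor angular order matches neither rotation direction"))
    direction <- -1
    ang <- -ang
  }

  a_sorted <- ang[o]
  anchor_pos <- which(is_anchor[o])
  anchor_lab <- anum[match(o[anchor_pos], which(is_anchor))]

  labels <- integer(length(o))
  labels[anchor_pos] <- anchor_lab
  k <- length(anchor_pos)
  for (ai in seq_len(k)) {
    i0 <- anchor_pos[ai]
    i1 <- anchor_pos[if (ai == k) 1L else ai + 1L]
    la <- anchor_lab[ai]
    lb <- anchor_lab[if (ai == k) 1L else ai + 1L]
    slots <- (lb - la - 1L) %% n_total
    # white points strictly between the two anchors in the cyclic ordering
    if (ai == k) {
      seg <- c(if (i0 < length(o)) (i0 + 1L):length(o) else integer(),
               if (i1 > 1L) 1L:(i1 - 1L) else integer())
    } else {
      seg <- if (i1 - i0 > 1L) (i0 + 1L):(i1 - 1L) else integer()
    }
    w <- length(seg)
    if (w > slots)
      stop(ply_err("overfull_segment",
                   sprintf("%d fiducials between anchors %d and %d (%d slots)",
                           w, la, lb, slots)))
    if (w == 0L) next
    # angles within the arc, unwrapped from anchor a
    th0 <- a_sorted[i0]
    th <- a_sorted[seg] - th0
    th[th < 0] <- th[th < 0] + 2 * pi
    th1 <- a_sorted[i1] - th0
    if (th1 <= 0) th1 <- th1 + 2 * pi
    choice <- best_slot_assignment(th, th1, slots)
    labels[seg] <- ((la - 1L + choice) %% n_total) + 1L
  }
  electrode_set(pts[o, , drop = FALSE], labels, n_total)
}

anchor_numbers <- function(nms, palette) {
  if (is.null(nms)) stop("anchors must be named by color or electrode number")
  num <- suppressWarnings(as.integer(nms))
  from_color <- palette$anchor_map[nms]
  out <- ifelse(is.na(num), from_color, num)
  if (anyNA(out)) stop("unknown anchor name(s): ",
                       paste(nms[is.na(out)], collapse = ", "))
  as.integer(out)
}

is_cyclic_increasing <- function(x) {
  if (length(x) < 2L) return(TRUE)
  if (anyDuplicated(x)) return(FALSE)
  # a cyclic rotation of an increasing sequence has exactly one descent
  sum(diff(c(x, x[1L])) < 0) == 1L
}

#' Choose which slots the whites occupy, minimizing spacing nonuniformity
#'
#' Given white angles `th` (increasing, relative to anchor a) inside an arc
#' of angular width `th1` holding `slots` label slots, returns the slot
#' offsets (1-based from anchor a) whose implied per-step angular spacing
#' is most uniform: minimizes sum over gaps of
#' (gap_angle / gap_steps - arc_mean)^2.
#' @noRd
best_slot_assignment <- function(th, th1, slots) {
  w <- length(th)
  if (w == slots) return(seq_len(slots))
  mean_step <- th1 / (slots + 1L)
  combos <- utils::combn(slots, w)
  best <- NULL; best_val <- Inf
  for (ci in seq_len(ncol(combos))) {
    sl <- combos[, ci]
    ang_pts <- c(0, th, th1)
    step_pts <- c(0L, sl, slots + 1L)
    gaps_a <- diff(ang_pts)
    gaps_s <- diff(step_pts)
    val <- sum((gaps_a / gaps_s - mean_step)^2 * gaps_s)
    if (val < best_val - 1e-12) { best_val <- val; best <- sl }
  }
  best
}

#' Orthonormal basis of the plane normal to `n`
#' @noRd
plane_basis <- function(n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

#' Read manually picked fiducials
#'
#' CSV with columns `label,x,y,z`; blank/NA label marks a white sticker.
#' Mirrors the click-based workflow so externally picked points can replace
#' automatic color detection.
#'
#' @param path CSV path.
#' @return list with `anchors` (named list number -> point) and `whites`
#'   (matrix).
#' @export
read_manual_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) stop("manual points CSV needs columns label,x,y,z")
  lab <- suppressWarnings(as.integer(df$label))
  pts <- as.matrix(df[, c("x", "y", "z")])
  is_a <- !is.na(lab)
  anchors <- lapply(which(is_a), function(i) pts[i, ])
  names(anchors) <- as.character(lab[is_a])
  list(anchors = anchors, whites = pts[!is_a, , drop = FALSE])
}

#' One-call fiducial identification
#'
#' Runs [detect_fiducials()], keeps the largest cluster per anchor color
#' and all white clusters, fits the belt plane, and numbers the electrodes
#' with [label_electrodes()].
#'
#' @inheritParams detect_fiducials
#' @return list with `electrodes` (an [electrode_set()]), `plane` (from
#'   [fit_plane()]) and `detections` (raw cluster lists).
#' @export
identify_electrodes <- function(surface, palette = default_palette(),
                                min_cluster = 5L) {
  det <- detect_fiducials(surface, palette, min_cluster)
  anchors <- list()
  for (cname in names(palette$anchor_map)) {
    cl <- det[[cname]]
    if (length(cl) > 0L) anchors[[cname]] <- cl[[1L]]$centroid
  }
  whites <- do.call(rbind, lapply(det$white, `[[`, "centroid"))
  allpts <- rbind(do.call(rbind, anchors), whites)
  if (is.null(allpts) || nrow(allpts) < 3L)
    stop("too few fiducial detections to identify electrodes")
  plane <- fit_plane(allpts)
  es <- label_electrodes(anchors, whites, plane$normal, palette)
  list(electrodes = es, plane = plane, detections = det)
}
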