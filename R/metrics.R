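#' Least-squares rigid alignment of labeled electrode sets
#'
#' Closed-form orthogonal Procrustes (Kabsch) over the electrode labels
#' common to both sets: the rotation + translation (no scaling, det +1)
#' minimizing the sum of squared distances from transformed source to
#' target.
#'
#' @param source,target [electrode_set()] objects with >= 3 common labels.
#' @return a [level_transform()] mapping source onto target.
#' @export
rigid_align <- function(source, target) {
  common <- intersect(source$labels, target$labels)
  if (length(common) < 3L)
    stop(ply_err("insufficient_correspondence",
                 "rigid alignment needs >= 3 common labels"))
  A <- source$positions[match(common, source$labels), , drop = FALSE]
  B <- target$positions[match(common, target$labels), , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  level_transform(R, cb - as.vector(R %*% ca))
}

#' Electrode position differences between two scans
#'
#' Per-label distances, RMS and maximum over the labels common to both
#' sets (occluded electrodes are dropped pairwise). With `align = TRUE`
#' the source is first rigidly registered to the target by label
#' correspondence — necessary when the two scans live in arbitrary
#' scanner frames.
#'
#' @param a,b [electrode_set()] objects.
#' @param align rigidly align `a` to `b` first (needs >= 3 common labels).
#' @return object of class `comparison_report`: `rms`, `max`,
#'   `per_electrode` (named distances, mm), `n_pairs`, `transform_used`.
#' @export
electrode_error <- function(a, b, align = TRUE) {
  common <- intersect(a$labels, b$labels)
  if (length(common) < 1L) stop("no common electrode labels")
  tr <- NULL
  pa <- a$positions[match(common, a$labels), , drop = FALSE]
  pb <- b$positions[match(common, b$labels), , drop = FALSE]
  if (align) {
    tr <- rigid_align(a, b)
    pa <- apply_transform(tr, pa)
  }
  d <- sqrt(rowSums((pa - pb)^2))
  names(d) <- common
  structure(list(rms = sqrt(mean(d^2)), max = max(d), per_electrode = d,
                 n_pairs = length(common), transform_used = tr),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> RMS %.2f mm, max %.2f mm over %d electrode pairs%s\n",
              x$rms, x$max, x$n_pairs,
              if (is.null(x$transform_used)) "" else " (aligned)"))
  invisible(x)
}

#' Distances from a traced contour to a surface
#'
#' Unsigned nearest-point distance from each contour sample to either a
#' surface triangulation (exact point-triangle distances) or a fitted
#' boundary model (magnitude of the radial signed distance). Mirrors the
#' contour-to-scan and contour-to-fit accuracy summaries.
#'
#' @param points n x 3 matrix of ordered contour samples, mm.
#' @param surface a [colored_surface()] or a `surface_fit`.
#' @return list with `distances` (mm), `mean`, `sd`, `max`.
#' @export
contour_to_surface <- function(points, surface) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) == 0L) stop("empty contour")
  d <- if (inherits(surface, "surface_fit")) {
    abs(signed_distance(surface, points))
  } else if (inherits(surface, "colored_surface")) {
    surface_distance(points, surface)$distance
  } else stop("surface must be a colored_surface or surface_fit")
  list(distances = d, mean = mean(d), sd = stats::sd(d), max = max(d))
}

#' Scan-to-scan precision report
#'
#' All unordered pairs of the supplied electrode sets are compared with
#' [electrode_error()]; the average and SD of the pairwise RMS and
#' maximum differences summarize scan reproducibility (k scans give
#' C(k,2) comparisons).
#'
#' @param scans list of >= 2 [electrode_set()] objects.
#' @param align align each pair before comparing.
#' @return list with `pairs` (list of `comparison_report`), `n_comparisons`,
#'   `rms_mean`, `rms_sd`, `max_mean`, `max_sd`.
#' @export
precision_report <- function(scans, align = TRUE) {
  k <- length(scans)
  if (k < 2L) stop("need at least two scans")
  combos <- utils::combn(k, 2L)
  reports <- lapply(seq_len(ncol(combos)), function(i)
    electrode_error(scans[[combos[1L, i]]], scans[[combos[2L, i]]], align))
  rms <- vapply(reports, `[[`, 1, "rms")
  mx <- vapply(reports, `[[`, 1, "max")
  list(pairs = reports, n_comparisons = ncol(combos),
       rms_mean = mean(rms), rms_sd = stats::sd(rms),
       max_mean = mean(mx), max_sd = stats::sd(mx))
}

#' Read / write labeled electrode CSVs (`label,x,y,z`)
#' @param electrodes an [electrode_set()].
#' @param path CSV path.
#' @export
write_electrodes <- function(electrodes, path) {
  utils::write.csv(data.frame(label = electrodes$labels,
                              x = electrodes$positions[, 1L],
                              y = electrodes$positions[, 2L],
                              z = electrodes$positions[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(path) {
  df <- utils::read.csv(path)
  electrode_set(as.matrix(df[, c("x", "y", "z")]), df$label)
}
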