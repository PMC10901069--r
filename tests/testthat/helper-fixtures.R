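# Shared fixtures, built once per test run and cached in this environment.
# Sizes are deliberately desk-scale: coarse scan resolution and large
# h-values keep the whole suite fast while exercising every stage.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# an analytic cylinder expressed as a surface_fit (constant-mode coefficients)
cylinder_model <- function(R = 150, zr = c(-60, 60), M = 7, N = 12) {
  structure(list(fourier_order = N,
                 centers = seq(zr[1], zr[2], length.out = M),
                 width = 1.25 * diff(zr) / (M - 1),
                 coeffs = rbind(rep(R, M), matrix(0, 2 * N, M)),
                 z_range = zr, n_params = (2 * N + 1) * M, rms = 0),
            class = "surface_fit")
}

# default noise-free phantom scan (coarse resolution)
phantom_clean <- function() fixture("phantom_clean", function() {
  make_scan(phantom_spec(perimeter = 1048, axis_ratio = 1.1, z_extent = 120,
                         bump_amplitude = 4, resolution = 3, seed = 11))
})

# small phantom + fitted model + electrode-encoded coarse FEM mesh,
# shared by the belt-mesh and EIT tests
eit_fixture <- function() fixture("eit_fixture", function() {
  ph <- make_scan(phantom_spec(perimeter = 700, axis_ratio = 1.15,
                               z_extent = 70, bump_amplitude = 3,
                               resolution = 3, seed = 5))
  fit <- fit_surface(ph$surface)
  es <- electrode_set(ph$truth$centers, ph$truth$labels)
  set.seed(100)
  belt <- suppressMessages(remesh_surface(
    fit, es, mesh_config(h_electrode = 4, h_background = 15,
                         electrode_radius = 5, max_iter = 150)))
  mesh <- build_fem_mesh(belt, n_shells = 3)
  list(phantom = ph, fit = fit, electrodes = es, belt = belt, mesh = mesh)
})

# finer companion mesh of the same phantom, for inverse-crime-free sims
eit_fixture_fine <- function() fixture("eit_fixture_fine", function() {
  fx <- eit_fixture()
  set.seed(101)
  belt <- suppressMessages(remesh_surface(
    fx$fit, fx$electrodes,
    mesh_config(h_electrode = 3.2, h_background = 11,
                electrode_radius = 5, max_iter = 150)))
  build_fem_mesh(belt, n_shells = 5)
})

# baseline Jacobian on the coarse mesh, shared by the EIT tests
eit_jac <- function() fixture("eit_jac", function() {
  jac <- eit_jacobian(eit_fixture()$mesh, protocol = eit_protocol())
  jac$op <- recon_operator(jac$J)
  jac
})

# one-triangle colored surface for IO edge cases
one_triangle <- function() {
  colored_surface(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                  rbind(c(1L, 2L, 3L)),
                  matrix(255L, 3L, 3L))
}

# brute-force electrode labeling oracle: enumerates both rotation
# directions and every consistent slot assignment, minimizing the
# angular-spacing variance objective; independent of label_electrodes()
oracle_label <- function(anchors, whites, normal, palette = default_palette()) {
  anum <- palette$anchor_map[names(anchors)]
  apts <- do.call(rbind, lapply(anchors, as.numeric))
  pts <- rbind(apts, if (length(whites)) matrix(whites, ncol = 3) else NULL)
  nw <- nrow(pts) - nrow(apts)
  nrm <- normal / sqrt(sum(normal^2))
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  cen <- colMeans(pts)
  rel <- sweep(pts, 2, cen)
  best <- NULL; best_val <- Inf
  for (dir in c(1, -1)) {
    ang <- atan2(dir * rel %*% e2, rel %*% e1)[, 1]
    o <- order(ang)
    n <- length(o)
    # try every rotation offset of the sorted order as "start"
    lab_of_sorted <- rep(NA_integer_, n)
    is_anchor <- c(rep(TRUE, nrow(apts)), rep(FALSE, nw))
    apos <- which(is_anchor[o])
    alab <- anum[match(o[apos], seq_len(nrow(apts)))]
    # anchor sequence must be cyclically increasing
    if (sum(diff(c(alab, alab[1])) < 0) != 1 && length(alab) > 1) next
    # enumerate slot assignments arc by arc, combining objectives
    k <- length(apos)
    arcs <- list(); ok <- TRUE
    for (ai in seq_len(k)) {
      i0 <- apos[ai]; i1 <- apos[if (ai == k) 1 else ai + 1]
      la <- alab[ai]; lb <- alab[if (ai == k) 1 else ai + 1]
      slots <- (lb - la - 1) %% 32
      seg <- if (ai == k) c(if (i0 < n) (i0 + 1):n else NULL,
                            if (i1 > 1) 1:(i1 - 1) else NULL)
             else if (i1 - i0 > 1) (i0 + 1):(i1 - 1) else integer()
      if (length(seg) > slots) { ok <- FALSE; break }
      arcs[[ai]] <- list(i0 = i0, i1 = i1, la = la, lb = lb,
                         slots = slots, seg = seg, ang = ang)
    }
    if (!ok) next
    labs <- integer(n); labs[apos] <- alab
    val_tot <- 0
    for (arc in arcs) {
      w <- length(arc$seg)
      if (w == 0) next
      th0 <- ang[o][arc$i0]
      th <- ang[o][arc$seg] - th0; th[th < 0] <- th[th < 0] + 2 * pi
      th1 <- ang[o][arc$i1] - th0; if (th1 <= 0) th1 <- th1 + 2 * pi
      mean_step <- th1 / (arc$slots + 1)
      cb <- utils::combn(arc$slots, w)
      bv <- Inf; bs <- NULL
      for (ci in seq_len(ncol(cb))) {
        sl <- cb[, ci]
        ga <- diff(c(0, th, th1)); gs <- diff(c(0, sl, arc$slots + 1))
        vv <- sum((ga / gs - mean_step)^2 * gs)
        if (vv < bv - 1e-12) { bv <- vv; bs <- sl }
      }
      labs[arc$seg] <- ((arc$la - 1 + bs) %% 32) + 1
      val_tot <- val_tot + bv
    }
    if (val_tot < best_val) {
      best_val <- val_tot
      best <- list(labels = labs, order = o, dir = dir)
    }
  }
  if (is.null(best)) stop("oracle: no consistent labeling")
  electrode_set(pts[best$order, , drop = FALSE], best$labels)
}
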