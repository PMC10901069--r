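#' EIT measurement protocol
#'
#' Pairwise current injection with a skip pattern on a ring of electrodes:
#' injection pairs are (i, i + skip + 1) for every electrode i, and for
#' each injection the voltage is read across every skip-separated pair not
#' involving an injecting electrode (32 electrodes, skip 4: 28 readings
#' per injection, 896 per frame). Current amplitude, carrier frequency and
#' frame rate are recorded as metadata of the belt system.
#'
#' @param n_electrodes number of belt electrodes.
#' @param skip injection/measurement skip (4 for the thoracic belt).
#' @param current_amplitude drive amplitude, A.
#' @param frequency carrier frequency, Hz (metadata only; the model is
#'   real-valued).
#' @param frame_rate frames per second.
#' @return object of class `eit_protocol` with a `measurements` table
#'   (`drive_pos`, `drive_neg`, `meas_pos`, `meas_neg`).
#' @export
eit_protocol <- function(n_electrodes = 32L, skip = 4L,
                         current_amplitude = 3e-3, frequency = 195e3,
                         frame_rate = 48) {
  L <- as.integer(n_electrodes)
  stepn <- as.integer(skip) + 1L
  wrap <- function(i) ((i - 1L) %% L) + 1L
  rows <- list()
  for (i in seq_len(L)) {
    dp <- i; dn <- wrap(i + stepn)
    for (j in seq_len(L)) {
      mp <- j; mn <- wrap(j + stepn)
      if (length(intersect(c(mp, mn), c(dp, dn))) > 0L) next
      rows[[length(rows) + 1L]] <- c(dp, dn, mp, mn)
    }
  }
  meas <- do.call(rbind, rows)
  colnames(meas) <- c("drive_pos", "drive_neg", "meas_pos", "meas_neg")
  structure(list(n_electrodes = L, skip = as.integer(skip),
                 current_amplitude = current_amplitude, frequency = frequency,
                 frame_rate = frame_rate, measurements = meas),
            class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("<eit_protocol> %d electrodes, skip-%d, %d measurements/frame, %.1f mA, %.0f kHz, %.0f Hz\n",
              x$n_electrodes, x$skip, nrow(x$measurements),
              1e3 * x$current_amplitude, x$frequency / 1e3, x$frame_rate))
  invisible(x)
}

#' Assemble and factorize the complete-electrode-model system
#'
#' Linear P1 finite elements with the complete electrode model: contact
#' impedance on each electrode patch and the zero-mean electrode-potential
#' gauge enforced by a Lagrange multiplier. Node coordinates are
#' converted from mm to metres so conductivities are in S/m and voltages
#' in volts.
#'
#' @param mesh a `fem_mesh` with labeled electrode facets.
#' @param sigma per-element conductivity, S/m (scalar recycled).
#' @param contact_impedance contact impedance, Ohm m^2 (scalar or per
#'   electrode).
#' @return object of class `eit_system` holding the factorization, the
#'   electrode-basis fields, and per-element gradient operators.
#' @export
eit_system <- function(mesh, sigma = 1, contact_impedance = 1e-3) {
  nodes <- mesh$nodes * 1e-3
  tets <- mesh$tets
  ne <- nrow(tets); nn <- nrow(nodes)
  labs <- names(mesh$electrode_facets)
  L <- length(labs)
  if (L == 0L) stop("mesh has no labeled electrode facets")
  sigma <- rep_len(sigma, ne)
  if (any(sigma <= 0)) stop("sigma must be positive")
  zeta <- rep_len(contact_impedance, L)

  g <- element_gradients(nodes, tets)     # list(gx, gy, gz [ne x 4], vol)
  if (any(g$vol <= 0)) stop("non-positive element volume; mesh is invalid")

  # stiffness: K[i,j] = sum_e sigma_e vol_e grad_i . grad_j
  ii <- jj <- xx <- vector("list", 16L)
  idx <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- idx + 1L
    ii[[idx]] <- tets[, a]; jj[[idx]] <- tets[, b]
    xx[[idx]] <- sigma * g$vol * (g$gx[, a] * g$gx[, b] +
                                  g$gy[, a] * g$gy[, b] +
                                  g$gz[, a] * g$gz[, b])
  }
  Ksp <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(nn, nn))

  # electrode boundary terms
  Bi <- Bj <- Bx <- list()
  Mi <- Mj <- Mx <- list()
  areas <- numeric(L)
  for (l in seq_len(L)) {
    f <- mesh$electrode_facets[[l]]
    cr <- face_cross(nodes, f)
    ar <- 0.5 * sqrt(rowSums(cr^2))      # m^2
    areas[l] <- sum(ar)
    # P1 surface mass matrix: A/12 * (2 I + ones)
    for (a in 1:3) for (b in 1:3) {
      Mi[[length(Mi) + 1L]] <- f[, a]
      Mj[[length(Mj) + 1L]] <- f[, b]
      Mx[[length(Mx) + 1L]] <- ar / 12 * (1 + (a == b)) / zeta[l]
    }
    for (a in 1:3) {
      Bi[[length(Bi) + 1L]] <- f[, a]
      Bj[[length(Bj) + 1L]] <- rep(l, nrow(f))
      Bx[[length(Bx) + 1L]] <- -ar / 3 / zeta[l]
    }
  }
  Msp <- Matrix::sparseMatrix(i = unlist(Mi), j = unlist(Mj), x = unlist(Mx),
                              dims = c(nn, nn))
  Bsp <- Matrix::sparseMatrix(i = unlist(Bi), j = unlist(Bj), x = unlist(Bx),
                              dims = c(nn, L))
  Dsp <- Matrix::Diagonal(L, areas / zeta)
  gauge <- Matrix::sparseMatrix(i = nn + seq_len(L), j = rep(1L, L), x = 1,
                                dims = c(nn + L, 1L))
  Sys <- rbind(cbind(Ksp + Msp, Bsp, gauge[seq_len(nn), , drop = FALSE]),
               cbind(Matrix::t(Bsp), Dsp, gauge[nn + seq_len(L), , drop = FALSE]),
               cbind(Matrix::t(gauge), Matrix::sparseMatrix(i = integer(),
                                                            j = integer(),
                                                            dims = c(1L, 1L))))
  fact <- Matrix::lu(Sys)

  # electrode-basis fields: unit current into electrode l (gauge-balanced)
  RHS <- matrix(0, nn + L + 1L, L)
  RHS[nn + seq_len(L), ] <- diag(L)
  W <- as.matrix(Matrix::solve(fact, RHS))
  structure(list(fact = fact, W_nodes = W[seq_len(nn), , drop = FALSE],
                 W_elec = W[nn + seq_len(L), , drop = FALSE],
                 grads = g, sigma = sigma, zeta = zeta, labels = labs,
                 n_nodes = nn, n_elec = L, mesh = mesh),
            class = "eit_system")
}

#' Electrode number -> column index of the electrode-basis fields
#' @noRd
electrode_column_map <- function(sys) {
  lab_of <- integer(max(as.integer(sys$labels)))
  lab_of[as.integer(sys$labels)] <- seq_along(sys$labels)
  lab_of
}

#' Per-element P1 gradient operators (units 1/m) and volumes (m^3)
#' @noRd
element_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  u <- nodes[tets[, 2L], , drop = FALSE] - p1
  v <- nodes[tets[, 3L], , drop = FALSE] - p1
  w <- nodes[tets[, 4L], , drop = FALSE] - p1
  d <- u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
       u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
       u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])
  vol <- d / 6
  # rows of inverse of [u; v; w]^T via cross products
  cvw <- cbind(v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L],
               v[, 3L] * w[, 1L] - v[, 1L] * w[, 3L],
               v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L]) / d
  cwu <- cbind(w[, 2L] * u[, 3L] - w[, 3L] * u[, 2L],
               w[, 3L] * u[, 1L] - w[, 1L] * u[, 3L],
               w[, 1L] * u[, 2L] - w[, 2L] * u[, 1L]) / d
  cuv <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
               u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
               u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]) / d
  gx <- cbind(-(cvw[, 1L] + cwu[, 1L] + cuv[, 1L]), cvw[, 1L], cwu[, 1L], cuv[, 1L])
  gy <- cbind(-(cvw[, 2L] + cwu[, 2L] + cuv[, 2L]), cvw[, 2L], cwu[, 2L], cuv[, 2L])
  gz <- cbind(-(cvw[, 3L] + cwu[, 3L] + cuv[, 3L]), cvw[, 3L], cwu[, 3L], cuv[, 3L])
  list(gx = gx, gy = gy, gz = gz, vol = vol)
}

#' Simulate one EIT frame (forward solve)
#'
#' @param mesh a `fem_mesh`, or a prebuilt [eit_system()] (faster when
#'   solving repeatedly at the same conductivity).
#' @param sigma per-element conductivity, S/m.
#' @param protocol an [eit_protocol()].
#' @param contact_impedance Ohm m^2.
#' @return list with `v` (voltages for every protocol measurement, volts),
#'   `U` (electrode potentials per injection, L x L), `system`.
#' @export
forward_solve <- function(mesh, sigma = 1, protocol = eit_protocol(),
                          contact_impedance = 1e-3) {
  sys <- if (inherits(mesh, "eit_system")) mesh
         else eit_system(mesh, sigma, contact_impedance)
  if (sys$n_elec != protocol$n_electrodes)
    stop("mesh has ", sys$n_elec, " labeled electrodes; protocol expects ",
         protocol$n_electrodes)
  lab_of <- electrode_column_map(sys)
  m <- protocol$measurements
  Ue <- sys$W_elec
  I0 <- protocol$current_amplitude
  v <- I0 * (Ue[cbind(lab_of[m[, "meas_pos"]], lab_of[m[, "drive_pos"]])] -
             Ue[cbind(lab_of[m[, "meas_neg"]], lab_of[m[, "drive_pos"]])] -
             Ue[cbind(lab_of[m[, "meas_pos"]], lab_of[m[, "drive_neg"]])] +
             Ue[cbind(lab_of[m[, "meas_neg"]], lab_of[m[, "drive_neg"]])])
  list(v = v, U = Ue, system = sys)
}

#' Sensitivity (Jacobian) of the measurements to element conductivity
#'
#' Adjoint-field formula: the derivative of measurement (drive pair d,
#' measurement pair m) with respect to the conductivity of element e is
#' `-vol_e grad(u_d) . grad(u_m)` with the measurement field normalized to
#' unit current.
#'
#' @param mesh a `fem_mesh` or prebuilt [eit_system()].
#' @param sigma0 baseline conductivity (used when building the system).
#' @param protocol an [eit_protocol()].
#' @param contact_impedance Ohm m^2.
#' @return list with `J` (n_meas x n_elements), `v0` (baseline voltages)
#'   and `system`.
#' @export
eit_jacobian <- function(mesh, sigma0 = 1, protocol = eit_protocol(),
                         contact_impedance = 1e-3) {
  sys <- if (inherits(mesh, "eit_system")) mesh
         else eit_system(mesh, sigma0, contact_impedance)
  fw <- forward_solve(sys, protocol = protocol)
  g <- sys$grads
  tets <- sys$mesh$tets
  lab_of <- electrode_column_map(sys)
  # per-element gradient of each electrode-basis field
  ne <- nrow(tets); L <- sys$n_elec
  GX <- GY <- GZ <- matrix(0, ne, L)
  for (l in seq_len(L)) {
    u <- sys$W_nodes[, l]
    un <- matrix(u[tets], ne, 4L)
    GX[, l] <- rowSums(g$gx * un)
    GY[, l] <- rowSums(g$gy * un)
    GZ[, l] <- rowSums(g$gz * un)
  }
  m <- protocol$measurements
  I0 <- protocol$current_amplitude
  J <- matrix(0, nrow(m), ne)
  for (r in seq_len(nrow(m))) {
    dp <- lab_of[m[r, "drive_pos"]]; dn <- lab_of[m[r, "drive_neg"]]
    mp <- lab_of[m[r, "meas_pos"]]; mn <- lab_of[m[r, "meas_neg"]]
    J[r, ] <- -g$vol * I0 *
      ((GX[, dp] - GX[, dn]) * (GX[, mp] - GX[, mn]) +
       (GY[, dp] - GY[, dn]) * (GY[, mp] - GY[, mn]) +
       (GZ[, dp] - GZ[, dn]) * (GZ[, mp] - GZ[, mn]))
  }
  list(J = J, v0 = fw$v, system = sys)
}

#' Reconstruction configuration
#'
#' @param lambda Tikhonov weight applied to the normalized problem (> 0).
#'   The default was chosen by an L-curve sweep on the synthetic two-lung
#'   phantom.
#' @param background_sigma baseline conductivity, S/m (relative scale).
#' @param contact_impedance Ohm m^2 per electrode.
#' @export
recon_config <- function(lambda = 1e-7, background_sigma = 1,
                         contact_impedance = 1e-3) {
  if (!(lambda > 0)) stop("lambda must be > 0")
  structure(list(lambda = lambda, background_sigma = background_sigma,
                 contact_impedance = contact_impedance),
            class = "recon_config")
}

#' One-step Gauss-Newton Tikhonov difference reconstruction
#'
#' With normalized voltage data b = (v1 - v0)/v0 and the row-normalized
#' Jacobian Jn = J / v0, returns
#' delta-sigma = (Jn' Jn + lambda I)^-1 Jn' b, computed through the
#' equivalent measurement-space system Jn' (Jn Jn' + lambda I)^-1 b.
#'
#' @param J sensitivity matrix (n_meas x n_elements) at the baseline.
#' @param v0 baseline voltage vector.
#' @param v1 data voltage vector.
#' @param config a [recon_config()].
#' @param mask logical channel mask; masked-out rows are excluded.
#' @return per-element conductivity change (delta sigma), length
#'   n_elements.
#' @export
reconstruct <- function(J, v0, v1, config = recon_config(), mask = NULL) {
  if (!inherits(config, "recon_config")) stop("config must be a recon_config")
  op <- if (inherits(J, "recon_operator")) J else recon_operator(J, mask)
  if (!is.null(mask) && !identical(mask, op$mask))
    stop("mask differs from the one the recon_operator was built with")
  mask <- op$mask
  if (any(v0[mask] == 0)) stop("baseline voltage contains zeros on unmasked channels")
  b <- (v1[mask] - v0[mask]) / v0[mask]
  w <- 1 / v0[mask]
  # Jn = diag(w) J, so Jn Jn' = diag(w) (J J') diag(w): the big Gram is
  # computed once in the operator and reweighted per baseline
  G <- op$JJT * tcrossprod(w)
  diag(G) <- diag(G) + config$lambda
  as.vector(crossprod(op$J, w * solve(G, b)))
}

#' Precompute the reconstruction operator for repeated calls
#'
#' Stores the masked Jacobian and its Gram matrix J J' so that repeated
#' [reconstruct()] calls (e.g. over noise realizations or frames) cost
#' only a measurement-space solve each.
#'
#' @param J sensitivity matrix (n_meas x n_elements).
#' @param mask logical channel mask (`NULL`: all channels).
#' @return object of class `recon_operator`.
#' @export
recon_operator <- function(J, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(J))
  Jm <- J[mask, , drop = FALSE]
  structure(list(J = Jm, JJT = tcrossprod(Jm), mask = mask),
            class = "recon_operator")
}

#' EIT voltage frame series
#'
#' @param frames n_meas x n_frames matrix, volts.
#' @param timestamps frame times, s.
#' @param protocol the [eit_protocol()] that produced the frames.
#' @param channel_mask logical per measurement; masked channels are
#'   excluded from norms and reconstruction.
#' @export
eit_frameset <- function(frames, timestamps = NULL, protocol = eit_protocol(),
                         channel_mask = NULL) {
  frames <- as.matrix(frames)
  if (is.null(timestamps))
    timestamps <- (seq_len(ncol(frames)) - 1L) / protocol$frame_rate
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nrow(frames))
  if (length(channel_mask) != nrow(frames))
    stop("channel_mask length must equal the measurement count")
  if (nrow(frames) != nrow(protocol$measurements))
    stop("frame rows (", nrow(frames), ") != protocol measurements (",
         nrow(protocol$measurements), ")")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 protocol = protocol, channel_mask = channel_mask),
            class = "eit_frames")
}

#' @export
print.eit_frames <- function(x, ...) {
  cat(sprintf("<eit_frames> %d channels x %d frames (%.1f s at %.1f Hz), %d masked\n",
              nrow(x$frames), ncol(x$frames), diff(range(x$timestamps)),
              x$protocol$frame_rate, sum(!x$channel_mask)))
  invisible(x)
}

#' Mask noisy measurement channels
#'
#' A simple variance screen standing in for device-specific impedance
#' filters: the noise statistic is the relative variance of the
#' frame-to-frame differences, var(diff(v))/(2 mean(v)^2), which is blind
#' to the slow breathing modulation but picks up broadband channel noise.
#' Channels above both an absolute floor and a multiple of the median are
#' masked (channels involving injecting electrodes are already excluded
#' by the protocol).
#'
#' @param frames an [eit_frameset()].
#' @param rel_var_floor absolute relative noise-variance threshold.
#' @param median_factor mask when above this multiple of the median
#'   relative noise variance.
#' @param hard_cap channels above this relative variance are always
#'   masked.
#' @param min_fraction error (`too-few-channels`) when fewer than this
#'   fraction survive.
#' @return logical mask (TRUE = keep).
#' @export
filter_channels <- function(frames, rel_var_floor = 1e-4, median_factor = 25,
                            hard_cap = 0.25, min_fraction = 0.5) {
  v <- frames$frames
  if (ncol(v) < 3L) stop("need at least 3 frames to assess channel noise")
  mu <- rowMeans(v)
  dv <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  rv <- apply(dv, 1L, stats::var) / (2 * pmax(mu^2, 1e-300))
  thr <- max(median_factor * stats::median(rv), rel_var_floor)
  mask <- rv <= thr & rv <= hard_cap
  if (mean(mask) < min_fraction)
    stop(ply_err("too_few_channels",
                 sprintf("only %d/%d channels pass the noise filter",
                         sum(mask), length(mask))))
  mask
}

#' Global breathing signal and breath detection
#'
#' The global signal is the per-frame sum of unmasked voltage magnitudes;
#' inhale peaks and exhale troughs are found by prominence-based peak
#' detection on the lightly smoothed signal.
#'
#' @param frames an [eit_frameset()].
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   signal range.
#' @return list with `signal`, `peaks`, `troughs` (frame indices).
#' @export
breath_detect <- function(frames, min_prominence_frac = 0.25) {
  mask <- frames$channel_mask
  sig <- colSums(abs(frames$frames[mask, , drop = FALSE]))
  # ~0.25 s moving-average smoothing
  w <- max(1L, round(frames$protocol$frame_rate * 0.25))
  sm <- stats::filter(sig, rep(1 / w, w), sides = 2L)
  sm[is.na(sm)] <- sig[is.na(sm)]
  sm <- as.numeric(sm)
  rng <- diff(range(sm))
  if (rng <= 0) return(list(signal = sig, peaks = integer(), troughs = integer()))
  peaks <- prominent_peaks(sm, min_prominence_frac * rng)
  troughs <- prominent_peaks(-sm, min_prominence_frac * rng)
  list(signal = sig, smoothed = sm, peaks = peaks, troughs = troughs)
}

#' Indices of local maxima with prominence above `min_prom`
#' @noRd
prominent_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left/right to the first higher point; prominence is peak minus
    # the higher of the two interval minima
    lmin <- x[i]; j <- i
    while (j > 1L && x[j] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    if (j == 1L && x[j] <= x[i]) lmin <- min(lmin, x[1L])
    rmin <- x[i]; j <- i
    while (j < n && x[j] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    if (j == n && x[j] <= x[i]) rmin <- min(rmin, x[n])
    base <- max(lmin, rmin)
    # peaks at the global max have no higher neighbour: use the lower side
    if (lmin == min(x[1:i]) && x[i] >= max(x)) base <- max(min(x[1:i]), rmin)
    keep[k] <- (x[i] - base) >= min_prom
  }
  cand[keep]
}

#' Tidal-breathing difference image
#'
#' Averages the frames at the detected inhale peaks (v1) and exhale
#' troughs (v0) of the global signal and reconstructs the conductivity
#' change between them: inflated lungs appear as negative delta-sigma.
#'
#' @param frames an [eit_frameset()].
#' @param J baseline Jacobian (from [eit_jacobian()] on the subject mesh).
#' @param v0_model optional baseline voltages; defaults to the trough mean.
#' @param config a [recon_config()].
#' @return list with `image` (per-element delta sigma), `n_breaths`,
#'   `peaks`, `troughs`.
#' @export
tidal_image <- function(frames, J, config = recon_config(), v0_model = NULL) {
  bd <- breath_detect(frames)
  n_breaths <- min(length(bd$peaks), length(bd$troughs))
  if (n_breaths < 2L)
    stop(ply_err("no_breaths", "fewer than 2 breaths detected in recording"))
  v1 <- rowMeans(frames$frames[, bd$peaks, drop = FALSE])
  v0 <- rowMeans(frames$frames[, bd$troughs, drop = FALSE])
  img <- reconstruct(J, v0, v1, config, mask = frames$channel_mask)
  list(image = img, n_breaths = n_breaths, peaks = bd$peaks,
       troughs = bd$troughs, v0 = v0, v1 = v1)
}

#' Simulate a tidal-breathing EIT recording on a phantom mesh
#'
#' Two ellipsoidal lung regions oscillate as
#' sigma_lung(t) = sigma0 (1 - depth (1 + sin 2 pi f t)/2); frames are
#' forward-solved at a small set of modulation levels and interpolated
#' per channel (the response is smooth in the modulation), then
#' multiplicative Gaussian noise is applied. Deterministic per seed.
#'
#' @param mesh a `fem_mesh` with 32 labeled electrodes.
#' @param lungs lung region definition (from `make_scan()` truth):
#'   list of `center`/`semi` ellipsoids, mm.
#' @param protocol an [eit_protocol()].
#' @param breath_rate breathing frequency, Hz.
#' @param depth fractional conductivity decrease at full inhale.
#' @param duration recording length, s.
#' @param noise_rel relative measurement noise SD.
#' @param sigma0 background conductivity, S/m.
#' @param seed RNG seed.
#' @param n_interp number of forward solves across the modulation range.
#' @return an [eit_frameset()].
#' @export
make_eit_sequence <- function(mesh, lungs, protocol = eit_protocol(),
                              breath_rate = 0.25, depth = 0.2, duration = 30,
                              noise_rel = 1e-3, sigma0 = 1, seed = 1L,
                              n_interp = 7L) {
  lung_el <- lung_elements(mesh, lungs)
  if (sum(lung_el) == 0L) stop("no mesh elements inside the lung regions")
  ms <- seq(0, 1, length.out = max(3L, n_interp))
  Vs <- sapply(ms, function(m) {
    sg <- rep(sigma0, nrow(mesh$tets))
    sg[lung_el] <- sigma0 * (1 - depth * m)
    forward_solve(mesh, sg, protocol)$v
  })
  nfr <- round(duration * protocol$frame_rate)
  t <- (seq_len(nfr) - 1L) / protocol$frame_rate
  mt <- (1 + sin(2 * pi * breath_rate * t)) / 2
  frames <- matrix(0, nrow(Vs), nfr)
  for (ch in seq_len(nrow(Vs))) {
    frames[ch, ] <- stats::spline(ms, Vs[ch, ], xout = mt)$y
  }
  with_seed(seed, {
    if (noise_rel > 0)
      frames <- frames * (1 + matrix(stats::rnorm(length(frames), 0, noise_rel),
                                     nrow(frames)))
    eit_frameset(frames, t, protocol)
  })
}

#' Logical index of mesh elements inside the lung ellipsoids
#' @param mesh a `fem_mesh`.
#' @param lungs list of ellipsoids with `center` and `semi` (mm).
#' @export
lung_elements <- function(mesh, lungs) {
  cen <- element_centroids(mesh)
  inside <- rep(FALSE, nrow(cen))
  for (lg in lungs) {
    d <- sweep(cen, 2L, lg$center)
    inside <- inside | rowSums(sweep(d, 2L, lg$semi, "/")^2) <= 1
  }
  inside
}

#' Read / write EIT frame matrices as CSV (channels x frames)
#' @param frames an [eit_frameset()] (write) .
#' @param path CSV path.
#' @param protocol protocol for [read_eit_frames()].
#' @export
write_eit_frames <- function(frames, path) {
  utils::write.table(frames$frames, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_eit_frames
#' @export
read_eit_frames <- function(path, protocol = eit_protocol()) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  eit_frameset(m, protocol = protocol)
}
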