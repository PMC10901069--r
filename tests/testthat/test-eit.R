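test_that("the skip-4 protocol enumerates the expected measurements", {
  p <- eit_protocol()
  m <- p$measurements
  expect_equal(nrow(m), 32 * 29)
  # injection pairs are (i, i+5) mod 32
  expect_setequal(unique(paste(m[, 1], m[, 2])),
                  paste(1:32, ((1:32 + 4) %% 32) + 1))
  # no measurement touches an injecting electrode
  expect_false(any(m[, 3] == m[, 1] | m[, 3] == m[, 2] |
                   m[, 4] == m[, 1] | m[, 4] == m[, 2]))
})

test_that("forward solves scale with conductivity and obey reciprocity", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  f1 <- forward_solve(fx$mesh, sigma = 1, protocol = prot,
                      contact_impedance = 1e-3)
  # exact scaling: doubling sigma and halving contact impedance halves v
  f2 <- forward_solve(fx$mesh, sigma = 2, protocol = prot,
                      contact_impedance = 5e-4)
  expect_lt(max(abs(2 * f2$v - f1$v) / abs(f1$v)), 1e-9)
  # with fixed contact impedance the halving is approximate (contact term)
  f3 <- forward_solve(fx$mesh, sigma = 2, protocol = prot,
                      contact_impedance = 1e-3)
  expect_lt(max(abs(2 * f3$v - f1$v) / abs(f1$v)), 0.02)
  # reciprocity: the electrode transfer matrix is symmetric
  U <- as.matrix(f1$U)
  expect_lt(max(abs(U - t(U))) / max(abs(U)), 1e-8)
})

test_that("forward measurements converge under mesh refinement", {
  fx <- eit_fixture()
  fine <- eit_fixture_fine()
  prot <- eit_protocol()
  v_c <- forward_solve(fx$mesh, protocol = prot)$v
  v_f <- forward_solve(fine, protocol = prot)$v
  expect_lt(median(abs(v_c - v_f) / abs(v_f)), 0.02)
})

test_that("the adjoint Jacobian matches central finite differences", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  jac <- eit_jac()
  set.seed(12)
  for (e0 in sample(nrow(fx$mesh$tets), 2)) {
    d <- 1e-4
    sp <- rep(1, nrow(fx$mesh$tets)); sp[e0] <- 1 + d
    sm <- rep(1, nrow(fx$mesh$tets)); sm[e0] <- 1 - d
    fd <- (forward_solve(fx$mesh, sp, prot)$v -
           forward_solve(fx$mesh, sm, prot)$v) / (2 * d)
    expect_lt(max(abs(fd - jac$J[, e0])) / max(abs(jac$J[, e0])), 0.01)
  }
})

test_that("summing J sigma over elements recovers -v up to the contact term", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  # with a small contact impedance the Euler relation J sigma = -v is tight
  sys <- eit_system(fx$mesh, sigma = 1, contact_impedance = 1e-7)
  jac <- eit_jacobian(sys, protocol = prot)
  lhs <- as.vector(jac$J %*% rep(1, ncol(jac$J)))
  expect_lt(median(abs(lhs + jac$v0) / abs(jac$v0)), 0.05)
})

test_that("degenerate meshes are rejected by the solver", {
  bad <- eit_fixture()$mesh
  bad$tets[1, ] <- c(1L, 2L, 3L, 3L)  # zero-volume element
  expect_error(eit_system(bad), "volume")
})

test_that("reconstruction basics: zero difference, Tikhonov limit, linearity", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  jac <- eit_jac()
  v0 <- jac$v0
  expect_equal(reconstruct(jac$op, v0, v0), rep(0, ncol(jac$J)))
  set.seed(13)
  v1 <- v0 * (1 + rnorm(length(v0), 0, 0.02))
  norms <- sapply(c(1e-6, 1e0, 1e6, 1e12), function(l)
    sqrt(sum(reconstruct(jac$op, v0, v1, recon_config(lambda = l))^2)))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4] / norms[1], 1e-6)
  # linearity in the data at fixed lambda
  v2 <- v0 * (1 + rnorm(length(v0), 0, 0.02))
  cfg <- recon_config(lambda = 1e-7)
  r12 <- reconstruct(jac$op, v0, v0 + (v1 - v0) + (v2 - v0), cfg)
  expect_equal(r12, reconstruct(jac$op, v0, v1, cfg) +
                    reconstruct(jac$op, v0, v2, cfg), tolerance = 1e-8)
  expect_error(recon_config(lambda = 0), "lambda")
})

test_that("a conductivity drop in one quadrant is localized there", {
  fx <- eit_fixture()
  fine <- eit_fixture_fine()
  prot <- eit_protocol()
  jac <- eit_jac()
  cen_f <- element_centroids(fine)
  incl <- cen_f[, 1] > 0 & cen_f[, 2] > 0
  sg <- rep(1, nrow(fine$tets)); sg[incl] <- 0.8
  v0 <- forward_solve(fine, protocol = prot)$v
  v1 <- forward_solve(fine, sg, prot)$v
  img <- reconstruct(jac$op, v0, v1)
  cen_c <- element_centroids(fx$mesh)
  qmin <- cen_c[which.min(img), ]
  expect_gt(qmin[1], 0)
  expect_gt(qmin[2], 0)
})

test_that("noisy channels are masked and hopeless recordings error", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  fr <- make_eit_sequence(fx$mesh, fx$phantom$truth$lungs, prot,
                          duration = 6, noise_rel = 1e-3, seed = 14)
  expect_true(all(filter_channels(fr)))
  fr2 <- fr
  set.seed(15)
  fr2$frames[100, ] <- fr2$frames[100, ] *
    (1 + rnorm(ncol(fr2$frames), 0, 0.1))
  mask <- filter_channels(fr2)
  expect_false(mask[100])
  expect_gt(mean(mask), 0.99)
  fr3 <- fr
  fr3$frames <- fr3$frames * matrix(exp(rnorm(length(fr3$frames), 0, 1)),
                                    nrow(fr3$frames))
  expect_error(filter_channels(fr3), class = "scan2fem_too_few_channels")
})

test_that("breath detection counts tidal cycles and flags flat signals", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  fr <- make_eit_sequence(fx$mesh, fx$phantom$truth$lungs, prot,
                          breath_rate = 0.25, depth = 0.15, duration = 30,
                          noise_rel = 1e-3, seed = 16)
  bd <- breath_detect(fr)
  expect_true(length(bd$peaks) %in% c(7L, 8L))
  flat <- eit_frameset(matrix(1e-3, nrow(prot$measurements), 100),
                       protocol = prot)
  expect_error(tidal_image(flat, matrix(0, nrow(prot$measurements), 4)),
               class = "scan2fem_no_breaths")
})

test_that("doubling the breathing depth doubles the signal amplitude", {
  fx <- eit_fixture()
  prot <- eit_protocol()
  amp <- sapply(c(0.05, 0.1), function(dep) {
    fr <- make_eit_sequence(fx$mesh, fx$phantom$truth$lungs, prot,
                            depth = dep, duration = 12, noise_rel = 0,
                            seed = 17)
    s <- breath_detect(fr)$signal
    max(s) - min(s)
  })
  expect_lt(abs(amp[2] / amp[1] - 2), 0.25)
})

test_that("a two-lung tidal recording reconstructs both lungs as negative", {
  fx <- eit_fixture()
  fine <- eit_fixture_fine()
  prot <- eit_protocol()
  jac <- eit_jac()
  fr <- make_eit_sequence(fine, fx$phantom$truth$lungs, prot,
                          breath_rate = 0.25, depth = 0.2, duration = 30,
                          noise_rel = 0.01, seed = 18)
  td <- tidal_image(fr, jac$op)
  expect_gte(td$n_breaths, 2)
  lungc <- lung_elements(fx$mesh, fx$phantom$truth$lungs)
  lft <- lung_elements(fx$mesh, fx$phantom$truth$lungs["left"])
  rgt <- lung_elements(fx$mesh, fx$phantom$truth$lungs["right"])
  expect_lt(mean(td$image[lft]), 0)
  expect_lt(mean(td$image[rgt]), 0)
  expect_lt(mean(td$image[lft]), mean(td$image[!lungc]))
  expect_lt(mean(td$image[rgt]), mean(td$image[!lungc]))
})
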