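test_that("the default model has exactly 175 free parameters", {
  ph <- phantom_clean()
  es <- electrode_set(ph$truth$centers, ph$truth$labels)
  lev <- apply_leveling(ph$surface, es)
  fit <- fit_surface(lev$surface)
  expect_identical(fit$n_params, 175L)
  expect_identical(dim(fit$coeffs), c(25L, 7L))
})

test_that("a circular cylinder is reproduced exactly by the constant mode", {
  tube <- sample_mesh(cylinder_model(), 150, 20)
  fit <- fit_surface(tube$vertices)
  th <- runif(400, -pi, pi); zz <- runif(400, -55, 55)
  expect_lt(max(abs(fit_radius(fit, th, zz) - 150)), 1e-6)
  # non-constant Fourier rows vanish
  expect_lt(max(abs(fit$coeffs[-1, ])), 1e-6)
  expect_lt(fit$rms, 1e-6)
})

test_that("an elliptic cylinder matches the analytic polar radius", {
  a <- 160; b <- 120
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  zz <- seq(-60, 60, length.out = 25)
  g <- expand.grid(th = th, z = zz)
  r <- a * b / sqrt((b * cos(g$th))^2 + (a * sin(g$th))^2)
  fit <- fit_surface(cbind(r * cos(g$th), r * sin(g$th), g$z))
  th_test <- seq(0, 2 * pi, length.out = 361)[-361]
  r_true <- a * b / sqrt((b * cos(th_test))^2 + (a * sin(th_test))^2)
  expect_lt(max(abs(fit_radius(fit, th_test, 0) - r_true)), 0.1)
})

test_that("fit residual stays near the noise floor on noisy phantoms", {
  ph <- make_scan(phantom_spec(perimeter = 1048, resolution = 3,
                               vertex_noise_sd = 1, seed = 41))
  id <- identify_electrodes(ph$surface)
  lev <- apply_leveling(ph$surface, id$electrodes)
  fit <- fit_surface(lev$surface)
  expect_lte(fit$rms, 1.5)
})

test_that("known coefficients are recovered from noisy samples", {
  truth <- cylinder_model()
  set.seed(7)
  truth$coeffs <- truth$coeffs + matrix(rnorm(length(truth$coeffs), 0, 2),
                                        nrow(truth$coeffs))
  truth$coeffs[1, ] <- 150
  th <- runif(60000, -pi, pi); zz <- runif(60000, -60, 60)
  p <- evaluate_fit(truth, th, zz) + matrix(rnorm(180000, 0, 0.5), ncol = 3)
  fit <- fit_surface(p, z_range = c(-60, 60), max_points = 60000L)
  expect_lt(sqrt(mean((fit$coeffs - truth$coeffs)^2)), 0.2)
})

test_that("residual decreases monotonically with Fourier order", {
  a <- 160; b <- 120
  th <- seq(0, 2 * pi, length.out = 301)[-301]
  zz <- seq(-60, 60, length.out = 35)
  g <- expand.grid(th = th, z = zz)
  r <- a * b / sqrt((b * cos(g$th))^2 + (a * sin(g$th))^2)
  pts <- cbind(r * cos(g$th), r * sin(g$th), g$z)
  rms <- sapply(c(2, 4, 8, 12), function(N)
    fit_surface(pts, fourier_order = N)$rms)
  expect_true(all(diff(rms) < 0))
})

test_that("the fit is invariant to vertex ordering", {
  tube <- sample_mesh(cylinder_model(140), 150, 14)
  set.seed(3)
  perm <- sample(nrow(tube$vertices))
  f1 <- fit_surface(tube$vertices)
  f2 <- fit_surface(tube$vertices[perm, ])
  expect_equal(f1$coeffs, f2$coeffs, tolerance = 1e-9)
})

test_that("evaluate and signed_distance are consistent", {
  m <- cylinder_model()
  th <- runif(200, -pi, pi); zz <- runif(200, -59, 59)
  p <- evaluate_fit(m, th, zz)
  expect_lt(max(abs(signed_distance(m, p))), 1e-6)
  expect_equal(signed_distance(m, rbind(c(0, 0, 0))), -150)
  # random exterior points vs brute-force nearest sampled surface point
  q <- cbind(200 * cos(th[1:20]), 200 * sin(th[1:20]), zz[1:20])
  dense <- sample_mesh(m, 720, 60)
  for (i in 1:20) {
    brute <- min(sqrt(rowSums(sweep(dense$vertices, 2, q[i, ])^2)))
    expect_equal(signed_distance(m, q[i, , drop = FALSE]), brute,
                 tolerance = 0.05)
  }
})

test_that("sample_mesh produces the promised tube topology", {
  m <- cylinder_model()
  s <- sample_mesh(m, 4, 2)
  expect_equal(nrow(s$vertices), 8)
  expect_equal(nrow(s$faces), 8)
  # refit of a sampled cylinder reproduces the coefficients
  s2 <- sample_mesh(m, 150, 20)
  fit <- fit_surface(s2$vertices, z_range = m$z_range)
  expect_lt(max(abs(fit$coeffs - m$coeffs)), 1e-6)
})

test_that("the fitted mid-slice perimeter matches the phantom belt", {
  ph <- phantom_clean()
  id <- identify_electrodes(ph$surface)
  lev <- apply_leveling(ph$surface, id$electrodes)
  fit <- fit_surface(lev$surface)
  expect_lt(abs(fit_perimeter(fit, 0) / 1048 - 1), 0.01)
})

test_that("degenerate height ranges raise thin-band errors", {
  tube <- sample_mesh(cylinder_model(), 150, 20)
  expect_error(fit_surface(tube$vertices, rbf_width = 200),
               class = "scan2fem_thin_band")
})
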