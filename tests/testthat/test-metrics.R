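random_electrodes <- function(n = 32, seed = 1) {
  set.seed(seed)
  th <- 2 * pi * (0:(n - 1)) / n
  electrode_set(cbind(150 * cos(th), 120 * sin(th), rnorm(n, 0, 4)), 1:n)
}

test_that("rigid_align recovers pure translations exactly", {
  a <- random_electrodes()
  b <- a; b$positions <- sweep(a$positions, 2, c(-10, 0, 0))
  tr <- rigid_align(a, b)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$translation, c(10, 0, 0), tolerance = 1e-12)
  rep <- electrode_error(a, b, align = TRUE)
  expect_lt(rep$rms, 1e-10)
})

test_that("rigid_align recovers a known rotation under noise within 0.5 deg", {
  a <- random_electrodes(seed = 2)
  ang <- 15 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  set.seed(3)
  b <- a
  b$positions <- a$positions %*% t(Rz) +
    matrix(rnorm(3 * 32, 0, 0.5), ncol = 3)
  tr <- rigid_align(a, b)
  rel <- tr$rotation %*% t(Rz)
  ang_err <- acos(min(1, (sum(diag(rel)) - 1) / 2)) * 180 / pi
  expect_lt(ang_err, 0.5)
})

test_that("rigid_align agrees with vegan procrustes", {
  a <- random_electrodes(seed = 4)
  ang <- 0.4
  R0 <- scan2fem:::minimal_rotation(c(0, 0, 1), c(0.2, 0.3, 0.93))
  b <- a; b$positions <- a$positions %*% t(R0) + 7
  tr <- rigid_align(a, b)
  pr <- vegan::procrustes(b$positions, a$positions, scale = FALSE)
  expect_equal(tr$rotation, t(pr$rotation), tolerance = 1e-8)
})

test_that("too few correspondences raise an error", {
  a <- random_electrodes()
  b <- electrode_set(a$positions[1:2, ], 1:2)
  expect_error(rigid_align(a, b),
               class = "scan2fem_insufficient_correspondence")
})

test_that("electrode_error reports exact and radial perturbations", {
  a <- random_electrodes(seed = 5)
  expect_equal(electrode_error(a, a, align = FALSE)$rms, 0)
  # move every point 2 mm radially outward (in-plane)
  b <- a
  rxy <- sqrt(rowSums(a$positions[, 1:2]^2))
  b$positions[, 1:2] <- a$positions[, 1:2] * (1 + 2 / rxy)
  rep <- electrode_error(a, b, align = FALSE)
  expect_equal(rep$rms, 2, tolerance = 1e-9)
  expect_equal(rep$max, 2, tolerance = 1e-9)
  expect_equal(rep$rms, sqrt(mean(rep$per_electrode^2)), tolerance = 1e-12)
  expect_lte(rep$rms, rep$max)
})

test_that("isotropic 3 mm/axis noise gives RMS near 3*sqrt(3)", {
  a <- random_electrodes(seed = 6)
  rms <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    b <- a
    b$positions <- a$positions + matrix(rnorm(96, 0, 3), ncol = 3)
    electrode_error(a, b, align = FALSE)$rms
  })
  expect_lt(abs(mean(rms) / (3 * sqrt(3)) - 1), 0.15)
})

test_that("aligned errors are invariant to rigid transforms of either input", {
  a <- random_electrodes(seed = 7)
  set.seed(8)
  b <- a; b$positions <- a$positions + matrix(rnorm(96, 0, 2), ncol = 3)
  e0 <- electrode_error(a, b, align = TRUE)
  R0 <- scan2fem:::minimal_rotation(c(0, 0, 1), c(-0.3, 0.1, 0.95))
  b2 <- b; b2$positions <- sweep(b$positions %*% t(R0), 2, -c(30, -40, 5))
  e1 <- electrode_error(a, b2, align = TRUE)
  expect_equal(e1$rms, e0$rms, tolerance = 1e-9)
  expect_equal(e1$per_electrode, e0$per_electrode, tolerance = 1e-8)
})

test_that("occluded electrodes are dropped pairwise", {
  a <- random_electrodes(seed = 9)
  b <- electrode_set(a$positions[-(2:6), ], setdiff(1:32, 2:6))
  rep <- electrode_error(a, b, align = TRUE)
  expect_equal(rep$n_pairs, 27)
})

test_that("contour distances are exact on analytic cases", {
  fx <- eit_fixture()
  # contour sampled on the triangulated surface itself
  s <- fx$belt$surface
  idx <- seq(1, nrow(s$vertices), by = 23)
  c0 <- contour_to_surface(s$vertices[idx, ], s)
  expect_lt(max(c0$distances), 1e-6)
  # cylinder offset 4 mm along the normals
  m <- cylinder_model()
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  off <- cbind(154 * cos(th), 154 * sin(th), 10)
  cf <- contour_to_surface(off, m)
  expect_lt(abs(cf$mean / 4 - 1), 0.01)
  expect_error(contour_to_surface(matrix(numeric(), 0, 3), m), "empty")
})

test_that("accelerated surface queries match the all-triangle scan", {
  fx <- eit_fixture()
  s <- fx$belt$surface
  set.seed(10)
  q <- cbind(runif(100, -120, 120), runif(100, -120, 120), runif(100, -30, 30))
  fast <- surface_distance(q, s)$distance
  slow <- vapply(seq_len(nrow(q)), function(i)
    scan2fem:::point_tri_dist(q[i, ], s$vertices, s$faces)$distance, 1)
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("precision_report compares all scan pairs", {
  a <- random_electrodes(seed = 11)
  pr <- precision_report(list(a, a, a))
  expect_equal(pr$n_comparisons, 3)
  expect_equal(pr$rms_mean, 0)
  expect_equal(pr$max_mean, 0)
  scans4 <- lapply(1:4, function(s) {
    set.seed(s)
    b <- a; b$positions <- a$positions + matrix(rnorm(96, 0, 1), ncol = 3)
    b
  })
  pr4 <- precision_report(scans4)
  expect_equal(pr4$n_comparisons, 6)
  expect_gt(pr4$rms_mean, 0)
})

test_that("electrode CSVs round-trip", {
  a <- random_electrodes(seed = 12)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_electrodes(a, tf)
  b <- read_electrodes(tf)
  expect_equal(b$positions, a$positions)
  expect_equal(b$labels, a$labels)
})
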