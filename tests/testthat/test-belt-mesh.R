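test_that("mesh_config validates its invariants", {
  expect_error(mesh_config(h_electrode = 6, h_background = 5), "h_electrode")
  expect_error(mesh_config(h_electrode = 2, electrode_radius = 1),
               "electrode_radius")
  expect_silent(mesh_config(h_electrode = 2, h_background = 10))
})

test_that("an electrode disc is resolved with the right facet area", {
  m <- cylinder_model()
  es <- electrode_set(rbind(c(150, 0, 0)), 1L)
  set.seed(42)
  rs <- suppressMessages(remesh_surface(
    m, es, mesh_config(h_electrode = 2, h_background = 10,
                       electrode_radius = 5, max_iter = 250)))
  area <- sum(triangle_areas(rs$surface)[rs$labels[["1"]]])
  expect_lt(abs(area / (pi * 25) - 1), 0.05)
})

test_that("32 electrodes give disjoint connected labeled patches", {
  fx <- eit_fixture()
  labs <- fx$belt$labels
  expect_length(labs, 32)
  all_f <- unlist(labs)
  expect_equal(anyDuplicated(all_f), 0L)
  faces <- fx$belt$surface$faces
  for (l in names(labs)) {
    f <- faces[labs[[l]], , drop = FALSE]
    # patch connectivity through shared edges
    ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    g <- igraph::graph_from_edgelist(
      matrix(match(ed, unique(as.vector(f))), ncol = 2), directed = FALSE)
    expect_equal(igraph::components(g)$no, 1L)
  }
})

test_that("background edge lengths honour the sizing field", {
  fx <- eit_fixture()
  s <- fx$belt$surface
  e <- scan2fem:::surface_edges(s$faces)
  mid <- (s$vertices[e[, 1], ] + s$vertices[e[, 2], ]) / 2
  len <- sqrt(rowSums((s$vertices[e[, 1], ] - s$vertices[e[, 2], ])^2))
  dmin <- FNN::get.knnx(fx$belt$electrode_centers, mid, k = 1)$nn.dist[, 1]
  far <- dmin > 3 * 5
  expect_lt(abs(median(len[far]) / 15 - 1), 0.2)
})

test_that("uniform-h remeshing of a sphere band reproduces h", {
  set.seed(8)
  R <- 80
  th <- runif(6000, 0, 2 * pi); zz <- runif(6000, -64, 64)
  sph <- fit_surface(cbind(sqrt(R^2 - zz^2) * cos(th),
                           sqrt(R^2 - zz^2) * sin(th), zz),
                     fourier_order = 2, n_centers = 12)
  rs <- suppressMessages(remesh_surface(
    sph, NULL, mesh_config(h_electrode = 8, h_background = 8,
                           electrode_radius = 10, max_iter = 400)))
  e <- scan2fem:::surface_edges(rs$surface$faces)
  len <- sqrt(rowSums((rs$surface$vertices[e[, 1], ] -
                       rs$surface$vertices[e[, 2], ])^2))
  expect_lt(abs(median(len) / 8 - 1), 0.15)
  expect_lt(abs(mean(len) / 8 - 1), 0.15)
})

test_that("halving h roughly quadruples the triangle count", {
  m <- cylinder_model(R = 100, zr = c(-40, 40))
  set.seed(9)
  n_tri <- sapply(c(16, 8), function(h) {
    rs <- suppressMessages(remesh_surface(
      m, NULL, mesh_config(h_electrode = h, h_background = h,
                           electrode_radius = 2 * h, max_iter = 120)))
    nrow(rs$surface$faces)
  })
  ratio <- n_tri[2] / n_tri[1]
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)
})

test_that("overlapping electrode discs are rejected", {
  m <- cylinder_model()
  es <- electrode_set(rbind(c(150, 0, 0),
                            evaluate_fit(m, 0.04, 0)), 1:2)
  expect_error(remesh_surface(m, es, mesh_config(h_electrode = 2,
                                                 h_background = 10)),
               class = "scan2fem_electrode_overlap")
})

test_that("prism splitting fills right prisms exactly and conforms", {
  set.seed(10)
  for (rep in 1:20) {
    tri <- matrix(runif(6, 0, 10), 3, 2)
    hgt <- runif(1, 1, 5)
    nodes <- rbind(cbind(tri, 0), cbind(tri, hgt))
    # random global ids to exercise the min-index diagonal rule
    ids <- sample(100, 6)
    bot <- matrix(ids[1:3], 1); top <- matrix(ids[4:6], 1)
    # bottom ids must be smaller than top ids, as in the shell extrusion
    if (max(bot) > min(top)) { sw <- pmin(bot, top); top <- pmax(bot, top); bot <- sw }
    lookup <- integer(100); lookup[c(bot, top)] <- 1:6
    tets <- scan2fem:::split_prisms(bot, top)
    tets <- matrix(lookup[tets], ncol = 4)
    v <- abs(scan2fem:::tet_volumes(nodes, tets))
    A <- abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
             (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])) / 2
    expect_equal(sum(v), A * hgt, tolerance = 1e-9)
    expect_true(all(v > 1e-12))
  }
})

test_that("the shell FEM mesh reproduces the cylinder volume", {
  m <- cylinder_model(R = 150, zr = c(-60, 60))
  set.seed(11)
  rs <- suppressMessages(remesh_surface(
    m, NULL, mesh_config(h_electrode = 10, h_background = 10,
                         electrode_radius = 11, max_iter = 120)))
  fm <- build_fem_mesh(rs, config = rs$config, n_shells = 4)
  vol <- sum(abs(scan2fem:::tet_volumes(fm$nodes, fm$tets)))
  expect_lt(abs(vol / (pi * 150^2 * 120) - 1), 0.02)
})

test_that("the tet mesh boundary is watertight and labels transfer exactly", {
  fx <- eit_fixture()
  fm <- fx$mesh
  bf <- scan2fem:::tet_boundary_faces(fm$tets)
  key <- function(f) sort(apply(f, 1, function(r) paste(sort(r), collapse = "-")))
  expect_identical(key(bf), key(fm$surface_tris))
  # label transfer is the identity on the surface triangles
  belt_faces <- fx$belt$surface$faces
  for (l in names(fx$belt$labels)) {
    expect_identical(key(fm$electrode_facets[[l]]),
                     key(belt_faces[fx$belt$labels[[l]], , drop = FALSE]))
  }
  # facet areas within 10% of the nominal disc area
  for (l in names(fm$electrode_facets)) {
    f <- fm$electrode_facets[[l]]
    ar <- sum(triangle_areas(colored_surface(fm$nodes, f, validate = FALSE)))
    expect_lt(abs(ar / (pi * 25) - 1), 0.10)
  }
  expect_true(all(scan2fem:::tet_volumes(fm$nodes, fm$tets) > 0))
})

test_that("mesh_quality reports sane statistics", {
  # regular tetrahedron has quality 1
  reg <- list(nodes = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
              tets = matrix(1:4, 1))
  class(reg) <- "fem_mesh"
  expect_equal(mesh_quality(reg)$min_quality, 1, tolerance = 1e-12)
  sliver <- list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(1, 1, 1e-4)),
                 tets = matrix(1:4, 1))
  class(sliver) <- "fem_mesh"
  expect_lt(mesh_quality(sliver)$min_quality, 0.1)
  fx <- eit_fixture()
  q <- mesh_quality(fx$mesh)
  expect_equal(q$n_elements, nrow(fx$mesh$tets))
  expect_lt(abs(q$z_extent_mm - 70), 15)
})

test_that("requesting the gmsh backend without gmsh reports backend-missing", {
  fx <- eit_fixture()
  expect_error(build_fem_mesh(fx$belt, backend = "gmsh"),
               class = "scan2fem_backend_missing")
})
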