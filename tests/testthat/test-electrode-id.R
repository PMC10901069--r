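test_that("anchor stickers are detected within 1 mm on a clean phantom", {
  ph <- phantom_clean()
  det <- detect_fiducials(ph$surface)
  pal <- default_palette()
  for (cname in names(pal$anchor_map)) {
    expect_gte(length(det[[cname]]), 1)
    cen <- det[[cname]][[1]]$centroid
    truth <- ph$truth$centers[pal$anchor_map[[cname]], ]
    expect_lt(sqrt(sum((cen - truth)^2)), 1)
  }
  expect_equal(length(det$white), 26)
})

test_that("an all-white surface yields no anchors and missing-anchor warnings", {
  s <- one_triangle()
  s$vertices <- s$vertices * 20
  w <- capture_warnings(det <- detect_fiducials(s, min_cluster = 1))
  expect_length(w, 6)
  expect_true(all(grepl("missing-anchor", w)))
  expect_equal(sum(lengths(det[names(default_palette()$anchor_map)])), 0)
})

test_that("detection survives scanner color noise (sigma = 10)", {
  ph <- make_scan(phantom_spec(perimeter = 1048, axis_ratio = 1.1,
                               resolution = 3, color_noise_sd = 10, seed = 21))
  det <- detect_fiducials(ph$surface)
  pal <- default_palette()
  for (cname in names(pal$anchor_map)) {
    cen <- det[[cname]][[1]]$centroid
    truth <- ph$truth$centers[pal$anchor_map[[cname]], ]
    expect_lt(sqrt(sum((cen - truth)^2)), 2)
  }
})

# equally spaced belt points with anchors at the standard positions
circle_inputs <- function(n = 32, drop = integer(), jitter = 0, seed = 1) {
  set.seed(seed)
  th <- 2 * pi * (0:(n - 1)) / n
  th <- th + runif(n, -jitter, jitter)
  pts <- cbind(150 * cos(th), 150 * sin(th), 0)
  pal <- default_palette()
  anchors <- lapply(pal$anchor_map, function(k) pts[k, ])
  names(anchors) <- names(pal$anchor_map)
  white_idx <- setdiff(seq_len(n), c(pal$anchor_map, drop))
  list(anchors = anchors, whites = pts[white_idx, , drop = FALSE])
}

test_that("a symmetric belt is labeled 1..32 in order", {
  ci <- circle_inputs()
  es <- label_electrodes(ci$anchors, ci$whites, c(0, 0, 1))
  expect_equal(es$labels, 1:32)
  expect_length(es$occluded, 0)
  # positions of label k must be the k-th circle point
  expect_equal(es$positions[7, ], c(150 * cos(2 * pi * 6 / 32),
                                    150 * sin(2 * pi * 6 / 32), 0))
})

test_that("five consecutive missing whites are inferred as occluded 2..6", {
  ci <- circle_inputs(drop = 2:6)
  es <- label_electrodes(ci$anchors, ci$whites, c(0, 0, 1))
  expect_setequal(es$occluded, 2:6)
  expect_equal(sort(es$labels), sort(setdiff(1:32, 2:6)))
})

test_that("label assignment matches the brute-force oracle on jittered belts", {
  set.seed(99)
  for (trial in 1:100) {
    ndrop <- sample(0:5, 1)
    drop <- if (ndrop > 0)
      sample(setdiff(1:32, default_palette()$anchor_map), ndrop) else integer()
    ci <- circle_inputs(drop = drop, jitter = 0.02, seed = 1000 + trial)
    es <- label_electrodes(ci$anchors, ci$whites, c(0, 0, 1))
    or <- oracle_label(ci$anchors, ci$whites, c(0, 0, 1))
    expect_equal(es$labels, or$labels, info = paste("trial", trial))
  }
})

test_that("labeling is invariant to rigid transforms of all inputs", {
  ci <- circle_inputs(drop = c(3, 20), jitter = 0.03, seed = 5)
  es0 <- label_electrodes(ci$anchors, ci$whites, c(0, 0, 1))
  ax <- c(1, 2, 3) / sqrt(14)
  R <- scan2fem:::minimal_rotation(c(0, 0, 1), ax)
  t0 <- c(40, -25, 12)
  anchors2 <- lapply(ci$anchors, function(p) as.vector(R %*% p) + t0)
  whites2 <- sweep(ci$whites %*% t(R), 2, -t0)
  es1 <- label_electrodes(anchors2, whites2, ax)
  expect_equal(es1$labels, es0$labels)
  expect_equal(es1$occluded, es0$occluded)
})

test_that("a reversed belt winding still numbers anchors in cyclic order", {
  ph <- make_scan(phantom_spec(perimeter = 900, resolution = 3,
                               winding = -1L, seed = 31))
  id <- identify_electrodes(ph$surface)
  err <- sqrt(rowSums((id$electrodes$positions -
                       ph$truth$centers[id$electrodes$labels, ])^2))
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("inconsistent anchor order and overfull segments error", {
  ci <- circle_inputs()
  bad <- ci$anchors
  names(bad) <- names(bad)[c(2, 1, 3, 4, 5, 6)]  # swap cyan/orange positions
  expect_error(label_electrodes(bad, ci$whites, c(0, 0, 1)),
               class = "scan2fem_anchor_order")
  # cram an extra white into the 4-slot arc between anchors 7 and 12
  extra <- rbind(ci$whites, c(150 * cos(2 * pi * 8.3 / 32),
                              150 * sin(2 * pi * 8.3 / 32), 0),
                 c(150 * cos(2 * pi * 9.9 / 32), 150 * sin(2 * pi * 9.9 / 32), 0))
  expect_error(label_electrodes(ci$anchors, extra, c(0, 0, 1)),
               class = "scan2fem_overfull_segment")
})
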