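# Synthetic scene generator: determinism, forced metric cases, class
# separation and the uniformity of uncoupled dot placement.

test_that("empty scenes are valid and deterministic", {
  g <- generate_fiber_image(fiber_scene_spec(c(64, 64), n_fibers = 0,
                                             seed = 3))
  expect_equal(nrow(g$fiber_table), 0)
  expect_equal(dim(g$image), c(64, 64))

  b <- generate_brightfield_image(dot_scene_spec(c(64, 64), n_dots = 0,
                                                 seed = 3))
  expect_equal(nrow(b$dot_table), 0)
  ratio <- compute_ratio_map(b$image)
  expect_false(any(ratio[b$tissue_mask] < 0.4))

  g2 <- generate_fiber_image(fiber_scene_spec(c(64, 64), n_fibers = 0,
                                              seed = 3))
  expect_identical(g$image, g2$image)
})

test_that("same seed reproduces scenes bit-identically", {
  sp <- fiber_scene_spec(c(128, 128), n_fibers = 20, seed = 11)
  g1 <- generate_fiber_image(sp)
  g2 <- generate_fiber_image(sp)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$fiber_table$length_um, g2$fiber_table$length_um)

  dsp <- dot_scene_spec(c(128, 128), n_dots = 15, seed = 12)
  b1 <- generate_brightfield_image(dsp)
  b2 <- generate_brightfield_image(dsp)
  expect_identical(b1$image, b2$image)
  expect_identical(b1$dot_table, b2$dot_table)
})

test_that("a straight horizontal fiber has the forced metrics", {
  # 50 axial skeleton pixels = 49 unit steps of 0.63 um
  sp <- fiber_scene_spec(c(200, 200), n_fibers = 1,
                         length_range = c(49 * 0.63, 49 * 0.63),
                         orientation_range = c(0, 0),
                         tortuosity_target = 1, seed = 5)
  g <- generate_fiber_image(sp)
  expect_equal(nrow(g$fiber_table), 1)
  expect_equal(g$fiber_table$n_pixels, 50L)
  expect_equal(g$fiber_table$length_um, 49 * 0.63, tolerance = 1e-12)
  expect_equal(g$fiber_table$length_um, 30.87, tolerance = 1e-9)
  expect_equal(g$fiber_table$orientation_rad, 0)
  expect_equal(g$fiber_table$tortuosity, 1, tolerance = 1e-12)
})

test_that("recorded ground truth equals the rendered scene content", {
  g <- generate_fiber_image(fiber_scene_spec(c(160, 160), n_fibers = 12,
                                             fiber_width_px = 1,
                                             background_noise_sd = 5,
                                             seed = 21))
  expect_equal(nrow(g$fiber_table), 12)
  # every recorded skeleton pixel is bright in the rendered image
  for (p in g$fiber_table$path)
    expect_true(all(g$image[cbind(p[, 1] + 1, p[, 2] + 1)] > 100))

  b <- generate_brightfield_image(dot_scene_spec(c(160, 160), n_dots = 18,
                                                 seed = 22))
  expect_equal(nrow(b$dot_table), 18)
  ratio <- compute_ratio_map(b$image)
  cand <- ratio < 0.4 & b$tissue_mask
  expect_equal(sum(cand), sum(b$dot_table$area_px))
  expect_true(all(b$dot_table$centroid_row %% 1 == 0))
  m <- b$tissue_mask
  expect_true(all(m[cbind(b$dot_table$centroid_row + 1,
                          b$dot_table$centroid_col + 1)]))
})

test_that("ground-truth metrics survive the render-and-retrace roundtrip", {
  g <- generate_fiber_image(fiber_scene_spec(c(220, 220), n_fibers = 18,
                                             fiber_width_px = 1,
                                             background_noise_sd = 4,
                                             seed = 7))
  seg <- segment_fibers(g$image, segmentation_backend("identity"))
  expect_equal(length(seg$paths), nrow(g$fiber_table))
  tt <- build_fiber_table(seg$paths, 0.63, "identity")
  expect_equal(sort(tt$length_um), sort(g$fiber_table$length_um),
               tolerance = 1e-12)
  expect_equal(sort(tt$tortuosity), sort(g$fiber_table$tortuosity),
               tolerance = 1e-12)
  expect_equal(sort(tt$orientation_rad),
               sort(g$fiber_table$orientation_rad), tolerance = 1e-12)
})

test_that("uncoupled dot centroids are uniform within the tissue mask", {
  b <- generate_brightfield_image(
    dot_scene_spec(c(560, 560), n_dots = 2000, dot_radius_range = c(1, 2),
                   min_gap_px = 2, seed = 42))
  m <- b$tissue_mask
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  cutr <- seq(rr[1] - 1, rr[2], length.out = 5)
  cutc <- seq(cc[1] - 1, cc[2], length.out = 5)
  obs <- table(cut(b$dot_table$centroid_row, cutr, include.lowest = TRUE),
               cut(b$dot_table$centroid_col, cutc, include.lowest = TRUE))
  exp_p <- table(cut(row(m)[m] - 1, cutr, include.lowest = TRUE),
                 cut(col(m)[m] - 1, cutc, include.lowest = TRUE)) / sum(m)
  p <- stats::chisq.test(as.vector(obs), p = as.vector(exp_p))$p.value
  expect_gt(p, 0.01)
})

test_that("paired samples honor the applied misalignment convention", {
  fs <- fiber_scene_spec(c(128, 128), n_fibers = 10, seed = 31)
  ds <- dot_scene_spec(c(128, 128), n_dots = 10, seed = 32)
  ps0 <- generate_paired_sample(fs, ds)
  b <- generate_brightfield_image(ds)
  expect_identical(ps0$brightfield, b$image)   # identity: unwarped
  expect_identical(ps0$ground_truth$dot_table_moving$centroid_row,
                   ps0$ground_truth$dot_table$centroid_row)

  tr <- c(8, -5)
  mis <- cm_transform("rigid", rotation = 0, translation = tr,
                      center = c(63.5, 63.5))
  ps <- generate_paired_sample(fs, ds, mis)
  # applied transform maps delivered coordinates into the SHG frame, so
  # delivered centroids are the true ones minus the translation
  expect_equal(ps$ground_truth$dot_table_moving$centroid_row,
               ps$ground_truth$dot_table$centroid_row - tr[1])
  expect_equal(ps$ground_truth$dot_table_moving$centroid_col,
               ps$ground_truth$dot_table$centroid_col - tr[2])
  # and warping them with the applied transform restores the SHG frame
  w <- warp_points(as.matrix(
    ps$ground_truth$dot_table_moving[, c("centroid_row", "centroid_col")]),
    ps$ground_truth$applied_transform)
  expect_equal(unname(w[, 1]), ps$ground_truth$dot_table$centroid_row,
               tolerance = 1e-9)
})

test_that("incompatible shapes and impossible placements raise errors", {
  expect_error(generate_paired_sample(fiber_scene_spec(c(64, 64)),
                                      dot_scene_spec(c(128, 128))),
               "share image_shape")
  expect_error(generate_fiber_image(
    fiber_scene_spec(c(24, 24), n_fibers = 60, length_range = c(30, 40),
                     seed = 1)), "placement failure")
  expect_error(generate_brightfield_image(
    dot_scene_spec(c(32, 32), n_dots = 500, seed = 1)),
    "placement failure")
})
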