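# Macroscale grid aggregation and the Spearman correlation matrix.

make_single_fiber_scene <- function() {
  # one horizontal fiber fully inside cell (0, 0) of a 2x2 grid of 30 px
  path <- cbind(rep(10, 11), 5:15)
  ft <- build_fiber_table(list(path), 0.63)
  maps <- list(length_um = make_property_map(ft, "length_um", c(60, 60)),
               orientation_rad = make_property_map(ft, "orientation_rad",
                                                   c(60, 60)),
               tortuosity = make_property_map(ft, "tortuosity", c(60, 60)))
  list(ft = ft, maps = maps)
}

test_that("a fiber confined to one cell fills only that cell", {
  sc <- make_single_fiber_scene()
  dots <- data.frame(id = integer(), centroid_row = numeric(),
                     centroid_col = numeric(), area_px = integer())
  gt <- grid_aggregate(sc$maps, dots, grid_spec(30, c(60, 60)))
  expect_equal(nrow(gt), 4)
  home <- gt$cell_row == 0 & gt$cell_col == 0
  expect_equal(gt$mean_length_um[home], sc$ft$length_um[1])
  expect_true(all(is.na(gt$mean_length_um[!home])))
  expect_equal(gt$n_skeleton_px[home], 11L)
})

test_that("dots on shared boundaries go to the lower-index cell", {
  maps <- list(length_um = matrix(NA_real_, 60, 60))
  dots <- data.frame(id = 1:2, centroid_row = c(30, 29.999),
                     centroid_col = c(30, 10), area_px = 1L)
  gt <- grid_aggregate(maps, dots, grid_spec(30, c(60, 60)))
  # (30, 30) is on the boundary: half-open convention assigns cell (1, 1)
  expect_equal(gt$dot_count[gt$cell_row == 1 & gt$cell_col == 1], 1L)
  expect_equal(gt$dot_count[gt$cell_row == 0 & gt$cell_col == 0], 1L)
  expect_equal(sum(gt$dot_count), 2L)
})

test_that("cell means equal a brute-force per-pixel aggregation", {
  g <- generate_fiber_image(fiber_scene_spec(c(90, 90), n_fibers = 12,
                                             seed = 33))
  maps <- list(length_um = make_property_map(g$fiber_table, "length_um",
                                             c(90, 90)),
               tortuosity = make_property_map(g$fiber_table, "tortuosity",
                                              c(90, 90)))
  dots <- data.frame(id = 1:5,
                     centroid_row = c(5, 35, 65, 10, 80),
                     centroid_col = c(5, 40, 70, 85, 15), area_px = 1L)
  gt <- grid_aggregate(maps, dots, grid_spec(30, c(90, 90)))
  for (k in seq_len(nrow(gt))) {
    expect_equal(gt$mean_length_um[k],
                 oracle_cell_mean(maps$length_um, gt$cell_row[k],
                                  gt$cell_col[k], 30))
    expect_equal(gt$mean_tortuosity[k],
                 oracle_cell_mean(maps$tortuosity, gt$cell_row[k],
                                  gt$cell_col[k], 30))
  }
  # dot conservation over the grid extent
  expect_equal(sum(gt$dot_count), 5L)
})

test_that("spearman_rho matches the mid-rank definition", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 2, 5, 1)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    a <- sample(1:6, 30, replace = TRUE)
    b <- sample(1:6, 30, replace = TRUE)
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))))
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  g <- generate_fiber_image(fiber_scene_spec(c(150, 150), n_fibers = 30,
                                             seed = 35))
  maps <- lapply(stats::setNames(nm = c("length_um", "orientation_rad",
                                        "tortuosity")),
                 function(p) make_property_map(g$fiber_table, p, c(150, 150)))
  b <- generate_brightfield_image(dot_scene_spec(c(150, 150), n_dots = 30,
                                                 seed = 36))
  gt <- grid_aggregate(maps, b$dot_table, grid_spec(30, c(150, 150)))
  m <- correlation_matrix(gt)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(abs(m[!is.na(m)]) <= 1))
})

test_that("a monotone length-dot coupling yields rho of one", {
  # construct a grid table directly: dot_count strictly increasing in
  # mean length
  gt <- data.frame(cell_row = 0:9, cell_col = 0,
                   mean_length_um = seq(5, 50, by = 5),
                   mean_orientation_rad = runif(10, 0, pi),
                   mean_tortuosity = 1 + runif(10) / 10,
                   dot_count = c(0, 1, 2, 4, 8, 9, 12, 20, 21, 30))
  class(gt) <- c("cm_grid_table", "data.frame")
  m <- correlation_matrix(gt)
  expect_equal(m["length", "dot_count"], 1)
})

test_that("independent features show negligible correlation", {
  set.seed(4)
  gt <- data.frame(cell_row = rep(0:19, 20), cell_col = rep(0:19, each = 20),
                   mean_length_um = rnorm(400, 20, 4),
                   mean_orientation_rad = runif(400, 0, pi),
                   mean_tortuosity = 1 + abs(rnorm(400, 0, 0.1)),
                   dot_count = rpois(400, 3))
  class(gt) <- c("cm_grid_table", "data.frame")
  m <- correlation_matrix(gt)
  off <- m[upper.tri(m)]
  expect_true(all(abs(off) < 0.15))
})

test_that("removing an invalid cell leaves unrelated entries unchanged", {
  set.seed(5)
  gt <- data.frame(cell_row = 0:29, cell_col = 0,
                   mean_length_um = rnorm(30, 20, 4),
                   mean_orientation_rad = runif(30, 0, pi),
                   mean_tortuosity = 1 + abs(rnorm(30, 0, 0.1)),
                   dot_count = rpois(30, 3))
  gt$mean_length_um[7] <- NA  # invalid for length only
  class(gt) <- c("cm_grid_table", "data.frame")
  m1 <- correlation_matrix(gt)
  m2 <- correlation_matrix(gt[-7, ])
  # entries not involving the dropped cell's only-NA feature pairs differ,
  # but pairwise-complete entries involving length are identical
  expect_equal(m1["length", "dot_count"], m2["length", "dot_count"])
  expect_equal(m1["length", "tortuosity"], m2["length", "tortuosity"])
})

test_that("generator coupling produces a significant length-dot entry", {
  g <- generate_fiber_image(fiber_scene_spec(c(200, 200), n_fibers = 40,
                                             length_range = c(6, 45),
                                             seed = 37))
  b <- generate_brightfield_image(dot_scene_spec(
    c(200, 200), n_dots = 40, seed = 38,
    enrichment = list(fiber_table = g$fiber_table, radius_px = 10,
                      length_quantile = 0.6)))
  maps <- list(length_um = make_property_map(g$fiber_table, "length_um",
                                             c(200, 200)))
  gt <- grid_aggregate(maps, b$dot_table, grid_spec(25, c(200, 200)))
  ok <- !is.na(gt$mean_length_um)
  rho <- spearman_rho(gt$mean_length_um[ok], gt$dot_count[ok])
  expect_gt(rho, 0)
  # permutation null: shuffle cell labels
  set.seed(39)
  null <- replicate(999, spearman_rho(gt$mean_length_um[ok],
                                      sample(gt$dot_count[ok])))
  expect_gt(rho, stats::quantile(null, 0.975))
})
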