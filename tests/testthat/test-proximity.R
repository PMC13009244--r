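# Microscale proximity analysis: inclusion rule, profile statistics,
# normalization, the randomized baseline and probe comparison.

test_that("the inclusion rule is a minimum-distance threshold", {
  # fiber whose nearest skeleton pixel sits exactly at distance 9.5
  ft <- build_fiber_table(list(cbind(rep(29L, 30), 10 + 0:29)), 0.63)
  dot <- c(19.5, 25)   # min distance = 9.5 exactly
  expect_equal(fibers_within_radius(dot, ft, 10), 1L)
  expect_equal(length(fibers_within_radius(dot, ft, 9)), 0L)
})

test_that("spatial-index distances equal the brute-force oracle", {
  for (s in 1:3) {
    g <- generate_fiber_image(fiber_scene_spec(c(200, 200), n_fibers = 30,
                                               seed = 500 + s))
    b <- generate_brightfield_image(dot_scene_spec(c(200, 200), n_dots = 50,
                                                   seed = 600 + s))
    d_grid <- corrmap:::.min_dist_matrix(b$dot_table, g$fiber_table,
                                         max_radius = 100, method = "grid")
    d_bf <- corrmap:::.min_dist_matrix(b$dot_table, g$fiber_table,
                                       method = "bruteforce")
    d_oracle <- oracle_min_dists(b$dot_table, g$fiber_table)
    expect_equal(d_bf, d_oracle, tolerance = 1e-12)
    capped <- d_oracle; capped[capped > 100] <- Inf
    expect_equal(d_grid, capped, tolerance = 1e-12)
    # per-dot inclusion sets agree with the oracle at several radii
    for (r in c(10, 50, 100)) {
      i <- 1 + (s %% nrow(b$dot_table))
      expect_equal(
        fibers_within_radius(c(b$dot_table$centroid_row[i],
                               b$dot_table$centroid_col[i]),
                             g$fiber_table, r),
        which(d_oracle[i, ] <= r))
    }
  }
})

test_that("single dot-fiber configurations give the stated profile", {
  ft <- build_fiber_table(list(cbind(rep(20L, 50), 10 + 0:49)), 0.63)
  expect_equal(ft$length_um, 49 * 0.63)
  dot <- data.frame(id = 1, centroid_row = 25, centroid_col = 30,
                    area_px = 1L)  # distance 5 from the fiber
  pp <- proximity_params(n_random = 10, seed = 1)
  prof <- proximity_profile(dot, ft, pp)
  expect_equal(prof$mean_length_um, rep(49 * 0.63, 10))
  expect_equal(prof$isolated_fraction, rep(0, 10))
  expect_equal(prof$mean_fiber_count, rep(1, 10))

  # nearest fiber at 35 px: isolated up to r = 30, included from r = 40
  dot2 <- data.frame(id = 1, centroid_row = 55, centroid_col = 30,
                     area_px = 1L)
  prof2 <- proximity_profile(dot2, ft, pp)
  expect_equal(prof2$isolated_fraction, c(1, 1, 1, rep(0, 7)))
  expect_true(all(is.na(prof2$mean_length_um[1:3])))
  expect_equal(prof2$mean_length_um[4:10], rep(49 * 0.63, 7))
})

test_that("profiles are monotone in radius and match brute force", {
  g <- generate_fiber_image(fiber_scene_spec(c(220, 220), n_fibers = 35,
                                             length_range = c(6, 40),
                                             seed = 71))
  b <- generate_brightfield_image(dot_scene_spec(c(220, 220), n_dots = 30,
                                                 seed = 72))
  pp <- proximity_params(n_random = 10, seed = 1)
  p1 <- proximity_profile(b$dot_table, g$fiber_table, pp, method = "grid")
  p2 <- proximity_profile(b$dot_table, g$fiber_table, pp,
                          method = "bruteforce")
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(diff(p1$mean_fiber_count) >= 0))
  expect_true(all(diff(p1$isolated_fraction) <= 0))
  expect_true(all(diff(p1$n_dots_contributing) >= 0))
  # SEM definition: sd across contributing dots over sqrt(n)
  r <- p1$radius_px[8]
  d <- corrmap:::.min_dist_matrix(b$dot_table, g$fiber_table, r)
  per_dot <- apply(d <= r, 1, function(inc)
    if (any(inc)) mean(g$fiber_table$length_um[inc]) else NA_real_)
  per_dot <- per_dot[!is.na(per_dot)]
  expect_equal(p1$sem_length_um[8], sd(per_dot) / sqrt(length(per_dot)),
               tolerance = 1e-12)
})

test_that("normalization anchors at the smallest radius with an OLS slope", {
  prof <- data.frame(radius_px = c(10, 20, 30),
                     radius_um = c(6.3, 12.6, 18.9),
                     mean_length_um = c(30, 27, 24))
  np <- normalize_profile(prof)
  expect_equal(np$normalized, c(1, 0.9, 0.8))
  expect_equal(profile_slope(np), -0.1 / 6.3, tolerance = 1e-9)
  const <- data.frame(radius_px = 1:5 * 10, radius_um = 1:5 * 6.3,
                      mean_length_um = rep(4, 5))
  npc <- normalize_profile(const)
  expect_equal(npc$normalized, rep(1, 5))
  expect_equal(profile_slope(npc), 0, tolerance = 1e-12)
  bad <- data.frame(radius_px = 1:3, radius_um = 1:3,
                    mean_length_um = c(NA, 2, 3))
  expect_error(normalize_profile(bad), "smallest radius")
})

test_that("the randomized baseline is deterministic and mask-constrained", {
  g <- generate_fiber_image(fiber_scene_spec(c(160, 160), n_fibers = 20,
                                             seed = 73))
  mask <- matrix(FALSE, 160, 160); mask[40:120, 40:120] <- TRUE
  pp <- proximity_params(n_random = 100, seed = 99)
  b1 <- randomized_baseline(g$fiber_table, mask, pp)
  b2 <- randomized_baseline(g$fiber_table, mask, pp)
  expect_identical(b1, b2)
  expect_error(randomized_baseline(g$fiber_table,
                                   matrix(FALSE, 10, 10), pp), "empty")
})

test_that("degenerate dot/fiber tables behave as specified", {
  g <- generate_fiber_image(fiber_scene_spec(c(100, 100), n_fibers = 5,
                                             seed = 74))
  empty_dots <- data.frame(id = integer(), centroid_row = numeric(),
                           centroid_col = numeric(), area_px = integer())
  expect_error(proximity_profile(empty_dots, g$fiber_table), ">= 1 dot")
  one_dot <- data.frame(id = 1, centroid_row = 50, centroid_col = 50,
                        area_px = 1L)
  empty_fibers <- build_fiber_table(list())
  prof <- proximity_profile(one_dot, empty_fibers)
  expect_equal(prof$isolated_fraction, rep(1, 10))
  expect_equal(prof$mean_fiber_count, rep(0, 10))
})

test_that("probe comparison differences recompute and propagate SEM", {
  g <- generate_fiber_image(fiber_scene_spec(c(200, 200), n_fibers = 30,
                                             seed = 75))
  b <- generate_brightfield_image(dot_scene_spec(c(200, 200), n_dots = 40,
                                                 seed = 76))
  pp <- proximity_params(n_random = 10, seed = 1)
  half <- seq_len(20)
  pa <- proximity_profile(b$dot_table[half, ], g$fiber_table, pp)
  pb <- proximity_profile(b$dot_table[-half, ], g$fiber_table, pp)
  cmp <- compare_probes(pa, pb)
  expect_equal(nrow(cmp), 10)
  same <- compare_probes(pa, pa)
  expect_equal(same$d_normalized, rep(0, 10))
  expect_equal(same$d_isolated_fraction, rep(0, 10))
  # quadrature: 0.3 and 0.4 combine to 0.5
  expect_equal(sqrt(0.3^2 + 0.4^2), 0.5)
  na <- normalize_profile(pa); nb <- normalize_profile(pb)
  expect_equal(cmp$d_normalized, na$normalized - nb$normalized)
  expect_error(compare_probes(pa, prof <- {
    p <- pa; p$radius_px <- p$radius_px + 1; p
  }), "identical radii")
})
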