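test_that("generation assignment follows the greedy tolerance rule", {
  tr <- make_chain_tree(c(20.4, 14.0, 10.1, 9.9, 7.0), leaf_diameter = 0.5)
  # drop the tiny sibling leaves from the comparison
  g <- assign_generations(tr, tol_mm = 0.3)
  tab <- branch_table(g)
  main <- tab[grepl("^c", tab$id), ]
  expect_identical(main$generation[order(main$id)], c(0L, 1L, 2L, 2L, 3L))
})

test_that("zero tolerance gives strictly increasing generations by diameter", {
  tr <- make_chain_tree(c(20, 15, 11, 8, 6), leaf_diameter = 0.5)
  g <- assign_generations(tr, tol_mm = 0)
  tab <- branch_table(g)
  main <- tab[grepl("^c", tab$id), ]
  expect_identical(main$generation[order(-main$diameter_mm)], 0:4)
})

test_that("a daughter within tolerance of its parent keeps the generation", {
  tr <- make_chain_tree(c(20, 10.0, 9.9, 5), leaf_diameter = 0.5)
  g <- assign_generations(tr, tol_mm = 0.3)
  tab <- branch_table(g)
  expect_identical(tab$generation[tab$id == "c02"],
                   tab$generation[tab$id == "c03"])
})

test_that("generation assignment is invariant to branch storage order", {
  tr <- generate_tree(generator_params(min_diameter_mm = 3), seed = 6)
  g1 <- branch_table(assign_generations(tr))
  tr2 <- tr
  tr2$branches <- tr2$branches[rev(names(tr2$branches))]
  g2 <- branch_table(assign_generations(tr2))
  g2 <- g2[match(g1$id, g2$id), ]
  expect_identical(g1$generation, g2$generation)
})

test_that("raising the tolerance never increases the number of generations", {
  for (seed in 1:3) {
    tr <- generate_tree(seed = seed)
    gmax <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.6), function(tol)
      max(branch_table(assign_generations(tr, tol))$generation), numeric(1))
    expect_true(all(diff(gmax) <= 0))
  }
})

test_that("unset diameters abort generation assignment with the branch name", {
  tr <- make_y_tree()
  tr$branches[["b"]]$diameter_mm <- NA_real_
  expect_error(assign_generations(tr), "'b'")
})

test_that("bifurcation geometry is measured from constructed directions", {
  tr <- make_y_tree(D = 10, d1 = 8.8, d2 = 5.7, angle1_deg = 0,
                    angle2_deg = 41.44)
  rec <- compute_bifurcations(tr)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$angle1_deg, 0, tolerance = 1e-9)
  expect_equal(rec$angle2_deg, 41.44, tolerance = 1e-9)
  expect_equal(rec$plane_rotation_deg, 0, tolerance = 1e-9)
  expect_identical(rec$planarity, "in_plane")
  expect_equal(rec$d1_ratio, 0.88, tolerance = 1e-12)
  expect_equal(rec$d2_ratio, 0.57, tolerance = 1e-12)

  out <- compute_bifurcations(make_y_tree(rotate_minor_deg = 90))
  expect_equal(out$plane_rotation_deg, 90, tolerance = 1e-9)
  expect_identical(out$planarity, "out_of_plane_pos")
  neg <- compute_bifurcations(make_y_tree(rotate_minor_deg = -90))
  expect_equal(neg$plane_rotation_deg, -90, tolerance = 1e-9)
  expect_identical(neg$planarity, "out_of_plane_neg")
})

test_that("angles and rotations are invariant under rigid transforms", {
  set.seed(11)
  tr <- generate_tree(generator_params(min_diameter_mm = 4), seed = 2)
  base <- compute_bifurcations(tr)
  for (k in 1:3) {
    R <- random_rotation()
    tr2 <- transform_tree(tr, R, translation = rnorm(3, sd = 20))
    rec <- compute_bifurcations(tr2)
    expect_equal(rec$angle1_deg, base$angle1_deg, tolerance = 1e-6)
    expect_equal(rec$angle2_deg, base$angle2_deg, tolerance = 1e-6)
    expect_equal(rec$plane_rotation_deg, base$plane_rotation_deg,
                 tolerance = 1e-6)
  }
})

test_that("ratios and angles are invariant under uniform scaling", {
  tr <- generate_tree(generator_params(min_diameter_mm = 4), seed = 2)
  tr2 <- tr
  tr2$branches <- lapply(tr2$branches, function(b) {
    b$centerline <- b$centerline * 2.5
    b$length_mm <- b$length_mm * 2.5
    b$diameter_mm <- b$diameter_mm * 2.5
    b
  })
  a <- compute_bifurcations(tr)
  b <- compute_bifurcations(tr2)
  expect_equal(a$d1_ratio, b$d1_ratio, tolerance = 1e-12)
  expect_equal(a$angle2_deg, b$angle2_deg, tolerance = 1e-9)
})

test_that("trifurcations are rejected", {
  tr <- make_y_tree()
  extra <- airway_branch("c", "t", character(),
                         rbind(c(0, 0, -30), c(5, 5, -40)), 3, 1L, "other")
  tr$branches[["c"]] <- extra
  tr$branches[["t"]]$child_ids <- c("a", "b", "c")
  expect_error(compute_bifurcations(tr), "children")
})

test_that("plane rotation series follows the schedule along mainstems", {
  tr <- generate_tree(generator_params(sd_scale = 0), seed = 5)
  n_ser <- integer(0)
  for (pw in c("right_mainstem", "left_mainstem")) {
    ser <- plane_rotation_series(tr, pw)
    n_ser <- c(n_ser, nrow(ser))
    expected <- rep(c(0, 90, -90), length.out = nrow(ser))
    expect_equal(ser$rotation_deg, expected, tolerance = 1e-6)
  }
  expect_gt(max(n_ser), 5)
  # alternative schedule: one out-of-plane step, as seen in some pathways
  tr2 <- generate_tree(generator_params(sd_scale = 0,
                                        plane_schedule = c(0, -90, 0)),
                       seed = 5)
  ser2 <- plane_rotation_series(tr2, "right_mainstem")
  expect_equal(ser2$rotation_deg, rep(c(0, -90, 0), length.out = nrow(ser2)),
               tolerance = 1e-6)
})

test_that("rotation series is invariant under rigid co-rotation", {
  tr <- generate_tree(generator_params(sd_scale = 0), seed = 5)
  ser <- plane_rotation_series(tr, "right_mainstem")
  set.seed(3)
  tr2 <- transform_tree(tr, random_rotation())
  ser2 <- plane_rotation_series(tr2, "right_mainstem")
  expect_equal(ser$rotation_deg, ser2$rotation_deg, tolerance = 1e-6)
})

test_that("summaries stratify by class with t-based confidence intervals", {
  rec1 <- compute_bifurcations(make_y_tree())
  recs <- dplyr::bind_rows(rec1, rec1, rec1)
  recs$minor_role <- "other"
  sm <- summarize_morphometry(recs)
  expect_equal(sm$by_class$angle2_ci, 0)        # identical records
  expect_identical(sm$n_bifurcations, 3L)

  out1 <- compute_bifurcations(make_y_tree(d2 = 3.5, rotate_minor_deg = 90))
  out1$minor_role <- "other"
  out1$d1_ratio <- 0.86
  mixed <- dplyr::bind_rows(rec1, out1, out1)
  mixed$minor_role <- "other"
  sm2 <- summarize_morphometry(mixed)
  expect_equal(sm2$pooled_d1_ratio, (0.88 + 2 * 0.86) / 3, tolerance = 1e-12)
  expect_error(summarize_morphometry(rec1[0, ]), "no bifurcation")
})

test_that("noise-free trees summarise to the exact class ratios", {
  tr <- generate_tree(generator_params(sd_scale = 0), seed = 8)
  sm <- summarize_morphometry(compute_bifurcations(tr), tree = tr)
  bc <- sm$by_class
  expect_equal(bc$d2_ratio_mean[bc$class == "in_plane"], 0.57,
               tolerance = 1e-12)
  expect_equal(bc$d2_ratio_mean[bc$class == "out_of_plane"], 0.35,
               tolerance = 1e-12)
})

test_that("transition-zone fraction is measured from the distal end", {
  cyl <- data.frame(position_mm = 0:20, aspect = 0.95)
  expect_equal(transition_zone_fraction(cyl), 0)
  expect_equal(transition_zone_fraction(cyl, aspect_threshold = 1), 1)
  prof <- data.frame(position_mm = 0:19,
                     aspect = c(rep(0.95, 15), rep(0.7, 5)))
  expect_equal(transition_zone_fraction(prof), 4 / 19, tolerance = 1e-12)
  # a non-contiguous dip near the proximal end does not count
  prof2 <- data.frame(position_mm = 0:19,
                      aspect = c(0.7, rep(0.95, 14), rep(0.7, 5)))
  expect_equal(transition_zone_fraction(prof2), 4 / 19, tolerance = 1e-12)
  expect_error(transition_zone_fraction(prof[1:2, ]), "3 samples")
})
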