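test_that("a straight tube skeletonizes to a single axial path", {
  mask <- generate_tube_phantom(7, 40, 0.4)
  g <- skeletonize_mask(mask)
  expect_identical(nrow(g$condensed$vpaths), 1L)
  expect_false(any(g$nodes$kind == "junction"))
  # skeleton lies within one voxel diagonal of the true axis
  radial <- sqrt(g$nodes$x^2 + g$nodes$y^2)
  interior <- g$nodes$z > 5 & g$nodes$z < 35
  expect_lt(max(radial[interior]), sqrt(3) * 0.4 + 1e-9)
})

test_that("a voxelized Y-bifurcation has exactly one junction", {
  tr <- make_y_tree(D = 6, d1 = 5, d2 = 3.5, angle1_deg = 10,
                    angle2_deg = 45, L = 25, Lc = 20)
  mask <- voxelize_tree(tr, 0.4)
  g <- skeletonize_mask(mask)
  junctions <- g$condensed$vertices$vid[
    g$condensed$vertices$kind == "junction" &
      g$condensed$vertices$vid %in%
        c(g$condensed$vpaths$from_vid, g$condensed$vpaths$to_vid)]
  expect_identical(length(junctions), 1L)
  expect_identical(nrow(g$condensed$vpaths), 3L)
})

test_that("disconnected foreground falls back to the largest component", {
  m1 <- generate_tube_phantom(5, 30, 0.5)
  dims <- dim(m1$data)
  big <- array(FALSE, dims + c(30L, 0L, 0L))
  big[seq_len(dims[1]), , ] <- m1$data
  # a second, shorter tube well separated in x
  m2 <- generate_tube_phantom(5, 15, 0.5)
  d2 <- dim(m2$data)
  big[dims[1] + 10 + seq_len(d2[1]), seq_len(d2[2]), seq_len(d2[3])] <- m2$data
  mask <- voxel_mask(big, rep(0.5, 3), m1$origin_mm)
  expect_warning(g <- skeletonize_mask(mask), "largest")
  zr <- range(g$nodes$z)
  expect_gt(diff(zr), 20)  # kept the long tube
})

test_that("empty masks are rejected", {
  mask <- voxel_mask(array(FALSE, c(5, 5, 5)), rep(1, 3))
  expect_error(skeletonize_mask(mask), "empty")
})

test_that("phantom tubes are measured within the validation bound", {
  for (d in c(7, 3)) {
    mask <- generate_tube_phantom(d, 60, 0.4)
    g <- skeletonize_mask(mask)
    tree <- build_measured_tree(g, mask, root_hint = c(0, 0, 2))
    expect_identical(length(tree$branches), 1L)
    expect_lt(abs(tree$branches[[tree$root_id]]$diameter_mm - d), 0.3)
    # flat-capped tubes erode by about one radius at each end
    expect_lt(abs(tree$branches[[tree$root_id]]$length_mm - (60 - d)), 2.5)
  }
})

test_that("root hints outside the foreground are rejected", {
  mask <- generate_tube_phantom(7, 30, 0.5)
  g <- skeletonize_mask(mask)
  expect_error(build_measured_tree(g, mask, root_hint = c(20, 20, 0)),
               "outside")
})

test_that("a measured Y tree recovers diameters, lengths and angles", {
  tr <- make_y_tree(D = 8, d1 = 7, d2 = 4.5, angle1_deg = 12,
                    angle2_deg = 42, L = 30, Lc = 25)
  mask <- voxelize_tree(tr, 0.4)
  g <- skeletonize_mask(mask)
  mt <- build_measured_tree(g, mask, root_hint = c(0, 0, -2))
  expect_identical(length(mt$branches), 3L)
  expect_identical(nrow(validate_tree(mt)), 0L)
  tab <- branch_table(mt)
  tab <- tab[order(-tab$diameter_mm), ]
  expect_equal(unname(tab$diameter_mm), c(8, 7, 4.5), tolerance = 0.3 / 4.5)
  rec <- compute_bifurcations(mt, junction_skip_factor = 1)
  expect_equal(rec$angle1_deg, 12, tolerance = 5 / 12)
  expect_equal(rec$angle2_deg, 42, tolerance = 5 / 42)
})

test_that("cross-section profiles resolve circular and elliptical lumens", {
  mask <- generate_tube_phantom(10, 40, 0.4)
  prof <- measure_diameter_profile(mask, rbind(c(0, 0, 8), c(0, 0, 32)))
  expect_true(all(prof$aspect >= 0.95))
  expect_equal(mean((prof$d_min_mm + prof$d_max_mm) / 2), 10,
               tolerance = 0.03)

  # elliptical cylinder, axes 10 and 8 mm
  xs <- seq(-6.5, 6.5, by = 0.3)
  ys <- seq(-5.5, 5.5, by = 0.3)
  zs <- seq(-1, 31, by = 0.3)
  px <- rep(xs, times = length(ys) * length(zs))
  py <- rep(rep(ys, each = length(xs)), times = length(zs))
  pz <- rep(zs, each = length(xs) * length(ys))
  inside <- (px / 5)^2 + (py / 4)^2 <= 1 & pz >= 0 & pz <= 30
  mk <- voxel_mask(array(inside, c(length(xs), length(ys), length(zs))),
                   rep(0.3, 3), c(min(xs), min(ys), min(zs)))
  prof2 <- measure_diameter_profile(mk, rbind(c(0, 0, 6), c(0, 0, 24)))
  expect_equal(mean(prof2$aspect), 0.8, tolerance = 0.05)

  expect_error(measure_diameter_profile(mask, rbind(c(0, 0, 8), c(0, 0, 8))),
               "duplicate")
  expect_error(measure_diameter_profile(mask, rbind(c(15, 15, 8), c(15, 15, 20))),
               "foreground")
})

test_that("transition zones of generated parents are detected", {
  b <- airway_branch("p", NA_character_, character(),
                     rbind(c(0, 0, 0), c(0, 0, -40)), 8, 0L, "trachea",
                     meta = list(aspect0 = 0.95, aspect_end = 0.6,
                                 tz_fraction = 0.25, ellipse_axis = c(1, 0, 0)))
  spec <- airwaymorph:::branch_lumen_spec(b, is_root = TRUE)
  spec$tz_fraction <- 0.25
  spec$aspect_end <- 0.6
  spec$ellipse_axis <- c(1, 0, 0)
  dims <- c(61L, 61L, 121L)
  sp <- rep(0.4, 3)
  orig <- c(-12, -12, -44)
  p <- airwaymorph:::paint_branch(spec, dims, sp, orig)
  arr <- array(FALSE, dims)
  arr[p$i0[1]:p$i1[1], p$i0[2]:p$i1[2], p$i0[3]:p$i1[3]] <- p$sub
  mask <- voxel_mask(arr, sp, orig)
  prof <- measure_diameter_profile(mask, rbind(c(0, 0, -0.5), c(0, 0, -39.5)))
  # aspect drops below 0.9 inside the zone, stays above outside
  expect_true(all(prof$aspect[prof$position_mm < 25] > 0.9))
  expect_lt(min(prof$aspect[prof$position_mm > 35]), 0.9)
  expect_lt(abs(transition_zone_fraction(prof) - 0.25), 0.05)
})
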