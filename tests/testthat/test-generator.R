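test_that("the same seed reproduces a tree bit-identically", {
  t1 <- generate_tree(seed = 4L)
  t2 <- generate_tree(seed = 4L)
  expect_identical(t1, t2)
  t3 <- generate_tree(seed = 5L)
  expect_false(identical(t1, t3))
})

test_that("generated trees satisfy the structural and lumen invariants", {
  for (seed in 1:4) {
    tr <- generate_tree(seed = seed)
    expect_identical(nrow(validate_tree(tr)), 0L)
    recs <- compute_bifurcations(tr)
    expect_true(all(recs$d1_mm >= recs$d2_mm))
    # the tracheal-bronchus event is the one place the parent continues
    # undiminished (d1/D = 1)
    ord <- recs[recs$minor_role != "tracheal_bronchus", ]
    expect_true(all(ord$d1_ratio < 1 & ord$d2_ratio > 0))
    for (b in tr$branches) {
      if (length(b$child_ids) != 2) next
      expect_true(b$meta$tz_fraction >= 0.15 && b$meta$tz_fraction <= 0.40)
      expect_true(b$meta$divider_radius_mm >= 0.5 &&
                    b$meta$divider_radius_mm <= 1.5)
      expect_true(b$meta$aspect0 >= 0.9 && b$meta$aspect0 <= 0.98)
    }
    gens <- branch_table(tr)
    expect_true(all(gens$diameter_mm >= 1))
    expect_true(max(gens$generation) <= 24)
  }
})

test_that("the tracheal bronchus branches off before the main carina", {
  tr <- generate_tree(seed = 1L)
  root <- tr$branches[[tr$root_id]]
  kids <- lapply(root$child_ids, function(id) tr$branches[[id]])
  roles <- vapply(kids, function(b) b$role_tag, character(1))
  expect_true("tracheal_bronchus" %in% roles)
  expect_true("trachea" %in% roles)
  # the smaller daughter is the tracheal bronchus
  tb <- kids[[which(roles == "tracheal_bronchus")]]
  dt <- kids[[which(roles == "trachea")]]
  expect_lt(tb$diameter_mm, dt$diameter_mm)
  # the distal trachea then splits into the two mainstems
  mains <- vapply(dt$child_ids, function(id) tr$branches[[id]]$role_tag,
                  character(1))
  expect_setequal(mains, c("right_mainstem", "left_mainstem"))
})

test_that("the noise-free limit reproduces the class means exactly", {
  tr <- generate_tree(generator_params(sd_scale = 0), seed = 7L)
  recs <- compute_bifurcations(tr)
  recs <- recs[recs$minor_role != "tracheal_bronchus", ]
  inp <- recs[recs$planarity == "in_plane", ]
  op <- recs[recs$planarity != "in_plane", ]
  expect_equal(unique(round(inp$d1_ratio, 12)), 0.88)
  expect_equal(unique(round(inp$d2_ratio, 12)), 0.57)
  expect_equal(unique(round(op$d1_ratio, 12)), 0.86)
  expect_equal(unique(round(op$d2_ratio, 12)), 0.35)
  # angles are exact wherever parent and daughters are straight (the left
  # mainstem is a circular arc, so directions at its ends are fitted)
  straight <- recs$minor_role == "other" &
    vapply(recs$parent_id, function(id)
      tr$branches[[id]]$role_tag != "left_mainstem", logical(1))
  si <- recs[straight & recs$planarity == "in_plane", ]
  so <- recs[straight & recs$planarity != "in_plane", ]
  expect_equal(si$angle1_deg, rep(14.34, nrow(si)), tolerance = 1e-6)
  expect_equal(si$angle2_deg, rep(41.44, nrow(si)), tolerance = 1e-6)
  expect_lt(max(so$angle1_deg), 1e-5)
  expect_equal(so$angle2_deg, rep(41.37, nrow(so)), tolerance = 1e-6)
})

test_that("ensemble means converge to the configured values within 3 SE", {
  recs <- ensemble_bifurcations(n_trees = 12, seed = 42L)
  recs <- recs[recs$minor_role != "tracheal_bronchus" & !is.na(recs$planarity), ]
  expect_gt(nrow(recs), 500)
  inp <- recs[recs$planarity == "in_plane", ]
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(inp$angle1_deg) - 14.34), 3 * se(inp$angle1_deg) + 0.25)
  expect_lt(abs(mean(inp$angle2_deg) - 41.44), 3 * se(inp$angle2_deg))
  inp5 <- inp[inp$D_mm >= 5, ]
  expect_lt(abs(mean(inp5$d1_ratio) - 0.88), 3 * se(inp5$d1_ratio))
})

test_that("growth terminates at the configured diameter floor and depth", {
  tr <- generate_tree(generator_params(min_diameter_mm = 6), seed = 3L)
  tab <- branch_table(tr)
  expect_true(all(tab$diameter_mm >= 6))
  tr2 <- generate_tree(generator_params(max_generation = 3), seed = 3L)
  expect_lte(max(branch_table(tr2)$generation), 3L)
  expect_error(generator_params(min_diameter_mm = 0, max_generation = Inf),
               "non-terminating")
})

test_that("branch lengths follow the per-generation model", {
  tr <- generate_tree(seed = 9L)
  tab <- branch_table(tr)
  gen2 <- tab$length_mm[tab$generation == 2 & tab$role_tag == "other"]
  expect_equal(gen2, rep(12, length(gen2)), tolerance = 1e-9)
  deep <- tab$length_mm[tab$generation >= 5]
  expect_true(all(deep >= 5 - 1e-9 & deep <= 12 + 1e-9))
})
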