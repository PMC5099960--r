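single_branch_tree <- function(d = 10, L = 50, aspect = 1) {
  b <- airway_branch("t", NA_character_, character(),
                     rbind(c(0, 0, 0), c(0, 0, -L)), d, 0L, "trachea",
                     meta = list(aspect0 = aspect))
  airway_tree(list(b), "t")
}

test_that("voxel counts match the analytic cylinder volume", {
  d <- 10; L <- 50; sp <- 0.5
  mask <- voxelize_tree(single_branch_tree(d, L), sp)
  vol <- sum(mask$data) * prod(mask$spacing_mm)
  # flat proximal end, hemispherical distal cap
  vol_true <- pi * (d / 2)^2 * L + 2 / 3 * pi * (d / 2)^3
  expect_lt(abs(vol - vol_true) / vol_true, 0.03)
})

test_that("halving the spacing about quadruples in-plane foreground", {
  m1 <- voxelize_tree(single_branch_tree(10, 30), 1)
  m2 <- voxelize_tree(single_branch_tree(10, 30), 0.5)
  mid1 <- sum(m1$data[, , dim(m1$data)[3] %/% 2])
  mid2 <- sum(m2$data[, , dim(m2$data)[3] %/% 2])
  expect_lt(abs(mid2 / mid1 - 4), 0.5)
})

test_that("invalid or oversized trees are rejected", {
  b <- airway_branch("t", NA_character_, character(),
                     rbind(c(0, 0, 0), c(0, 0, 0)), 5, 0L, "trachea")
  degenerate <- airway_tree(list(b), "t")
  expect_error(voxelize_tree(degenerate, 0.5), "invalid tree")
  expect_error(voxelize_tree(single_branch_tree(), 0.5, max_voxels = 1000),
               "grid")
})

test_that("dilating diameters never decreases the foreground", {
  tr <- generate_tree(generator_params(min_diameter_mm = 6), seed = 2)
  m1 <- voxelize_tree(tr, 1)
  tr2 <- tr
  tr2$branches <- lapply(tr2$branches, function(b) {
    b$diameter_mm <- b$diameter_mm * 1.1
    b
  })
  m2 <- voxelize_tree(tr2, 1)
  expect_gte(sum(m2$data), sum(m1$data))
})

test_that("rigid 90-degree rotation changes foreground counts by < 2%", {
  tr <- generate_tree(generator_params(min_diameter_mm = 6), seed = 2)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  tr2 <- transform_tree(tr, Rz)
  n1 <- sum(voxelize_tree(tr, 0.5)$data)
  n2 <- sum(voxelize_tree(tr2, 0.5)$data)
  expect_lt(abs(n2 - n1) / n1, 0.02)
})

test_that("tube phantoms obey the voxel-centre rule and padding", {
  mask <- generate_tube_phantom(20, 30, 0.4)
  edt <- distance_transform(mask)
  expect_lt(abs(2 * max(edt) - 20), 2 * 0.4)
  # translation symmetry: interior axial slices share one footprint
  zs <- which(apply(mask$data, 3, sum) == max(apply(mask$data, 3, sum)))
  ref <- mask$data[, , zs[1]]
  expect_true(all(vapply(zs, function(z) identical(mask$data[, , z], ref),
                         logical(1))))
  # padded border is background
  expect_false(any(mask$data[1:2, , ]) || any(mask$data[, 1:2, ]) ||
                 any(mask$data[, , 1:2]))
  expect_error(generate_tube_phantom(0.5, 30, 0.4), "resolvable")
})

test_that("NIfTI masks round-trip with spacing and origin", {
  mask <- generate_tube_phantom(7, 20, 0.5)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mask, f)
  m2 <- read_mask(f)
  expect_identical(mask$data, m2$data)
  expect_equal(mask$spacing_mm, m2$spacing_mm)
  expect_equal(mask$origin_mm, m2$origin_mm)
})

test_that("surface meshes are watertight with analytic area and bbox", {
  tr <- single_branch_tree(10, 50)
  tris <- surface_mesh(tr, n_around = 48, step_mm = 0.5)
  expect_true(airwaymorph:::mesh_is_watertight(tris))
  area <- sum(airwaymorph:::triangle_areas(tris))
  area_true <- 2 * pi * 5 * 50 + 2 * pi * 25
  expect_lt(abs(area - area_true) / area_true, 0.02)
  pts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  expect_equal(apply(pts, 2, min), c(-5, -5, -50), tolerance = 0.02)
  expect_equal(apply(pts, 2, max), c(5, 5, 0), tolerance = 0.02)

  f <- withr::local_tempfile(fileext = ".stl")
  export_mesh(tr, f)
  expect_identical(file.info(f)$size, 84 + 50 * nrow(surface_mesh(tr)))
})

test_that("a generated tree yields a watertight multi-component mesh", {
  tr <- generate_tree(generator_params(min_diameter_mm = 8), seed = 1)
  tris <- surface_mesh(tr, n_around = 16, step_mm = 2)
  expect_true(airwaymorph:::mesh_is_watertight(tris))
})
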