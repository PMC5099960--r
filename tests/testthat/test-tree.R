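test_that("a minimal valid tree passes validation", {
  expect_identical(nrow(validate_tree(make_y_tree())), 0L)
})

test_that("validation reports structural violations by rule name", {
  tr <- make_y_tree()

  two_roots <- tr
  two_roots$branches[["a"]]$parent_id <- NA_character_
  expect_true("multiple_roots" %in% validate_tree(two_roots)$rule)

  gen_bad <- tr
  gen_bad$branches[["a"]]$generation <- -1L
  gen_bad$branches[["t"]]$generation <- 0L
  d <- validate_tree(gen_bad)
  expect_true("generation_order" %in% d$rule)
  expect_true("a" %in% d$branch_id[d$rule == "generation_order"])

  one_child <- tr
  one_child$branches[["t"]]$child_ids <- "a"
  one_child$branches[["b"]]$parent_id <- NA_character_
  expect_true("internal_degree" %in% validate_tree(one_child)$rule)

  bad_len <- tr
  bad_len$branches[["a"]]$length_mm <- bad_len$branches[["a"]]$length_mm + 1
  expect_true("length_consistency" %in% validate_tree(bad_len)$rule)

  bad_diam <- tr
  bad_diam$branches[["b"]]$diameter_mm <- -1
  expect_true("positive_diameter" %in% validate_tree(bad_diam)$rule)
})

test_that("validation never mutates its input and is idempotent", {
  tr <- make_y_tree()
  before <- tr
  d1 <- validate_tree(tr)
  d2 <- validate_tree(tr)
  expect_identical(tr, before)
  expect_identical(d1, d2)
})

test_that("JSON serialization round-trips bit-identically", {
  for (seed in 1:3) {
    tr <- generate_tree(generator_params(min_diameter_mm = 3), seed = seed)
    f <- withr::local_tempfile(fileext = ".json")
    write_tree(tr, f)
    tr2 <- read_tree(f)
    expect_identical(names(tr$branches), names(tr2$branches))
    for (id in names(tr$branches)) {
      expect_identical(tr$branches[[id]]$centerline, tr2$branches[[id]]$centerline)
      expect_identical(tr$branches[[id]]$diameter_mm, tr2$branches[[id]]$diameter_mm)
      expect_identical(tr$branches[[id]]$generation, tr2$branches[[id]]$generation)
    }
    expect_identical(tr$reference_plane$normal, tr2$reference_plane$normal)
  }
})

test_that("malformed tree files are rejected with a named field", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "1.0", "branches": []}', f)
  expect_error(read_tree(f), "root_id")

  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "9.9", "root_id": "x", "branches": []}', f2)
  expect_error(read_tree(f2), "schema version")

  expect_error(read_tree(file.path(tempdir(), "no-such-file.json")),
               "not found")
})

test_that("an invalid tree is refused by write_tree", {
  tr <- make_y_tree()
  tr$branches[["b"]]$diameter_mm <- -2
  expect_error(write_tree(tr, tempfile()), "invalid tree")
})

test_that("branch CSV export has one row per branch with unit columns", {
  tr <- generate_tree(generator_params(min_diameter_mm = 4), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_branch_csv(tr, f)
  tab <- utils::read.csv(f)
  expect_identical(nrow(tab), length(tr$branches))
  expect_true(all(c("id", "parent_id", "generation", "diameter_mm",
                    "length_mm") %in% names(tab)))
})

test_that("branch_table mirrors the tree", {
  tr <- make_y_tree()
  tab <- branch_table(tr)
  expect_identical(nrow(tab), 3L)
  expect_setequal(tab$id, c("t", "a", "b"))
  expect_equal(tab$length_mm[tab$id == "t"], 30)
})
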