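test_that("the reproduction run is deterministic and complete", {
  r1 <- run_reproduction(seed = 3, n_trees = 2)
  r2 <- run_reproduction(seed = 3, n_trees = 2)
  expect_identical(r1$value, r2$value)
  expect_identical(r1$target, sprintf("t%d", 1:12))
  expect_true(all(is.finite(r1$value)))
})

test_that("the reproduction report is written as JSON", {
  out <- file.path(withr::local_tempdir(), "rep", "report.json")
  r <- run_reproduction(seed = 2, n_trees = 2, out = out)
  expect_true(file.exists(out))
  payload <- jsonlite::fromJSON(out)
  expect_identical(sort(names(payload$targets)), sort(r$target))
  expect_equal(payload$targets$t1$value, r$value[r$target == "t1"])
})

test_that("reference values carry comparison semantics", {
  ref <- reference_morphometry()
  expect_identical(nrow(ref), 12L)
  expect_true(all(ref$cmp %in% c("eq", "le")))
})
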