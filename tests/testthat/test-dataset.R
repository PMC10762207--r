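test_that("dataset assembly unions formulas and validates metadata", {
  tabs <- list(S1 = data.frame(formula = "C6H12O6", intensity = 1),
               S2 = data.frame(formula = "C15H8O2", intensity = 1))
  md <- sample_metadata(c("S1", "S2"), c("C1", "C1"), c("shoulder", "back"),
                        c(5, 5), c("soil", "soil"))
  ds <- build_dataset(tabs, md)
  expect_equal(dim(ds$intensity), c(2L, 2L))
  expect_equal(unname(ds$intensity["C6H12O6", ]), c(1, 0))
  expect_equal(unname(ds$intensity["C15H8O2", ]), c(0, 1))
  # orphan metadata
  md3 <- sample_metadata(c("S1", "S2", "S3"), rep("C1", 3),
                         rep("shoulder", 3), rep(5, 3), rep("soil", 3))
  expect_error(build_dataset(tabs, md3), "S3")
  # metadata validity
  expect_error(sample_metadata("X", "C1", "stream", 5, "stream"), "depth")
  expect_error(sample_metadata(c("A", "A"), c("C1", "C1"),
                               c("back", "back"), c(5, 5), c("soil", "soil")),
               "duplicate")
})

test_that("sample order only permutes columns", {
  tabs <- list(S1 = data.frame(formula = c("C6H12O6", "C15H8O2"),
                               intensity = c(0.4, 0.6)),
               S2 = data.frame(formula = "C6H12O6", intensity = 1))
  md <- sample_metadata(c("S1", "S2"), c("C1", "C1"), c("shoulder", "back"),
                        c(5, 5), c("soil", "soil"))
  a <- build_dataset(tabs, md)
  b <- build_dataset(rev(tabs), md)
  expect_identical(a$intensity, b$intensity[, colnames(a$intensity)])
  expect_identical(a$formulas, b$formulas)
})

test_that("TSV round trip is lossless", {
  sim <- simulate_dataset(small_config(seed = 4))
  ds <- sim$dataset
  dp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_dataset(ds, dp, mp)
  back <- read_dataset(dp, mp)
  expect_identical(colnames(back$intensity), sort(colnames(ds$intensity)))
  common <- colnames(ds$intensity)
  expect_equal(back$intensity[rownames(ds$intensity), common],
               ds$intensity[, common], tolerance = 1e-12)
  unlink(c(dp, mp))
})

test_that("subsetting filters without renormalising and composes", {
  ds <- toy_dataset()
  sub <- subset_dataset(ds, formulas = function(f) f$formula == "C10H12O6")
  expect_equal(nrow(sub$intensity), 1L)
  expect_equal(unname(sub$intensity[1, ]), c(0.7, 0.5, 0.4))  # untouched
  s1 <- subset_dataset(ds, samples = c("S1", "S2"))
  expect_equal(ncol(s1$intensity), 2L)
  # composition equals conjunction
  both <- subset_dataset(subset_dataset(ds, samples = c("S1", "S2")),
                         formulas = function(f) f$o >= 6)
  direct <- subset_dataset(ds, formulas = function(f) f$o >= 6,
                           samples = c("S1", "S2"))
  expect_identical(both$intensity, direct$intensity)
  expect_warning(subset_dataset(ds, formulas = character(0)), "empty")
})

test_that("each sample column sums to one", {
  sim <- simulate_dataset(small_config(seed = 6))
  expect_equal(unname(colSums(sim$dataset$intensity)),
               rep(1, ncol(sim$dataset$intensity)), tolerance = 1e-9)
})
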