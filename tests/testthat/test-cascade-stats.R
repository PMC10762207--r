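test_that("the universal pool is the occupancy-thresholded formula set", {
  ds <- toy_dataset()  # A everywhere, B in 2/3, C in 1/3
  pool <- universal_set(ds)
  expect_equal(pool$formulas, "C10H12O6")
  pool23 <- universal_set(ds, threshold = 2 / 3)
  expect_setequal(pool23$formulas, c("C10H12O6", "C6H12O6"))
  # single-sample dataset: everything is universal
  one <- subset_dataset(ds, samples = "S1")
  expect_setequal(universal_set(one)$formulas, rownames(one$intensity))
  # monotone non-increasing in the threshold
  expect_true(all(universal_set(ds, 1)$formulas %in% pool23$formulas))
})

test_that("universal fractions report richness and intensity percentages", {
  ds <- toy_dataset()
  pool <- universal_set(ds)
  uf <- universal_fractions(ds, pool)
  expect_equal(uf$richness_pct, c(50, 50, 50))
  expect_equal(uf$intensity_pct, c(70, 50, 40))
  # pool = everything present in a sample gives 100 / 100
  one <- subset_dataset(ds, samples = "S1")
  uf1 <- universal_fractions(one, universal_set(one))
  expect_equal(uf1$richness_pct, 100)
  expect_equal(uf1$intensity_pct, 100)
})

test_that("universal and non-universal intensity shares are complementary", {
  sim <- simulate_dataset(small_config(seed = 2))
  pool <- universal_set(sim$dataset)
  uf <- universal_fractions(sim$dataset, pool)
  nonuni <- class_profile(sim$dataset, "intensity", "non-universal",
                          pool = pool)
  non_share <- tapply(nonuni$value, nonuni$sample_id, sum)
  expect_equal(uf$intensity_pct + 100 * as.numeric(non_share[uf$sample_id]),
               rep(100, nrow(uf)), tolerance = 1e-9)
})

test_that("class profiles sum correctly under both weightings", {
  sim <- simulate_dataset(small_config(seed = 3))
  cp <- class_profile(sim$dataset, "count", "all")
  tot <- tapply(cp$value, cp$sample_id, sum)
  expect_equal(unname(as.numeric(tot)), rep(100, length(tot)),
               tolerance = 1e-9)
  ci <- class_profile(sim$dataset, "intensity", "all")
  ti <- tapply(ci$value, ci$sample_id, sum)
  expect_equal(unname(as.numeric(ti)), rep(1, length(ti)), tolerance = 1e-9)
})

test_that("weighted mass is the intensity-weighted mean and scale-invariant", {
  ds <- toy_dataset()
  # override annotation masses with round numbers to check the arithmetic
  ds$formulas$neutral_mass <- c(200, 400, 300)[
    match(ds$formulas$formula, c("C10H12O6", "C6H12O6", "C16H22O11"))]
  ds$intensity["C10H12O6", "S2"] <- 0.5
  ds$intensity["C6H12O6", "S2"] <- 0.5
  wm <- weighted_mass(ds)
  expect_equal(wm$mz_wm[wm$sample_id == "S2"], 300, tolerance = 1e-12)
  ds$intensity["C10H12O6", "S1"] <- 0.75
  ds$intensity["C6H12O6", "S1"] <- 0.25
  wm <- weighted_mass(ds)
  expect_equal(wm$mz_wm[wm$sample_id == "S1"], 250, tolerance = 1e-12)
  # single contributing compound: its own mass
  one <- weighted_mass(ds, group = "all")
  s3 <- subset_dataset(ds, samples = "S3")
  expect_equal(weighted_mass(s3)$mz_wm,
               sum(s3$formulas$neutral_mass * s3$intensity[, 1]) /
                 sum(s3$intensity[, 1]))
  # scaling all intensities leaves the weighted mass unchanged
  ds2 <- ds
  ds2$intensity <- ds2$intensity * 7
  expect_equal(weighted_mass(ds2)$mz_wm, weighted_mass(ds)$mz_wm,
               tolerance = 1e-12)
})

test_that("carbohydrate weighted mass rises along the gradient when low-mass
           members are preferentially removed", {
  cfg0 <- small_config(seed = 100)
  lib <- generate_library(cfg0)
  up <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_dataset(small_config(seed = 1000 + s), library = lib)
    pool <- universal_set(sim$dataset)
    wm <- weighted_mass(sim$dataset, group = "carbohydrate-like",
                        subset = "non-universal", pool = pool)
    wm <- merge(wm, sim$dataset$samples, by = "sample_id")
    first <- mean(wm$mz_wm[wm$depth_cm == 5], na.rm = TRUE)
    last <- mean(wm$mz_wm[wm$depth_cm == 60], na.rm = TRUE)
    if (last > first) up <- up + 1L
  }
  # sign test against a fair coin
  expect_lt(binom.test(up, n_seeds, 0.5, alternative = "greater")$p.value,
            0.01)
})
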