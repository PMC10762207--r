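test_that("the generated library meets size, bounds and class targets", {
  cfg <- small_config(seed = 3)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), cfg$library_size)
  expect_false(anyDuplicated(lib$formula) > 0)
  expect_true(all(lib$neutral_mass >= 150 & lib$neutral_mass <= 1001))
  expect_true(all(lib$c <= 100 & lib$h >= 2 & lib$h <= 200 & lib$o <= 70 &
                    lib$n <= 3 & lib$s <= 2 & lib$p <= 2))
  # class shares within 2 points of targets (exact by construction here)
  shares <- table(lib$compound_class)[names(cfg$class_mixture)] /
    cfg$library_size
  expect_true(all(abs(shares - cfg$class_mixture) <= 0.02))
  # labels verified by the classifier itself
  expect_identical(lib$compound_class, classify(lib))
  # single-class mixture
  pure <- simulation_config(n_catchments = 1, library_size = 50,
                            universal_core_size = 10,
                            class_mixture = c("lignin-like" = 1),
                            core_mixture = c("lignin-like" = 1), seed = 2)
  expect_true(all(generate_library(pure)$compound_class == "lignin-like"))
})

test_that("the simulated dataset honours its ground truth", {
  cfg <- small_config(seed = 8)
  sim <- simulate_dataset(cfg)
  # core present in every sample, and the detected pool is exactly the core
  core_rows <- sim$dataset$intensity[sim$truth$core_formulas, ]
  expect_true(all(core_rows > 0))
  expect_setequal(universal_set(sim$dataset)$formulas,
                  sim$truth$core_formulas)
  # realised universal intensity share tracks the configured target
  uf <- universal_fractions(sim$dataset, universal_set(sim$dataset))
  tgt <- sim$truth$target_universal_share
  expect_equal(uf$intensity_pct / 100,
               tgt$share[match(uf$sample_id, tgt$sample_id)],
               tolerance = 0.02)
  # determinism under the seed
  sim2 <- simulate_dataset(small_config(seed = 8))
  expect_identical(sim$dataset$intensity, sim2$dataset$intensity)
})

test_that("a null configuration has no universal-share gradient", {
  cfg <- small_config(seed = 12, universal_intensity_slope_pp = 0,
                      gradient_effects = c("tannin-like" = 0))
  sim <- simulate_dataset(cfg)
  uf <- merge(universal_fractions(sim$dataset, universal_set(sim$dataset)),
              sim$dataset$samples, by = "sample_id")
  soil <- uf[uf$sample_type == "soil", ]
  fit <- lm(intensity_pct ~ as.numeric(as.character(depth_cm)), soil)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("noiseless peak lists round-trip through assignment exactly", {
  cfg <- small_config(seed = 13, ppm_jitter_sd = 0, noise_peak_rate = 0,
                      intensity_rep_sd = 0)
  sim <- simulate_dataset(cfg)
  tab <- data.frame(formula = rownames(sim$dataset$intensity),
                    intensity = sim$dataset$intensity[, 1])
  tab <- tab[tab$intensity > 0, ][1:120, ]
  pk <- simulate_peaklist(tab, cfg)
  res <- assign_peaklist(pk, assignment_config(mdl_factor = 0))
  expect_true(all(tab$formula %in% res$table$formula))
  # recovered intensities proportional to the planted ones
  m <- match(tab$formula, res$table$formula)
  expect_equal(res$table$intensity[m], tab$intensity / sum(tab$intensity),
               tolerance = 1e-9)
})

test_that("sub-detection-limit noise peaks do not affect assignment", {
  cfg <- small_config(seed = 14, ppm_jitter_sd = 0, noise_peak_rate = 0.2)
  sim <- simulate_dataset(cfg)
  tab <- data.frame(formula = rownames(sim$dataset$intensity),
                    intensity = sim$dataset$intensity[, 2])
  tab <- tab[tab$intensity > 0, ][1:150, ]
  pk <- simulate_peaklist(tab, cfg)
  res <- assign_peaklist(pk, assignment_config())
  expect_true(all(res$table$formula %in% tab$formula))
  expect_gte(mean(tab$formula %in% res$table$formula), 0.99)
  expect_true(any(res$log$status == "below_mdl"))
})
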