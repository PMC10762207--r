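test_that("ion-neutral mass conversion uses the proton convention", {
  expect_equal(neutral_mass_from_mz(179.056111), 180.063388, tolerance = 1e-8)
  expect_error(neutral_mass_from_mz(0), "positive")
  x <- c(150.1, 400.5, 999.9)
  expect_equal(ion_mz(neutral_mass_from_mz(x)), x, tolerance = 1e-9)
})

test_that("chemical filters reject half-integer and negative dbe", {
  cfg <- assignment_config()
  expect_false(passes_chemical_filters(
    data.frame(c = 6, h = 13, n = 0, o = 6, s = 0, p = 0), cfg))
  expect_false(passes_chemical_filters(
    data.frame(c = 2, h = 8, n = 0, o = 0, s = 0, p = 0), cfg))
  expect_true(passes_chemical_filters(
    data.frame(c = 6, h = 12, n = 0, o = 6, s = 0, p = 0), cfg))
})

test_that("candidate enumeration finds glucose and respects the window", {
  cand <- enumerate_candidates(180.063388)
  expect_true("C6H12O6" %in% cand$formula)
  expect_lt(abs(cand$mass_error_ppm[match("C6H12O6", cand$formula)]), 0.01)
  # sorted by absolute error
  expect_true(!is.unsorted(abs(cand$mass_error_ppm)))
  expect_error(enumerate_candidates(16.0313), "out of analytical window")
})

test_that("enumeration equals the exhaustive element-grid oracle", {
  set.seed(21)
  masses <- runif(8, 150 + PROTON_MASS, 400)
  for (m in masses) {
    mine <- enumerate_candidates(m)
    orc <- oracle_candidates(m)
    expect_setequal(mine$formula, orc$formula)
    if (nrow(mine)) {
      o <- orc$mass_error_ppm[match(mine$formula, orc$formula)]
      expect_equal(mine$mass_error_ppm, o, tolerance = 1e-9)
    }
  }
})

test_that("tightening the tolerance never adds candidates", {
  set.seed(22)
  masses <- runif(10, 200, 500)
  for (m in masses) {
    loose <- enumerate_candidates(m, assignment_config(ppm_tolerance = 0.5))
    tight <- enumerate_candidates(m, assignment_config(ppm_tolerance = 0.1))
    expect_true(all(tight$formula %in% loose$formula))
  }
})

test_that("replicate merging keeps only matched peaks and averages them", {
  cfg <- assignment_config()
  pk <- data.frame(mz = c(300.000000, 300.000060, 250.0),
                   intensity = c(10, 12, 5),
                   replicate_id = c("A", "B", "A"))
  m <- merge_replicates(pk, cfg)
  expect_equal(nrow(m), 1L)  # the 250 peak is only in A and is dropped
  expect_equal(m$mz, (300 * 10 + 300.00006 * 12) / 22, tolerance = 1e-12)
  expect_equal(m$intensity, 11)
  empty <- merge_replicates(data.frame(mz = numeric(), intensity = numeric(),
                                       replicate_id = character()), cfg)
  expect_equal(nrow(empty), 0L)
  expect_error(merge_replicates(data.frame(mz = 1, intensity = 1,
                                           replicate_id = "A"), cfg),
               "exactly two")
})

test_that("the detection limit keeps peaks at or above factor x noise", {
  cfg <- assignment_config()
  pk <- data.frame(mz = 1:5 + 200, intensity = c(1, 1, 1, 100, 200))
  out <- suppressMessages(apply_mdl(pk, cfg))
  expect_setequal(out$intensity, c(100, 200))
  flat <- data.frame(mz = 1:5 + 200, intensity = rep(3, 5))
  expect_warning(res <- suppressMessages(apply_mdl(flat, cfg)),
                 "detection limit")
  expect_equal(nrow(res), 0L)
  expect_equal(nrow(apply_mdl(pk[0, ], cfg)), 0L)
})

test_that("peak-list assignment normalises, sums collisions and logs", {
  cfg <- assignment_config(mdl_factor = 1)  # tiny toy: keep all real peaks
  # three peaks: two assignable (C6H12O6, C15H8O2), one hopeless m/z
  mz <- c(ion_mz(exact_neutral_mass(parse_formula("C6H12O6"))),
          ion_mz(exact_neutral_mass(parse_formula("C15H8O2"))),
          500.1234567)
  pk <- data.frame(mz = rep(mz, 2), intensity = rep(c(200, 300, 250), 2),
                   replicate_id = rep(c("A", "B"), each = 3))
  res <- suppressMessages(assign_peaklist(pk, cfg))
  expect_setequal(res$table$formula, c("C6H12O6", "C15H8O2"))
  expect_equal(sort(res$table$intensity), c(0.4, 0.6))
  expect_equal(sum(res$table$intensity), 1, tolerance = 1e-12)
  expect_equal(sum(res$log$status == "unassigned"), 1L)
  # duplicate-formula collision: two peaks both resolving to glucose
  pk2 <- data.frame(mz = rep(c(mz[1], mz[1] + mz[1] * 0.1e-6, mz[2]), 2),
                    intensity = rep(c(0.3, 0.2, 0.5), 2),
                    replicate_id = rep(c("A", "B"), each = 3))
  cfg2 <- assignment_config(replicate_match_ppm = 0.01, mdl_factor = 0)
  res2 <- suppressMessages(assign_peaklist(pk2, cfg2))
  glu <- res2$table$intensity[res2$table$formula == "C6H12O6"]
  expect_equal(glu, 0.5, tolerance = 1e-9)
  # determinism: identical input and config give identical output
  res3 <- suppressMessages(assign_peaklist(pk, cfg))
  expect_identical(res, res3)
})
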