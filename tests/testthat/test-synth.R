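# Synthetic-data generators and the packaged component catalogue.

test_that("planted peaks land exactly on theoretical adduct m/z", {
  sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 3),
                              seed = 1)
  expect_equal(sim$spectrum$mz,
               adduct_mz("C10H16O4", "[M+NH4]+") + (0:2) * monoisotopic_mass("C10H16O4"),
               tolerance = 1e-12)
  expect_equal(sim$spectrum$mz, c(218.13869, 418.24355, 618.34841),
               tolerance = 1e-7)
})

test_that("intensity decays geometrically along a series", {
  sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 4,
                                          base_intensity = 1e6, decay = 0.5),
                              seed = 2)
  expect_equal(sim$truth$intensity, 1e6 * 0.5^(0:3))
})

test_that("generators are deterministic under a fixed seed", {
  plans <- random_series_plans(enumerate_oligo_db(), n_plans = 5, seed = 808)
  a <- simulate_di_spectrum(plans, jitter_sd = 2e-4, n_noise = 40, seed = 9)
  b <- simulate_di_spectrum(plans, jitter_sd = 2e-4, n_noise = 40, seed = 9)
  expect_identical(a$spectrum, b$spectrum)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_nmr_integrals(c(A = 60, B = 40), c(2, 3),
                                          mw = c(100, 200), noise_sd = 0.05,
                                          seed = 3),
                   simulate_nmr_integrals(c(A = 60, B = 40), c(2, 3),
                                          mw = c(100, 200), noise_sd = 0.05,
                                          seed = 3))
  expect_identical(simulate_gc_run(c(X = 100), c(X = 1), noise_sd = 0.02,
                                   seed = 4),
                   simulate_gc_run(c(X = 100), c(X = 1), noise_sd = 0.02,
                                   seed = 4))
})

test_that("noise peaks respect the guard band around planted ions", {
  sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 3),
                              n_noise = 500, seed = 5)
  noise_mz <- setdiff(sim$spectrum$mz, sim$truth$mz)
  for (m in sim$truth$mz) {
    expect_true(all(abs(noise_mz - m) > 0.005))
  }
  expect_true(all(sim$spectrum$intensity[sim$spectrum$mz %in% noise_mz] < 1e4))
})

test_that("satellites sit one 13C shift up at sub-parent intensity", {
  sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 2),
                              satellites = TRUE, seed = 6)
  sat <- sim$truth[sim$truth$is_satellite, ]
  par <- sim$truth[!sim$truth$is_satellite, ]
  expect_equal(sat$mz - par$mz, rep(1.0033548, 2), tolerance = 1e-6)
  expect_true(all(sat$intensity < par$intensity))
})

test_that("members outside the scan range are clipped with a warning", {
  plan <- series_plan("cyclic [AA-BD]5-[TA-BD]4", family = "AA-BD",
                      n_members = 3)
  expect_warning(sim <- simulate_di_spectrum(plan, seed = 7), "scan range")
  expect_true(all(sim$spectrum$mz <= 2000))
})

test_that("zero concentration yields zero area", {
  run <- simulate_gc_run(c(X = 0, Y = 10), c(X = 1, Y = 1))
  expect_identical(run$area[run$analyte == "X"], 0)
})

test_that("the packaged catalogue transcribes the reference table", {
  catal <- mulch_catalogue()
  expect_identical(nrow(catal), 42L)
  atbc <- catal[catal$assignment == "ATBC", ]
  expect_identical(atbc$gcms_ions, "185;129;259")
  expect_equal(atbc$concentration_ug_g, 4210)
  expect_equal(atbc$concentration_sd, 135)
  expect_true(atbc$confirmed)
  expect_identical(sum(!is.na(catal$concentration_ug_g)), 12L)
  expect_identical(sum(grepl("Cyclic", catal$type) & !is.na(catal$gcms_ions)), 8L)
  # surrogate-quantified concentrations stay flagged
  expect_true(catal$surrogate_rf[catal$assignment == "TBA"])
  expect_false(catal$surrogate_rf[catal$assignment == "[AA-BD]2"])
})

test_that("ground truth suffices to score recall without re-deriving theory", {
  db <- enumerate_oligo_db()
  plans <- random_series_plans(db, n_plans = 5, seed = 909)
  sim <- simulate_di_spectrum(plans, seed = 910)
  s <- score_extraction(di_extract(sim$spectrum, db), sim$truth)
  expect_identical(s$n_planted, length(unique(sim$truth$label)))
  expect_identical(s$n_recovered, s$n_planted)
})
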