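# Direct-infusion sequence extraction, assignment and summarisation.

db <- enumerate_oligo_db()

test_that("threshold filtering keeps the boundary and preserves order", {
  sp <- tibble::tibble(mz = c(200, 300, 400), intensity = c(9999, 10000, 10001))
  kept <- threshold_filter(sp)
  expect_identical(kept$mz, c(300, 400))
  expect_identical(nrow(threshold_filter(sp[0, ])), 0L)
  expect_identical(nrow(threshold_filter(tibble::tibble(mz = 200, intensity = 1))), 0L)
})

test_that("a planted charge-1 ladder is extracted as one sequence", {
  sp <- tibble::tibble(mz = c(218.13869, 418.24355, 618.34841), intensity = 1e6)
  lad <- extract_ladders(sp)
  expect_identical(dplyr::n_distinct(lad$sequence_id), 1L)
  expect_identical(lad$family, rep("AA-BD", 3))
  expect_identical(lad$charge, rep(1L, 3))
  expect_identical(nrow(extract_ladders(sp[0, ])), 0L)
})

test_that("half-spacing ladders are detected at charge 2", {
  base <- 438.21234
  sp <- tibble::tibble(mz = base + (0:2) * 200.10486 / 2, intensity = 1e6)
  lad <- extract_ladders(sp)
  expect_identical(unique(lad$charge), 2L)
  expect_identical(unique(lad$family), "AA-BD")
})

test_that("sequence assignment fixes adduct and propagates by one repeat", {
  sp <- tibble::tibble(mz = c(218.13869, 418.24355, 618.34841), intensity = 1e6)
  ions <- assign_sequences(extract_ladders(sp), db)
  expect_identical(ions$label,
                   c("cyclic [AA-BD]", "cyclic [AA-BD]2", "cyclic [AA-BD]3"))
  expect_identical(unique(ions$adduct), "[M+NH4]+")
  expect_true(all(ions$assigned))
  expect_true(all(abs(ions$error_da) <= 0.001))
})

test_that("the printed 2:2 ring precursor seeds a mixed-series assignment", {
  mzs <- adduct_mz("C44H56O16", "[M+NH4]+") + (0:2) * 200.10486
  ions <- assign_sequences(extract_ladders(tibble::tibble(mz = mzs, intensity = 1e6)), db)
  expect_identical(ions$label[1], "cyclic [AA-BD]2-[TA-BD]2")
  expect_identical(ions$label[3], "cyclic [AA-BD]4-[TA-BD]2")
  expect_identical(unique(ions$adduct), "[M+NH4]+")
})

test_that("a seed matching nothing leaves the sequence unassigned", {
  sp <- tibble::tibble(mz = c(500.5, 500.5 + 72.02113), intensity = 1e6)
  ions <- assign_sequences(extract_ladders(sp), db)
  expect_true(all(!ions$assigned))
  expect_true(all(is.na(ions$label)))
})

test_that("isotopologue satellites are flagged by spacing and intensity", {
  parent_mz <- 218.13869
  sat_mz <- parent_mz + 1.00336
  sp <- tibble::tibble(mz = c(parent_mz, sat_mz, parent_mz + 200.10486),
                       intensity = c(1e6, 1.1e5, 5e5))
  ions <- assign_sequences(extract_ladders(sp), db)
  iso <- flag_isotopologues(ions, sp)
  expect_identical(iso$isotopologue, "13C")
  expect_equal(iso$mz, sat_mz)

  # satellite more intense than the parent fails the intensity rule
  sp2 <- sp
  sp2$intensity[2] <- 2e6
  expect_identical(nrow(flag_isotopologues(assign_sequences(extract_ladders(sp2), db),
                                           sp2)), 0L)
  # no satellite present
  sp3 <- sp[c(1, 3), ]
  expect_identical(nrow(flag_isotopologues(assign_sequences(extract_ladders(sp3), db),
                                           sp3)), 0L)
})

test_that("components deduplicate across adducts and exclude isotopologues", {
  mz_nh4 <- adduct_mz("C10H16O4", "[M+NH4]+") + c(0, 1, 2) * 200.10486
  mz_na <- adduct_mz("C10H16O4", "[M+Na]+") + c(0, 1, 2) * 200.10486
  sp <- tibble::tibble(mz = c(mz_nh4, mz_na), intensity = c(1e6, 8e5, 6e5, 3e5, 2e5, 1e5))
  ions <- assign_sequences(extract_ladders(sp), db)
  comp <- summarize_components(ions)
  expect_identical(nrow(comp), 3L)
  expect_identical(unique(comp$n_adducts), 2L)
  expect_identical(unique(comp$adducts), "[M+NH4]+;[M+Na]+")
  expect_identical(nrow(summarize_components(ions[0, ])), 0L)
})

test_that("single-ion species are recovered by direct database matching", {
  lone <- adduct_mz(parse_species_label("cyclic [AA-BD]6")$mass, "[M+NH4]+")
  sp <- tibble::tibble(mz = lone, intensity = 5e5)
  res <- di_extract(sp, db)
  expect_identical(res$components$label, "cyclic [AA-BD]6")
  expect_identical(res$components$n_sequences, 0L)
})

test_that("extraction recalls planted ladders perfectly on clean spectra", {
  plans <- random_series_plans(db, n_plans = 10, seed = 301)
  sim <- simulate_di_spectrum(plans, seed = 302)
  res <- di_extract(sim$spectrum, db)
  s <- score_extraction(res, sim$truth)
  expect_identical(s$recall, 1)
  expect_identical(s$n_false, 0L)
  expect_true(all(abs(res$ions$error_da[res$ions$assigned]) <= 0.001))
})

test_that("recall survives mass jitter and sub-threshold noise", {
  plans <- random_series_plans(db, n_plans = 10, seed = 303)
  sim <- simulate_di_spectrum(plans, jitter_sd = 2e-4,
                              n_noise = 10 * sum(plans$n_members), seed = 304)
  res <- di_extract(sim$spectrum, db)
  s <- score_extraction(res, sim$truth)
  expect_identical(s$recall, 1)
  expect_identical(s$n_false, 0L)
})

test_that("reported sequences are maximal under a brute-force scan", {
  plans <- random_series_plans(db, n_plans = 8, seed = 305)
  sim <- simulate_di_spectrum(plans, jitter_sd = 2e-4, seed = 306)
  filtered <- threshold_filter(sim$spectrum)
  lad <- extract_ladders(filtered)
  ru <- repeat_units()
  for (sid in unique(lad$sequence_id)) {
    s <- lad[lad$sequence_id == sid, ]
    spacing <- ru$mass[ru$unit == s$family[1]] / s$charge[1]
    below <- min(s$mz) - spacing
    above <- max(s$mz) + spacing
    expect_false(any(abs(filtered$mz - below) <= 0.001))
    expect_false(any(abs(filtered$mz - above) <= 0.001))
  }
})
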