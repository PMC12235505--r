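# LC-MS/MS annotation: EICs, precursor assignment, diagnostic fragments,
# confidence levels.

db <- enumerate_oligo_db()

test_that("EIC grouping resolves the two isomer peaks at 27.10/27.35 min", {
  feats <- dplyr::bind_rows(
    tibble::tibble(rt = c(27.00, 27.05, 27.10, 27.15, 27.20),
                   mz = 858.3907, intensity = c(1e4, 2e5, 6e5, 2e5, 1e4)),
    tibble::tibble(rt = c(27.25, 27.30, 27.35, 27.40, 27.45),
                   mz = 858.3908, intensity = c(2e4, 3e5, 8e5, 3e5, 2e4)),
    tibble::tibble(rt = 27.2, mz = 900.0, intensity = 1e6)  # outside window
  )
  pk <- extract_eic(feats, 858.3907)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$rt, c(27.10, 27.35))
  expect_identical(nrow(extract_eic(feats, 123.0)), 0L)
  single <- extract_eic(feats[1:5, ], 858.3907)
  expect_identical(nrow(single), 1L)
  expect_equal(single$rt, 27.10)
})

test_that("apexes closer than the separation threshold merge", {
  feats <- tibble::tibble(rt = c(10.00, 10.02, 10.04), mz = 500,
                          intensity = c(5e5, 1e5, 6e5))
  expect_identical(nrow(extract_eic(feats, 500)), 1L)
  expect_identical(nrow(extract_eic(feats, 500, min_separation = 0.01)), 2L)
})

test_that("precursor annotation recovers the printed 2:2 ring assignment", {
  cands <- annotate_precursor(858.3907, db)
  expect_identical(cands$label[1], "cyclic [AA-BD]2-[TA-BD]2")
  expect_identical(cands$adduct[1], "[M+NH4]+")
  expect_identical(cands$source[1], "database")
  expect_lt(abs(cands$error_ppm[1]), 5)
})

test_that("unmatched precursors fall back to CHNO formula candidates", {
  # caffeine [M+H]+; nothing ester-like in the database
  cands <- annotate_precursor(195.0877, db)
  expect_true(all(cands$source == "formula"))
  expect_true("C8H10N4O2" %in% cands$formula)
})

test_that("formula search finds the true composition within tolerance", {
  fs <- formula_search(monoisotopic_mass("C10H16O4"), tol_ppm = 3)
  expect_true("C10H16O4" %in% fs$formula)
  expect_true(all(abs(fs$error_ppm) <= 3))
  expect_false(is.unsorted(abs(fs$error_da)))
})

test_that("diagnostic generator explains the printed characteristic ions", {
  # terephthalate acylium from a TA-containing ring
  fm <- match_fragments("cyclic [AA-BD]-[TA-BD]", 149.02332)
  expect_true(fm$matched)
  # protonated adipate repeat from the AA-BD dimer ring (+0.35 ppm observed)
  fm2 <- match_fragments("cyclic [AA-BD]2", 201.11221)
  expect_true(fm2$matched)
  expect_lt(abs(fm2$error_ppm), 1)
  # empty fragment list scores zero
  fm3 <- match_fragments("cyclic [AA-BD]2", numeric(0))
  expect_identical(attr(fm3, "score"), 0)
  expect_identical(nrow(fm3), 0L)
})

test_that("every catalogued cyclic MS/MS ion is within 1 mDa of a diagnostic", {
  catal <- mulch_catalogue()
  cyc <- catal[grepl("Cyclic", catal$type) & !is.na(catal$hplc_ions) &
                 !is.na(catal$representative_species), ]
  expect_identical(nrow(cyc), 17L)
  for (i in seq_len(nrow(cyc))) {
    ions <- as.numeric(strsplit(cyc$hplc_ions[i], ";")[[1]])
    theo <- diagnostic_ions(cyc$representative_species[i])
    dev <- vapply(ions, function(m) min(abs(theo$mz - m)), numeric(1))
    expect_true(all(dev <= 1e-3),
                info = paste(cyc$assignment[i], "max dev", max(dev)))
  }
})

test_that("confidence level is a pure function of the evidence", {
  grid <- expand.grid(ref = c(TRUE, FALSE), n = 0:3)
  lvl <- assign_confidence(grid$ref, grid$n)
  expect_identical(lvl, ifelse(grid$ref, 1L, ifelse(grid$n >= 1, 2L, 3L)))
})

test_that("event annotation ties the stages together", {
  ms2 <- tibble::tibble(
    precursor_mz = 858.3907, rt = 27.10,
    fragment_mz = c(201.11221, 221.08086, 149.02332)
  )
  ann <- lc_annotate(ms2, db)
  expect_identical(ann$label, "cyclic [AA-BD]2-[TA-BD]2")
  expect_identical(ann$confidence_level, 2L)
  expect_identical(ann$n_matched, 3L)
  ann_ref <- lc_annotate(ms2, db,
                         reference_standards = "cyclic [AA-BD]2-[TA-BD]2")
  expect_identical(ann_ref$confidence_level, 1L)
})
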