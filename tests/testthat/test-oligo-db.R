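# Species construction and database enumeration/matching.

test_that("species formulas and labels follow the construction rules", {
  ring1 <- species_tbl("cyclic", n_aa_bd = 1) %>% species_formula()
  expect_identical(ring1$label, "cyclic [AA-BD]")
  expect_identical(ring1$formula, "C10H16O4")
  expect_equal(round(ring1$mass, 5), 200.10486)

  lactide <- species_tbl("cyclic", n_la = 2) %>% species_formula()
  expect_identical(lactide$formula, "C6H8O4")
  expect_equal(round(lactide$mass, 5), 144.04226)

  me_la3 <- species_tbl("linear", end_group = "methyl", n_la = 3) %>%
    species_formula()
  expect_identical(me_la3$label, "Me-[LA]3")
  expect_equal(me_la3$mass, 248.08961, tolerance = 1e-7)

  bd2 <- species_tbl("linear", end_group = "bd", n_aa_bd = 2) %>%
    species_formula()
  expect_identical(bd2$label, "BD-[AA-BD]2")
  expect_identical(bd2$formula, "C24H42O10")
  expect_equal(round(bd2$mass, 5), 490.27780)
})

test_that("inconsistent topology/end-group combinations are rejected", {
  expect_error(species_formula(species_tbl("cyclic", end_group = "free",
                                           n_la = 2)), "cyclic")
  expect_error(species_formula(species_tbl("linear", end_group = "none",
                                           n_la = 2)), "end group")
  expect_error(species_formula(species_tbl("cyclic")), "at least one")
})

test_that("species labels round-trip through the parser", {
  labels <- c("cyclic [AA-BD]2-[TA-BD]2", "Me-[LA]3", "BD-[AA-BD]2",
              "linear [AA-BD]2-[TA-BD]", "cyclic [TA-BD]-[SeA-BD]5")
  parsed <- parse_species_label(labels)
  expect_identical(parsed$label, labels)
})

test_that("enumeration matches brute-force multiset counts for small bounds", {
  # one ring per family
  cfg1 <- oligo_db_config(
    blocks = list(db_block("cyclic", "none",
                           list("AA-BD" = c(0, 1), "TA-BD" = c(0, 1),
                                "SeA-BD" = c(0, 1), "LA" = c(0, 1)),
                           total = c(1, 1))),
    min_ring_size = c("LA" = 1L, "AA-BD" = 1L, "TA-BD" = 1L, "SeA-BD" = 1L)
  )
  expect_identical(nrow(enumerate_oligo_db(cfg1)), 4L)

  # all cyclic compositions of total size <= 2 over 4 families: 4 + C(5,2)
  cfg2 <- oligo_db_config(
    blocks = list(db_block("cyclic", "none",
                           list("AA-BD" = c(0, 2), "TA-BD" = c(0, 2),
                                "SeA-BD" = c(0, 2), "LA" = c(0, 2)),
                           total = c(1, 2))),
    min_ring_size = c("LA" = 1L, "AA-BD" = 1L, "TA-BD" = 1L, "SeA-BD" = 1L)
  )
  expect_identical(nrow(enumerate_oligo_db(cfg2)), 14L)

  # closed form per total size, a few sizes
  for (t in 1:4) {
    cfg <- oligo_db_config(
      blocks = list(db_block("cyclic", "none",
                             list("AA-BD" = c(0, t), "TA-BD" = c(0, t),
                                  "SeA-BD" = c(0, t), "LA" = c(0, t)),
                             total = c(t, t))),
      min_ring_size = c("LA" = 1L, "AA-BD" = 1L, "TA-BD" = 1L, "SeA-BD" = 1L)
    )
    expect_identical(nrow(enumerate_oligo_db(cfg)),
                     as.integer(multiset_count(t, 4)))
  }
})

test_that("default database covers the observed series and is stable", {
  db <- enumerate_oligo_db()
  expect_true("cyclic [AA-BD]5-[TA-BD]4" %in% db$label)
  expect_true("cyclic [AA-BD]6-[TA-BD]3" %in% db$label)
  expect_true("Me-[LA]20" %in% db$label)
  expect_true("Me-[AA-BD]4-[LA]7" %in% db$label)  # canonical unit order
  expect_true("cyclic [TA-BD]3-[SeA-BD]4" %in% db$label)
  expect_false("cyclic [LA]" %in% db$label)  # below minimum ring size
  expect_identical(anyDuplicated(db$label), 0L)
  expect_false(is.unsorted(db$mass))
  expect_identical(db, enumerate_oligo_db())
})

test_that("every enumerated mass equals the naive monomer-summation oracle", {
  db <- enumerate_oligo_db()
  oracle <- mapply(oracle_species_mass, db$n_aa_bd, db$n_ta_bd,
                   db$n_sea_bd, db$n_la, db$end_group)
  expect_true(all(abs(db$mass - oracle) < 1e-9))
})

test_that("cyclic masses are exact integer combinations of repeat masses", {
  db <- enumerate_oligo_db()
  cyc <- db[db$topology == "cyclic", ]
  ru <- repeat_units()
  combo <- as.matrix(cyc[c("n_aa_bd", "n_ta_bd", "n_sea_bd", "n_la")]) %*%
    ru$mass[match(c("AA-BD", "TA-BD", "SeA-BD", "LA"), ru$unit)]
  expect_true(all(abs(cyc$mass - as.numeric(combo)) < 1e-9))
})

test_that("neutral-mass matching ranks by absolute error and can be empty", {
  db <- enumerate_oligo_db()
  hit <- match_neutral(db, 840.35684)
  expect_identical(hit$label[1], "cyclic [AA-BD]2-[TA-BD]2")
  hit2 <- match_neutral(db, 200.10486)
  expect_identical(hit2$label, "cyclic [AA-BD]")  # free linear is at 218.115
  expect_identical(nrow(match_neutral(db, 500.0)), 0L)
})

test_that("an oversized configuration is refused before enumeration", {
  cfg <- oligo_db_config(
    blocks = list(db_block("cyclic", "none",
                           list("AA-BD" = c(0, 60), "TA-BD" = c(0, 60),
                                "SeA-BD" = c(0, 60), "LA" = c(0, 60)))),
    max_species = 1e5
  )
  expect_error(enumerate_oligo_db(cfg), "tighten")
})

test_that("database CSV export/import round-trips", {
  db <- enumerate_oligo_db()
  path <- withr::local_tempfile(fileext = ".csv")
  write_oligo_db(db, path)
  back <- read_oligo_db(path)
  expect_equal(as.data.frame(back), as.data.frame(db))
  expect_error(read_oligo_db(withr::local_tempfile(lines = "a,b\n1,2",
                                                   fileext = ".csv")),
               "lacks column")
})
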