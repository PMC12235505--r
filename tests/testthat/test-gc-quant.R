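# Internal-standard GC quantification.

test_that("response factors follow the area-per-concentration convention", {
  expect_identical(response_factor(100, 0.1, 100, 0.1), 1)
  expect_identical(response_factor(200, 0.1, 100, 0.1), 2)
  expect_equal(response_factor(150, 0.10, 100, 0.10), 1.5)
  expect_error(response_factor(0, 0.1, 100, 0.1), "positive")
})

test_that("the unit arithmetic of quantification is correct", {
  run <- tibble::tibble(analyte = c("X", "BBP"), area = c(1e5, 1e5))
  calib <- tibble::tibble(analyte = "X", rf = 1)
  q <- gc_quantify(run, calib, is_amount_ug = 250, sample_mass_g = 0.1)
  expect_equal(q$concentration_ug_g, 2500)
})

test_that("a noiseless simulated run round-trips exactly", {
  conc <- c(ATBC = 4210, TBA = 1400, `cyclic [AA-BD]2` = 772)
  rfs <- c(ATBC = 1.2, TBA = 0.8, `cyclic [AA-BD]2` = 1.05)
  run <- simulate_gc_run(conc, rfs)
  calib <- tibble::tibble(analyte = names(rfs), rf = unname(rfs),
                          surrogate = c(FALSE, TRUE, FALSE))
  q <- gc_quantify(run, calib)
  expect_equal(stats::setNames(q$concentration_ug_g, q$analyte)[names(conc)],
               conc, tolerance = 1e-12)
  expect_identical(q$surrogate[q$analyte == "TBA"], TRUE)
})

test_that("quantification is linear in area and inverse in RF and mass", {
  set.seed(606)
  for (i in 1:10) {
    area <- stats::runif(1, 1e4, 1e6)
    rf <- stats::runif(1, 0.5, 2)
    mass <- stats::runif(1, 0.05, 0.5)
    base <- gc_quantify(tibble::tibble(analyte = c("X", "BBP"),
                                       area = c(area, 1e5)),
                        tibble::tibble(analyte = "X", rf = rf),
                        sample_mass_g = mass)$concentration_ug_g
    doubled <- gc_quantify(tibble::tibble(analyte = c("X", "BBP"),
                                          area = c(2 * area, 1e5)),
                           tibble::tibble(analyte = "X", rf = rf),
                           sample_mass_g = mass)$concentration_ug_g
    expect_equal(doubled, 2 * base)
    half_rf <- gc_quantify(tibble::tibble(analyte = c("X", "BBP"),
                                          area = c(area, 1e5)),
                           tibble::tibble(analyte = "X", rf = rf / 2),
                           sample_mass_g = mass)$concentration_ug_g
    expect_equal(half_rf, 2 * base)
    double_mass <- gc_quantify(tibble::tibble(analyte = c("X", "BBP"),
                                              area = c(area, 1e5)),
                               tibble::tibble(analyte = "X", rf = rf),
                               sample_mass_g = 2 * mass)$concentration_ug_g
    expect_equal(double_mass, base / 2)
  }
})

test_that("replicates are averaged with their own internal standards", {
  run <- dplyr::bind_rows(
    tibble::tibble(analyte = c("X", "BBP"), area = c(1e5, 1e5), replicate = 1L),
    tibble::tibble(analyte = c("X", "BBP"), area = c(2.2e5, 2e5), replicate = 2L)
  )
  q <- gc_quantify(run, tibble::tibble(analyte = "X", rf = 1))
  expect_identical(q$n, 2L)
  expect_equal(q$concentration_ug_g, mean(c(2500, 2750)))
  expect_equal(q$sd, stats::sd(c(2500, 2750)))
})

test_that("area noise leaves the mean concentration unbiased", {
  conc <- c(A = 500, B = 2000)
  rfs <- c(A = 1.3, B = 0.7)
  reps <- 300
  est <- matrix(NA_real_, reps, 2)
  set.seed(707)
  for (r in 1:reps) {
    run <- simulate_gc_run(conc, rfs, noise_sd = 0.02)
    q <- gc_quantify(run, tibble::tibble(analyte = names(rfs), rf = unname(rfs)))
    est[r, ] <- stats::setNames(q$concentration_ug_g, q$analyte)[names(conc)]
  }
  rel_bias <- abs(colMeans(est) - conc) / conc
  expect_true(all(rel_bias < 0.005))
})

test_that("missing inputs are refused with the analyte named", {
  run <- tibble::tibble(analyte = c("X", "Y", "BBP"), area = c(1, 2, 3))
  expect_error(gc_quantify(run, tibble::tibble(analyte = "X", rf = 1)), "Y")
  expect_error(gc_quantify(run, tibble::tibble(analyte = c("X", "Y"), rf = c(1, 0))),
               "response factors")
  expect_error(gc_quantify(tibble::tibble(analyte = "X", area = 1),
                           tibble::tibble(analyte = "X", rf = 1)),
               "internal-standard")
})

test_that("catalogued cyclic concentrations reproduce the combined figure", {
  catal <- mulch_catalogue()
  cyc_sum <- sum(catal$concentration_ug_g[grepl("Cyclic", catal$type)],
                 na.rm = TRUE)
  expect_lt(abs(cyc_sum - 2900) / 2900, 0.005)
})

test_that("recovery is a plain percentage with a guarded denominator", {
  expect_identical(recovery(50, 50), 100)
  expect_identical(recovery(33.5, 50), 67)
  expect_identical(recovery(0, 50), 0)
  expect_error(recovery(10, 0), "positive")
})
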