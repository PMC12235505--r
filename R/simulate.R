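# Seeded synthetic-data generators: direct-infusion spectra with planted
# oligomer ladders, NMR integral tables and GC run tables, each the exact
# inverse of the corresponding analysis stage so that round-trip recovery can
# be scored without instrument data.

#' Plan one synthetic oligomer ion series
#'
#' Describes a ladder to plant in a synthetic direct-infusion spectrum: a
#' seed species, the repeat family along which it extends, the adduct (which
#' fixes the charge), the number of members, and a geometric intensity decay
#' (real oligoester series decay in intensity as size grows).
#'
#' @param species Canonical species label of the seed (lowest-mass member),
#'   e.g. `"cyclic [AA-BD]"`.
#' @param family Repeat family appended per step; defaults to the first
#'   family present in the seed.
#' @param adduct Adduct name (see [adducts()]).
#' @param n_members Number of ladder members (>= 1).
#' @param base_intensity Intensity of the seed ion.
#' @param decay Per-step intensity multiplier in (0, 1].
#' @return A one-row tibble; rows from repeated calls can be bound together.
#' @examples
#' series_plan("cyclic [AA-BD]", n_members = 3)
#' @export
series_plan <- function(species, family = NULL, adduct = "[M+NH4]+",
                        n_members = 3, base_intensity = 1e6, decay = 0.6) {
  stopifnot(n_members >= 1, base_intensity > 0, decay > 0, decay <= 1)
  sp <- parse_species_label(species)
  if (is.null(family)) {
    family <- .FAMILIES[which(as.numeric(sp[1, .COUNT_COLS]) > 0)[1]]
  }
  stopifnot(family %in% .FAMILIES)
  .adduct_row(adduct)  # validates
  tibble(species = species, family = family, adduct = adduct,
         n_members = as.integer(n_members), base_intensity = base_intensity,
         decay = decay)
}

# Gaussian jitter truncated at +/-2.5 sd (rejection sampling; seeded callers
# stay deterministic)
.truncated_jitter <- function(n, sd) {
  j <- stats::rnorm(n, 0, sd)
  bad <- abs(j) > 2.5 * sd
  while (any(bad)) {
    j[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(j) > 2.5 * sd
  }
  j
}

#' Simulate a direct-infusion centroid spectrum
#'
#' Plants the planned ion series at their theoretical adduct m/z (plus
#' optional Gaussian mass jitter), adds optional 13C satellite peaks and
#' uniform-random noise peaks, and returns both the spectrum and the ground
#' truth needed to score extraction recall. Noise peaks are kept out of a
#' +/-0.005 Da guard band around every planted peak so that ground-truth
#' scoring is unambiguous. Output is deterministic for a given seed.
#'
#' @param plans A plan table from [series_plan()] (rows bound together).
#' @param jitter_sd Gaussian m/z jitter standard deviation in Da; draws are
#'   truncated at +/- 2.5 standard deviations, mirroring an instrument
#'   mass-accuracy specification (a bounded error, not a heavy tail).
#' @param n_noise Number of random noise peaks.
#' @param noise_intensity Intensity range `c(min, max)` for noise peaks
#'   (default below the 1e4 working threshold).
#' @param satellites Add a 13C isotopologue satellite to every planted peak
#'   at relative intensity `0.011 * nC` (the ~1.1% per-carbon natural
#'   abundance heuristic; only the flagging rule downstream depends on it).
#' @param mz_range Instrument scan range; planted members falling outside are
#'   dropped with a warning.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `di_simulation`: `spectrum` (tibble `mz`,
#'   `intensity`), `truth` (planted ions with `label`, `adduct`, `charge`,
#'   `theo_mz`, `mz`, `intensity`, `is_satellite`), and `params`.
#' @examples
#' sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 3),
#'                             seed = 42)
#' sim$spectrum
#' @export
simulate_di_spectrum <- function(plans, jitter_sd = 0, n_noise = 0,
                                 noise_intensity = c(1e2, 9e3),
                                 satellites = FALSE,
                                 mz_range = c(150, 2000), seed = NULL) {
  stopifnot(jitter_sd >= 0, n_noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  fam_col <- stats::setNames(.COUNT_COLS, .FAMILIES)
  truth <- list()
  for (i in seq_len(nrow(plans))) {
    p <- plans[i, ]
    seed_sp <- parse_species_label(p$species)
    n <- p$n_members
    members <- seed_sp[rep(1, n), c("topology", "end_group", .COUNT_COLS)]
    members[[fam_col[[p$family]]]] <- members[[fam_col[[p$family]]]] + seq_len(n) - 1L
    members <- species_formula(members)
    z <- .adduct_row(p$adduct)$charge
    theo <- adduct_mz(members$mass, p$adduct)
    obs <- theo + if (jitter_sd > 0) .truncated_jitter(n, jitter_sd) else 0
    keep <- obs >= mz_range[1] & obs <= mz_range[2]
    if (any(!keep)) {
      warn(paste0("plan ", i, " (", p$species, "): ", sum(!keep),
                  " member(s) outside the m/z scan range were dropped"))
    }
    if (!any(keep)) next
    truth[[length(truth) + 1]] <- tibble(
      label = members$label[keep], formula = members$formula[keep],
      adduct = p$adduct, charge = z, theo_mz = theo[keep], mz = obs[keep],
      intensity = p$base_intensity * p$decay^(seq_len(n) - 1)[keep],
      is_satellite = FALSE
    )
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) == 0) abort("no planted peaks fall inside the scan range")

  if (satellites) {
    sat <- truth %>%
      mutate(mz = .data$mz + .ISOTOPE_SHIFTS[["13C"]] / .data$charge,
             theo_mz = .data$theo_mz + .ISOTOPE_SHIFTS[["13C"]] / .data$charge,
             intensity = .data$intensity * 0.011 * element_count(.data$formula, "C"),
             is_satellite = TRUE)
    truth <- dplyr::bind_rows(truth, sat)
  }

  noise <- tibble(mz = numeric(0), intensity = numeric(0))
  if (n_noise > 0) {
    guard <- 0.005
    mzs <- numeric(0)
    while (length(mzs) < n_noise) {
      cand <- stats::runif(n_noise, mz_range[1], mz_range[2])
      ok <- vapply(cand, function(m) all(abs(truth$mz - m) > guard), logical(1))
      mzs <- c(mzs, cand[ok])
    }
    mzs <- mzs[seq_len(n_noise)]
    noise <- tibble(mz = mzs,
                    intensity = stats::runif(n_noise, noise_intensity[1],
                                             noise_intensity[2]))
  }

  spectrum <- dplyr::bind_rows(truth[c("mz", "intensity")], noise) %>% .as_spectrum()
  structure(
    list(spectrum = spectrum, truth = truth,
         params = list(jitter_sd = jitter_sd, n_noise = n_noise,
                       noise_intensity = noise_intensity,
                       satellites = satellites, mz_range = mz_range,
                       seed = seed)),
    class = "di_simulation"
  )
}

#' Simulate an NMR signal table
#'
#' Inverse of [mole_percent()]: integrals are generated proportional to
#' `mol% * protons`, arbitrarily scaled, with optional multiplicative
#' Gaussian noise. Default molecular weights are the average repeat-unit
#' masses of the four film polyesters (PBA, PBT, PLA, PBSe) when the polymer
#' names match; otherwise supply `mw`.
#'
#' @param mol_percents Named numeric vector of molar percentages; must sum to
#'   100 within 1e-6.
#' @param proton_counts Integer protons per assigned signal, same length.
#' @param mw Repeat-unit molecular weights (average-mass basis); defaults to
#'   built-in values for PBA/PBT/PLA/PBSe names.
#' @param noise_sd Multiplicative noise standard deviation (0 = exact).
#' @param scale Arbitrary overall intensity scale.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A signal tibble (`polymer`, `signal`, `integral`, `protons`, `mw`)
#'   ready for [nmr_composition()].
#' @export
simulate_nmr_integrals <- function(mol_percents, proton_counts, mw = NULL,
                                   noise_sd = 0, scale = 100, seed = NULL) {
  if (abs(sum(mol_percents) - 100) > 1e-6) {
    abort("mol_percents must sum to 100")
  }
  stopifnot(length(proton_counts) == length(mol_percents), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  polymers <- names(mol_percents) %||% paste0("P", seq_along(mol_percents))
  if (is.null(mw)) {
    defaults <- c(PBA = average_mass("C10H16O4"), PBT = average_mass("C12H12O4"),
                  PLA = average_mass("C3H4O2"), PBSe = average_mass("C14H24O4"))
    mw <- unname(defaults[polymers])
    if (any(is.na(mw))) {
      abort("no default molecular weight for these polymer names; supply mw")
    }
  }
  integral <- mol_percents * proton_counts * scale
  if (noise_sd > 0) integral <- integral * (1 + stats::rnorm(length(integral), 0, noise_sd))
  tibble(
    polymer = polymers,
    signal = letters[seq_along(polymers)],
    integral = unname(integral),
    protons = as.integer(proton_counts),
    mw = mw
  )
}

#' Simulate a GC run table
#'
#' Inverse of [gc_quantify()]: peak areas are generated from known
#' concentrations and response factors, `area_i = conc_i * RF_i *
#' m_sample / m_IS * area_IS`, with optional multiplicative Gaussian noise on
#' the analyte areas. The internal-standard row is included noise-free.
#'
#' @param concentrations Named numeric vector of true concentrations (ug/g).
#' @param rfs Named response factors covering every analyte.
#' @param is_analyte,is_amount_ug,sample_mass_g,is_area Internal-standard
#'   name, amount (ug), sample mass (g) and IS peak area.
#' @param noise_sd Multiplicative area noise standard deviation.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A run tibble (`analyte`, `area`) including the IS row.
#' @export
simulate_gc_run <- function(concentrations, rfs, is_analyte = "BBP",
                            is_amount_ug = 250, sample_mass_g = 0.1,
                            is_area = 1e6, noise_sd = 0, seed = NULL) {
  stopifnot(all(concentrations >= 0), is_amount_ug > 0, sample_mass_g > 0,
            is_area > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  analytes <- names(concentrations)
  if (is.null(analytes)) abort("concentrations must be a named vector")
  rf <- rfs[analytes]
  if (any(is.na(rf))) {
    abort(paste0("missing response factor for: ",
                 paste(analytes[is.na(rf)], collapse = ", ")))
  }
  area <- concentrations * rf * sample_mass_g / is_amount_ug * is_area
  if (noise_sd > 0) area <- area * (1 + stats::rnorm(length(area), 0, noise_sd))
  tibble(analyte = c(analytes, is_analyte),
         area = c(unname(area), is_area))
}

#' Packaged catalogue of detected mulch-film components
#'
#' The reference catalogue of organic components detected in a commercial
#' PLA/PBAT mulch film: additives, lubricants and oligoester NIAS series,
#' with their characteristic GC-MS (nominal) and HPLC-MS/MS (accurate) ions,
#' direct-infusion detection status, reference-standard confirmation,
#' GC-FID concentrations in ug per g film (sd alongside), and a flag for
#' concentrations quantified with a surrogate response factor.
#' `representative_species` gives the canonical label of the largest series
#' member, where the assignment maps onto the oligoester species model.
#'
#' @return A tibble with one row per catalogue entry (series sub-ranges keep
#'   their own rows, mirroring the source table layout).
#' @examples
#' mulch_catalogue() %>% dplyr::filter(!is.na(concentration_ug_g))
#' @export
mulch_catalogue <- function() {
  path <- system.file("extdata", "mulch_components.csv", package = "oligoscreen",
                      mustWork = TRUE)
  readr::read_csv(
    path,
    col_types = readr::cols(
      assignment = "c", type = "c", n_range = "c", m_range = "c",
      gcms_ions = "c", di_detected = "c", hplc_ions = "c", confirmed = "c",
      concentration_ug_g = "d", concentration_sd = "d", surrogate_rf = "c",
      representative_species = "c"
    )
  ) %>%
    mutate(confirmed = !is.na(.data$confirmed) & .data$confirmed == "yes",
           surrogate_rf = dplyr::if_else(is.na(.data$surrogate_rf), NA,
                                         .data$surrogate_rf == "yes"))
}

#' Draw random, identifiable series plans from a database
#'
#' Samples ladder plans for recall/precision benchmarking of the extraction
#' stage. The generator only produces ground truths that are identifiable in
#' principle: (a) seed species are restricted to those whose seed ion is
#' mass-unambiguous, i.e. no other database species lies within `margin` Da
#' of the neutral mass implied by any supported adduct hypothesis at that
#' charge; (b) a drawn plan set is rejected and redrawn if any pair of
#' planted peaks from different plans falls within the ladder tolerance of a
#' repeat spacing (or near-coincides), which would create unintended chains.
#' Both guards concern the construction of the truth, not the extractor.
#'
#' @param db Species table from [enumerate_oligo_db()].
#' @param n_plans Number of ladders to plant.
#' @param adducts Adducts to sample from.
#' @param members Range `c(min, max)` of members per ladder.
#' @param base_intensity Range for seed intensities (log-uniform).
#' @param decay Range for per-step decay factors.
#' @param margin Seed-ambiguity margin in Da.
#' @param tol Ladder tolerance the extractor will use (sets the collision
#'   guard band).
#' @param mz_range Instrument scan range every member must fall in.
#' @param seed Integer seed.
#' @return A plan tibble for [simulate_di_spectrum()].
#' @export
random_series_plans <- function(db, n_plans = 20,
                                adducts = c("[M+NH4]+", "[M+H]+", "[M+Na]+", "[M+2NH4]2+"),
                                members = c(2, 5),
                                base_intensity = c(1e5, 1e7),
                                decay = c(0.4, 0.9),
                                margin = 0.003, tol = 0.001,
                                mz_range = c(150, 2000), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam_col <- stats::setNames(.COUNT_COLS, .FAMILIES)
  adduct_info <- .adduct_row(adducts)
  adduct_info$adduct <- adducts

  # candidate (species, adduct) pairs with unambiguous seeds
  cands <- list()
  for (j in seq_len(nrow(adduct_info))) {
    a <- adduct_info$adduct[j]
    z <- adduct_info$charge[j]
    seed_mz <- adduct_mz(db$mass, a)
    ok <- seed_mz >= mz_range[1] & seed_mz <= mz_range[2]
    hyp <- adduct_info[adduct_info$charge == z, , drop = FALSE]
    for (h in hyp$adduct) {
      neutral_h <- neutral_mass_from_mz(pmax(seed_mz, 1e-6), h)
      n_hits <- vapply(neutral_h, function(m) sum(abs(db$mass - m) <= margin),
                       integer(1))
      expected <- as.integer(h == a)  # only the true self-match is allowed
      ok <- ok & n_hits == expected
    }
    if (any(ok)) {
      cands[[length(cands) + 1]] <- tibble(label = db$label[ok], adduct = a,
                                           mass = db$mass[ok], charge = z)
    }
  }
  cands <- dplyr::bind_rows(cands)
  if (nrow(cands) < n_plans) {
    abort("not enough unambiguous (species, adduct) candidates for n_plans")
  }

  spacings <- c(0, as.vector(outer(repeat_units()$mass,
                                   unique(adduct_info$charge), `/`)))
  guard <- 2 * tol + 5e-4  # tolerance plus two truncated jitters

  plan_peaks <- function(p) {
    sp <- parse_species_label(p$species)
    mem <- sp[rep(1, p$n_members), c("topology", "end_group", .COUNT_COLS)]
    mem[[fam_col[[p$family]]]] <- mem[[fam_col[[p$family]]]] +
      seq_len(p$n_members) - 1L
    adduct_mz(species_formula(mem)$mass, p$adduct)
  }
  # accept plans one at a time: species differing by whole repeat units under
  # the same adduct are systematically spacing-related, so whole-set draws
  # would almost always collide somewhere
  order_idx <- sample.int(nrow(cands))
  plans <- NULL
  accepted_mz <- numeric(0)
  for (i in order_idx) {
    p <- series_plan(
      cands$label[i], adduct = cands$adduct[i],
      n_members = sample(seq.int(members[1], members[2]), 1),
      base_intensity = exp(stats::runif(1, log(base_intensity[1]),
                                        log(base_intensity[2]))),
      decay = stats::runif(1, decay[1], decay[2])
    )
    pk <- plan_peaks(p)
    if (any(pk < mz_range[1] | pk > mz_range[2])) next
    d <- abs(outer(pk, accepted_mz, `-`))
    if (length(accepted_mz) > 0 &&
        any(vapply(spacings, function(s) any(abs(d - s) <= guard), logical(1)))) {
      next
    }
    plans <- dplyr::bind_rows(plans, p)
    accepted_mz <- c(accepted_mz, pk)
    if (nrow(plans) == n_plans) return(plans)
  }
  abort("could not assemble a collision-free plan set; lower n_plans")
}

#' Score extraction recall against a planted ground truth
#'
#' Compares the component table of a [di_extract()] result with the planted
#' (non-satellite) species of a [simulate_di_spectrum()] ground truth.
#'
#' @param result A `di_extraction` object.
#' @param truth The `truth` tibble of a `di_simulation`.
#' @return A one-row tibble: `n_planted`, `n_recovered`, `recall`,
#'   `n_false` (components not planted), `false_labels`.
#' @export
score_extraction <- function(result, truth) {
  planted <- unique(truth$label[!truth$is_satellite])
  found <- result$components$label
  false_labels <- setdiff(found, planted)
  tibble(
    n_planted = length(planted),
    n_recovered = sum(planted %in% found),
    recall = sum(planted %in% found) / length(planted),
    n_false = length(false_labels),
    false_labels = paste(false_labels, collapse = ";")
  )
}
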