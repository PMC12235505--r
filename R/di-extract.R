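# Direct-infusion oligomer sequence extraction.
#
# The algorithm follows the screening workflow for polyester films: threshold
# the centroided spectrum, walk it for chains of peaks separated by a repeat-
# unit mass (divided by charge) within an absolute tolerance, assign the
# lowest ion of each chain against the predicted structure database under all
# supported adduct hypotheses, propagate the assignment up the chain one
# repeat unit at a time, flag 13C/18O isotopologue satellites, and collapse
# the assigned ions into a deduplicated component table.

.as_spectrum <- function(spectrum) {
  spectrum <- as_tibble(spectrum)
  if (!all(c("mz", "intensity") %in% names(spectrum))) {
    abort("a centroid spectrum needs 'mz' and 'intensity' columns")
  }
  if (nrow(spectrum) == 0) return(spectrum[c("mz", "intensity")])
  if (any(!is.finite(spectrum$mz)) || any(!is.finite(spectrum$intensity))) {
    abort("spectrum contains non-finite m/z or intensity values")
  }
  if (any(spectrum$mz <= 0) || any(spectrum$intensity < 0)) {
    abort("spectrum m/z must be > 0 and intensities >= 0")
  }
  spectrum <- spectrum[order(spectrum$mz), c("mz", "intensity")]
  # merge centroids closer than 1e-6 Da (duplicate export artefacts)
  grp <- cumsum(c(TRUE, diff(spectrum$mz) > 1e-6))
  if (max(grp) < nrow(spectrum)) {
    spectrum <- spectrum %>%
      mutate(.grp = grp) %>%
      group_by(.data$.grp) %>%
      summarise(mz = .data$mz[1], intensity = sum(.data$intensity),
                .groups = "drop") %>%
      select("mz", "intensity")
  }
  spectrum
}

#' Intensity threshold filter
#'
#' Retains peaks at or above the minimum intensity (inclusive boundary), the
#' first step of the direct-infusion sequence-extraction workflow. The default
#' of 1e4 counts is the working Orbitrap threshold below which centroid mass
#' accuracy degrades.
#'
#' @param spectrum A data frame with `mz` and `intensity` columns.
#' @param min_intensity Minimum retained intensity (default `1e4`).
#' @return The filtered spectrum as a tibble, m/z-sorted.
#' @export
threshold_filter <- function(spectrum, min_intensity = 1e4) {
  stopifnot(min_intensity >= 0)
  spectrum <- .as_spectrum(spectrum)
  spectrum[spectrum$intensity >= min_intensity, , drop = FALSE]
}

# greedy maximal-chain search for one family and charge; returns a list of
# integer index vectors into the peak table
.find_chains <- function(mz, intensity, spacing, tol) {
  n <- length(mz)
  chains <- list()
  for (i in seq_len(n)) {
    # maximality at the front: a peak with an in-tolerance predecessor will be
    # reached from that predecessor's chain instead
    if (any(abs(mz - (mz[i] - spacing)) <= tol)) next
    chain <- i
    repeat {
      expected <- mz[chain[length(chain)]] + spacing
      err <- abs(mz - expected)
      cand <- which(err <= tol)
      if (length(cand) == 0) break
      # smallest |mass error| wins; ties go to the most intense candidate
      best <- cand[order(err[cand], -intensity[cand])][1]
      chain <- c(chain, best)
    }
    if (length(chain) >= 2) chains[[length(chains) + 1]] <- chain
  }
  chains
}

#' Extract oligomer ion ladders
#'
#' Finds maximal chains of peaks whose successive m/z values differ by a
#' repeat-unit mass divided by the charge, within an absolute tolerance
#' (default +/-0.001 Da applied to each pairwise difference). Extension is
#' greedy and deterministic: among candidate peaks inside the tolerance
#' window of the expected next m/z, the smallest absolute error wins, ties
#' broken by intensity. Chains shorter than `min_length` are dropped; a
#' chain wholly contained in a longer chain of the same family and charge is
#' never started (its seed has an in-tolerance predecessor), and a chain
#' whose peaks form a strict subset of a longer same-family chain at another
#' charge is dropped as a duplicate explanation of the same ions.
#'
#' @param spectrum A threshold-filtered centroid spectrum.
#' @param repeats A repeat-unit table ([repeat_units()] by default); rows are
#'   searched independently.
#' @param tol Absolute tolerance in Da for each spacing.
#' @param charges Integer charges to consider (spacing `mass / z`).
#' @param min_length Minimum number of ions per reported sequence.
#' @return A tibble with one row per ladder member: `sequence_id`, `family`,
#'   `charge`, `position` (1 = lowest m/z), `mz`, `intensity`.
#' @examples
#' sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 3), seed = 1)
#' extract_ladders(sim$spectrum)
#' @export
extract_ladders <- function(spectrum, repeats = repeat_units(), tol = 0.001,
                            charges = c(1L, 2L), min_length = 2L) {
  stopifnot(tol > 0, min_length >= 2, all(charges >= 1))
  spectrum <- .as_spectrum(spectrum)
  if (nrow(spectrum) == 0) {
    return(tibble(sequence_id = character(0), family = character(0),
                  charge = integer(0), position = integer(0),
                  mz = numeric(0), intensity = numeric(0)))
  }
  out <- list()
  for (f in seq_len(nrow(repeats))) {
    fam_chains <- list()
    fam_charge <- integer(0)
    for (z in sort(as.integer(charges))) {
      spacing <- repeats$mass[f] / z
      chains <- .find_chains(spectrum$mz, spectrum$intensity, spacing, tol)
      chains <- chains[vapply(chains, length, integer(1)) >= min_length]
      fam_chains <- c(fam_chains, chains)
      fam_charge <- c(fam_charge, rep(z, length(chains)))
    }
    # a chain whose peaks are a strict subset of a longer chain of the same
    # family duplicates it (e.g. the alternating members of a charge-2 ladder
    # form an exact charge-1 ladder of the half composition); keep the longer
    # explanation
    if (length(fam_chains) > 1) {
      len <- vapply(fam_chains, length, integer(1))
      keep <- vapply(seq_along(fam_chains), function(i) {
        !any(vapply(seq_along(fam_chains), function(j) {
          j != i && len[j] > len[i] && all(fam_chains[[i]] %in% fam_chains[[j]])
        }, logical(1)))
      }, logical(1))
      fam_chains <- fam_chains[keep]
      fam_charge <- fam_charge[keep]
    }
    for (k in seq_along(fam_chains)) {
      ch <- fam_chains[[k]]
      out[[length(out) + 1]] <- tibble(
        family = repeats$unit[f], charge = fam_charge[k],
        position = seq_along(ch),
        mz = spectrum$mz[ch], intensity = spectrum$intensity[ch]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(sequence_id = character(0), family = character(0),
                  charge = integer(0), position = integer(0),
                  mz = numeric(0), intensity = numeric(0)))
  }
  seqs <- dplyr::bind_rows(out, .id = ".chain")
  # deterministic ordering: by seed m/z within family and charge
  order_tbl <- seqs %>%
    group_by(.data$.chain) %>%
    summarise(family = .data$family[1], charge = .data$charge[1],
              seed = min(.data$mz), .groups = "drop") %>%
    arrange(.data$family, .data$charge, .data$seed) %>%
    mutate(sequence_id = sprintf("S%03d", row_number()))
  seqs %>%
    left_join(order_tbl[c(".chain", "sequence_id")], by = ".chain") %>%
    arrange(.data$sequence_id, .data$position) %>%
    select("sequence_id", "family", "charge", "position", "mz", "intensity")
}

# adduct priority for tie-breaking seed assignments
.ADDUCT_PRIORITY <- c("[M+NH4]+" = 1, "[M+2NH4]2+" = 1, "[M+H]+" = 2, "[M+Na]+" = 3)

.empty_ions <- function() {
  tibble(sequence_id = character(0), family = character(0), charge = integer(0),
         adduct = character(0), position = integer(0), mz = numeric(0),
         intensity = numeric(0), label = character(0), formula = character(0),
         theo_mz = numeric(0), error_da = numeric(0), error_ppm = numeric(0),
         assigned = logical(0))
}

#' Assign extracted sequences against the database
#'
#' For each ladder, the lowest-m/z ion is tested under every supported adduct
#' hypothesis of matching charge: the implied neutral mass is looked up in
#' the predicted database within `tol` Da, and the best hit (smallest
#' absolute error, ties broken by adduct priority NH4+ > H+ > Na+) fixes the
#' adduct and seed species for the whole sequence. Consecutive ions are then
#' the seed species plus one repeat unit of the ladder family each, with
#' theoretical m/z recomputed from theory (re-anchoring, so tolerance errors
#' do not accumulate along long ladders). Sequences whose seed matches
#' nothing are kept with `assigned = FALSE` (formula-only candidates can be
#' sought with [formula_search()]). Assigned identifications carry
#' Schymanski-scale confidence level 3 (formula plus tentative structure).
#'
#' @param ladders Output of [extract_ladders()].
#' @param db A species table from [enumerate_oligo_db()].
#' @param adducts Adduct names to consider as hypotheses.
#' @param tol Absolute tolerance in Da for database matching and for each
#'   ion's final theoretical error.
#' @return A tibble of assigned ions (one row per ladder member) with species
#'   `label`, `formula`, `theo_mz`, `error_da`, `error_ppm`, `assigned`.
#' @export
assign_sequences <- function(ladders, db,
                             adducts = c("[M+NH4]+", "[M+H]+", "[M+Na]+", "[M+2NH4]2+"),
                             tol = 0.001) {
  if (nrow(ladders) == 0) return(.empty_ions())
  adduct_info <- .adduct_row(adducts)
  adduct_info$adduct <- adducts
  fam_col <- stats::setNames(.COUNT_COLS, .FAMILIES)

  one_seq <- function(seq_tbl) {
    seed_mz <- seq_tbl$mz[1]
    z <- seq_tbl$charge[1]
    fam <- seq_tbl$family[1]
    hyp <- adduct_info[adduct_info$charge == z, , drop = FALSE]
    best <- NULL
    for (a in hyp$adduct) {
      neutral <- neutral_mass_from_mz(seed_mz, a)
      hits <- match_neutral(db, neutral, tol)
      if (nrow(hits) == 0) next
      cand <- hits[1, ]
      if (is.null(best) ||
          abs(cand$error_da) < abs(best$error_da) - 1e-12 ||
          (abs(abs(cand$error_da) - abs(best$error_da)) <= 1e-12 &&
           .ADDUCT_PRIORITY[[a]] < .ADDUCT_PRIORITY[[best$adduct]])) {
        cand$adduct <- a
        best <- cand
      }
    }
    n <- nrow(seq_tbl)
    if (is.null(best)) {
      return(seq_tbl %>%
               mutate(adduct = NA_character_, label = NA_character_,
                      formula = NA_character_, theo_mz = NA_real_,
                      error_da = NA_real_, error_ppm = NA_real_,
                      assigned = FALSE))
    }
    # consecutive ions: seed species plus (position - 1) repeats of the family
    members <- best[rep(1, n), c("topology", "end_group", .COUNT_COLS)]
    members[[fam_col[[fam]]]] <- members[[fam_col[[fam]]]] + seq_len(n) - 1L
    members <- species_formula(members)
    theo <- adduct_mz(members$mass, best$adduct)
    err <- seq_tbl$mz - theo
    seq_tbl %>%
      mutate(adduct = best$adduct, label = members$label,
             formula = members$formula, theo_mz = theo,
             error_da = err, error_ppm = err / theo * 1e6,
             assigned = abs(err) <= tol)
  }

  ladders %>%
    group_by(.data$sequence_id) %>%
    dplyr::group_modify(~ one_seq(.x) %>% select(-dplyr::any_of("sequence_id"))) %>%
    ungroup() %>%
    arrange(.data$sequence_id, .data$position)
}

#' Flag isotopologue satellite peaks
#'
#' Searches the spectrum for peaks sitting one 13C (+1.00335/z) or one 18O
#' (+2.00424/z) isotope shift above an assigned ion, within `tol` Da, and
#' with intensity strictly below the parent's. Such satellites are the same
#' species carrying a heavy isotope and must not be counted as components.
#'
#' @param ions Assigned ions from [assign_sequences()].
#' @param spectrum The (threshold-filtered) spectrum the ions came from.
#' @param tol Absolute tolerance in Da.
#' @return A tibble of flagged satellite peaks: `mz`, `intensity`,
#'   `isotopologue` (`"13C"` or `"18O"`), `parent_mz`, `parent_label`.
#' @export
flag_isotopologues <- function(ions, spectrum, tol = 0.001) {
  spectrum <- .as_spectrum(spectrum)
  parents <- ions[ions$assigned %in% TRUE, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(parents))) {
    p <- parents[i, ]
    for (iso in names(.ISOTOPE_SHIFTS)) {
      target <- p$mz + .ISOTOPE_SHIFTS[[iso]] / p$charge
      sel <- which(abs(spectrum$mz - target) <= tol &
                     spectrum$intensity < p$intensity)
      if (length(sel) > 0) {
        out[[length(out) + 1]] <- tibble(
          mz = spectrum$mz[sel], intensity = spectrum$intensity[sel],
          isotopologue = iso, parent_mz = p$mz, parent_label = p$label
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(mz = numeric(0), intensity = numeric(0),
                  isotopologue = character(0), parent_mz = numeric(0),
                  parent_label = character(0)))
  }
  dplyr::bind_rows(out) %>% distinct(.data$mz, .data$isotopologue, .keep_all = TRUE)
}

#' Deduplicated component summary
#'
#' Collapses assigned ions into one row per unique species, regardless of how
#' many sequences, adducts or charge states supported it. Unassigned ions and
#' ions flagged as isotopologue satellites are excluded.
#'
#' @param ions Assigned ions from [assign_sequences()].
#' @param isotopologues Optional satellite table from [flag_isotopologues()];
#'   ions whose m/z appears there are dropped.
#' @return A tibble with `label`, `formula`, `mass`, `n_ions`, `n_sequences`,
#'   `n_adducts`, `adducts` (collapsed string) and `max_intensity`, sorted by
#'   mass.
#' @export
summarize_components <- function(ions, isotopologues = NULL) {
  keep <- ions[ions$assigned %in% TRUE, , drop = FALSE]
  if (!is.null(isotopologues) && nrow(isotopologues) > 0) {
    flagged <- vapply(keep$mz, function(m) {
      any(abs(isotopologues$mz - m) <= 1e-9)
    }, logical(1))
    keep <- keep[!flagged, , drop = FALSE]
  }
  if (nrow(keep) == 0) {
    return(tibble(label = character(0), formula = character(0),
                  mass = numeric(0), n_ions = integer(0),
                  n_sequences = integer(0), n_adducts = integer(0),
                  adducts = character(0), max_intensity = numeric(0)))
  }
  keep %>%
    group_by(.data$label) %>%
    summarise(
      formula = .data$formula[1],
      mass = monoisotopic_mass(.data$formula[1]),
      n_ions = dplyr::n_distinct(.data$mz),
      n_sequences = dplyr::n_distinct(.data$sequence_id[!is.na(.data$sequence_id)]),
      n_adducts = dplyr::n_distinct(.data$adduct),
      adducts = paste(sort(unique(.data$adduct)), collapse = ";"),
      max_intensity = max(.data$intensity),
      .groups = "drop"
    ) %>%
    arrange(.data$mass)
}

#' Match leftover single peaks against the database
#'
#' Peaks that belong to no assigned ladder are tested individually under each
#' adduct hypothesis; the best database hit within tolerance (smallest
#' absolute error, adduct priority on ties) is reported. Single-ion species
#' (series of length one) are otherwise invisible to ladder extraction.
#'
#' @param spectrum Threshold-filtered spectrum.
#' @param db Species table.
#' @param adducts Adduct hypotheses.
#' @param tol Tolerance in Da.
#' @param exclude_mz m/z values already claimed by ladders (exact match).
#' @return An ion tibble in the same shape as [assign_sequences()] output,
#'   with `sequence_id = NA` and `position = 1`.
#' @export
match_singletons <- function(spectrum, db,
                             adducts = c("[M+NH4]+", "[M+H]+", "[M+Na]+", "[M+2NH4]2+"),
                             tol = 0.001, exclude_mz = numeric(0)) {
  spectrum <- .as_spectrum(spectrum)
  if (length(exclude_mz) > 0) {
    claimed <- vapply(spectrum$mz, function(m) any(abs(exclude_mz - m) <= 1e-9),
                      logical(1))
    spectrum <- spectrum[!claimed, , drop = FALSE]
  }
  adduct_info <- .adduct_row(adducts)
  adduct_info$adduct <- adducts
  out <- list()
  for (i in seq_len(nrow(spectrum))) {
    m <- spectrum$mz[i]
    best <- NULL
    for (j in seq_len(nrow(adduct_info))) {
      a <- adduct_info$adduct[j]
      neutral <- neutral_mass_from_mz(m, a)
      hits <- match_neutral(db, neutral, tol)
      if (nrow(hits) == 0) next
      cand <- hits[1, ]
      if (is.null(best) ||
          abs(cand$error_da) < abs(best$error_da) - 1e-12 ||
          (abs(abs(cand$error_da) - abs(best$error_da)) <= 1e-12 &&
           .ADDUCT_PRIORITY[[a]] < .ADDUCT_PRIORITY[[best$adduct]])) {
        cand$adduct <- a
        cand$charge <- adduct_info$charge[j]
        best <- cand
      }
    }
    if (is.null(best)) next
    fam <- .FAMILIES[which(as.numeric(best[.COUNT_COLS]) > 0)[1]]
    theo <- adduct_mz(best$mass, best$adduct)
    out[[length(out) + 1]] <- tibble(
      sequence_id = NA_character_, family = fam, charge = best$charge,
      adduct = best$adduct, position = 1L, mz = m,
      intensity = spectrum$intensity[i], label = best$label,
      formula = best$formula, theo_mz = theo, error_da = m - theo,
      error_ppm = (m - theo) / theo * 1e6, assigned = TRUE
    )
  }
  if (length(out) == 0) return(.empty_ions())
  dplyr::bind_rows(out)
}

#' Full direct-infusion extraction pipeline
#'
#' Runs threshold filtering, ladder extraction, database assignment,
#' isotopologue flagging, optional singleton matching and component
#' summarisation in one call.
#'
#' @param spectrum A centroid spectrum (`mz`, `intensity`).
#' @param db Species table; defaults to [enumerate_oligo_db()].
#' @param min_intensity Intensity threshold.
#' @param tol Absolute tolerance in Da.
#' @param charges Charges to search.
#' @param adducts Adduct hypotheses.
#' @param min_length Minimum ladder length.
#' @param include_singletons Also match unclaimed single peaks directly
#'   against the database.
#' @return An object of class `di_extraction`: a list with `ions`,
#'   `components`, `isotopologues`, `spectrum` (filtered) and `params`.
#'   Use [tidy()] for the per-ion table, [glance()] for run counts,
#'   [autoplot()] for an annotated spectrum plot.
#' @examples
#' sim <- simulate_di_spectrum(series_plan("cyclic [AA-BD]", n_members = 3), seed = 1)
#' res <- di_extract(sim$spectrum)
#' res$components
#' @export
di_extract <- function(spectrum, db = enumerate_oligo_db(),
                       min_intensity = 1e4, tol = 0.001, charges = c(1L, 2L),
                       adducts = c("[M+NH4]+", "[M+H]+", "[M+Na]+", "[M+2NH4]2+"),
                       min_length = 2L, include_singletons = TRUE) {
  filtered <- threshold_filter(spectrum, min_intensity)
  ladders <- extract_ladders(filtered, tol = tol, charges = charges,
                             min_length = min_length)
  ions <- assign_sequences(ladders, db, adducts = adducts, tol = tol)
  iso <- flag_isotopologues(ions, filtered, tol = tol)
  if (include_singletons) {
    singles <- match_singletons(filtered, db, adducts = adducts, tol = tol,
                                exclude_mz = c(ions$mz, iso$mz))
    ions <- dplyr::bind_rows(ions, singles)
  }
  components <- summarize_components(ions, iso)
  structure(
    list(ions = ions, components = components, isotopologues = iso,
         spectrum = filtered,
         params = list(min_intensity = min_intensity, tol = tol,
                       charges = charges, adducts = adducts,
                       min_length = min_length,
                       include_singletons = include_singletons)),
    class = "di_extraction"
  )
}

#' @export
print.di_extraction <- function(x, ...) {
  g <- glance(x)
  cat("<di_extraction>\n")
  cat("  peaks:      ", g$n_peaks, "\n")
  cat("  ions:       ", g$n_ions, " (", g$n_assigned, " assigned)\n", sep = "")
  cat("  sequences:  ", g$n_sequences, "\n")
  cat("  components: ", g$n_components, "\n")
  invisible(x)
}

#' @rdname di_extract
#' @param x A `di_extraction` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.di_extraction <- function(x, ...) x$ions

#' @rdname di_extract
#' @exportS3Method generics::glance
glance.di_extraction <- function(x, ...) {
  err <- x$ions$error_da[x$ions$assigned %in% TRUE]
  tibble(
    n_peaks = nrow(x$spectrum),
    n_ions = nrow(x$ions),
    n_assigned = sum(x$ions$assigned %in% TRUE),
    n_sequences = dplyr::n_distinct(x$ions$sequence_id[!is.na(x$ions$sequence_id)]),
    n_components = nrow(x$components),
    n_isotopologues = nrow(x$isotopologues),
    error_da_min = if (length(err)) min(err) else NA_real_,
    error_da_max = if (length(err)) max(err) else NA_real_
  )
}
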