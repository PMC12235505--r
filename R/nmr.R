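# Copolymer blend composition from assigned 1H NMR signals.
#
# One integrated signal per polymer, each representing the repeat unit of
# that polymer. Molar fractions are proton-normalised integrals; weight
# fractions additionally weight by the repeat-unit molecular weight (average
# masses: the NMR molecular-weight convention). End-group contributions are
# neglected, which is the usual approximation for polymeric samples where
# chain ends are a vanishing mass fraction.

.check_signals <- function(signals, need_mw = FALSE) {
  signals <- as_tibble(signals)
  need <- c("polymer", "integral", "protons")
  if (need_mw) need <- c(need, "mw")
  missing <- setdiff(need, names(signals))
  if (length(missing) > 0) {
    abort(paste0("signal table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(signals$polymer)) {
    abort("signal table must have exactly one row per polymer")
  }
  bad <- which(!is.finite(signals$integral) | signals$integral <= 0)
  if (length(bad) > 0) {
    abort(paste0("integral must be > 0; offending polymer(s): ",
                 paste(signals$polymer[bad], collapse = ", ")))
  }
  bad <- which(!is.finite(signals$protons) | signals$protons < 1 |
                 signals$protons != round(signals$protons))
  if (length(bad) > 0) {
    abort(paste0("proton count must be an integer >= 1; offending polymer(s): ",
                 paste(signals$polymer[bad], collapse = ", ")))
  }
  if (need_mw) {
    bad <- which(!is.finite(signals$mw) | signals$mw <= 0)
    if (length(bad) > 0) {
      abort(paste0("repeat-unit molecular weight must be > 0; offending polymer(s): ",
                   paste(signals$polymer[bad], collapse = ", ")))
    }
  }
  signals
}

#' Molar percentages from NMR integrals
#'
#' `mol%_i = (I_i / m_i) / sum_j (I_j / m_j) * 100`, where `I` is the
#' integral of the assigned signal and `m` the number of protons it
#' represents. The result is invariant to rescaling all integrals and sums
#' to exactly 100 before display rounding.
#'
#' @param signals A data frame with one row per polymer: `polymer`,
#'   `integral`, `protons` (and `mw` for [weight_percent()]).
#' @return A tibble `polymer`, `mol_percent`.
#' @examples
#' sig <- simulate_nmr_integrals(c(PBA = 35, PBT = 40, PLA = 13, PBSe = 12),
#'                               c(4, 4, 1, 4))
#' mole_percent(sig)
#' @export
mole_percent <- function(signals) {
  signals <- .check_signals(signals)
  molar <- signals$integral / signals$protons
  tibble(polymer = signals$polymer,
         mol_percent = molar / sum(molar) * 100)
}

#' Weight percentages from NMR integrals
#'
#' As [mole_percent()], but each molar equivalent is multiplied by the
#' repeat-unit molecular weight before normalising:
#' `wt%_i = (I_i / m_i) Mw_i / sum_j (I_j / m_j) Mw_j * 100`. Average (not
#' monoisotopic) repeat-unit masses should be supplied. End groups are
#' neglected.
#'
#' @inheritParams mole_percent
#' @return A tibble `polymer`, `wt_percent`.
#' @export
weight_percent <- function(signals) {
  signals <- .check_signals(signals, need_mw = TRUE)
  w <- signals$integral / signals$protons * signals$mw
  tibble(polymer = signals$polymer,
         wt_percent = w / sum(w) * 100)
}

#' Copolymer composition from NMR signals
#'
#' Joint molar and weight composition for a signal table; both columns sum to
#' exactly 100 at full precision. Printing rounds to whole percent (the
#' reporting convention); the underlying tibble keeps full precision.
#'
#' @inheritParams mole_percent
#' @return A tibble of class `nmr_composition` with columns `polymer`,
#'   `mol_percent`, `wt_percent`, carrying the attribute
#'   `end_groups_ignored = TRUE` to flag the approximation.
#' @examples
#' sig <- simulate_nmr_integrals(c(PBA = 35, PBT = 40, PLA = 13, PBSe = 12),
#'                               c(4, 4, 1, 4))
#' nmr_composition(sig)
#' @export
nmr_composition <- function(signals) {
  res <- mole_percent(signals) %>%
    left_join(weight_percent(signals), by = "polymer")
  attr(res, "end_groups_ignored") <- TRUE
  class(res) <- c("nmr_composition", class(res))
  res
}

#' @export
print.nmr_composition <- function(x, ...) {
  cat("Copolymer composition (1H NMR; end groups neglected)\n")
  disp <- data.frame(polymer = x$polymer,
                     `mol%` = round(x$mol_percent),
                     `wt%` = round(x$wt_percent),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @rdname nmr_composition
#' @param x An `nmr_composition` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nmr_composition <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nmr_composition")
  attr(out, "end_groups_ignored") <- NULL
  as_tibble(out)
}

#' @rdname nmr_composition
#' @exportS3Method generics::glance
glance.nmr_composition <- function(x, ...) {
  tibble(n_polymers = nrow(x),
         mol_percent_sum = sum(x$mol_percent),
         wt_percent_sum = sum(x$wt_percent))
}
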