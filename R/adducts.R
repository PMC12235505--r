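# Positive-mode ESI adducts and the m/z algebra around them.
#
# m/z = (M + k * mass(delta) - z * m_e) / z
#
# The electron mass is always subtracted per elementary charge: omitting it
# shifts singly charged ions by ~0.55 mDa, which is outside the +/-1 mDa
# matching tolerance used throughout direct-infusion assignment.

.ADDUCTS <- data.frame(
  adduct  = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+2NH4]2+"),
  delta   = c("H", "NH4", "Na", "NH4"),
  k       = c(1L, 1L, 1L, 2L),
  charge  = c(1L, 1L, 1L, 2L),
  stringsAsFactors = FALSE
)

.adduct_row <- function(adduct) {
  i <- match(adduct, .ADDUCTS$adduct)
  if (any(is.na(i))) {
    abort(paste0("unsupported adduct: ",
                 paste(unique(adduct[is.na(i)]), collapse = ", "),
                 " (supported: ", paste(.ADDUCTS$adduct, collapse = ", "), ")"))
  }
  .ADDUCTS[i, , drop = FALSE]
}

#' Supported electrospray adducts
#'
#' The positive-mode adducts recognised throughout the package. `mass_shift`
#' is the total m/z-numerator addition, `k * mass(delta) - z * m_e`, so that
#' the observed m/z of a neutral of monoisotopic mass `M` is
#' `(M + mass_shift) / charge`.
#'
#' @return A tibble with columns `adduct`, `delta` (formula added per unit),
#'   `k` (number of adduct units), `charge`, and `mass_shift` (Da).
#' @examples
#' adducts()
#' @export
adducts <- function() {
  out <- as_tibble(.ADDUCTS)
  out$mass_shift <- out$k * monoisotopic_mass(out$delta) -
    out$charge * .ELECTRON_MASS
  out
}

#' Observed m/z of an adduct ion
#'
#' Computes `(M + k * mass(delta) - z * m_e) / z` for a neutral given either
#' as a monoisotopic mass in Da or as a formula string. Full floating-point
#' precision is kept; round only for display (4-5 decimals is the working
#' convention for Orbitrap m/z).
#'
#' @param neutral Numeric neutral monoisotopic masses (Da), or character
#'   formula strings.
#' @param adduct Adduct names from [adducts()]. Recycled against `neutral`.
#' @return Numeric vector of m/z values.
#' @examples
#' adduct_mz("C44H56O16", "[M+NH4]+")  # 858.3907
#' adduct_mz(200.10486, "[M+NH4]+")
#' @export
adduct_mz <- function(neutral, adduct) {
  if (is.character(neutral)) neutral <- monoisotopic_mass(neutral)
  info <- .adduct_row(adduct)
  (neutral + info$k * monoisotopic_mass(info$delta) -
     info$charge * .ELECTRON_MASS) / info$charge
}

#' Neutral mass from an observed adduct m/z
#'
#' Exact algebraic inverse of [adduct_mz()]; the round trip is the identity to
#' well below 1e-9 Da.
#'
#' @param mz Positive numeric m/z values.
#' @param adduct Adduct names from [adducts()].
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' neutral_mass_from_mz(858.3907, "[M+NH4]+")  # 840.35687
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  stopifnot(all(mz > 0))
  info <- .adduct_row(adduct)
  mz * info$charge - info$k * monoisotopic_mass(info$delta) +
    info$charge * .ELECTRON_MASS
}

#' Mass accuracy error
#'
#' Signed difference between an observed and a theoretical m/z, in Da and in
#' ppm relative to the theoretical value (`delta_ppm = delta_da / theoretical
#' * 1e6`).
#'
#' @param observed,theoretical Numeric m/z vectors (recycled).
#' @return A tibble with columns `observed`, `theoretical`, `delta_da`,
#'   `delta_ppm`.
#' @examples
#' mass_error(201.11221, adduct_mz("C10H16O4", "[M+H]+"))
#' @export
mass_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  delta <- observed - theoretical
  tibble(
    observed = observed,
    theoretical = theoretical,
    delta_da = delta,
    delta_ppm = delta / theoretical * 1e6
  )
}

#' Electron mass constant
#'
#' The CODATA electron mass in Da used for charge correction.
#' @return A single numeric value.
#' @export
electron_mass <- function() .ELECTRON_MASS
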