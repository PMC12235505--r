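# Internal-standard GC quantification.
#
# Analyte amounts are referenced to a known mass of internal standard (IS)
# added post extraction, via response factors (RF) measured with reference
# compounds where available and borrowed from a chemically similar surrogate
# otherwise. Surrogate-derived concentrations stay flagged all the way to the
# output rather than being silently merged.

#' Response factor relative to the internal standard
#'
#' `RF = (area_ref / conc_ref) / (area_is / conc_is)`: detector response per
#' unit concentration of the analyte, normalised to the internal standard's.
#' An analyte responding identically to the IS has RF 1. If your convention
#' is the reciprocal, invert before passing RFs to [gc_quantify()].
#'
#' @param area_ref,conc_ref Peak area and concentration of the analyte
#'   reference standard.
#' @param area_is,conc_is Peak area and concentration of the internal
#'   standard in the same run.
#' @return Numeric response factors.
#' @examples
#' response_factor(150, 0.10, 100, 0.10)  # 1.5
#' @export
response_factor <- function(area_ref, conc_ref, area_is, conc_is) {
  inputs <- cbind(area_ref, conc_ref, area_is, conc_is)
  if (any(!is.finite(inputs)) || any(inputs <= 0)) {
    abort("all response-factor inputs must be positive and finite")
  }
  (area_ref / conc_ref) / (area_is / conc_is)
}

#' Quantify analytes against the internal standard
#'
#' `conc_i (ug/g) = (area_i / area_IS) * m_IS(ug) / (RF_i * m_sample(g))`.
#' When the run table carries a `replicate` column, each replicate is
#' quantified against its own IS area and the result reports mean and sd per
#' analyte; otherwise the single-run concentration is returned with `sd = NA`.
#'
#' @param run A data frame with `analyte`, `area` (and optional `replicate`),
#'   containing one IS row per replicate.
#' @param calibration A data frame with `analyte`, `rf` and optional logical
#'   `surrogate` (RF borrowed from a similar compound).
#' @param is_analyte Name of the internal-standard row (default `"BBP"`,
#'   butyl benzyl phthalate).
#' @param is_amount_ug Internal-standard mass added, in ug (default 250).
#' @param sample_mass_g Sample mass extracted, in g (default 0.1).
#' @return A tibble `analyte`, `concentration_ug_g`, `sd`, `n`, `surrogate`.
#' @examples
#' run <- simulate_gc_run(c(ATBC = 4210), rfs = c(ATBC = 1.2))
#' calib <- tibble::tibble(analyte = "ATBC", rf = 1.2)
#' gc_quantify(run, calib)
#' @export
gc_quantify <- function(run, calibration, is_analyte = "BBP",
                        is_amount_ug = 250, sample_mass_g = 0.1) {
  stopifnot(is_amount_ug > 0, sample_mass_g > 0)
  run <- as_tibble(run)
  calibration <- as_tibble(calibration)
  if (!all(c("analyte", "area") %in% names(run))) {
    abort("run table needs 'analyte' and 'area' columns")
  }
  if (!all(c("analyte", "rf") %in% names(calibration))) {
    abort("calibration table needs 'analyte' and 'rf' columns")
  }
  if (any(!is.finite(calibration$rf) | calibration$rf <= 0)) {
    abort(paste0("response factors must be > 0; offending analyte(s): ",
                 paste(calibration$analyte[!is.finite(calibration$rf) |
                                             calibration$rf <= 0], collapse = ", ")))
  }
  if (!"surrogate" %in% names(calibration)) calibration$surrogate <- FALSE
  if (!"replicate" %in% names(run)) run$replicate <- 1L

  analytes <- run[run$analyte != is_analyte, , drop = FALSE]
  missing_rf <- setdiff(unique(analytes$analyte), calibration$analyte)
  if (length(missing_rf) > 0) {
    abort(paste0("no response factor (own or surrogate) for: ",
                 paste(missing_rf, collapse = ", ")))
  }
  is_rows <- run[run$analyte == is_analyte, , drop = FALSE]
  if (nrow(is_rows) == 0) {
    abort(paste0("internal-standard row '", is_analyte, "' missing from run table"))
  }
  if (any(is_rows$area <= 0)) abort("internal-standard area must be > 0")

  per_rep <- analytes %>%
    left_join(is_rows %>% select("replicate", is_area = "area"),
              by = "replicate") %>%
    left_join(calibration %>% select("analyte", "rf", "surrogate"),
              by = "analyte") %>%
    mutate(concentration_ug_g =
             (.data$area / .data$is_area) * is_amount_ug /
             (.data$rf * sample_mass_g))

  per_rep %>%
    group_by(.data$analyte) %>%
    summarise(
      mean_conc = mean(.data$concentration_ug_g),
      sd = if (dplyr::n() > 1) stats::sd(.data$concentration_ug_g) else NA_real_,
      n = dplyr::n(),
      surrogate = .data$surrogate[1],
      .groups = "drop"
    ) %>%
    rename(concentration_ug_g = "mean_conc")
}

#' Recovery percentage
#'
#' `100 * measured / spiked` for spike-recovery experiments.
#'
#' @param measured_amount Amount recovered.
#' @param spiked_amount Amount spiked (must be > 0).
#' @return Numeric recovery in percent.
#' @examples
#' recovery(33.5, 50)  # 67
#' @export
recovery <- function(measured_amount, spiked_amount) {
  if (any(!is.finite(spiked_amount)) || any(spiked_amount <= 0)) {
    abort("spiked amount must be positive")
  }
  100 * measured_amount / spiked_amount
}
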