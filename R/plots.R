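# ggplot2 displays for the main result types.

#' Plot an annotated direct-infusion spectrum
#'
#' Stick spectrum with assigned ladder ions coloured by repeat family;
#' unassigned peaks in grey.
#'
#' @param object A `di_extraction` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.di_extraction <- function(object, ...) {
  spec <- object$spectrum
  ions <- object$ions[object$ions$assigned %in% TRUE, , drop = FALSE]
  p <- ggplot2::ggplot(spec, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity),
                          colour = "grey70", linewidth = 0.3)
  if (nrow(ions) > 0) {
    p <- p + ggplot2::geom_segment(
      data = ions,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                   yend = .data$intensity, colour = .data$family),
      linewidth = 0.6
    )
  }
  p +
    ggplot2::labs(x = "m/z", y = "intensity", colour = "repeat family",
                  title = "Direct-infusion spectrum with assigned oligomer ladders") +
    ggplot2::theme_minimal()
}

#' Plot a copolymer composition
#'
#' Side-by-side molar and weight percentages per polyester.
#'
#' @param object An `nmr_composition` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nmr_composition <- function(object, ...) {
  long <- tidy(object) %>%
    tidyr::pivot_longer(c("mol_percent", "wt_percent"),
                        names_to = "basis", values_to = "percent") %>%
    mutate(basis = dplyr::recode(.data$basis, mol_percent = "mol%",
                                 wt_percent = "wt%"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$polymer, y = .data$percent,
                                     fill = .data$basis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL,
                  title = "Polyester blend composition") +
    ggplot2::theme_minimal()
}

#' Plot an extracted-ion chromatogram
#'
#' Draws the features inside the ppm window of a target m/z against
#' retention time and marks the apexes found by [extract_eic()].
#'
#' @param features LC feature table (`rt`, `mz`, `intensity`).
#' @param target_mz Target m/z.
#' @param tol_ppm Window half-width in ppm.
#' @param min_separation Apex merge distance in minutes.
#' @return A ggplot object.
#' @export
plot_eic <- function(features, target_mz, tol_ppm = 5, min_separation = 0.05) {
  win <- abs(features$mz - target_mz) / target_mz <= tol_ppm * 1e-6
  pts <- as_tibble(features[win, , drop = FALSE]) %>% arrange(.data$rt)
  peaks <- extract_eic(features, target_mz, tol_ppm, min_separation)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = peaks, colour = "red", size = 2) +
    ggplot2::labs(x = "retention time (min)", y = "intensity",
                  title = sprintf("EIC m/z %.4f (+/- %g ppm), %d peak(s)",
                                  target_mz, tol_ppm, nrow(peaks))) +
    ggplot2::theme_minimal()
}
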