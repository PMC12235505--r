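# Elemental-formula arithmetic and exact masses.
#
# Atomic masses are pinned here (CODATA 2018 electron mass; IUPAC/AME2020
# monoisotopic masses; IUPAC 2021 standard atomic weights, abridged) rather
# than looked up at run time, so that every mass printed by the package is
# reproducible from this one table.

.ELEMENTS <- data.frame(
  symbol  = c("C", "H", "N", "O", "Na"),
  mono    = c(12, 1.00782503207, 14.0030740048, 15.9949146196, 22.9897692809),
  average = c(12.011, 1.008, 14.007, 15.999, 22.98976928),
  stringsAsFactors = FALSE
)

# CODATA electron mass in Da; subtracted once per positive charge
.ELECTRON_MASS <- 0.000548579909

# proton m/z: H minus one electron
.PROTON_MASS <- 1.00782503207 - 0.000548579909

# isotope mass shifts used for satellite (isotopologue) detection, in Da
.ISOTOPE_SHIFTS <- c("13C" = 1.0033548378, "18O" = 2.0042449924)

# parse one Hill-notation formula string into a named count vector
.parse_formula <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    abort(paste0("cannot parse elemental formula: '", x, "'"))
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(sym, .ELEMENTS$symbol)
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol: ",
                 paste(unique(unknown), collapse = ", "),
                 " (supported: ", paste(.ELEMENTS$symbol, collapse = ", "), ")"))
  }
  counts <- tapply(cnt, sym, sum)
  counts <- counts[order(names(counts))]
  stats::setNames(as.numeric(counts), names(counts))
}

# counts vector back to a Hill-order string (C, H, then alphabetical)
.deparse_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0) return("")
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[hill]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

.formula_combine <- function(x, y, sign = 1) {
  a <- .parse_formula(x)
  b <- .parse_formula(y)
  all_sym <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(all_sym)), all_sym)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + sign * b
  if (any(out < 0)) {
    abort(paste0("formula subtraction '", x, "' - '", y,
                 "' yields negative count for: ",
                 paste(names(out)[out < 0], collapse = ", ")))
  }
  .deparse_formula(out)
}

#' Combine elemental formulas
#'
#' Element-wise addition, subtraction and integer multiplication of
#' Hill-notation formula strings (e.g. `"C10H16O4"`). Subtraction that would
#' drive any element count negative is an error: chemically it would mean
#' removing atoms that are not there.
#'
#' @param x,y Formula strings. Vectorised; recycled to a common length.
#' @param n Non-negative integer multiplier.
#' @return A character vector of formula strings in Hill order.
#' @examples
#' formula_add("C6H10O4", "C4H10O2")
#' formula_subtract("C10H20O6", "H4O2")
#' formula_multiply("C3H4O2", 3)
#' @export
formula_add <- function(x, y) {
  mapply(.formula_combine, x, y, MoreArgs = list(sign = 1), USE.NAMES = FALSE)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(x, y) {
  mapply(.formula_combine, x, y, MoreArgs = list(sign = -1), USE.NAMES = FALSE)
}

#' @rdname formula_add
#' @export
formula_multiply <- function(x, n) {
  stopifnot(all(n >= 0), all(n == round(n)))
  mapply(function(xi, ni) {
    cnt <- .parse_formula(xi) * ni
    .deparse_formula(cnt)
  }, x, n, USE.NAMES = FALSE)
}

.formula_mass <- function(x, column) {
  counts <- .parse_formula(x)
  if (length(counts) == 0) return(0)
  masses <- .ELEMENTS[[column]][match(names(counts), .ELEMENTS$symbol)]
  sum(counts * masses)
}

#' Monoisotopic and average masses of elemental formulas
#'
#' `monoisotopic_mass()` sums the principal-isotope masses (the exact mass
#' observed for the all-light-isotope ion in high-resolution MS);
#' `average_mass()` sums standard atomic weights (the molecular-weight
#' convention used for NMR weight fractions). Both are vectorised over
#' formula strings; the empty formula has mass 0.
#'
#' @param formula Character vector of Hill-notation formulas.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass("C3H4O2")   # lactate repeat unit, 72.02113
#' average_mass("C10H16O4")      # butylene adipate repeat unit, 200.23
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, .formula_mass, numeric(1), column = "mono", USE.NAMES = FALSE)
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(formula) {
  vapply(formula, .formula_mass, numeric(1), column = "average", USE.NAMES = FALSE)
}

#' Count atoms of one element in a formula
#'
#' @param formula Character vector of formulas.
#' @param element Single element symbol, e.g. `"C"`.
#' @return Integer vector of counts.
#' @export
element_count <- function(formula, element) {
  vapply(formula, function(x) {
    counts <- .parse_formula(x)
    k <- unname(counts[element])
    as.integer(if (is.na(k)) 0 else k)
  }, integer(1), USE.NAMES = FALSE)
}
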