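# Monomers, ester repeat units and oligoester species construction.
#
# Repeat units are the condensed forms that separate consecutive members of an
# oligomer ion series: diacid + butanediol - 2 H2O for the diacid-diol
# families, lactic acid - H2O for lactate.

.FAMILIES <- c("AA-BD", "TA-BD", "SeA-BD", "LA")
.COUNT_COLS <- c("n_aa_bd", "n_ta_bd", "n_sea_bd", "n_la")

.REPEATS <- data.frame(
  unit    = .FAMILIES,
  formula = c("C10H16O4", "C12H12O4", "C14H24O4", "C3H4O2"),
  diacid  = c("AA", "TA", "SeA", NA),
  stringsAsFactors = FALSE
)

.MONOMERS <- data.frame(
  monomer = c("AA", "TA", "SeA", "BD", "LA"),
  name    = c("adipic acid", "terephthalic acid", "sebacic acid",
              "1,4-butanediol", "lactic acid"),
  formula = c("C6H10O4", "C8H6O4", "C10H18O4", "C4H10O2", "C3H6O3"),
  stringsAsFactors = FALSE
)

# end-group additions to the sum of repeat units; cyclic species add nothing
.END_GROUPS <- data.frame(
  end_group = c("none", "free", "methyl", "bd"),
  addition  = c("", "H2O", "CH4O", "C4H10O2"),
  prefix    = c("cyclic ", "linear ", "Me-", "BD-"),
  stringsAsFactors = FALSE
)

#' Monomer and repeat-unit catalogues
#'
#' `monomers()` lists the five building blocks (adipic acid AA, terephthalic
#' acid TA, sebacic acid SeA, 1,4-butanediol BD, lactic acid LA);
#' `repeat_units()` lists the four condensed ester repeat units whose
#' monoisotopic masses (72.02113, 200.10486, 220.07356, 256.16746 Da) are the
#' spacings looked for in oligomer ion series.
#'
#' @return A tibble with formula and monoisotopic `mass` columns.
#' @examples
#' repeat_units()
#' @export
repeat_units <- function() {
  out <- as_tibble(.REPEATS)
  out$mass <- monoisotopic_mass(out$formula)
  out
}

#' @rdname repeat_units
#' @export
monomers <- function() {
  out <- as_tibble(.MONOMERS)
  out$mass <- monoisotopic_mass(out$formula)
  out
}

.end_group_row <- function(end_group) {
  i <- match(end_group, .END_GROUPS$end_group)
  if (any(is.na(i))) {
    abort(paste0("unknown end group: ",
                 paste(unique(end_group[is.na(i)]), collapse = ", "),
                 " (supported: ", paste(.END_GROUPS$end_group, collapse = ", "), ")"))
  }
  .END_GROUPS[i, , drop = FALSE]
}

# canonical label from one set of counts; unit order is fixed (AA-BD, TA-BD,
# SeA-BD, LA) so labels are string-stable for deduplication
.species_label_one <- function(topology, end_group, counts) {
  present <- counts > 0
  units <- paste0("[", .FAMILIES[present], "]",
                  ifelse(counts[present] == 1, "", counts[present]))
  paste0(.end_group_row(end_group)$prefix, paste(units, collapse = "-"))
}

.species_formula_one <- function(topology, end_group, counts) {
  if (sum(counts) < 1) abort("species must contain at least one repeat unit")
  if (topology == "cyclic" && end_group != "none") {
    abort("cyclic species cannot carry an end group (use end_group = 'none')")
  }
  if (topology == "linear" && end_group == "none") {
    abort("linear species require an end group ('free', 'methyl' or 'bd')")
  }
  f <- ""
  for (i in seq_along(.FAMILIES)) {
    if (counts[i] > 0) {
      f <- formula_add(f, formula_multiply(.REPEATS$formula[i], counts[i]))
    }
  }
  add <- .end_group_row(end_group)$addition
  if (nzchar(add)) f <- formula_add(f, add)
  f
}

#' Formula, mass and canonical label of oligoester species
#'
#' Takes a species table (one row per species) with columns `topology`
#' (`"cyclic"` or `"linear"`), `end_group` (`"none"`, `"free"`, `"methyl"`,
#' `"bd"`) and per-family repeat counts `n_aa_bd`, `n_ta_bd`, `n_sea_bd`,
#' `n_la`, and appends `label`, `formula` and monoisotopic `mass`. The formula
#' is the sum of the repeat-unit formulas plus the end-group addition (H2O for
#' free linear chains, CH4O for methyl-capped, C4H10O2 for butanediol-capped;
#' nothing for rings). Labels list units in the fixed order AA-BD, TA-BD,
#' SeA-BD, LA, e.g. `"cyclic [AA-BD]2-[TA-BD]2"`, `"Me-[LA]3"`.
#'
#' @param species A data frame as described above. Missing count columns are
#'   treated as zero.
#' @return The input as a tibble with `label`, `formula`, `mass` and
#'   `total_units` columns added.
#' @examples
#' species_tbl(topology = "cyclic", n_aa_bd = 2, n_ta_bd = 2) %>% species_formula()
#' @export
species_formula <- function(species) {
  species <- as_tibble(species)
  for (col in .COUNT_COLS) {
    if (!col %in% names(species)) species[[col]] <- 0L
  }
  if (!"end_group" %in% names(species)) {
    species$end_group <- ifelse(species$topology == "cyclic", "none", "free")
  }
  cnt <- as.matrix(species[.COUNT_COLS])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    abort("repeat-unit counts must be non-negative integers")
  }
  n <- nrow(species)
  lab <- frm <- character(n)
  for (i in seq_len(n)) {
    frm[i] <- .species_formula_one(species$topology[i], species$end_group[i], cnt[i, ])
    lab[i] <- .species_label_one(species$topology[i], species$end_group[i], cnt[i, ])
  }
  species$label <- lab
  species$formula <- frm
  species$mass <- monoisotopic_mass(frm)
  species$total_units <- as.integer(rowSums(cnt))
  species
}

#' Build a one-row species table
#'
#' Convenience constructor for a single oligoester species, pipeable into
#' [species_formula()].
#'
#' @param topology `"cyclic"` or `"linear"`.
#' @param end_group End group name; defaults to `"none"` for cyclic and
#'   `"free"` for linear species.
#' @param n_aa_bd,n_ta_bd,n_sea_bd,n_la Repeat-unit counts.
#' @return A one-row tibble.
#' @export
species_tbl <- function(topology = "cyclic", end_group = NULL,
                        n_aa_bd = 0, n_ta_bd = 0, n_sea_bd = 0, n_la = 0) {
  tibble(
    topology = topology,
    end_group = end_group %||% ifelse(topology == "cyclic", "none", "free"),
    n_aa_bd = n_aa_bd, n_ta_bd = n_ta_bd, n_sea_bd = n_sea_bd, n_la = n_la
  )
}

#' Parse a canonical species label
#'
#' Inverse of the labelling in [species_formula()]: turns labels such as
#' `"cyclic [AA-BD]2-[TA-BD]2"`, `"Me-[LA]3"`, `"BD-[AA-BD]2"` or
#' `"linear [AA-BD]2-[TA-BD]"` back into a species table row.
#'
#' @param label Character vector of canonical labels.
#' @return A species tibble with `topology`, `end_group` and count columns
#'   (one row per label), with `label`, `formula`, `mass` filled in.
#' @examples
#' parse_species_label("cyclic [AA-BD]2-[TA-BD]2")
#' @export
parse_species_label <- function(label) {
  one <- function(lab) {
    rest <- NULL
    if (startsWith(lab, "cyclic ")) {
      topology <- "cyclic"; end_group <- "none"
      rest <- substring(lab, nchar("cyclic ") + 1)
    } else if (startsWith(lab, "linear ")) {
      topology <- "linear"; end_group <- "free"
      rest <- substring(lab, nchar("linear ") + 1)
    } else if (startsWith(lab, "Me-")) {
      topology <- "linear"; end_group <- "methyl"
      rest <- substring(lab, 4)
    } else if (startsWith(lab, "BD-")) {
      topology <- "linear"; end_group <- "bd"
      rest <- substring(lab, 4)
    } else {
      abort(paste0("cannot parse species label: '", lab, "'"))
    }
    m <- gregexpr("\\[([A-Za-z-]+)\\]([0-9]*)", rest)[[1]]
    toks <- regmatches(rest, list(m))[[1]]
    if (length(toks) == 0) abort(paste0("cannot parse species label: '", lab, "'"))
    units <- sub("^\\[([A-Za-z-]+)\\].*$", "\\1", toks)
    cnts <- as.integer(ifelse(grepl("\\][0-9]+$", toks),
                              sub("^.*\\]", "", toks), "1"))
    bad <- setdiff(units, .FAMILIES)
    if (length(bad) > 0) {
      abort(paste0("unknown repeat unit in label '", lab, "': ",
                   paste(bad, collapse = ", ")))
    }
    counts <- stats::setNames(integer(length(.FAMILIES)), .FAMILIES)
    counts[units] <- counts[units] + cnts
    tibble(
      topology = topology, end_group = end_group,
      n_aa_bd = counts[["AA-BD"]], n_ta_bd = counts[["TA-BD"]],
      n_sea_bd = counts[["SeA-BD"]], n_la = counts[["LA"]]
    )
  }
  purrr::map_dfr(label, one) %>% species_formula()
}
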