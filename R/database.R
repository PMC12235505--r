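# Enumeration of the predicted oligoester structure database and neutral-mass
# matching against it.
#
# The enumeration is organised in "blocks": each block fixes a topology and
# end group and gives per-family count ranges plus a total-unit range. The
# default configuration mirrors the series observed for a PLA/PBAT(/PBSeT)
# film: cyclic homopolymer rings [LA]n (n = 2-12), [AA-BD]n (1-6), [TA-BD]n
# (2-3), [SeA-BD]n (1-4); mixed rings over AA-BD/TA-BD and TA-BD/SeA-BD up to
# 9 units; methyl-capped PLA chains Me-[LA]n (2-20, optionally carrying up to
# 4 AA-BD units); and free and BD-capped linear PBAT chains up to 7 units.

.db_block <- function(topology, end_group, ranges, total = NULL) {
  list(topology = topology, end_group = end_group, ranges = ranges,
       total = total %||% c(1L, Inf))
}

.default_blocks <- function() {
  list(
    .db_block("cyclic", "none", list("LA" = c(2, 12))),
    .db_block("cyclic", "none", list("AA-BD" = c(1, 6))),
    .db_block("cyclic", "none", list("TA-BD" = c(2, 3))),
    .db_block("cyclic", "none", list("SeA-BD" = c(1, 4))),
    .db_block("cyclic", "none",
              list("AA-BD" = c(1, 8), "TA-BD" = c(1, 8)), total = c(2, 9)),
    .db_block("cyclic", "none",
              list("TA-BD" = c(1, 8), "SeA-BD" = c(1, 8)), total = c(2, 9)),
    .db_block("linear", "methyl",
              list("LA" = c(2, 20), "AA-BD" = c(0, 4))),
    .db_block("linear", "bd",
              list("AA-BD" = c(0, 7), "TA-BD" = c(0, 7)), total = c(1, 7)),
    .db_block("linear", "free",
              list("AA-BD" = c(0, 7), "TA-BD" = c(0, 7)), total = c(1, 7))
  )
}

#' Configuration for database enumeration
#'
#' @param blocks A list of enumeration blocks from [db_block()]; the default
#'   covers every oligoester family reported for PLA/PBAT/PBSeT mulch film
#'   extracts (see Details in [enumerate_oligo_db()]).
#' @param min_ring_size Named integer vector: the minimum repeat count for a
#'   homopolymer ring of each family. Lactide (two LA units) is the smallest
#'   observed lactate ring, while the 12-membered [AA-BD] monomer ring is
#'   observed, hence the defaults.
#' @param max_species Safety cap on the number of candidate species a single
#'   enumeration may generate.
#' @return A list with class `oligo_db_config`.
#' @export
oligo_db_config <- function(blocks = .default_blocks(),
                            min_ring_size = c("LA" = 2L, "AA-BD" = 1L,
                                              "TA-BD" = 1L, "SeA-BD" = 1L),
                            max_species = 1e5) {
  stopifnot(max_species >= 1, all(min_ring_size >= 1))
  structure(list(blocks = blocks, min_ring_size = min_ring_size,
                 max_species = max_species),
            class = "oligo_db_config")
}

#' @rdname oligo_db_config
#' @param topology,end_group Topology and end group for every species in the
#'   block.
#' @param ranges Named list mapping repeat-unit family (`"AA-BD"`, `"TA-BD"`,
#'   `"SeA-BD"`, `"LA"`) to `c(min, max)` counts.
#' @param total Optional `c(min, max)` bound on the total repeat count.
#' @export
db_block <- function(topology, end_group, ranges, total = NULL) {
  bad <- setdiff(names(ranges), .FAMILIES)
  if (length(bad) > 0) {
    abort(paste0("unknown repeat family in db_block: ", paste(bad, collapse = ", ")))
  }
  .db_block(topology, end_group, ranges, total)
}

#' Enumerate the predicted oligoester database
#'
#' Exhaustively enumerates every cyclic/linear oligoester composition allowed
#' by the configuration, removes duplicates by canonical label, computes
#' formula and monoisotopic mass for each species, and sorts by mass. The
#' result is deterministic: the same configuration always yields the same
#' table in the same order.
#'
#' @param config An [oligo_db_config()].
#' @return A tibble with one row per species: `label`, `topology`,
#'   `end_group`, count columns, `total_units`, `formula`, `mass`.
#' @examples
#' db <- enumerate_oligo_db()
#' nrow(db)
#' db %>% match_neutral(840.35684)
#' @export
enumerate_oligo_db <- function(config = oligo_db_config()) {
  stopifnot(inherits(config, "oligo_db_config"))
  sizes <- vapply(config$blocks, function(b) {
    prod(vapply(b$ranges, function(r) r[2] - r[1] + 1, numeric(1)))
  }, numeric(1))
  if (sum(sizes) > config$max_species) {
    abort(paste0("enumeration would generate ", format(sum(sizes), big.mark = ","),
                 " candidate species (cap ", format(config$max_species, big.mark = ","),
                 "); tighten the block ranges or raise max_species"))
  }
  rows <- purrr::map(config$blocks, function(b) {
    grids <- lapply(.FAMILIES, function(f) {
      r <- b$ranges[[f]]
      if (is.null(r)) 0L else seq.int(r[1], r[2])
    })
    names(grids) <- .COUNT_COLS
    g <- do.call(expand.grid, grids)
    tot <- rowSums(g)
    keep <- tot >= max(1, b$total[1]) & tot <= b$total[2]
    # for blocks mixing several families, every listed family with a
    # min bound of 0 may be absent, but at least one unit must remain
    g <- g[keep, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    g$topology <- b$topology
    g$end_group <- b$end_group
    g
  })
  cand <- as_tibble(dplyr::bind_rows(rows))
  attr(cand, "out.attrs") <- NULL
  if (is.null(cand) || nrow(cand) == 0) {
    abort("configuration generated no species")
  }
  # minimum ring size applies to homopolymer rings
  cnt <- as.matrix(cand[.COUNT_COLS])
  fam_n <- rowSums(cnt > 0)
  single_fam <- .FAMILIES[apply(cnt > 0, 1, function(x) which(x)[1])]
  ring_min <- config$min_ring_size[single_fam]
  ring_min[is.na(ring_min)] <- 1
  drop <- cand$topology == "cyclic" & fam_n == 1 & rowSums(cnt) < ring_min
  cand <- cand[!drop, , drop = FALSE]

  out <- species_formula(cand)
  out <- out[!duplicated(out$label), , drop = FALSE]
  out %>%
    select("label", "topology", "end_group", dplyr::all_of(.COUNT_COLS),
           "total_units", "formula", "mass") %>%
    arrange(.data$mass, .data$label)
}

#' Match a neutral mass against the database
#'
#' Returns every species whose theoretical monoisotopic mass lies within
#' `tol` Da of each query mass, ranked by absolute error (an empty result is a
#' valid outcome, not an error).
#'
#' @param db A species table from [enumerate_oligo_db()].
#' @param mass Numeric vector of neutral monoisotopic masses (Da).
#' @param tol Absolute matching tolerance in Da (default 0.001, the
#'   direct-infusion assignment tolerance).
#' @return A tibble of candidate rows with `query_mass`, `error_da` and
#'   `rank` columns, ordered by query then `abs(error_da)`.
#' @export
match_neutral <- function(db, mass, tol = 0.001) {
  stopifnot(tol > 0)
  hits <- purrr::map_dfr(mass, function(m) {
    sel <- abs(db$mass - m) <= tol
    if (!any(sel)) return(NULL)
    h <- db[sel, , drop = FALSE]
    h$query_mass <- m
    h$error_da <- h$mass - m
    h <- h[order(abs(h$error_da)), , drop = FALSE]
    h$rank <- seq_len(nrow(h))
    h
  })
  if (nrow(hits) == 0) {
    hits <- db[0, , drop = FALSE]
    hits$query_mass <- numeric(0)
    hits$error_da <- numeric(0)
    hits$rank <- integer(0)
  }
  as_tibble(hits)
}

#' Read and write a species database as CSV
#'
#' Plain-text export/import of the enumerated database (columns as produced
#' by [enumerate_oligo_db()]); masses are written at full precision.
#'
#' @param db A species table.
#' @param path File path.
#' @return `read_oligo_db()` returns the species tibble; `write_oligo_db()`
#'   returns `path` invisibly.
#' @export
write_oligo_db <- function(db, path) {
  readr::write_csv(db, path)
  invisible(path)
}

#' @rdname write_oligo_db
#' @export
read_oligo_db <- function(path) {
  db <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("label", "topology", "end_group", .COUNT_COLS, "formula", "mass")
  missing <- setdiff(need, names(db))
  if (length(missing) > 0) {
    abort(paste0("database file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  as_tibble(db)
}
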