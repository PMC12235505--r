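# Readers, writers and workflow configuration.
#
# CSV dialect throughout: comma-separated, UTF-8, "." decimal. Readers
# validate and reject malformed input rather than silently coercing. mzML
# access goes through the mzR parser (reading requires centroided spectra,
# matching the upstream vendor-file conversion step).

#' Read a peak-list CSV as a centroid spectrum
#'
#' Expects columns `mz` and `intensity`; rows must be numeric and complete.
#' The spectrum is returned m/z-sorted, with centroids closer than 1e-6 Da
#' merged (intensities summed).
#'
#' @param path CSV file path.
#' @return A spectrum tibble (`mz`, `intensity`).
#' @export
read_peaklist_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  missing <- setdiff(c("mz", "intensity"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("peak list '", path, "' lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  mz <- suppressWarnings(as.numeric(raw$mz))
  intensity <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(is.na(mz) | is.na(intensity))
  if (length(bad) > 0) {
    abort(paste0("non-numeric or missing value in '", path, "' at data row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  .as_spectrum(tibble(mz = mz, intensity = intensity))
}

#' Write a spectrum as a peak-list CSV
#'
#' @param spectrum A spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(spectrum, path) {
  readr::write_csv(.as_spectrum(spectrum), path)
  invisible(path)
}

#' Read centroided spectra from an mzML file
#'
#' Opens the file with the mzR parser and returns all MS1 peak lists as one
#' tibble with a `spectrum` index column. Profile-mode spectra are rejected
#' with an explicit error: sequence extraction operates on centroids, and
#' centroiding belongs upstream in the vendor-file conversion.
#'
#' @param path mzML file path.
#' @return A tibble `spectrum`, `mz`, `intensity`.
#' @export
read_mzml_centroids <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package")
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) {
    warn(paste0("'", path, "' contains no spectra"))
    return(tibble(spectrum = integer(0), mz = numeric(0), intensity = numeric(0)))
  }
  if (any(!hdr$centroided %in% TRUE)) {
    abort(paste0("'", path, "' contains profile-mode spectra; centroid required ",
                 "(convert with peak picking enabled)"))
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  purrr::imap_dfr(pk, function(m, i) {
    colnames(m) <- c("mz", "intensity")
    out <- .as_spectrum(as_tibble(m))
    out$spectrum <- as.integer(i)
    out[c("spectrum", "mz", "intensity")]
  })
}

#' Write a centroid spectrum to mzML
#'
#' Writes a single positive-mode MS1 centroid spectrum through mzR, suitable
#' for round-tripping synthetic spectra through the mzML reader.
#'
#' @param spectrum A spectrum tibble (`mz`, `intensity`).
#' @param path Output path (overwritten).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectrum, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("writing mzML requires the mzR package")
  }
  spectrum <- .as_spectrum(spectrum)
  if (nrow(spectrum) == 0) abort("refusing to write an empty spectrum")
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = nrow(spectrum), totIonCurrent = sum(spectrum$intensity),
    retentionTime = 0,
    basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
    basePeakIntensity = max(spectrum$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "", spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(spectrum$mz),
    scanWindowUpperLimit = max(spectrum$mz),
    stringsAsFactors = FALSE
  )
  if (file.exists(path)) unlink(path)
  mzR::writeMSData(list(cbind(mz = spectrum$mz, intensity = spectrum$intensity)),
                   file = path, header = hdr)
  invisible(path)
}

#' Workflow configuration
#'
#' Bundles the tunable parameters of the screening workflow: the absolute
#' direct-infusion tolerance, the LC ppm tolerance, the intensity threshold,
#' adduct and charge sets, minimum ladder length and the RNG seed. The
#' object serialises to/from YAML and hashes stably, so reports can record
#' exactly which parameters produced them.
#'
#' @param di_tol_da Direct-infusion tolerance (Da).
#' @param lc_tol_ppm LC match tolerance (ppm).
#' @param min_intensity Intensity threshold.
#' @param adducts Adduct set.
#' @param charges Charge set.
#' @param min_length Minimum ladder length.
#' @param seed Optional integer seed.
#' @param output_dir Output directory for reports.
#' @return A list of class `workflow_config`.
#' @export
workflow_config <- function(di_tol_da = 0.001, lc_tol_ppm = 5,
                            min_intensity = 1e4,
                            adducts = c("[M+NH4]+", "[M+H]+", "[M+Na]+", "[M+2NH4]2+"),
                            charges = c(1L, 2L), min_length = 2L,
                            seed = NULL, output_dir = ".") {
  stopifnot(di_tol_da > 0, lc_tol_ppm > 0, min_intensity >= 0, min_length >= 2)
  structure(
    list(di_tol_da = di_tol_da, lc_tol_ppm = lc_tol_ppm,
         min_intensity = min_intensity, adducts = adducts,
         charges = as.integer(charges), min_length = as.integer(min_length),
         seed = seed, output_dir = output_dir),
    class = "workflow_config"
  )
}

#' @rdname workflow_config
#' @param config A `workflow_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname workflow_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(workflow_config, raw)
}

#' @rdname workflow_config
#' @export
config_hash <- function(config) {
  rlang::hash(yaml::as.yaml(unclass(config)))
}

#' Write a CSV/JSON report bundle
#'
#' Writes whichever result tables are supplied (components, annotations,
#' quantification, composition) as CSVs with stable column order, plus a
#' `metadata.json` recording package version, configuration, its hash and
#' the seed. All m/z columns are positive-ion observed values
#' (electron-corrected).
#'
#' @param dir Output directory (created if needed).
#' @param components,annotations,quantification,composition Optional tibbles.
#' @param config A [workflow_config()].
#' @return The directory path, invisibly.
#' @export
write_report <- function(dir, components = NULL, annotations = NULL,
                         quantification = NULL, composition = NULL,
                         config = workflow_config()) {
  tables <- list(components = components, annotations = annotations,
                 quantification = quantification, composition = composition)
  tables <- tables[!vapply(tables, is.null, logical(1))]
  if (length(tables) == 0) abort("write_report needs at least one table")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    readr::write_csv(as_tibble(tables[[nm]]), file.path(dir, paste0(nm, ".csv")))
  }
  meta <- list(
    package = "oligoscreen",
    version = as.character(utils::packageVersion("oligoscreen")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    config_hash = config_hash(config),
    tables = names(tables)
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
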