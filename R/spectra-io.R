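#' Read tandem-MS spectra from an MSP library file
#'
#' Parses the NIST text dialect of MSP: records separated by blank
#' lines, each with `Name:`, a precursor mass field (`PrecursorMZ:`,
#' `Precursor_mz:` or `PEPMASS:`), `Num Peaks:` and a peak list of
#' `m/z intensity` pairs.  Records without a parseable positive
#' precursor mass or without at least one usable fragment are skipped,
#' never silently: each skip is messaged and tallied in the `skipped`
#' attribute of the result.
#'
#' Redundant spectra of the same compound are deliberately kept as
#' separate rows — instrument-to-instrument variability in fragmentation
#' is part of the signal the downstream model must absorb — and peak
#' order within a record is preserved exactly as printed.
#'
#' @param path Path to an MSP file.
#' @param quiet Suppress per-record skip messages. Default `FALSE`.
#'
#' @return A tibble with one row per spectrum and columns
#'   `spectrum_id`, `compound_id` (InChIKey if present, else SMILES,
#'   else `NA`), `precursor_mz`, `adduct`, `fragments` (list-column of
#'   tibbles with `mz`, `intensity`) and `meta` (list-column of named
#'   character vectors with the remaining header fields).  Attribute
#'   `skipped` is a tibble of skipped records with reasons.
#' @seealso [read_mgf()], [write_msp()]
#' @export
read_msp <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read MSP file: ", path)
  lines <- readLines(path, warn = FALSE)
  # records are blank-line separated; a Name: line also opens a new record
  blocks <- split_blocks(lines, is_open = function(x) grepl("^name\\s*:", tolower(x)))
  parse_spectrum_blocks(blocks, path, format = "msp", quiet = quiet)
}

#' Read tandem-MS spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `KEY=value` headers;
#' `PEPMASS` (first number) is the precursor ion m/z, `TITLE` the
#' spectrum id.  Skip semantics and the returned shape match
#' [read_msp()]; duplicate blocks yield duplicate rows.
#'
#' @inheritParams read_msp
#' @return A tibble of spectra; see [read_msp()].
#' @export
read_mgf <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*BEGIN IONS\\s*$", lines, ignore.case = TRUE)
  ends <- grep("^\\s*END IONS\\s*$", lines, ignore.case = TRUE)
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  blocks <- purrr::map2(starts, ends, function(s, e) {
    if (e <= s + 1) character(0) else lines[(s + 1):(e - 1)]
  })
  parse_spectrum_blocks(blocks, path, format = "mgf", quiet = quiet)
}

#' Write spectra to a minimal MSP file
#'
#' Emits `Name`, `PrecursorMZ`, optional identifier/adduct headers,
#' `Num Peaks` and the peak list, one blank line between records.
#' Intended for fixtures and round-trip checks; masses are printed with
#' enough digits (`%.6g`) to round-trip the 0.01 Da grid.
#'
#' @param spectra A spectra tibble as returned by [read_msp()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  stopifnot(is.data.frame(spectra))
  out <- purrr::pmap(
    list(spectra$spectrum_id, spectra$compound_id, spectra$precursor_mz,
         spectra$adduct, spectra$fragments),
    function(id, cid, pmz, adduct, fr) {
      hdr <- c(
        paste0("Name: ", id),
        if (!is.na(cid)) paste0("InChIKey: ", cid),
        if (!is.na(adduct)) paste0("Precursor_type: ", adduct),
        paste0("PrecursorMZ: ", sprintf("%.9g", pmz)),
        paste0("Num Peaks: ", nrow(fr))
      )
      c(hdr, sprintf("%.9g %.6g", fr$mz, fr$intensity), "")
    }
  )
  writeLines(unlist(out), path)
  invisible(path)
}

# ---- internals --------------------------------------------------------------

split_blocks <- function(lines, is_open) {
  lines <- sub("\\s+$", "", lines)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(is_open(lines) | c(TRUE, blank[-length(blank)]))
  blocks <- split(lines[!blank], grp[!blank])
  blocks[vapply(blocks, length, 1L) > 0L]
}

header_value <- function(headers, keys) {
  nm <- tolower(names(headers))
  for (k in keys) {
    hit <- which(nm == k)
    if (length(hit)) return(headers[[hit[1]]])
  }
  NA_character_
}

parse_one_block <- function(block, format) {
  if (format == "msp") {
    hdr_re <- "^([^:]+):\\s*(.*)$"
    is_hdr <- grepl(hdr_re, block) & !grepl("^[[:space:]]*[0-9.eE+-]+[[:space:];,:]", block)
  } else {
    hdr_re <- "^([A-Za-z][A-Za-z0-9_]*)=(.*)$"
    is_hdr <- grepl(hdr_re, block)
  }
  headers <- block[is_hdr]
  keys <- trimws(sub(hdr_re, "\\1", headers))
  vals <- trimws(sub(hdr_re, "\\2", headers))
  headers <- stats::setNames(vals, keys)

  peak_lines <- block[!is_hdr]
  peaks <- parse_peaks(peak_lines)

  pm_raw <- header_value(
    headers,
    c("precursormz", "precursor_mz", "pepmass", "precursor m/z", "ms:1000744")
  )
  precursor_mz <- suppressWarnings(as.numeric(strsplit(trimws(pm_raw), "\\s+")[[1]][1]))

  id <- header_value(headers, c("name", "title", "spectrum_id"))
  inchikey <- header_value(headers, c("inchikey", "inchi_key"))
  smiles <- header_value(headers, c("smiles", "canonical_smiles"))
  compound_id <- if (!is.na(inchikey)) inchikey else smiles
  adduct <- header_value(headers, c("precursor_type", "precursortype", "adduct", "ion_mode_adduct"))

  used <- tolower(keys) %in% c("precursormz", "precursor_mz", "pepmass", "name",
                               "title", "inchikey", "inchi_key", "smiles",
                               "num peaks", "numpeaks", "precursor_type", "adduct")
  list(
    spectrum_id = if (is.na(id)) NA_character_ else id,
    compound_id = compound_id,
    precursor_mz = precursor_mz,
    adduct = adduct,
    fragments = peaks,
    meta = as.list(headers[!used])
  )
}

parse_peaks <- function(peak_lines) {
  peak_lines <- trimws(peak_lines)
  peak_lines <- peak_lines[nzchar(peak_lines)]
  if (!length(peak_lines)) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  toks <- strsplit(peak_lines, "[[:space:];,]+")
  mz <- suppressWarnings(vapply(toks, function(x) as.numeric(x[1]), 0))
  it <- suppressWarnings(vapply(
    toks, function(x) if (length(x) >= 2) as.numeric(x[2]) else 1, 0))
  keep <- is.finite(mz)
  tibble::tibble(mz = mz[keep], intensity = ifelse(is.finite(it[keep]), it[keep], 0))
}

parse_spectrum_blocks <- function(blocks, path, format, quiet) {
  skipped <- list()
  rows <- list()
  for (i in seq_along(blocks)) {
    rec <- tryCatch(parse_one_block(blocks[[i]], format), error = function(e) e)
    reason <- NULL
    if (inherits(rec, "error")) {
      reason <- paste("unparseable block:", conditionMessage(rec))
    } else if (!length(rec$fragments) || !nrow(rec$fragments)) {
      reason <- "no fragment peaks"
    } else if (!is.finite(rec$precursor_mz) || rec$precursor_mz <= 0) {
      reason <- "missing or non-positive precursor mass"
    } else if (any(rec$fragments$mz <= 0)) {
      reason <- "non-positive fragment m/z"
    }
    if (!is.null(reason)) {
      id <- if (inherits(rec, "error")) NA_character_ else rec$spectrum_id
      if (!quiet) message(sprintf("skipping record %d (%s): %s", i, id %||% "?", reason))
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(record = i, spectrum_id = id, reason = reason)
      next
    }
    if (is.na(rec$spectrum_id)) rec$spectrum_id <- sprintf("%s#%d", basename(path), i)
    rows[[length(rows) + 1L]] <- rec
  }
  out <- tibble::tibble(
    spectrum_id = purrr::map_chr(rows, "spectrum_id"),
    compound_id = purrr::map_chr(rows, "compound_id"),
    precursor_mz = purrr::map_dbl(rows, "precursor_mz"),
    adduct = purrr::map_chr(rows, "adduct"),
    fragments = purrr::map(rows, "fragments"),
    meta = purrr::map(rows, "meta")
  )
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(record = integer(0), spectrum_id = character(0), reason = character(0))
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
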