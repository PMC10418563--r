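#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, optional
#' `CHARGE`, `TITLE` and `POLARITY` headers followed by one
#' `mz intensity` pair per line. Peaks are sorted ascending by m/z on
#' the way in; blocks with no peaks are retained (they are legal, if
#' useless, queries). The provenance (`source_id`) of each spectrum is
#' its `TITLE`, or `<file basename>#<block ordinal>` when no title is
#' present.
#'
#' A block without a `PEPMASS` line is a record-level error: the parse
#' stops with an error naming the offending block number.
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  base <- basename(path)
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "#")]
    is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getval <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- getval("PEPMASS")
    if (is.na(pep))
      stop(sprintf("MGF block %d in %s is missing PEPMASS", b, base), call. = FALSE)
    precursor_mz <- suppressWarnings(as.numeric(strsplit(pep, "[ \t]+")[[1]][1]))
    if (!is.finite(precursor_mz))
      stop(sprintf("MGF block %d in %s has a non-numeric PEPMASS", b, base),
           call. = FALSE)
    charge <- NA_integer_
    ch <- getval("CHARGE")
    if (!is.na(ch)) {
      sign <- if (grepl("-", ch, fixed = TRUE)) -1L else 1L
      num <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch)))
      if (!is.na(num)) charge <- sign * num
    }
    polarity <- NA_character_
    pol <- getval("POLARITY")
    if (!is.na(pol)) {
      pol <- tolower(pol)
      if (pol %in% c("positive", "negative")) polarity <- pol
    } else if (!is.na(charge)) {
      polarity <- if (charge < 0) "negative" else "positive"
    }
    title <- getval("TITLE")
    source_id <- if (is.na(title) || !nzchar(title))
      sprintf("%s#%d", base, b) else title
    peak_lines <- block[!is_kv]
    mz <- numeric()
    int <- numeric()
    if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      mz <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1])), 0)
      int <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2])), 0)
      bad <- !is.finite(mz) | !is.finite(int)
      if (any(bad))
        stop(sprintf("MGF block %d in %s has an unparseable peak line", b, base),
             call. = FALSE)
    }
    out[[b]] <- spectrum(precursor_mz, mz, int, charge = charge,
                         source_id = source_id, polarity = polarity)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] for spectra whose peak lists are already
#' normalized: reading the written file back yields equal precursor,
#' charge and peak values (m/z and intensity are printed with enough
#' digits to round-trip doubles).
#'
#' @param spectra A list of [spectrum()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(is_spectrum(s))
    writeLines("BEGIN IONS", con)
    if (!is.na(s$source_id)) writeLines(paste0("TITLE=", s$source_id), con)
    writeLines(sprintf("PEPMASS=%.*g", 15L, s$precursor_mz), con)
    if (!is.na(s$charge))
      writeLines(sprintf("CHARGE=%d%s", abs(s$charge),
                         if (s$charge < 0) "-" else "+"), con)
    if (!is.na(s$polarity)) writeLines(paste0("POLARITY=", s$polarity), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.*g %.*g", 15L, s$peaks[, "mz"],
                         15L, s$peaks[, "intensity"]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read MS2 spectra from an mzML file
#'
#' Read-only mzML support, limited to MS2 scans with a recorded
#' precursor m/z (MS1 and precursor-less scans are skipped); MGF
#' remains the canonical interchange format. Requires the `mzR`
#' package.
#'
#' @param path Path to an mzML file.
#' @return A list of [spectrum()] objects, `source_id` =
#'   `<file basename>#<acquisition number>`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  if (!file.exists(path)) stop("cannot read mzML file: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  keep <- which(hdr$msLevel == 2L & !is.na(hdr$precursorMZ) &
                  hdr$precursorMZ > 0)
  base <- basename(path)
  lapply(keep, function(i) {
    pk <- mzR::peaks(handle, i)
    pol <- if (!"polarity" %in% names(hdr) || is.na(hdr$polarity[i]))
      NA_character_
    else if (hdr$polarity[i] > 0) "positive"
    else if (hdr$polarity[i] == 0) "negative" else NA_character_
    charge <- hdr$precursorCharge[i]
    spectrum(hdr$precursorMZ[i], pk[, 1], pk[, 2],
             charge = if (is.na(charge) || charge == 0) NA_integer_
               else as.integer(charge),
             source_id = sprintf("%s#%d", base, hdr$acquisitionNum[i]),
             polarity = pol)
  })
}
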