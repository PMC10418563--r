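#' Parse a Universal Spectrum Identifier
#'
#' Accepts the `mzspec:<collection>:<run>:scan|index:<n>` convention
#' used by public proteomics/metabolomics repositories. Attribute
#' segments after the index (e.g. a ProForma annotation) are tolerated
#' and ignored. The parsed reference round-trips losslessly through
#' [format_usi()].
#'
#' @param text A single USI string.
#' @return An object of class `usi_ref` with fields `collection`,
#'   `run`, `index_type` (`"scan"` or `"index"`) and `index_value`.
#' @export
parse_usi <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) < 1L || parts[1] != "mzspec")
    stop("USI must start with 'mzspec:': ", text, call. = FALSE)
  if (length(parts) < 5L)
    stop("USI has too few segments (need mzspec:collection:run:scan|index:n): ",
         text, call. = FALSE)
  if (!nzchar(parts[2])) stop("USI collection segment is empty: ", text, call. = FALSE)
  if (!nzchar(parts[3])) stop("USI run segment is empty: ", text, call. = FALSE)
  if (!parts[4] %in% c("scan", "index"))
    stop("USI index-type segment must be 'scan' or 'index', got '", parts[4],
         "'", call. = FALSE)
  idx <- suppressWarnings(as.integer(parts[5]))
  if (is.na(idx) || !grepl("^[0-9]+$", parts[5]))
    stop("USI index segment must be a non-negative integer, got '", parts[5],
         "'", call. = FALSE)
  structure(
    list(collection = parts[2], run = parts[3],
         index_type = parts[4], index_value = idx),
    class = "usi_ref"
  )
}

#' Serialize a USI reference to its canonical string
#' @param ref A `usi_ref` from [parse_usi()].
#' @return The canonical `mzspec:` string.
#' @export
format_usi <- function(ref) {
  stopifnot(inherits(ref, "usi_ref"))
  sprintf("mzspec:%s:%s:%s:%d", ref$collection, ref$run,
          ref$index_type, ref$index_value)
}

#' @export
print.usi_ref <- function(x, ...) {
  cat("<usi_ref>", format_usi(x), "\n")
  invisible(x)
}

#' Build a local spectrum store for USI resolution
#'
#' A spectrum store maps `(collection, run)` pairs to spectrum files on
#' disk so USIs can be resolved without network access. `scan` indices
#' are matched against a `scan=<n>` or trailing `#<n>` pattern in each
#' spectrum's `source_id`, falling back to the 1-based block ordinal;
#' `index` indices are 0-based block ordinals.
#'
#' @param collection Character vector of collection accessions.
#' @param run Character vector of run (file) names, same length.
#' @param path Character vector of MGF file paths, same length.
#' @return An object of class `spectrum_store`.
#' @export
spectrum_store <- function(collection, run, path) {
  stopifnot(length(collection) == length(run), length(run) == length(path))
  structure(
    list(table = data.frame(collection = as.character(collection),
                            run = as.character(run),
                            path = as.character(path),
                            stringsAsFactors = FALSE)),
    class = "spectrum_store"
  )
}

scan_of_source_id <- function(source_id, ordinal) {
  m <- regmatches(source_id, regexpr("scan[=:]([0-9]+)", source_id))
  if (length(m) && nzchar(m)) return(as.integer(gsub("[^0-9]", "", m)))
  m <- regmatches(source_id, regexpr("#([0-9]+)$", source_id))
  if (length(m) && nzchar(m)) return(as.integer(sub("#", "", m, fixed = TRUE)))
  ordinal
}

#' Resolve a USI against a local spectrum store
#'
#' @param ref A `usi_ref` or USI string.
#' @param store A [spectrum_store()].
#' @return The matching [spectrum()], with its `source_id` set to the
#'   canonical USI string.
#' @export
resolve_usi <- function(ref, store) {
  if (is.character(ref)) ref <- parse_usi(ref)
  stopifnot(inherits(ref, "usi_ref"), inherits(store, "spectrum_store"))
  hit <- which(store$table$collection == ref$collection &
                 store$table$run == ref$run)
  if (!length(hit))
    stop("unknown collection/run in spectrum store: ",
         ref$collection, ":", ref$run, call. = FALSE)
  spectra <- read_mgf(store$table$path[hit[1]])
  if (ref$index_type == "index") {
    pos <- ref$index_value + 1L
    if (pos < 1L || pos > length(spectra))
      stop("index ", ref$index_value, " not found in ", ref$run, call. = FALSE)
  } else {
    scans <- vapply(seq_along(spectra), function(i)
      scan_of_source_id(spectra[[i]]$source_id, i), integer(1))
    pos <- match(ref$index_value, scans)
    if (is.na(pos))
      stop("scan ", ref$index_value, " not found in ", ref$run, call. = FALSE)
  }
  s <- spectra[[pos]]
  s$source_id <- format_usi(ref)
  s
}
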