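#' Search parameters
#'
#' Bundle of thresholds and tolerances controlling a library search.
#' The defaults are the tool's standard settings: precursor and
#' fragment ion mass tolerances of 0.05 Th, minimum modified cosine of
#' 0.7, minimum of 3 matching fragment ions, analog search off. In
#' analog mode the precursor window is widened to `analog_window`
#' (symmetric, default 200 Th) and shifted fragment pairing is enabled.
#'
#' @param precursor_tol Precursor m/z tolerance in Th (exact mode
#'   candidate half-window).
#' @param frag_tol Fragment m/z tolerance in Th (absolute).
#' @param min_cosine Minimum modified cosine score for a reported match.
#' @param min_matched_ions Minimum number of matched fragment ions.
#' @param analog Enable analog (precursor-mass-shift-tolerant) search.
#' @param analog_window Maximum absolute precursor mass difference in
#'   analog mode, Th.
#' @param weighting Peak weighting for scoring; see [modified_cosine()].
#' @return An object of class `search_params`.
#' @export
search_params <- function(precursor_tol = 0.05, frag_tol = 0.05,
                          min_cosine = 0.7, min_matched_ions = 3L,
                          analog = FALSE, analog_window = 200,
                          weighting = "sqrt") {
  stopifnot(precursor_tol > 0, frag_tol > 0,
            min_cosine >= 0, min_cosine <= 1,
            min_matched_ions >= 1, analog_window > 0)
  structure(
    list(precursor_tol = precursor_tol, frag_tol = frag_tol,
         min_cosine = min_cosine,
         min_matched_ions = as.integer(min_matched_ions),
         analog = isTRUE(analog), analog_window = analog_window,
         weighting = weighting),
    class = "search_params"
  )
}

#' Format search parameters for display
#'
#' One `name=value` line per parameter, in a fixed order — the
#' parameter dump printed by the command-line `params` subcommand.
#'
#' @param p A [search_params()] object.
#' @return A character vector of lines.
#' @export
format_search_params <- function(p = search_params()) {
  stopifnot(inherits(p, "search_params"))
  c(sprintf("precursor_tol=%.2f", p$precursor_tol),
    sprintf("frag_tol=%.2f", p$frag_tol),
    sprintf("min_cosine=%.1f", p$min_cosine),
    sprintf("min_matched_ions=%d", p$min_matched_ions),
    sprintf("analog=%s", if (p$analog) "on" else "off"),
    sprintf("analog_window=%g", p$analog_window))
}

#' Build a precursor-indexed reference library
#'
#' Stores reference spectra together with their file metadata and an
#' index sorted by precursor m/z supporting range queries, the basis of
#' fast candidate retrieval: a search only scores the spectra whose
#' precursor falls inside the query window instead of the whole
#' library.
#'
#' @param spectra List of normalized [spectrum()] objects with unique
#'   `source_id`s.
#' @param records Data frame of file metadata ([load_metadata()]) with
#'   one row per entry of `spectra` (recycled by `file_id` lookup when
#'   a `file_id` column maps entries to files), or `NULL` for an
#'   annotation-style library without file metadata.
#' @param file_ids Character vector linking each spectrum to the
#'   `file_id` of its source file in `records`; defaults to the prefix
#'   of each spectrum's `source_id` before the last `#`.
#' @return A `library_index` object.
#' @export
build_index <- function(spectra, records = NULL, file_ids = NULL) {
  ids <- vapply(spectra, function(s) s$source_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate source_id in library: ",
         ids[anyDuplicated(ids)], call. = FALSE)
  if (is.null(file_ids) && length(spectra))
    file_ids <- sub("#[0-9]+$", "", ids)
  if (is.null(file_ids)) file_ids <- character()
  if (!is.null(records)) {
    missing <- setdiff(unique(file_ids), records$file_id)
    if (length(missing))
      stop("spectra reference file_ids absent from metadata: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  o <- order(prec)
  structure(
    list(spectra = spectra[o], source_id = ids[o], file_id = file_ids[o],
         precursor = prec[o], records = records),
    class = "library_index"
  )
}

#' @export
print.library_index <- function(x, ...) {
  cat(sprintf("<library_index> %d spectra, %d files\n",
              length(x$spectra), length(unique(x$file_id))))
  invisible(x)
}

#' Range query on a library index
#'
#' @param idx A [build_index()] object.
#' @param lo,hi Inclusive precursor m/z bounds.
#' @return Integer positions (into the index order) of entries with
#'   `lo <= precursor_mz <= hi`.
#' @export
range_query <- function(idx, lo, hi) {
  stopifnot(inherits(idx, "library_index"))
  if (!length(idx$precursor) || hi < lo) return(integer())
  # findInterval on the sorted precursor vector; both ends inclusive
  from <- findInterval(lo, idx$precursor, left.open = TRUE) + 1L
  to <- findInterval(hi, idx$precursor)
  if (from > to) return(integer())
  from:to
}

empty_matches <- function() {
  data.frame(query_id = character(), ref_source_id = character(),
             file_id = character(), score = numeric(),
             n_matched = integer(), delta_mz = numeric(),
             stringsAsFactors = FALSE)
}

#' Search a query spectrum against an indexed library
#'
#' Candidates are retrieved by a precursor range query (half-width
#' `precursor_tol`, or `analog_window` in analog mode), scored with the
#' modified cosine (shifted pairing enabled in analog mode), and
#' reported when `score >= min_cosine` and
#' `n_matched >= min_matched_ions`. Results are sorted by descending
#' score, then ascending `|delta_mz|`, then reference id.
#'
#' @param q A normalized, non-empty query [spectrum()].
#' @param idx A [build_index()] library.
#' @param params A [search_params()] object.
#' @return A data frame of matches with columns `query_id`,
#'   `ref_source_id`, `file_id`, `score`, `n_matched`, `delta_mz`.
#' @export
search_library <- function(q, idx, params = search_params()) {
  stopifnot(is_spectrum(q), inherits(idx, "library_index"),
            inherits(params, "search_params"))
  if (n_peaks(q) == 0L)
    stop("query spectrum has no peaks", call. = FALSE)
  half <- if (params$analog) params$analog_window else params$precursor_tol
  cand <- range_query(idx, q$precursor_mz - half, q$precursor_mz + half)
  if (!length(cand)) return(empty_matches())
  rows <- lapply(cand, function(i) {
    r <- idx$spectra[[i]]
    if (n_peaks(r) == 0L) return(NULL)
    sim <- modified_cosine(q, r, frag_tol = params$frag_tol,
                           allow_shift = params$analog,
                           weighting = params$weighting)
    if (sim$score >= params$min_cosine &&
        sim$n_matched >= params$min_matched_ions)
      data.frame(query_id = q$source_id, ref_source_id = idx$source_id[i],
                 file_id = idx$file_id[i], score = sim$score,
                 n_matched = sim$n_matched, delta_mz = sim$delta_mz,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_matches())
  out <- out[order(-out$score, abs(out$delta_mz), out$ref_source_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Batch search of spectra or USIs
#'
#' Runs [search_library()] for each query; each element may be a
#' [spectrum()] or a USI string/`usi_ref` resolved against `store`.
#' Per-query failures (e.g. an unresolvable USI or an empty spectrum)
#' are recorded and do not abort the batch.
#'
#' @param queries List of spectra, USI strings or `usi_ref`s.
#' @param idx A [build_index()] library.
#' @param params A [search_params()] object.
#' @param store Optional [spectrum_store()] for USI resolution.
#' @return A list with `results` (named list of match data frames keyed
#'   by query id) and `failures` (data frame of `query`, `error`).
#' @export
batch_search <- function(queries, idx, params = search_params(),
                         store = NULL) {
  results <- list()
  failures <- data.frame(query = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (k in seq_along(queries)) {
    qq <- queries[[k]]
    label <- if (is.character(qq)) qq
      else if (inherits(qq, "usi_ref")) format_usi(qq)
      else qq$source_id
    res <- tryCatch({
      if (is.character(qq) || inherits(qq, "usi_ref")) {
        if (is.null(store)) stop("no spectrum store for USI resolution")
        qq <- resolve_usi(qq, store)
      }
      search_library(qq, idx, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(query = label,
                                   error = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else {
      results[[label]] <- res
    }
  }
  list(results = results, failures = failures)
}

#' Annotate a query against a compound reference library
#'
#' Same scoring and thresholds as [search_library()], against an
#' annotation library of (spectrum, compound name, accession) entries —
#' the 'Library matches' view of a search job.
#'
#' @param q A normalized query [spectrum()].
#' @param annots A list with elements `spectra` (list of spectra),
#'   `name` and `accession` (character vectors, same length).
#' @param params A [search_params()] object.
#' @return Data frame with columns `query_id`, `accession`,
#'   `compound_name`, `score`, `n_matched`, `delta_mz`, sorted like
#'   [search_library()] results.
#' @export
annotate_against_reference_library <- function(q, annots,
                                               params = search_params()) {
  stopifnot(is_spectrum(q))
  n <- length(annots$spectra)
  empty <- data.frame(query_id = character(), accession = character(),
                      compound_name = character(), score = numeric(),
                      n_matched = integer(), delta_mz = numeric(),
                      stringsAsFactors = FALSE)
  if (!n) return(empty)
  idx <- build_index(annots$spectra,
                     file_ids = as.character(annots$accession))
  m <- search_library(q, idx, params)
  if (!nrow(m)) return(empty)
  data.frame(query_id = m$query_id, accession = m$file_id,
             compound_name = annots$name[match(m$file_id,
                                               as.character(annots$accession))],
             score = m$score, n_matched = m$n_matched,
             delta_mz = m$delta_mz, stringsAsFactors = FALSE)
}
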