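as_bool <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "y")
}

#' Load the per-file metadata table
#'
#' Reads the 10-column reference metadata table (CSV or TSV, detected
#' from the delimiter of the header line) describing every file of the
#' library: its repository path, unique dataset-qualified file id,
#' dataset accession, submitted and alternative taxon names, NCBI
#' taxonomy id, whether that id was assigned automatically or curated
#' manually, whether harmonized sample metadata exists, and blank/QC
#' flags. Column order is irrelevant; extra columns are kept.
#'
#' @param path Path to the metadata CSV/TSV.
#' @return A validated data frame of file records (one row per file).
#' @export
load_metadata <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata table: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  validate_metadata(df)
}

#' Validate a file-record data frame
#'
#' @param df Data frame with the columns of `METADATA_COLUMNS`.
#' @return The validated data frame with typed columns.
#' @export
validate_metadata <- function(df) {
  missing <- setdiff(METADATA_COLUMNS, names(df))
  if (length(missing))
    stop("metadata table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$ncbi_id <- suppressWarnings(as.integer(df$ncbi_id))
  df$has_redu_metadata <- as_bool(df$has_redu_metadata)
  df$is_blank <- as_bool(df$is_blank)
  df$is_qc <- as_bool(df$is_qc)
  dup <- df$file_id[duplicated(df$file_id)]
  if (length(dup))
    stop("duplicate file_id in metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  both <- df$is_blank & df$is_qc
  if (any(both))
    stop("file(s) flagged both blank and QC: ",
         paste(df$file_id[both], collapse = ", "), call. = FALSE)
  bad_assign <- !df$id_assignment %in% c("automatic", "manual")
  if (any(bad_assign))
    stop("id_assignment must be 'automatic' or 'manual' for: ",
         paste(df$file_id[bad_assign], collapse = ", "), call. = FALSE)
  no_id <- is.na(df$ncbi_id) & !(df$is_blank | df$is_qc) &
    !nzchar(df$taxon_name_submitted) & !nzchar(df$taxon_name_alternative)
  if (any(no_id))
    stop("non-blank/QC file(s) with neither NCBI id nor taxon name: ",
         paste(df$file_id[no_id], collapse = ", "), call. = FALSE)
  df
}

#' Read a lineage table
#'
#' A lineage table is a TSV with columns `ncbi_id` and `lineage`, the
#' latter a `;`-separated list of `rank:name:id` triplets ordered
#' coarse to fine down to the terminal taxon. It is a one-time export
#' of the ranked lineages of every taxon in the library, so no live
#' taxonomy service is needed at search time.
#'
#' @param path Path to the TSV.
#' @return A named list mapping NCBI id (as character) to a lineage
#'   data frame with columns `ncbi_id`, `name`, `rank`.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  stopifnot(all(c("ncbi_id", "lineage") %in% names(df)))
  out <- lapply(df$lineage, parse_lineage_string)
  names(out) <- as.character(df$ncbi_id)
  out
}

parse_lineage_string <- function(s) {
  trip <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(trip, length, 0L) != 3L
  if (any(bad)) stop("malformed lineage triplet in: ", s, call. = FALSE)
  data.frame(rank = vapply(trip, `[`, "", 1L),
             name = vapply(trip, `[`, "", 2L),
             ncbi_id = as.integer(vapply(trip, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

format_lineage_string <- function(lin) {
  paste(sprintf("%s:%s:%d", lin$rank, lin$name, lin$ncbi_id), collapse = ";")
}

#' Write a lineage table
#' @param lineages Named list of lineage data frames ([read_lineage_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineages, path) {
  df <- data.frame(ncbi_id = names(lineages),
                   lineage = vapply(lineages, format_lineage_string, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a taxon-name fallback map from a lineage table
#'
#' Maps every taxon name appearing on any lineage to its NCBI id (first
#' occurrence wins), so submitted or curated alternative names can be
#' resolved to their closest accurate taxon without a separate export.
#'
#' @param lineage_table Named list from [read_lineage_table()].
#' @return Named integer vector mapping scientific names to NCBI ids.
#' @export
fallback_from_lineages <- function(lineage_table) {
  names_all <- unlist(lapply(lineage_table, `[[`, "name"), use.names = FALSE)
  ids_all <- unlist(lapply(lineage_table, `[[`, "ncbi_id"), use.names = FALSE)
  keep <- !duplicated(names_all)
  stats::setNames(as.integer(ids_all[keep]), names_all[keep])
}

domain_lineage <- function(which) {
  switch(which,
         bacteria = data.frame(rank = "domain", name = "Bacteria",
                               ncbi_id = 2L, stringsAsFactors = FALSE),
         fungi = data.frame(rank = c("domain", "kingdom"),
                            name = c("Eukaryota", "Fungi"),
                            ncbi_id = c(2759L, 4751L),
                            stringsAsFactors = FALSE),
         archaea = data.frame(rank = "domain", name = "Archaea",
                              ncbi_id = 2157L, stringsAsFactors = FALSE),
         stop("unknown domain: ", which, call. = FALSE))
}

#' Resolve a file record to a ranked lineage
#'
#' Resolution order mirrors the curation fallback used when a submitted
#' taxon is not present in the NCBI taxonomy: (1) the record's
#' `ncbi_id`, when present in the lineage table; (2) the alternative
#' then submitted taxon name through the `fallback` name-to-id map
#' (the "closest accurate taxon" route, e.g. an unavailable strain
#' curated to its species); (3) a generic domain-level placeholder
#' (Bacteria or Fungi) when the name only indicates the broad group.
#'
#' @param record One row of a [load_metadata()] table (data frame or
#'   list).
#' @param lineage_table Named list from [read_lineage_table()].
#' @param fallback Named integer vector mapping taxon names to NCBI ids.
#' @return A lineage data frame (`rank`, `name`, `ncbi_id`).
#' @export
resolve_taxon <- function(record, lineage_table, fallback = integer()) {
  key <- as.character(record$ncbi_id)
  if (!is.na(record$ncbi_id) && key %in% names(lineage_table))
    return(lineage_table[[key]])
  for (nm in c(record$taxon_name_alternative, record$taxon_name_submitted)) {
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) next
    if (nm %in% names(fallback)) {
      id <- fallback[[nm]]
      key <- as.character(id)
      if (key %in% names(lineage_table)) return(lineage_table[[key]])
      # an intermediate taxon (e.g. a genus): truncate any lineage
      # passing through it
      for (l in lineage_table) {
        hit <- match(id, l$ncbi_id)
        if (!is.na(hit)) return(l[seq_len(hit), , drop = FALSE])
      }
    }
  }
  nm <- paste(record$taxon_name_alternative, record$taxon_name_submitted)
  if (grepl("bacteri", nm, ignore.case = TRUE)) return(domain_lineage("bacteria"))
  if (grepl("fung", nm, ignore.case = TRUE)) return(domain_lineage("fungi"))
  if (grepl("archae", nm, ignore.case = TRUE)) return(domain_lineage("archaea"))
  stop("cannot resolve taxon for file ", record$file_id,
       " (ncbi_id ", record$ncbi_id, ", name '",
       record$taxon_name_submitted, "')", call. = FALSE)
}

#' Resolve all records of a metadata table
#'
#' Applies [resolve_taxon()] to every biological record; blank and QC
#' files need no lineage and map to `NULL`.
#'
#' @param records A [load_metadata()] data frame.
#' @inheritParams resolve_taxon
#' @return A named list (by `file_id`) of lineage data frames.
#' @export
resolve_taxa <- function(records, lineage_table, fallback = NULL) {
  if (is.null(fallback)) fallback <- fallback_from_lineages(lineage_table)
  out <- vector("list", nrow(records))
  names(out) <- records$file_id
  for (i in seq_len(nrow(records))) {
    if (records$is_blank[i] || records$is_qc[i]) next
    out[[i]] <- resolve_taxon(records[i, ], lineage_table, fallback)
  }
  out
}
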