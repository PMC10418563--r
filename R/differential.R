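#' Read a feature table
#'
#' Rows are consensus-spectrum ids, columns are sample ids, values are
#' non-negative abundances (0 = absent after any upstream gap filling).
#'
#' @param path TSV path; first column `spectrum_id`.
#' @return A data frame with rownames = spectrum ids, one numeric
#'   column per sample.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  stopifnot(names(df)[1] == "spectrum_id")
  rownames(df) <- as.character(df$spectrum_id)
  df$spectrum_id <- NULL
  df
}

#' Read a sample-condition label table
#' @param path TSV path with columns `sample_id`, `condition`.
#' @return Named character vector mapping sample id to condition.
#' @export
read_condition_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  stopifnot(all(c("sample_id", "condition") %in% names(df)))
  stats::setNames(df$condition, df$sample_id)
}

#' Read a spectral-network edge list
#' @param path TSV path with columns `id1`, `id2`, `cosine`, `delta_mz`.
#' @return Data frame with those columns.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  stopifnot(all(c("id1", "id2", "cosine", "delta_mz") %in% names(df)))
  df
}

presence_in <- function(table, samples, min_abundance = 0) {
  cols <- intersect(samples, colnames(table))
  if (!length(cols)) return(rep(FALSE, nrow(table)))
  rowSums(as.matrix(table[, cols, drop = FALSE]) > min_abundance) > 0
}

#' Spectra unique to one condition
#'
#' Returns the spectrum ids present (abundance above `min_abundance`)
#' in at least one sample of the target condition and absent from
#' every sample of all other conditions — e.g. spectra seen only in
#' colonized (SPF) animals and never in germ-free ones.
#'
#' @param table Feature table ([read_feature_table()]).
#' @param labels Named condition vector ([read_condition_labels()])
#'   covering all sample columns.
#' @param target The condition whose unique spectra are wanted.
#' @param min_abundance Presence floor (default 0: any positive value
#'   counts as present).
#' @return Character vector of spectrum ids, in table order.
#' @export
condition_unique <- function(table, labels, target, min_abundance = 0) {
  if (!target %in% labels)
    stop("unknown condition label: ", target, call. = FALSE)
  missing <- setdiff(colnames(table), names(labels))
  if (length(missing))
    stop("unlabeled sample column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  target_samples <- names(labels)[labels == target]
  other_samples <- names(labels)[labels != target]
  in_target <- presence_in(table, target_samples, min_abundance)
  in_other <- presence_in(table, other_samples, min_abundance)
  rownames(table)[in_target & !in_other]
}

#' Remove near-duplicates of control spectra
#'
#' Drops from `uniq` every spectrum connected by a network edge to a
#' control-condition spectrum with cosine similarity above `cos_thr`
#' AND absolute precursor mass difference within `delta_thr` — the
#' extra filtering layer that removes spectra whose close analogs also
#' occur in the control condition.
#'
#' @param uniq Character vector of candidate spectrum ids.
#' @param edges Edge data frame ([read_edge_list()]).
#' @param control_ids Spectrum ids present in the control condition.
#' @param cos_thr Cosine threshold (edge kept for removal when
#'   `cosine > cos_thr`); default 0.7.
#' @param delta_thr Max absolute precursor delta in Th; default 0.02.
#' @return The surviving subset of `uniq`, order preserved.
#' @export
remove_control_analogs <- function(uniq, edges, control_ids,
                                   cos_thr = 0.7, delta_thr = 0.02) {
  if (!length(uniq) || !nrow(edges) || !length(control_ids)) return(uniq)
  hit <- edges$cosine > cos_thr & abs(edges$delta_mz) <= delta_thr
  e <- edges[hit, , drop = FALSE]
  bad <- union(e$id1[e$id2 %in% control_ids], e$id2[e$id1 %in% control_ids])
  uniq[!uniq %in% bad]
}

#' Screen candidate spectra against the microbial reference library
#'
#' Batch-searches every candidate spectrum against the indexed
#' monoculture library and partitions the ids into `matched` (at least
#' one microbial match and no cell-line overlap), `matched_but_cell_line`
#' (matched, but also found in human cell-line files — set aside as
#' not unambiguously microbial) and `unmatched`. Matched ids carry a
#' domain label (`bacteria_only`, `fungi_only`, `both`, `none`).
#'
#' @param spectra Named list of query spectra (names = spectrum ids).
#' @param idx Reference [build_index()].
#' @param tree The library's [build_taxon_tree()].
#' @param params [search_params()].
#' @return A list with character vectors `matched`,
#'   `matched_but_cell_line`, `unmatched`, and `domain` (named
#'   character vector over all matched ids, cell-line ones included).
#' @export
microbial_screen <- function(spectra, idx, tree, params = search_params()) {
  ids <- names(spectra)
  stopifnot(!is.null(ids) || !length(spectra))
  matched <- character()
  cell_line <- character()
  unmatched <- character()
  domain <- character()
  for (id in ids) {
    m <- search_library(spectra[[id]], idx, params)
    biological <- m[is.na(tree$files$special[match(m$file_id,
                                                   tree$files$file_id)]), ,
                    drop = FALSE]
    has_cell <- flag_cell_line_overlap(m, tree)
    if (!nrow(biological) && !has_cell) {
      unmatched <- c(unmatched, id)
      next
    }
    domain[id] <- as.character(classify_domain(biological, tree))
    if (has_cell)
      cell_line <- c(cell_line, id)
    else
      matched <- c(matched, id)
  }
  list(matched = matched, matched_but_cell_line = cell_line,
       unmatched = unmatched, domain = domain)
}

#' Persistence of candidate spectra in a second dataset
#'
#' Searches every surviving spectrum against the spectra of a second
#' study (e.g. antibiotics-treated vs untreated animals).
#' `overlapping` spectra have at least one match passing the score and
#' matched-ion thresholds; of these, `untreated_only` spectra match
#' only second-dataset spectra that never occur in treated samples.
#'
#' @param survivors Named list of query spectra.
#' @param second_spectra Named list of second-dataset spectra (names =
#'   ids, i.e. rownames of `second_table`).
#' @param second_table Feature table of the second dataset.
#' @param second_labels Condition labels with values `"treated"` /
#'   `"untreated"`.
#' @param params [search_params()].
#' @param min_abundance Presence floor for the second feature table.
#' @return List of character vectors `overlapping` and `untreated_only`.
#' @export
cross_dataset_persistence <- function(survivors, second_spectra,
                                      second_table, second_labels,
                                      params = search_params(),
                                      min_abundance = 0) {
  treated_samples <- names(second_labels)[second_labels == "treated"]
  in_treated <- presence_in(second_table, treated_samples, min_abundance)
  names(in_treated) <- rownames(second_table)
  idx <- build_index(unname(second_spectra),
                     file_ids = names(second_spectra))
  overlapping <- character()
  untreated_only <- character()
  for (id in names(survivors)) {
    m <- search_library(survivors[[id]], idx, params)
    if (!nrow(m)) next
    overlapping <- c(overlapping, id)
    if (all(!in_treated[m$file_id])) untreated_only <- c(untreated_only, id)
  }
  list(overlapping = overlapping, untreated_only = untreated_only)
}

#' Run the full differential pipeline
#'
#' Chains the stages: condition-unique extraction, control-analog
#' removal, microbial screening with cell-line exclusion, and (when a
#' second dataset is supplied) cross-dataset persistence. Each stage
#' refines the previous one, so the stage counts form a non-increasing
#' funnel.
#'
#' @param table,labels,target First dataset ([condition_unique()]).
#' @param spectra Named list of the first dataset's spectra.
#' @param edges Edge list for analog removal ([read_edge_list()]).
#' @param idx,tree Reference library index and tree.
#' @param second Optional list with `spectra`, `table`, `labels` for
#'   [cross_dataset_persistence()].
#' @param params [search_params()].
#' @param min_abundance Presence floor.
#' @return A list with per-stage id vectors (`unique`,
#'   `after_analog_removal`, `screen` as returned by
#'   [microbial_screen()], `overlapping`, `untreated_only`) and a
#'   `funnel` data frame of stage names and counts.
#' @export
run_differential_pipeline <- function(table, labels, target, spectra,
                                      edges, idx, tree, second = NULL,
                                      params = search_params(),
                                      min_abundance = 0) {
  uniq <- condition_unique(table, labels, target, min_abundance)
  control_ids <- rownames(table)[presence_in(
    table, names(labels)[labels != target], min_abundance)]
  kept <- remove_control_analogs(uniq, edges, control_ids)
  screen <- microbial_screen(spectra[kept], idx, tree, params)
  survivors <- screen$matched
  stages <- data.frame(
    stage = c("condition_unique", "after_analog_removal",
              "microbial_matched", "non_cell_line"),
    n = c(length(uniq), length(kept),
          length(screen$matched) + length(screen$matched_but_cell_line),
          length(survivors)),
    stringsAsFactors = FALSE)
  out <- list(unique = uniq, after_analog_removal = kept, screen = screen)
  if (!is.null(second)) {
    per <- cross_dataset_persistence(spectra[survivors], second$spectra,
                                     second$table, second$labels, params,
                                     min_abundance)
    out$overlapping <- per$overlapping
    out$untreated_only <- per$untreated_only
    stages <- rbind(stages,
                    data.frame(stage = c("overlapping_second",
                                         "untreated_only"),
                               n = c(length(per$overlapping),
                                     length(per$untreated_only)),
                               stringsAsFactors = FALSE))
  }
  out$funnel <- stages
  out
}
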