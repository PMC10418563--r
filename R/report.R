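# nested per-node list mirroring the displayed tree: name, ncbi_id,
# rank, n_samples, n_matched, proportion, children
tree_to_list <- function(tree) {
  kids <- children_of(tree)
  nd <- tree$nodes
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    list(name = nd$name[id],
         ncbi_id = nd$ncbi_id[id],
         rank = nd$rank[id],
         n_samples = nd$n_samples[id],
         n_matched = nd$n_matched[id],
         proportion = nd$proportion[id],
         children = if (is.null(ch)) list() else lapply(ch, rec))
  }
  rec(1L)
}

#' Serialize an aggregated tree to JSON
#'
#' @param tree An aggregated `taxon_tree`.
#' @return A JSON string (nested objects with `name`, `ncbi_id`,
#'   `rank`, `n_samples`, `n_matched`, `proportion`, `children`).
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(tree_to_list(tree), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

tree_to_details_html <- function(tree) {
  kids <- children_of(tree)
  nd <- tree$nodes
  rec <- function(id) {
    label <- sprintf(
      "%s <span class='meta'>[%s] samples %d, matches %d (%.1f%%)</span>",
      html_escape(nd$name[id]), html_escape(nd$rank[id]),
      nd$n_samples[id], nd$n_matched[id], 100 * nd$proportion[id])
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || !length(ch))
      return(sprintf("<div class='leaf'>%s</div>", label))
    sprintf("<details open><summary>%s</summary><div class='kids'>%s</div></details>",
            label, paste(vapply(ch, rec, ""), collapse = "\n"))
  }
  rec(1L)
}

#' Write a standalone interactive HTML tree
#'
#' A self-contained HTML file (no network assets) with a collapsible
#' rendering of the aggregated taxonomic tree and the full tree JSON
#' embedded in a `<script type="application/json">` block for
#' downstream use.
#'
#' @param tree An aggregated `taxon_tree`.
#' @param path Output HTML path.
#' @param title Page title.
#' @return `path`, invisibly.
#' @export
write_tree_html <- function(tree, path, title = "Taxonomic match tree") {
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>\n<title>",
    html_escape(title), "</title>\n",
    "<style>body{font-family:sans-serif;font-size:14px}",
    ".kids{margin-left:1.5em}.meta{color:#666;font-size:12px}",
    "summary{cursor:pointer}.leaf{margin-left:1.1em}</style>\n",
    "</head><body>\n<h1>", html_escape(title), "</h1>\n",
    tree_to_details_html(tree),
    "\n<script type='application/json' id='tree-data'>\n",
    tree_to_json(tree),
    "\n</script>\n</body></html>\n")
  writeLines(html, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Dataset-level match table
#'
#' One row per matching reference scan with its taxon annotation — the
#' 'Datasets matches' view. The reference scan is addressed by a USI
#' built from its dataset and file.
#'
#' @param matches Combined match data frame (columns as returned by
#'   [search_library()]).
#' @param tree A `taxon_tree`.
#' @param records Metadata data frame ([load_metadata()]).
#' @return Data frame with columns `query_id`, `ref_usi`,
#'   `scientific_name`, `ncbi_id`, `rank`, `n_matched_ions`, `cosine`,
#'   `delta_mz`.
#' @export
dataset_match_table <- function(matches, tree, records) {
  if (!nrow(matches))
    return(data.frame(query_id = character(), ref_usi = character(),
                      scientific_name = character(), ncbi_id = numeric(),
                      rank = character(), n_matched_ions = integer(),
                      cosine = numeric(), delta_mz = numeric(),
                      stringsAsFactors = FALSE))
  fpos <- match(matches$file_id, tree$files$file_id)
  node <- tree$files$node_id[fpos]
  rpos <- match(matches$file_id, records$file_id)
  scan <- sub("^.*#", "", matches$ref_source_id)
  usi <- sprintf("mzspec:%s:%s:scan:%s", records$dataset_id[rpos],
                 matches$file_id, scan)
  out <- data.frame(query_id = matches$query_id, ref_usi = usi,
                    scientific_name = tree$nodes$name[node],
                    ncbi_id = tree$nodes$ncbi_id[node],
                    rank = tree$nodes$rank[node],
                    n_matched_ions = matches$n_matched,
                    cosine = matches$score, delta_mz = matches$delta_mz,
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id, -out$cosine, abs(out$delta_mz),
                   out$ref_usi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit the result tables and tree exports of a search job
#'
#' Writes the three result tables — `library_matches.tsv` (annotation
#' hits), `dataset_matches.tsv` (per-scan reference matches with taxon
#' context) and `taxa_matches.tsv` (per-taxon counts and proportions)
#' — plus `tree.json` and a standalone `tree.html`. Output is
#' deterministic: fixed column order and row sort, so identical inputs
#' give byte-identical files.
#'
#' @param matches Combined match data frame over all queries.
#' @param tree The matching `taxon_tree` (aggregation is applied here).
#' @param records Metadata data frame.
#' @param annotations Data frame from
#'   [annotate_against_reference_library()] (possibly empty).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the five written paths, invisibly.
#' @export
emit_outputs <- function(matches, tree, records, annotations = NULL,
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  agg <- aggregate_matches(matches, tree)
  if (is.null(annotations))
    annotations <- data.frame(query_id = character(), accession = character(),
                              compound_name = character(), score = numeric(),
                              n_matched = integer(), delta_mz = numeric(),
                              stringsAsFactors = FALSE)
  ann <- annotations[order(annotations$query_id, -annotations$score,
                           annotations$accession), , drop = FALSE]
  paths <- c(
    library_matches = file.path(out_dir, "library_matches.tsv"),
    dataset_matches = file.path(out_dir, "dataset_matches.tsv"),
    taxa_matches = file.path(out_dir, "taxa_matches.tsv"),
    tree_json = file.path(out_dir, "tree.json"),
    tree_html = file.path(out_dir, "tree.html")
  )
  write_tsv(ann, paths[["library_matches"]])
  write_tsv(dataset_match_table(matches, agg, records),
            paths[["dataset_matches"]])
  write_tsv(taxa_match_table(agg), paths[["taxa_matches"]])
  writeLines(tree_to_json(agg), paths[["tree_json"]])
  write_tree_html(agg, paths[["tree_html"]])
  invisible(paths)
}
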