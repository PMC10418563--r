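match_files <- function(matches) unique(matches$file_id)

#' Project matches onto the taxonomic tree
#'
#' Credits every matched file to its terminal taxon and propagates the
#' match upstream through the lineage. Counts are of distinct matched
#' files — a file matched by several scans counts once — so each
#' node's matched-file set is the union of its children's sets and
#' `n_matched <= n_samples` holds everywhere. Matches to blank, QC or
#' cell-line files are recorded on their special nodes only and do not
#' enter the biological totals (including the root's).
#'
#' @param matches A match data frame from [search_library()] or a
#'   combined batch (column `file_id` is used).
#' @param tree A [build_taxon_tree()] object.
#' @return The tree with `n_matched` and `proportion`
#'   (`n_matched / n_samples`) populated on every node.
#' @export
aggregate_matches <- function(matches, tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  files <- match_files(matches)
  unknown <- setdiff(files, tree$files$file_id)
  if (length(unknown))
    stop("match references file(s) not attached to the tree: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  counts <- integer(nrow(tree$nodes))
  anc <- ancestor_chains(tree)
  pos <- match(files, tree$files$file_id)
  for (k in seq_along(pos)) {
    chain <- anc[[tree$files$node_id[pos[k]]]]
    if (!is.na(tree$files$special[pos[k]]))
      chain <- chain[chain != 1L]
    counts[chain] <- counts[chain] + 1L
  }
  tree$nodes$n_matched <- counts
  tree$nodes$proportion <- ifelse(tree$nodes$n_samples > 0,
                                  counts / tree$nodes$n_samples, 0)
  tree
}

# node ids of the subtree rooted at each of the given nodes
subtree_ids <- function(tree, roots) {
  kids <- children_of(tree)
  out <- integer()
  stack <- roots
  while (length(stack)) {
    id <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, id)
    ch <- kids[[as.character(id)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

find_node <- function(tree, ncbi_id) {
  which(!is.na(tree$nodes$ncbi_id) & tree$nodes$ncbi_id == ncbi_id &
          !tree$nodes$special)
}

#' Does a query's match set touch the human cell-line subtree?
#'
#' @param matches Match data frame of one query.
#' @param tree A `taxon_tree`.
#' @return `TRUE` iff at least one matched file is a cell-line file.
#' @export
flag_cell_line_overlap <- function(matches, tree) {
  files <- match_files(matches)
  pos <- match(files, tree$files$file_id)
  any(!is.na(pos) & !is.na(tree$files$special[pos]) &
        tree$files$special[pos] == "cell_line")
}

#' Classify the domain membership of a query's matches
#'
#' Labels a query by where its matched biological files sit:
#' `"bacteria_only"`, `"fungi_only"`, `"both"`, or `"none"` (archaeal
#' matches are reported via the `archaea` attribute and do not affect
#' the label). Domain subtrees are located by their NCBI ids (Bacteria
#' 2, Fungi 4751, Archaea 2157).
#'
#' @param matches Match data frame of one query.
#' @param tree An aggregated `taxon_tree`.
#' @return A character label with attribute `archaea` (logical).
#' @export
classify_domain <- function(matches, tree) {
  files <- match_files(matches)
  pos <- match(files, tree$files$file_id)
  pos <- pos[!is.na(pos) & is.na(tree$files$special[pos])]
  in_domain <- function(ncbi) {
    node <- find_node(tree, ncbi)
    if (!length(node)) return(FALSE)
    ids <- subtree_ids(tree, node)
    any(tree$files$node_id[pos] %in% ids)
  }
  bact <- in_domain(2)
  fungi <- in_domain(4751)
  arch <- in_domain(2157)
  label <- if (bact && fungi) "both"
    else if (bact) "bacteria_only"
    else if (fungi) "fungi_only"
    else "none"
  attr(label, "archaea") <- arch
  label
}

#' Filter an aggregated tree
#'
#' Collapses nodes finer than `max_rank` into their nearest kept
#' ancestor (whose counts, already upstream-propagated, are unchanged)
#' and prunes nodes with fewer than `min_matches` matched files. Since
#' matched counts are non-increasing from ancestor to descendant, every
#' ancestor of a surviving node survives too.
#'
#' @param tree An aggregated `taxon_tree`.
#' @param max_rank Optional finest rank to keep (e.g. `"genus"`);
#'   special nodes are always kept.
#' @param min_matches Minimum `n_matched` for a node to be kept
#'   (default 0 keeps everything).
#' @return The filtered `taxon_tree`; files attached to removed nodes
#'   are re-attached to their nearest kept ancestor.
#' @export
filter_tree <- function(tree, max_rank = NULL, min_matches = 0) {
  stopifnot(inherits(tree, "taxon_tree"), min_matches >= 0)
  keep <- rep(TRUE, nrow(tree$nodes))
  if (!is.null(max_rank)) {
    if (!max_rank %in% names(RANK_LEVEL))
      stop("unknown rank: ", max_rank, call. = FALSE)
    lvl <- RANK_LEVEL[[max_rank]]
    biological <- !tree$nodes$special
    keep[biological] <- RANK_LEVEL[tree$nodes$rank[biological]] <= lvl
  }
  keep <- keep & (tree$nodes$n_matched >= min_matches | tree$nodes$special)
  if (min_matches > 0) {
    # special nodes obey the same threshold; the root always stays
    keep[tree$nodes$special] <- tree$nodes$n_matched[tree$nodes$special] >=
      min_matches
  }
  keep[1L] <- TRUE
  # nearest kept ancestor of every node
  parent <- tree$nodes$parent
  nearest <- function(id) {
    while (!is.na(id) && !keep[id]) id <- parent[id]
    if (is.na(id)) 1L else id
  }
  new_id <- cumsum(keep)
  nodes <- tree$nodes[keep, , drop = FALSE]
  nodes$id <- new_id[nodes$id]
  # re-parent each kept node onto its nearest kept ancestor
  old_ids <- tree$nodes$id[keep]
  nodes$parent <- vapply(old_ids, function(id) {
    p <- parent[id]
    if (is.na(p)) return(NA_integer_)
    new_id[nearest(p)]
  }, integer(1))
  files <- tree$files
  files$node_id <- vapply(files$node_id, function(id) new_id[nearest(id)],
                          integer(1))
  out <- structure(list(nodes = nodes, files = files), class = "taxon_tree")
  rownames(out$nodes) <- NULL
  out
}

#' Per-taxon match table
#'
#' One row per taxon with its matched-file count, available sample
#' count and the match proportion — the 'Taxa matches' view. Rows are
#' sorted by descending matched count, then rank coarse to fine, then
#' name.
#'
#' @param tree An aggregated `taxon_tree`.
#' @param all_taxa Keep rows for unmatched taxa too (default drops
#'   them).
#' @return Data frame with columns `ncbi_id`, `scientific_name`,
#'   `rank`, `n_matched_files`, `n_samples`, `proportion`.
#' @export
taxa_match_table <- function(tree, all_taxa = FALSE) {
  nd <- tree$nodes
  if (!all_taxa) nd <- nd[nd$n_matched > 0, , drop = FALSE]
  nd <- nd[nd$rank != "root", , drop = FALSE]
  out <- data.frame(ncbi_id = nd$ncbi_id, scientific_name = nd$name,
                    rank = nd$rank, n_matched_files = nd$n_matched,
                    n_samples = nd$n_samples, proportion = nd$proportion,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_matched_files, RANK_SORT[out$rank],
                   out$scientific_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
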