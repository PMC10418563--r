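#' Build the taxonomic tree of a reference library
#'
#' Creates one node per distinct taxon appearing on any resolved
#' lineage (restricted to the kept ranks, domain through strain plus
#' subgenus/subspecies/varietas), attaches every biological file at its
#' terminal taxon, and adds dedicated children of the root for blanks,
#' QCs and human cell-line files. Cell-line files (any lineage
#' containing *Homo sapiens*) are grouped under a `cell_line` node with
#' one child per distinct submitted name. Per-node sample counts
#' (`n_samples`) are accumulated bottom-up over biological files;
#' blank/QC/cell-line files count only on their special nodes, so the
#' sample totals of biological taxa reflect biological files only.
#'
#' @param records A validated metadata data frame ([load_metadata()]).
#' @param lineages Named list of resolved lineages ([resolve_taxa()]).
#' @return An object of class `taxon_tree` with elements `nodes` (data
#'   frame: `id`, `parent`, `ncbi_id`, `name`, `rank`, `special`,
#'   `n_samples`, `n_matched`, `proportion`) and `files` (data frame:
#'   `file_id`, `node_id`, `special`).
#' @export
build_taxon_tree <- function(records, lineages) {
  nodes <- data.frame(id = 1L, parent = NA_integer_, ncbi_id = 1,
                      name = "root", rank = "root", special = TRUE,
                      n_samples = 0L, n_matched = 0L, proportion = 0,
                      stringsAsFactors = FALSE)
  by_ncbi <- new.env(parent = emptyenv())   # ncbi_id -> node id (biological)
  special_ids <- new.env(parent = emptyenv())
  add_node <- function(parent, ncbi_id, name, rank, special = FALSE) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, parent, ncbi_id, name, rank, special, 0L, 0L, 0)
    id
  }
  get_special <- function(key, name, rank, ncbi_id) {
    if (!is.null(special_ids[[key]])) return(special_ids[[key]])
    id <- add_node(1L, ncbi_id, name, rank, special = TRUE)
    special_ids[[key]] <- id
    id
  }
  file_node <- integer(nrow(records))
  file_special <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (rec$is_blank) {
      file_node[i] <- get_special("blank", "Blanks", "blank", -1)
      file_special[i] <- "blank"
      next
    }
    if (rec$is_qc) {
      file_node[i] <- get_special("qc", "QCs", "qc", -2)
      file_special[i] <- "qc"
      next
    }
    lin <- lineages[[rec$file_id]]
    if (is.null(lin))
      stop("no resolved lineage for biological file ", rec$file_id,
           call. = FALSE)
    if (NCBI_HOMO_SAPIENS %in% lin$ncbi_id) {
      cl <- get_special("cell_line", "Human cell lines", "cell_line", -3)
      nm <- if (nzchar(rec$taxon_name_submitted)) rec$taxon_name_submitted
        else "cell line"
      key <- paste0("cell_line:", nm)
      if (is.null(special_ids[[key]])) {
        special_ids[[key]] <- add_node(cl, -3 - length(ls(special_ids)),
                                       nm, "cell_line", special = TRUE)
      }
      file_node[i] <- special_ids[[key]]
      file_special[i] <- "cell_line"
      next
    }
    lin <- lin[lin$rank %in% KEPT_RANKS, , drop = FALSE]
    if (!nrow(lin))
      stop("lineage of file ", rec$file_id, " has no kept ranks",
           call. = FALSE)
    parent <- 1L
    for (j in seq_len(nrow(lin))) {
      key <- as.character(lin$ncbi_id[j])
      id <- by_ncbi[[key]]
      if (is.null(id)) {
        id <- add_node(parent, lin$ncbi_id[j], lin$name[j], lin$rank[j])
        by_ncbi[[key]] <- id
      } else {
        if (nodes$parent[id] != parent)
          stop("inconsistent lineages: taxon ", lin$name[j], " (",
               lin$ncbi_id[j], ") has two different parents", call. = FALSE)
      }
      parent <- id
    }
    file_node[i] <- parent
  }
  tree <- structure(
    list(nodes = nodes,
         files = data.frame(file_id = records$file_id, node_id = file_node,
                            special = file_special,
                            stringsAsFactors = FALSE)),
    class = "taxon_tree"
  )
  recount_samples(tree)
}

# recompute n_samples bottom-up: biological files count on every
# biological ancestor (root included); special files only on their own
# special chain below the root
recount_samples <- function(tree) {
  n <- nrow(tree$nodes)
  counts <- integer(n)
  anc <- ancestor_chains(tree)
  for (i in seq_len(nrow(tree$files))) {
    chain <- anc[[tree$files$node_id[i]]]
    if (!is.na(tree$files$special[i]))
      chain <- chain[chain != 1L]     # keep special counts off the root
    counts[chain] <- counts[chain] + 1L
  }
  tree$nodes$n_samples <- counts
  tree
}

# list of self-plus-ancestors id chains, one per node
ancestor_chains <- function(tree) {
  parent <- tree$nodes$parent
  n <- length(parent)
  chains <- vector("list", n)
  for (i in seq_len(n)) {
    chain <- i
    p <- parent[i]
    while (!is.na(p)) {
      chain <- c(chain, p)
      p <- parent[p]
    }
    chains[[i]] <- chain
  }
  chains
}

children_of <- function(tree) {
  split(tree$nodes$id[-1L], tree$nodes$parent[-1L])
}

#' @export
print.taxon_tree <- function(x, ...) {
  cat(sprintf("<taxon_tree> %d nodes, %d files (%d biological)\n",
              nrow(x$nodes), nrow(x$files), sum(is.na(x$files$special))))
  invisible(x)
}

quote_newick <- function(name) {
  if (grepl("[](),:;'[[:space:]]", name) || grepl("\\[", name))
    paste0("'", gsub("'", "''", name), "'")
  else name
}

#' Export a taxonomic tree to Newick
#'
#' Topology and node names only; counts travel in the JSON export.
#' Names containing Newick metacharacters are single-quoted per the
#' standard.
#'
#' @param tree A `taxon_tree`.
#' @return A single Newick string terminated by `;`.
#' @export
export_newick <- function(tree) {
  kids <- children_of(tree)
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    label <- quote_newick(tree$nodes$name[id])
    if (is.null(ch) || !length(ch)) return(label)
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", label)
  }
  paste0(rec(1L), ";")
}

#' Parse a Newick string to a nested name/children list
#'
#' Thin wrapper over [ape::read.tree()]; the result is a plain nested
#' list (`name`, `children`) mirroring the topology, including unary
#' internal chains as produced by ranked lineages.
#'
#' @param text A Newick string.
#' @return Nested list with elements `name` and `children`.
#' @export
parse_newick <- function(text) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("cannot parse Newick string", call. = FALSE)
  ntip <- length(phy$tip.label)
  unquote <- function(x) {
    quoted <- grepl("^'.*'$", x)
    x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
    x
  }
  label_of <- function(v) {
    if (v <= ntip) unquote(phy$tip.label[v]) else
      unquote(phy$node.label[v - ntip])
  }
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    list(name = label_of(v),
         children = if (is.null(ch)) list() else lapply(ch, rec))
  }
  rec(ntip + 1L)
}

# nested name/children view of a taxon_tree, for topology comparison
tree_topology <- function(tree) {
  kids <- children_of(tree)
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    list(name = tree$nodes$name[id],
         children = if (is.null(ch)) list() else lapply(ch, rec))
  }
  rec(1L)
}
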