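# shared test helpers: tiny spectra, a hand-built taxonomy, and an
# independent brute-force scorer used as oracle against the engine

spec2 <- function(precursor, mz, int = rep(1, length(mz)), id = "s") {
  spectrum(precursor, mz, int, source_id = id)
}

# independent modified-cosine oracle: enumerate ALL one-to-one pairings
# of candidate pairs recursively and take the best total weight; shares
# no code with the package's greedy/exact selection
oracle_modified_cosine <- function(q, r, frag_tol = 0.05,
                                   allow_shift = FALSE,
                                   weighting = "sqrt") {
  w <- function(s) switch(weighting, sqrt = sqrt(s$peaks[, "intensity"]),
                          raw = s$peaks[, "intensity"])
  wq <- w(q); wr <- w(r)
  delta <- q$precursor_mz - r$precursor_mz
  cand <- list()
  for (i in seq_along(wq)) for (j in seq_along(wr)) {
    d <- q$peaks[i, "mz"] - r$peaks[j, "mz"]
    if (abs(d) <= frag_tol || (allow_shift && abs(d - delta) <= frag_tol))
      cand[[length(cand) + 1L]] <- c(i, j, wq[i] * wr[j])
  }
  best <- 0
  rec <- function(k, uq, ur, acc) {
    if (acc > best) best <<- acc
    if (k > length(cand)) return()
    rec(k + 1L, uq, ur, acc)                      # skip pair k
    p <- cand[[k]]
    if (!(p[1] %in% uq) && !(p[2] %in% ur))
      rec(k + 1L, c(uq, p[1]), c(ur, p[2]), acc + p[3])
  }
  rec(1L, integer(), integer(), 0)
  norm <- sqrt(sum(wq^2)) * sqrt(sum(wr^2))
  if (norm > 0) best / norm else 0
}

rand_test_spectrum <- function(n = 6, precursor = runif(1, 300, 800)) {
  spec2(precursor, runif(n, 50, precursor - 30), runif(n, 1, 100))
}

# minimal 2-species / 1-genus library with optional blanks etc.
toy_records <- function(extra = NULL) {
  df <- data.frame(
    massive_path = paste0("MSV1/peak/f", 1:4, ".mzML"),
    file_id = paste0("f", 1:4),
    dataset_id = "MSV1",
    taxon_name_submitted = c("Aspergillus terreus", "Aspergillus terreus",
                             "Aspergillus flavus", "Aspergillus flavus"),
    taxon_name_alternative = "",
    ncbi_id = c(33178L, 33178L, 5059L, 5059L),
    id_assignment = "automatic",
    has_redu_metadata = TRUE,
    is_blank = FALSE, is_qc = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  validate_metadata(df)
}

toy_lineages <- function() {
  list(
    "33178" = data.frame(
      rank = c("domain", "kingdom", "genus", "species"),
      name = c("Eukaryota", "Fungi", "Aspergillus", "Aspergillus terreus"),
      ncbi_id = c(2759L, 4751L, 5052L, 33178L), stringsAsFactors = FALSE),
    "5059" = data.frame(
      rank = c("domain", "kingdom", "genus", "species"),
      name = c("Eukaryota", "Fungi", "Aspergillus", "Aspergillus flavus"),
      ncbi_id = c(2759L, 4751L, 5052L, 5059L), stringsAsFactors = FALSE),
    "1280" = data.frame(
      rank = c("domain", "genus", "species"),
      name = c("Bacteria", "Staphylococcus", "Staphylococcus aureus"),
      ncbi_id = c(2L, 1279L, 1280L), stringsAsFactors = FALSE),
    "9606" = data.frame(
      rank = c("domain", "species"),
      name = c("Eukaryota", "Homo sapiens"),
      ncbi_id = c(2759L, 9606L), stringsAsFactors = FALSE))
}

toy_tree <- function(records = toy_records()) {
  build_taxon_tree(records, resolve_taxa(records, toy_lineages()))
}

extra_record <- function(file_id, submitted = "x", ncbi_id = NA_integer_,
                         blank = FALSE, qc = FALSE, dataset_id = "MSV1",
                         alternative = "") {
  data.frame(massive_path = paste0(dataset_id, "/peak/", file_id, ".mzML"),
             file_id = file_id, dataset_id = dataset_id,
             taxon_name_submitted = submitted,
             taxon_name_alternative = alternative, ncbi_id = ncbi_id,
             id_assignment = "manual", has_redu_metadata = FALSE,
             is_blank = blank, is_qc = qc, stringsAsFactors = FALSE)
}

# linear-scan matched-file count for one node: files whose attachment
# node lies in the node's subtree (independent of aggregate_matches)
oracle_node_matched <- function(tree, matched_files, node_id) {
  kids <- split(tree$nodes$id[-1L], tree$nodes$parent[-1L])
  in_subtree <- function(id) {
    while (!is.na(id)) {
      if (id == node_id) return(TRUE)
      id <- tree$nodes$parent[id]
    }
    FALSE
  }
  pos <- match(unique(matched_files), tree$files$file_id)
  sum(vapply(tree$files$node_id[pos], in_subtree, logical(1)))
}

# one shared default repository per test run (cheap, but no need to
# rebuild per file)
.shared <- new.env(parent = emptyenv())
shared_repo <- function() {
  if (is.null(.shared$repo)) .shared$repo <- make_repository(fixture_spec())
  .shared$repo
}
shared_index <- function() {
  if (is.null(.shared$idx)) .shared$idx <- repository_index(shared_repo())
  .shared$idx
}
shared_tree <- function() {
  if (is.null(.shared$tree)) .shared$tree <- repository_tree(shared_repo())
  .shared$tree
}
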