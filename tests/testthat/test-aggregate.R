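fake_matches <- function(file_ids, query = "q", scans = 1L) {
  if (!length(file_ids))
    return(data.frame(query_id = character(), ref_source_id = character(),
                      file_id = character(), score = numeric(),
                      n_matched = integer(), delta_mz = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(file_ids, function(f)
    data.frame(query_id = query,
               ref_source_id = paste0(f, "#", seq_len(scans)),
               file_id = f, score = 0.9, n_matched = 5L, delta_mz = 0,
               stringsAsFactors = FALSE)))
}

test_that("a single matched file propagates upstream through its lineage", {
  tree <- toy_tree()
  agg <- aggregate_matches(fake_matches("f1"), tree)
  nd <- agg$nodes
  for (name in c("Aspergillus terreus", "Aspergillus", "Fungi",
                 "Eukaryota", "root"))
    expect_equal(nd$n_matched[nd$name == name], 1L)
  expect_equal(nd$n_matched[nd$name == "Aspergillus flavus"], 0L)
  # proportion = matched / available
  expect_equal(nd$proportion[nd$name == "Aspergillus"], 0.25)
  expect_equal(nd$proportion[nd$name == "Aspergillus terreus"], 0.5)
})

test_that("matches count distinct files, not scans", {
  tree <- toy_tree()
  # 3 scans of the same file count once everywhere
  agg <- aggregate_matches(fake_matches("f1", scans = 3L), tree)
  expect_equal(max(agg$nodes$n_matched), 1L)
  # two species with one matched file each sum at the genus
  agg2 <- aggregate_matches(fake_matches(c("f1", "f3")), tree)
  nd <- agg2$nodes
  expect_equal(nd$n_matched[nd$name == "Aspergillus"], 2L)
  expect_equal(nd$n_matched[nd$name == "Aspergillus terreus"], 1L)
  expect_error(aggregate_matches(fake_matches("ghost"), tree),
               "not attached")
})

test_that("internal matched counts equal linear-scan subtree counts", {
  repo <- shared_repo()
  tree <- shared_tree()
  set.seed(3)
  files <- sample(repo$records$file_id, 40)
  agg <- aggregate_matches(fake_matches(files), tree)
  bio_files <- files[is.na(tree$files$special[match(files,
                                                    tree$files$file_id)])]
  for (id in sample(which(!agg$nodes$special), 15)) {
    expect_equal(agg$nodes$n_matched[id],
                 oracle_node_matched(tree, bio_files, id))
  }
})

test_that("blank, QC and cell-line matches stay on their special nodes", {
  recs <- toy_records(rbind(extra_record("b1", "media", blank = TRUE),
                            extra_record("c1", "HeLa", ncbi_id = 9606L)))
  tree <- toy_tree(recs)
  agg <- aggregate_matches(fake_matches(c("b1", "c1")), tree)
  nd <- agg$nodes
  expect_equal(nd$n_matched[nd$rank == "blank"], 1L)
  expect_equal(sum(nd$n_matched[nd$rank == "cell_line"]), 2L) # node + child
  expect_equal(nd$n_matched[1L], 0L)   # root counts biological only
  expect_true(all(nd$n_matched <= nd$n_samples))
})

test_that("cell-line overlap flag fires only on cell-line matches", {
  recs <- toy_records(extra_record("c1", "HeLa", ncbi_id = 9606L))
  tree <- toy_tree(recs)
  expect_false(flag_cell_line_overlap(fake_matches("f1"), tree))
  expect_true(flag_cell_line_overlap(fake_matches(c("f1", "c1")), tree))
  expect_true(flag_cell_line_overlap(fake_matches("c1"), tree))
})

test_that("domain classification follows planted membership", {
  recs <- toy_records(extra_record("s1", "Staphylococcus aureus",
                                   ncbi_id = 1280L))
  tree <- toy_tree(recs)
  expect_equal(as.character(classify_domain(fake_matches("s1"), tree)),
               "bacteria_only")
  expect_equal(as.character(classify_domain(fake_matches("f1"), tree)),
               "fungi_only")
  expect_equal(as.character(classify_domain(fake_matches(c("f1", "s1")),
                                            tree)), "both")
  expect_equal(as.character(classify_domain(fake_matches("s1")[0, ], tree)),
               "none")
  # fixture queries with planted domains recover their labels
  repo <- shared_repo()
  tree2 <- shared_tree()
  idx <- shared_index()
  for (m in names(repo$templates)) {
    q <- repo$templates[[m]]
    q$source_id <- "q"
    hits <- search_library(q, idx)
    sp <- repo$producer[[m]]
    dom <- repo$lineages[[as.character(sp)]]$name[1]
    want <- if (dom == "Bacteria") "bacteria_only" else "fungi_only"
    expect_equal(as.character(classify_domain(hits, tree2)), want)
  }
})

test_that("filter_tree collapses ranks conservatively and prunes by matches", {
  tree <- toy_tree()
  agg <- aggregate_matches(fake_matches(c("f1", "f3")), tree)
  # min_matches 0 is the identity
  expect_equal(filter_tree(agg, min_matches = 0)$nodes, agg$nodes)
  # collapsing to genus removes species but keeps genus counts
  g <- filter_tree(agg, max_rank = "genus")
  expect_false(any(g$nodes$rank == "species"))
  expect_equal(g$nodes$n_matched[g$nodes$name == "Aspergillus"], 2L)
  expect_equal(g$nodes$n_samples[g$nodes$name == "Aspergillus"], 4L)
  # species files re-attach at the genus
  expect_equal(unique(g$files$node_id),
               g$nodes$id[g$nodes$name == "Aspergillus"])
  # min_matches 2 on one-match-per-species: species pruned, genus kept
  f2 <- filter_tree(agg, min_matches = 2)
  expect_false(any(f2$nodes$rank == "species"))
  expect_true("Aspergillus" %in% f2$nodes$name)
  expect_error(filter_tree(agg, max_rank = "clade"), "unknown rank")
})

test_that("pruning is monotone in the match threshold", {
  repo <- shared_repo()
  tree <- shared_tree()
  set.seed(17)
  agg <- aggregate_matches(fake_matches(sample(repo$records$file_id, 60)),
                           tree)
  sizes <- vapply(0:4, function(m)
    nrow(filter_tree(agg, min_matches = m)$nodes), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("collapse-only filtering commutes with aggregation", {
  tree <- toy_tree()
  matches <- fake_matches(c("f1", "f2", "f3"))
  collapse_then_count <- aggregate_matches(
    matches, filter_tree(tree, max_rank = "genus"))
  count_then_collapse <- filter_tree(
    aggregate_matches(matches, tree), max_rank = "genus")
  expect_equal(collapse_then_count$nodes$n_matched,
               count_then_collapse$nodes$n_matched)
  expect_equal(collapse_then_count$nodes$name,
               count_then_collapse$nodes$name)
})

test_that("taxa table rows mirror the aggregated counts with integer ratios", {
  tree <- toy_tree()
  agg <- aggregate_matches(fake_matches(c("f1", "f3")), tree)
  tab <- taxa_match_table(agg)
  expect_true(all(tab$n_matched_files <= tab$n_samples))
  expect_equal(tab$proportion * tab$n_samples, tab$n_matched_files)
  genus_row <- tab[tab$scientific_name == "Aspergillus", ]
  expect_equal(genus_row$n_matched_files, 2L)
  # sorted by matched count descending
  expect_false(is.unsorted(rev(tab$n_matched_files)))
})

test_that("emit_outputs writes the three tables and tree exports deterministically", {
  repo <- shared_repo()
  tree <- shared_tree()
  idx <- shared_index()
  q <- repo$templates[[1]]
  q$source_id <- "q"
  matches <- search_library(q, idx)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- emit_outputs(matches, tree, repo$records, out_dir = dir1)
  p2 <- emit_outputs(matches, tree, repo$records, out_dir = dir2)
  for (k in names(p1)) {
    expect_true(file.exists(p1[[k]]))
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])))
  }
  dm <- read.delim(p1[["dataset_matches"]])
  expect_equal(sort(unique(dm$ref_usi)),
               sort(sprintf("mzspec:%s:%s:scan:%s",
                            repo$records$dataset_id[
                              match(matches$file_id, repo$records$file_id)],
                            matches$file_id,
                            sub("^.*#", "", matches$ref_source_id))))
  tm <- read.delim(p1[["taxa_matches"]])
  agg <- aggregate_matches(matches, tree)
  expect_equal(nrow(tm), sum(agg$nodes$n_matched > 0 &
                               agg$nodes$rank != "root"))
  js <- jsonlite::fromJSON(readLines(p1[["tree_json"]]),
                           simplifyVector = FALSE)
  expect_equal(js$name, "root")
  expect_equal(js$n_samples, agg$nodes$n_samples[1])
})

test_that("zero matches yield header-only tables and an all-zero tree", {
  repo <- shared_repo()
  tree <- shared_tree()
  dir <- withr::local_tempdir()
  paths <- emit_outputs(fake_matches(character()), tree, repo$records,
                        out_dir = dir)
  expect_equal(nrow(read.delim(paths[["taxa_matches"]])), 0L)
  expect_equal(nrow(read.delim(paths[["dataset_matches"]])), 0L)
  js <- jsonlite::fromJSON(readLines(paths[["tree_json"]]),
                           simplifyVector = FALSE)
  expect_equal(js$n_matched, 0L)
})
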