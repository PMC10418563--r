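toy_table <- function() {
  tab <- data.frame(
    A1 = c(5, 0, 2, 0), A2 = c(1, 0, 0, 0),
    B1 = c(0, 3, 1, 0), B2 = c(0, 0, 0, 4),
    row.names = c("u1", "c1", "shared", "c2"))
  tab
}
toy_labels <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")

test_that("condition-unique extraction keeps target-only spectra", {
  expect_equal(condition_unique(toy_table(), toy_labels, "A"), "u1")
  expect_setequal(condition_unique(toy_table(), toy_labels, "B"),
                  c("c1", "c2"))
  expect_error(condition_unique(toy_table(), toy_labels, "C"),
               "unknown condition")
  expect_error(condition_unique(toy_table(), toy_labels[-1], "A"),
               "unlabeled")
  # a presence floor can demote low-abundance occurrences
  expect_setequal(condition_unique(toy_table(), toy_labels, "A",
                                   min_abundance = 1.5),
                  c("u1", "shared"))
})

test_that("control-analog removal needs both the cosine and the delta criterion", {
  uniq <- c("a", "b", "c", "d")
  edges <- data.frame(
    id1 = c("a", "b", "c", "x"),
    id2 = c("g1", "g1", "g2", "d"),
    cosine = c(0.9, 0.9, 0.5, 0.95),
    delta_mz = c(0.01, 0.5, 0.01, -0.015))
  out <- remove_control_analogs(uniq, edges, c("g1", "g2", "x"))
  # a: both criteria met -> removed; b: delta fails; c: cosine fails;
  # d: removed via the reversed edge direction
  expect_equal(out, c("b", "c"))
  # empty control set is the identity
  expect_equal(remove_control_analogs(uniq, edges, character()), uniq)
  # cosine exactly at the threshold is not an edge (strict >)
  e2 <- data.frame(id1 = "a", id2 = "g1", cosine = 0.7, delta_mz = 0)
  expect_equal(remove_control_analogs(uniq, e2, "g1"), uniq)
})

test_that("removal agrees with a brute-force double loop on a random fixture", {
  set.seed(41)
  ids <- sprintf("s%02d", 1:30)
  ctrl <- sprintf("g%02d", 1:10)
  edges <- data.frame(id1 = sample(ids, 60, TRUE),
                      id2 = sample(ctrl, 60, TRUE),
                      cosine = runif(60, 0.4, 1),
                      delta_mz = runif(60, -0.1, 0.1))
  got <- remove_control_analogs(ids, edges, ctrl)
  brute <- ids[vapply(ids, function(id) {
    !any(vapply(seq_len(nrow(edges)), function(k) {
      (edges$id1[k] == id && edges$id2[k] %in% ctrl ||
         edges$id2[k] == id && edges$id1[k] %in% ctrl) &&
        edges$cosine[k] > 0.7 && abs(edges$delta_mz[k]) <= 0.02
    }, logical(1)))
  }, logical(1))]
  expect_equal(got, brute)
})

test_that("microbial screening partitions queries with domain labels", {
  repo <- shared_repo()
  idx <- shared_index()
  tree <- shared_tree()
  qs <- list(
    microbial = repo$templates[[1]],
    host = repo$host_template,
    stray = spec2(750.123, c(111.1, 222.2, 333.3), c(5, 5, 5))
  )
  out <- microbial_screen(qs, idx, tree)
  expect_equal(out$matched, "microbial")
  expect_equal(out$matched_but_cell_line, "host")
  expect_equal(out$unmatched, "stray")
  expect_true(length(out$matched) + length(out$matched_but_cell_line) +
                length(out$unmatched) == length(qs))
  expect_equal(unname(out$domain["microbial"]), "bacteria_only")
  # empty input gives an empty partition
  empty <- microbial_screen(stats::setNames(list(), character()), idx, tree)
  expect_length(empty$matched, 0L)
  expect_length(empty$unmatched, 0L)
})

test_that("the planted differential funnel is recovered exactly", {
  repo <- shared_repo()
  idx <- shared_index()
  tree <- shared_tree()
  fx <- make_differential_fixture(repo)
  res <- run_differential_pipeline(fx$table, fx$labels, "SPF", fx$spectra,
                                   fx$edges, idx, tree, second = fx$second)
  expect_setequal(res$unique, fx$truth$unique)
  expect_setequal(res$after_analog_removal, fx$truth$after_analog_removal)
  expect_setequal(res$screen$matched, fx$truth$non_cell_line)
  expect_setequal(res$screen$matched_but_cell_line, fx$truth$cell_line)
  expect_setequal(res$overlapping, fx$truth$overlapping)
  expect_setequal(res$untreated_only, fx$truth$untreated_only)
  expect_equal(res$funnel$n, fx$truth$funnel$n)
})

test_that("each pipeline stage refines the previous one", {
  repo <- shared_repo()
  idx <- shared_index()
  tree <- shared_tree()
  for (seed in c(2, 3)) {
    fx <- make_differential_fixture(repo, seed = seed, n_unique = 30L,
                                    n_analog_removed = 10L,
                                    n_microbial = 9L, n_cell = 1L,
                                    n_overlap = 5L, n_untreated_only = 3L)
    res <- run_differential_pipeline(fx$table, fx$labels, "SPF",
                                     fx$spectra, fx$edges, idx, tree,
                                     second = fx$second)
    expect_true(all(res$after_analog_removal %in% res$unique))
    expect_true(all(res$screen$matched %in% res$after_analog_removal))
    expect_true(all(res$overlapping %in% res$screen$matched))
    expect_true(all(res$untreated_only %in% res$overlapping))
    expect_true(all(diff(res$funnel$n[-3]) <= 0))
  }
})

test_that("stage outputs ignore sample and row ordering", {
  repo <- shared_repo()
  idx <- shared_index()
  tree <- shared_tree()
  fx <- make_differential_fixture(repo)
  set.seed(8)
  tab <- fx$table[sample(nrow(fx$table)), sample(ncol(fx$table))]
  res1 <- run_differential_pipeline(fx$table, fx$labels, "SPF", fx$spectra,
                                    fx$edges, idx, tree)
  res2 <- run_differential_pipeline(tab, fx$labels, "SPF", fx$spectra,
                                    fx$edges, idx, tree)
  expect_setequal(res1$unique, res2$unique)
  expect_setequal(res1$screen$matched, res2$screen$matched)
  expect_equal(sort(res1$funnel$n), sort(res2$funnel$n))
})

test_that("cross-dataset persistence separates treated-touched spectra", {
  repo <- shared_repo()
  fx <- make_differential_fixture(repo)
  surv <- fx$spectra[fx$truth$non_cell_line]
  per <- cross_dataset_persistence(surv, fx$second$spectra,
                                   fx$second$table, fx$second$labels)
  expect_setequal(per$overlapping, fx$truth$overlapping)
  expect_setequal(per$untreated_only, fx$truth$untreated_only)
  # survivors with no second-dataset counterpart never overlap
  expect_false(any(setdiff(fx$truth$non_cell_line, fx$truth$overlapping)
                   %in% per$overlapping))
})

test_that("differential I/O round-trips through the on-disk layout", {
  repo <- shared_repo()
  fx <- make_differential_fixture(repo)
  dir <- withr::local_tempdir()
  write_differential_fixture(fx, dir)
  tab <- read_feature_table(file.path(dir, "features.tsv"))
  expect_equal(rownames(tab), rownames(fx$table))
  expect_equal(unname(as.matrix(tab)), unname(as.matrix(fx$table)))
  lab <- read_condition_labels(file.path(dir, "labels.tsv"))
  expect_equal(lab, fx$labels)
  edges <- read_edge_list(file.path(dir, "edges.tsv"))
  expect_equal(edges$id1, fx$edges$id1)
  ss <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_length(ss, length(fx$spectra))
})
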