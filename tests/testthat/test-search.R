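make_lib <- function(precursors, prefix = "f") {
  lapply(seq_along(precursors), function(i) {
    s <- spec2(precursors[i], c(100, 150, 200.5), c(5, 10, 2))
    s$source_id <- sprintf("%s%d#1", prefix, i)
    s
  })
}

test_that("range queries return exactly the in-window entries", {
  idx <- build_index(make_lib(c(100, 200, 300)))
  hit <- range_query(idx, 150, 250)
  expect_equal(idx$precursor[hit], 200)
  # inclusive at both ends
  expect_equal(idx$precursor[range_query(idx, 200, 300)], c(200, 300))
  expect_length(range_query(idx, 400, 500), 0L)
  empty <- build_index(list())
  expect_length(range_query(empty, 0, 1e6), 0L)
})

test_that("range queries agree with a linear scan on random windows", {
  set.seed(13)
  prec <- runif(1000, 100, 1500)
  idx <- build_index(make_lib(prec))
  for (k in 1:100) {
    lo <- runif(1, 50, 1500)
    hi <- lo + runif(1, 0, 300)
    expect_setequal(idx$precursor[range_query(idx, lo, hi)],
                    prec[prec >= lo & prec <= hi])
  }
})

test_that("duplicate provenance is a build error and entry count is conserved", {
  lib <- make_lib(c(100, 200))
  lib[[2]]$source_id <- lib[[1]]$source_id
  expect_error(build_index(lib), "duplicate source_id")
  idx <- build_index(make_lib(runif(50, 100, 1000)))
  expect_length(idx$spectra, 50L)
})

test_that("an exact copy of a library spectrum is found at score 1", {
  repo <- shared_repo()
  idx <- shared_index()
  q <- repo$templates[[3]]
  q$source_id <- "q"
  m <- search_library(q, idx)
  expect_true(all(m$score >= 0.7 & m$n_matched >= 3))
  expect_true(any(m$score == 1))
  truth <- repo$truth[repo$truth$molecule == "molecule_03", ]
  expect_setequal(unique(m$file_id), truth$file_id)
})

test_that("exact-mode candidates respect the precursor window", {
  lib <- make_lib(c(500.03, 500.20))
  idx <- build_index(lib)
  q <- spec2(500.00, c(100, 150, 200.5), c(5, 10, 2), id = "q")
  m <- search_library(q, idx, search_params(min_cosine = 0, frag_tol = 0.05,
                                            min_matched_ions = 1))
  expect_equal(unique(m$ref_source_id), "f1#1")
})

test_that("analog search finds planted precursor-shifted analogs that exact misses", {
  repo <- shared_repo()
  idx <- shared_index()
  q <- repo$templates[[1]]
  q$source_id <- "q"
  tr <- repo$truth[repo$truth$molecule == "molecule_01", ]
  m_ex <- search_library(q, idx, search_params())
  m_an <- search_library(q, idx, search_params(analog = TRUE))
  expect_setequal(unique(m_ex$file_id),
                  tr$file_id[tr$type == "exact"])
  expect_setequal(unique(m_an$file_id), tr$file_id)
  analog_rows <- m_an[m_an$file_id %in% tr$file_id[tr$type == "analog"], ]
  expect_true(all(abs(abs(analog_rows$delta_mz) -
                        repo$spec$analog_shift) < 1e-6))
})

test_that("exact-mode results are a subset of analog-mode results", {
  repo <- shared_repo()
  idx <- shared_index()
  set.seed(77)
  queries <- c(repo$templates[1:4],
               lapply(1:4, function(i) rand_test_spectrum(8)))
  for (q in queries) {
    q$source_id <- "q"
    ex <- search_library(q, idx, search_params())
    an <- search_library(q, idx, search_params(analog = TRUE))
    expect_true(all(ex$ref_source_id %in% an$ref_source_id))
  }
})

test_that("indexed search equals brute-force scoring of the whole library", {
  repo <- shared_repo()
  idx <- shared_index()
  params <- search_params()
  brute <- function(q, analog = FALSE) {
    p <- search_params(analog = analog)
    rows <- lapply(seq_along(idx$spectra), function(i) {
      r <- idx$spectra[[i]]
      if (abs(q$precursor_mz - r$precursor_mz) >
          (if (analog) p$analog_window else p$precursor_tol)) return(NULL)
      sim <- modified_cosine(q, r, frag_tol = p$frag_tol,
                             allow_shift = analog)
      if (sim$score >= p$min_cosine && sim$n_matched >= p$min_matched_ions)
        data.frame(ref_source_id = idx$source_id[i], score = sim$score)
      else NULL
    })
    do.call(rbind, rows)
  }
  set.seed(99)
  queries <- c(repo$templates[c(2, 5)], list(rand_test_spectrum(8)))
  for (q in queries) {
    q$source_id <- "q"
    for (analog in c(FALSE, TRUE)) {
      got <- search_library(q, idx, search_params(analog = analog))
      want <- brute(q, analog)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_setequal(got$ref_source_id, want$ref_source_id)
        expect_equal(got$score[order(got$ref_source_id)],
                     want$score[order(want$ref_source_id)])
      }
    }
  }
})

test_that("raising thresholds never adds results; widening the window never removes", {
  repo <- shared_repo()
  idx <- shared_index()
  q <- repo$templates[[6]]
  q$source_id <- "q"
  base <- search_library(q, idx, search_params(min_cosine = 0.5,
                                               min_matched_ions = 1))
  stricter <- search_library(q, idx, search_params(min_cosine = 0.9,
                                                   min_matched_ions = 4))
  expect_true(all(stricter$ref_source_id %in% base$ref_source_id))
  narrow <- search_library(q, idx, search_params(precursor_tol = 0.01))
  wide <- search_library(q, idx, search_params(precursor_tol = 1))
  expect_true(all(narrow$ref_source_id %in% wide$ref_source_id))
})

test_that("search output is deterministically sorted and empty queries error", {
  repo <- shared_repo()
  idx <- shared_index()
  q <- repo$templates[[2]]
  q$source_id <- "q"
  m1 <- search_library(q, idx)
  m2 <- search_library(q, idx)
  expect_identical(m1, m2)
  expect_false(is.unsorted(rev(m1$score)))
  expect_error(search_library(spec2(100, numeric(), numeric()), idx),
               "no peaks")
})

test_that("batch search composes single searches and isolates failures", {
  repo <- shared_repo()
  idx <- shared_index()
  q1 <- repo$templates[[1]]; q1$source_id <- "q1"
  q2 <- repo$templates[[2]]; q2$source_id <- "q2"
  res <- batch_search(list(q1, q2), idx)
  expect_named(res$results, c("q1", "q2"))
  expect_equal(res$results$q1, search_library(q1, idx))
  expect_equal(res$results$q2, search_library(q2, idx))
  expect_equal(nrow(res$failures), 0L)
  # a bad USI fails alone; the rest of the batch is intact
  res2 <- batch_search(list(q1, "mzspec:NOPE:run:scan:1"), idx,
                       store = spectrum_store(character(), character(),
                                              character()))
  expect_equal(nrow(res2$failures), 1L)
  expect_match(res2$failures$query, "NOPE")
  expect_equal(res2$results$q1, search_library(q1, idx))
})

test_that("annotation search labels compounds and reacts to peak perturbation", {
  repo <- shared_repo()
  annots <- list(spectra = lapply(seq_along(repo$templates), function(i) {
    s <- repo$templates[[i]]
    s$source_id <- sprintf("CCMSLIB%07d#1", i)
    s
  }),
  accession = sprintf("CCMSLIB%07d", seq_along(repo$templates)),
  name = paste("compound", seq_along(repo$templates)))
  q <- repo$templates[[4]]
  q$source_id <- "q"
  hits <- annotate_against_reference_library(q, annots)
  expect_equal(hits$accession[1], "CCMSLIB0000004")
  expect_equal(hits$compound_name[1], "compound 4")
  expect_equal(hits$score[1], 1)
  # empty annotation library
  none <- annotate_against_reference_library(
    q, list(spectra = list(), accession = character(), name = character()))
  expect_equal(nrow(none), 0L)
  # perturbing one peak beyond frag_tol drops exactly one matched ion
  q2 <- q
  q2$peaks[2, "mz"] <- q2$peaks[2, "mz"] + 0.2
  q2 <- spec2(q$precursor_mz, q2$peaks[, "mz"], q2$peaks[, "intensity"],
              id = "q2")
  hits2 <- annotate_against_reference_library(
    q2, annots, search_params(min_cosine = 0))
  row <- hits2[hits2$accession == "CCMSLIB0000004", ]
  expect_equal(row$n_matched, hits$n_matched[1] - 1L)
})

test_that("parameter dump prints the standard defaults", {
  lines <- format_search_params()
  expect_identical(lines,
                   c("precursor_tol=0.05", "frag_tol=0.05",
                     "min_cosine=0.7", "min_matched_ions=3",
                     "analog=off", "analog_window=200"))
})
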