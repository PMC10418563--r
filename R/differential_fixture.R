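#' Generate a differential-analysis fixture with a planted funnel
#'
#' Emulates the two-study setup used to mine host-associated data for
#' microbial spectra: a first feature table contrasting colonized
#' (target, e.g. SPF) with control (e.g. germ-free) samples, a
#' molecular-network edge list, and a second study contrasting
#' antibiotics-treated with untreated animals. Memberships are planted
#' so the differential pipeline's funnel counts are known by
#' construction:
#' `n_total` consensus spectra, of which `n_unique` occur only in
#' target samples; `n_analog_removed` of those have a qualifying edge
#' (cosine > 0.7, |delta| <= 0.02) to a control spectrum; of the
#' survivors, `n_microbial` are copies of repository molecules, of
#' which `n_cell` are the host molecule also found in cell lines;
#' `n_overlap` of the remaining survivors recur in the second dataset
#' and `n_untreated_only` of those only in untreated samples. Decoy
#' edges failing exactly one of the two removal criteria are planted
#' too.
#'
#' @param repo A [make_repository()] result providing the reference
#'   library the microbial copies are drawn from.
#' @param seed RNG seed.
#' @param n_total,n_unique,n_analog_removed,n_microbial,n_cell,n_overlap,n_untreated_only
#'   Planted funnel sizes (see above); defaults 100, 40, 15, 12, 2,
#'   8, 6.
#' @param n_samples_per_condition Samples per condition in each study.
#' @return A list with `table`, `labels`, `spectra` (named list),
#'   `edges`, `second` (list of `spectra`, `table`, `labels`) and
#'   `truth` (planted id sets plus a `funnel` data frame).
#' @export
make_differential_fixture <- function(repo, seed = repo$spec$seed + 1L,
                                      n_total = 100L, n_unique = 40L,
                                      n_analog_removed = 15L,
                                      n_microbial = 12L, n_cell = 2L,
                                      n_overlap = 8L,
                                      n_untreated_only = 6L,
                                      n_samples_per_condition = 5L) {
  stopifnot(n_unique <= n_total,
            n_analog_removed <= n_unique,
            n_microbial <= n_unique - n_analog_removed,
            n_cell <= n_microbial,
            n_overlap <= n_microbial - n_cell,
            n_untreated_only <= n_overlap)
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_total))
  uniq_ids <- ids[seq_len(n_unique)]
  removed_ids <- uniq_ids[seq_len(n_analog_removed)]
  surv_ids <- setdiff(uniq_ids, removed_ids)
  microbial_ids <- surv_ids[seq_len(n_microbial)]
  cell_ids <- microbial_ids[seq_len(n_cell)]
  clean_ids <- setdiff(microbial_ids, cell_ids)
  overlap_ids <- clean_ids[seq_len(n_overlap)]
  untreated_ids <- overlap_ids[seq_len(n_untreated_only)]
  other_ids <- setdiff(ids, uniq_ids)

  if (length(clean_ids) > length(repo$templates))
    stop("need at least as many repository molecules as microbial, ",
         "non-cell-line ids (distinct templates avoid cross-matches)",
         call. = FALSE)
  spectra <- vector("list", n_total)
  names(spectra) <- ids
  k <- 0L
  for (id in ids) {
    if (id %in% cell_ids) {
      spectra[[id]] <- repo$host_template
    } else if (id %in% microbial_ids) {
      k <- k + 1L
      spectra[[id]] <- repo$templates[[names(repo$templates)[k]]]
    } else {
      spectra[[id]] <- rand_template()
    }
    spectra[[id]]$source_id <- id
  }

  target_samples <- sprintf("SPF_%d", seq_len(n_samples_per_condition))
  control_samples <- sprintf("GF_%d", seq_len(n_samples_per_condition))
  samples <- c(target_samples, control_samples)
  labels <- stats::setNames(rep(c("SPF", "GF"),
                                each = n_samples_per_condition), samples)
  tab <- matrix(0, n_total, length(samples),
                dimnames = list(ids, samples))
  present <- function(n_avail) sample.int(n_avail, sample.int(n_avail, 1))
  for (id in uniq_ids)
    tab[id, target_samples[present(n_samples_per_condition)]] <-
      stats::runif(1, 1e3, 1e6)
  # non-unique spectra: first chunk control-only (edge partners live
  # here), the rest present in both conditions
  n_control_only <- max(n_analog_removed, length(other_ids) %/% 3L)
  for (j in seq_along(other_ids)) {
    id <- other_ids[j]
    if (j <= n_control_only) {
      tab[id, control_samples[present(n_samples_per_condition)]] <-
        stats::runif(1, 1e3, 1e6)
    } else {
      tab[id, target_samples[present(n_samples_per_condition)]] <-
        stats::runif(1, 1e3, 1e6)
      tab[id, control_samples[present(n_samples_per_condition)]] <-
        stats::runif(1, 1e3, 1e6)
    }
  }
  table <- as.data.frame(tab)

  partners <- other_ids[seq_len(n_analog_removed)]
  edges <- data.frame(id1 = removed_ids, id2 = partners,
                      cosine = stats::runif(n_analog_removed, 0.75, 0.95),
                      delta_mz = stats::runif(n_analog_removed, -0.02, 0.02),
                      stringsAsFactors = FALSE)
  # decoy edges: one criterion fails each time, so neither may remove
  decoys <- data.frame(
    id1 = c(surv_ids[1], surv_ids[2]),
    id2 = c(partners[1], partners[2]),
    cosine = c(0.9, 0.5),
    delta_mz = c(0.5, 0.01),
    stringsAsFactors = FALSE)
  edges <- rbind(edges, decoys)

  t_samples <- sprintf("T_%d", seq_len(n_samples_per_condition))
  u_samples <- sprintf("U_%d", seq_len(n_samples_per_condition))
  labels2 <- stats::setNames(rep(c("treated", "untreated"),
                                 each = n_samples_per_condition),
                             c(t_samples, u_samples))
  n_extra2 <- 10L
  ids2 <- sprintf("X%03d", seq_len(n_overlap + n_extra2))
  spectra2 <- vector("list", length(ids2))
  names(spectra2) <- ids2
  tab2 <- matrix(0, length(ids2), 2L * n_samples_per_condition,
                 dimnames = list(ids2, c(t_samples, u_samples)))
  for (j in seq_len(n_overlap)) {
    id2 <- ids2[j]
    spectra2[[id2]] <- spectra[[overlap_ids[j]]]
    spectra2[[id2]]$source_id <- id2
    tab2[id2, u_samples[present(n_samples_per_condition)]] <-
      stats::runif(1, 1e3, 1e6)
    if (!overlap_ids[j] %in% untreated_ids)
      tab2[id2, t_samples[present(n_samples_per_condition)]] <-
        stats::runif(1, 1e3, 1e6)
  }
  for (j in (n_overlap + 1L):length(ids2)) {
    id2 <- ids2[j]
    spectra2[[id2]] <- rand_template()
    spectra2[[id2]]$source_id <- id2
    cols <- sample(colnames(tab2), sample.int(4L, 1))
    tab2[id2, cols] <- stats::runif(1, 1e3, 1e6)
  }

  truth <- list(
    unique = uniq_ids,
    after_analog_removal = surv_ids,
    microbial = microbial_ids,
    cell_line = cell_ids,
    non_cell_line = clean_ids,
    overlapping = overlap_ids,
    untreated_only = untreated_ids,
    funnel = data.frame(
      stage = c("condition_unique", "after_analog_removal",
                "microbial_matched", "non_cell_line",
                "overlapping_second", "untreated_only"),
      n = c(n_unique, length(surv_ids), n_microbial, length(clean_ids),
            n_overlap, n_untreated_only),
      stringsAsFactors = FALSE)
  )
  list(table = table, labels = labels, spectra = spectra, edges = edges,
       second = list(spectra = spectra2, table = as.data.frame(tab2),
                     labels = labels2),
       truth = truth)
}

#' Write a differential fixture to disk
#'
#' Feature table, condition labels, spectra MGF and edge list in the
#' TSV/MGF layout the command-line interface consumes; the second
#' dataset, when present, goes into a `second_` -prefixed set.
#'
#' @param fx A [make_differential_fixture()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_differential_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ft <- cbind(spectrum_id = rownames(fx$table), fx$table)
  wt(ft, "features.tsv")
  wt(data.frame(sample_id = names(fx$labels), condition = fx$labels),
     "labels.tsv")
  write_mgf(fx$spectra, file.path(dir, "spectra.mgf"))
  wt(fx$edges, "edges.tsv")
  if (!is.null(fx$second)) {
    ft2 <- cbind(spectrum_id = rownames(fx$second$table), fx$second$table)
    wt(ft2, "second_features.tsv")
    wt(data.frame(sample_id = names(fx$second$labels),
                  condition = fx$second$labels), "second_labels.tsv")
    write_mgf(fx$second$spectra, file.path(dir, "second_spectra.mgf"))
  }
  invisible(dir)
}
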