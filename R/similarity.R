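# weighting: "sqrt" (GNPS-style), "raw", or c(intensity_power, mz_power)
peak_weights <- function(s, weighting) {
  int <- s$peaks[, "intensity"]
  mz <- s$peaks[, "mz"]
  if (is.numeric(weighting)) {
    stopifnot(length(weighting) == 2L)
    return(int^weighting[1] * mz^weighting[2])
  }
  switch(weighting,
         sqrt = sqrt(int),
         raw = int,
         stop("unknown weighting: ", weighting, call. = FALSE))
}

#' Candidate fragment-ion pairs between two spectra
#'
#' Lists every query/reference peak pair eligible for the modified
#' cosine: direct pairs with `|mz_q - mz_r| <= frag_tol` plus, when
#' `allow_shift`, shifted pairs with `|mz_q - mz_r - delta| <= frag_tol`
#' where `delta` is the precursor m/z difference (query minus
#' reference). A pair satisfying both is reported once, as direct. Each
#' pair carries the product of the two peaks' weights.
#'
#' @param q,r Normalized [spectrum()] objects.
#' @param frag_tol Fragment mass tolerance in Th (absolute).
#' @param allow_shift Enable precursor-mass-shift (analog) pairing.
#' @param weighting Peak weighting applied before scoring: `"sqrt"`
#'   (square-root intensity, the default) or `"raw"` intensity.
#' @return A data frame with columns `q`, `r` (1-based peak indices),
#'   `shifted` (logical) and `weight`.
#' @export
candidate_pairs <- function(q, r, frag_tol = 0.05, allow_shift = FALSE,
                            weighting = "sqrt") {
  stopifnot(is_spectrum(q), is_spectrum(r), frag_tol > 0)
  delta <- q$precursor_mz - r$precursor_mz
  res <- cpp_candidate_pairs(q$peaks[, "mz"], peak_weights(q, weighting),
                             r$peaks[, "mz"], peak_weights(r, weighting),
                             frag_tol, delta, allow_shift)
  data.frame(q = res$q, r = res$r, shifted = res$shifted, weight = res$w)
}

# Exact maximum-weight one-to-one selection over a candidate pair list,
# by branch-and-bound over pairs sorted by descending weight. Intended
# for small spectra; used as the optimal-assignment scoring route.
exact_assignment <- function(pairs, nq, nr) {
  np <- nrow(pairs)
  if (!np) return(integer())
  o <- order(-pairs$weight, pairs$q, pairs$r)
  pairs <- pairs[o, , drop = FALSE]
  suffix <- rev(cumsum(rev(pairs$weight)))
  best <- new.env(parent = emptyenv())
  best$val <- -1
  best$sel <- integer()
  used_q <- logical(nq)
  used_r <- logical(nr)
  recurse <- function(k, acc, sel) {
    if (acc > best$val) {
      best$val <- acc
      best$sel <- sel
    }
    if (k > np) return()
    if (acc + suffix[k] <= best$val) return()
    for (i in k:np) {
      if (acc + suffix[i] <= best$val) break
      qi <- pairs$q[i]; ri <- pairs$r[i]
      if (used_q[qi] || used_r[ri]) next
      used_q[qi] <<- TRUE; used_r[ri] <<- TRUE
      recurse(i + 1L, acc + pairs$weight[i], c(sel, i))
      used_q[qi] <<- FALSE; used_r[ri] <<- FALSE
    }
  }
  recurse(1L, 0, integer())
  o[best$sel]
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' The modified cosine pairs fragment peaks either at equal m/z or
#' offset by the precursor mass difference, selects a one-to-one
#' assignment of peaks maximizing the summed pair weight, and normalizes
#' by the weight norms of the complete peak lists:
#' `score = sum(w_q * w_r over selected pairs) / (||w_q|| * ||w_r||)`.
#' A spectrum scored against itself gives exactly 1.
#'
#' Pair selection is greedy by descending pair weight with deterministic
#' tie-breaking (smaller query index, then smaller reference index) by
#' default — the convention of molecular-networking tools. An exact
#' branch-and-bound assignment solver is available via
#' `method = "exact"`; on typical spectra with a tight fragment
#' tolerance the two agree, and the exact route serves as a reference
#' in validation.
#'
#' @inheritParams candidate_pairs
#' @param method `"greedy"` (default) or `"exact"` pair selection.
#' @return A list of class `similarity_result` with `score` (in
#'   \[0, 1\]), `n_matched` (selected pair count), `delta_mz` (query
#'   minus reference precursor m/z) and `pairs` (data frame as in
#'   [candidate_pairs()], selected rows only).
#' @export
modified_cosine <- function(q, r, frag_tol = 0.05, allow_shift = FALSE,
                            weighting = "sqrt", method = c("greedy", "exact")) {
  stopifnot(is_spectrum(q), is_spectrum(r), frag_tol > 0)
  method <- match.arg(method)
  if (n_peaks(q) == 0L && n_peaks(r) == 0L)
    stop("modified cosine is undefined for two empty spectra", call. = FALSE)
  delta <- q$precursor_mz - r$precursor_mz
  wq <- peak_weights(q, weighting)
  wr <- peak_weights(r, weighting)
  norm <- sqrt(sum(wq^2)) * sqrt(sum(wr^2))
  if (method == "greedy") {
    res <- cpp_greedy_match(q$peaks[, "mz"], wq, r$peaks[, "mz"], wr,
                            frag_tol, delta, allow_shift)
    sel <- data.frame(q = res$q, r = res$r, shifted = res$shifted,
                      weight = res$w)
    total <- res$total
  } else {
    cand <- candidate_pairs(q, r, frag_tol, allow_shift, weighting)
    keep <- exact_assignment(cand, n_peaks(q), n_peaks(r))
    sel <- cand[keep, , drop = FALSE]
    rownames(sel) <- NULL
    total <- sum(sel$weight)
  }
  score <- if (norm > 0) min(1, total / norm) else 0
  structure(
    list(score = score, n_matched = nrow(sel), delta_mz = delta, pairs = sel),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> score %.4f, %d matched ions, delta m/z %+.4f\n",
              x$score, x$n_matched, x$delta_mz))
  invisible(x)
}

#' Write a mirror-plot table for a scored spectrum pair
#'
#' Emits a TSV of the aligned peaks of a query/reference pair, one row
#' per selected pair plus one row per unmatched peak of either spectrum,
#' for downstream mirror-plot rendering.
#'
#' @param q,r The two spectra.
#' @param result A `similarity_result` from [modified_cosine()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mirror_plot <- function(q, r, result, path) {
  pr <- result$pairs
  rows <- data.frame(mz_q = q$peaks[pr$q, "mz"],
                     int_q = q$peaks[pr$q, "intensity"],
                     mz_r = r$peaks[pr$r, "mz"],
                     int_r = r$peaks[pr$r, "intensity"],
                     pair_type = ifelse(pr$shifted, "shifted", "direct"))
  un_q <- setdiff(seq_len(n_peaks(q)), pr$q)
  if (length(un_q))
    rows <- rbind(rows, data.frame(mz_q = q$peaks[un_q, "mz"],
                                   int_q = q$peaks[un_q, "intensity"],
                                   mz_r = NA_real_, int_r = NA_real_,
                                   pair_type = "unmatched_query"))
  un_r <- setdiff(seq_len(n_peaks(r)), pr$r)
  if (length(un_r))
    rows <- rbind(rows, data.frame(mz_q = NA_real_, int_q = NA_real_,
                                   mz_r = r$peaks[un_r, "mz"],
                                   int_r = r$peaks[un_r, "intensity"],
                                   pair_type = "unmatched_reference"))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
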