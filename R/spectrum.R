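#' Construct an MS/MS spectrum
#'
#' A spectrum holds a precursor m/z, an optional charge and polarity, a
#' provenance string, and a peak list. Peaks are stored as a two-column
#' numeric matrix (`mz`, `intensity`) and are always kept sorted by
#' ascending m/z; intensities are kept raw at I/O time, any weighting is
#' applied inside scoring only.
#'
#' @param precursor_mz Precursor mass-to-charge ratio (Th); must be a
#'   single finite positive number.
#' @param mz Numeric vector of fragment m/z values (Th, all positive).
#' @param intensity Numeric vector of fragment intensities (arbitrary
#'   units, all non-negative), same length as `mz`.
#' @param charge Optional signed integer charge; `NA` if unknown.
#' @param source_id Opaque provenance string (typically file + scan).
#' @param polarity Optional ionization mode, `"positive"`, `"negative"`
#'   or `NA`.
#' @return An object of class `masst_spectrum`.
#' @export
spectrum <- function(precursor_mz, mz = numeric(), intensity = numeric(),
                     charge = NA_integer_, source_id = NA_character_,
                     polarity = NA_character_) {
  if (length(precursor_mz) != 1L || !is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a single finite positive number", call. = FALSE)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0))
      stop("all peak m/z values must be finite and positive", call. = FALSE)
    if (any(!is.finite(intensity)) || any(intensity < 0))
      stop("all peak intensities must be finite and non-negative", call. = FALSE)
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (!is.na(polarity) && !polarity %in% c("positive", "negative"))
    stop("polarity must be 'positive', 'negative' or NA", call. = FALSE)
  structure(
    list(
      precursor_mz = as.numeric(precursor_mz),
      charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
      peaks = cbind(mz = mz, intensity = intensity),
      source_id = as.character(source_id),
      polarity = polarity
    ),
    class = "masst_spectrum"
  )
}

#' @export
print.masst_spectrum <- function(x, ...) {
  cat(sprintf("<masst_spectrum> %s\n", x$source_id))
  cat(sprintf("  precursor m/z %.4f, charge %s, %d peaks\n",
              x$precursor_mz,
              if (is.na(x$charge)) "?" else x$charge,
              nrow(x$peaks)))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s A `masst_spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(s) nrow(s$peaks)

is_spectrum <- function(x) inherits(x, "masst_spectrum")

#' Clean a spectrum's peak list
#'
#' Merges peaks closer than `merge_tol` (intensities are summed; the
#' merged m/z is the intensity-weighted mean) and removes peaks in the
#' precursor region: anything above `precursor_mz - precursor_window`,
#' which takes out the residual precursor and its near losses (water,
#' ammonia). Either step can be disabled by passing 0 (merge) or `NA`
#' (precursor removal). The operation is idempotent.
#'
#' @param s A `masst_spectrum`.
#' @param merge_tol Peak merge tolerance in Th; 0 disables merging.
#' @param precursor_window Width in Th of the removed region below the
#'   precursor; peaks with `mz > precursor_mz - precursor_window` are
#'   dropped. `NA` disables precursor removal.
#' @return A cleaned `masst_spectrum` (possibly with zero peaks).
#' @export
normalize_spectrum <- function(s, merge_tol = 0.002, precursor_window = 17) {
  stopifnot(is_spectrum(s))
  mz <- s$peaks[, "mz"]
  int <- s$peaks[, "intensity"]
  if (length(mz) && !is.na(precursor_window)) {
    keep <- mz <= s$precursor_mz - precursor_window
    mz <- mz[keep]
    int <- int[keep]
  }
  if (merge_tol > 0) {
    # merge runs of adjacent peaks closer than merge_tol (peaks sorted);
    # iterate to a fixed point so the operation is idempotent even when
    # merged centroids drift within merge_tol of a neighbour
    while (length(mz) > 1L) {
      grp <- cumsum(c(1, diff(mz) > merge_tol))
      if (max(grp) == length(mz)) break
      wsum <- tapply(int, grp, sum)
      wmz <- tapply(mz * int, grp, sum)
      # zero-intensity groups fall back to the plain mean position
      mmz <- tapply(mz, grp, mean)
      mz <- as.numeric(ifelse(wsum > 0, wmz / wsum, mmz))
      int <- as.numeric(wsum)
    }
  }
  out <- s
  out$peaks <- cbind(mz = as.numeric(mz), intensity = as.numeric(int))
  out
}
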