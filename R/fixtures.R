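#' Specification of a synthetic reference repository
#'
#' Describes a deterministic, fully synthetic stand-in for a curated
#' monoculture repository: a small taxonomy (bacterial and fungal
#' genera with species underneath), files per species, spectra per
#' file, planted marker molecules with known producer taxa (two of
#' which also get analog variants — precursor and a random subset of
#' fragments shifted by a common delta), blank and QC files carrying
#' shared media/QC spectra, human cell-line files, and a noise model
#' (fragment m/z jitter, peak dropout, decoy peaks). The default is
#' noise-free so every planted occurrence is exactly recoverable; the
#' scale (about 200 files, about 2,000 spectra) keeps full validation
#' runs fast on one CPU.
#'
#' @param seed RNG seed; all outputs are deterministic given it.
#' @param n_genera Named integer vector, genera per domain
#'   (`bacteria`, `fungi`).
#' @param n_species_per_genus Species under each genus.
#' @param files_per_species Reference files per species.
#' @param spectra_per_file MS/MS scans per file.
#' @param n_molecules Number of planted marker molecules.
#' @param planted_fraction Fraction of a producer species' files that
#'   carry its molecule.
#' @param n_analog_molecules How many molecules also get planted
#'   analog variants (in additional producer files).
#' @param analog_shift Analog precursor delta in Th (default +14.0157,
#'   a methylene homolog).
#' @param n_blanks,n_qcs,n_cell_line_files Special file counts.
#' @param noise Named numeric vector `jitter_sd` (Th), `drop_prob`,
#'   `decoy_rate`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_genera = c(bacteria = 6L, fungi = 3L),
                         n_species_per_genus = 2L,
                         files_per_species = 10L,
                         spectra_per_file = 10L,
                         n_molecules = 10L,
                         planted_fraction = 0.5,
                         n_analog_molecules = 2L,
                         analog_shift = 14.0157,
                         n_blanks = 10L, n_qcs = 5L,
                         n_cell_line_files = 5L,
                         noise = c(jitter_sd = 0, drop_prob = 0,
                                   decoy_rate = 0)) {
  stopifnot(planted_fraction > 0, planted_fraction <= 1,
            noise[["jitter_sd"]] >= 0, noise[["jitter_sd"]] < 0.025,
            noise[["drop_prob"]] >= 0, noise[["drop_prob"]] <= 1,
            noise[["decoy_rate"]] >= 0)
  n_species <- sum(n_genera) * n_species_per_genus
  if (n_molecules > n_species)
    stop("more planted molecules than species to produce them",
         call. = FALSE)
  n_exact <- ceiling(planted_fraction * files_per_species)
  if (n_analog_molecules > 0 && n_exact + 2L > files_per_species)
    stop("no free producer files left for analog variants", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_genera = n_genera,
         n_species_per_genus = as.integer(n_species_per_genus),
         files_per_species = as.integer(files_per_species),
         spectra_per_file = as.integer(spectra_per_file),
         n_molecules = as.integer(n_molecules),
         planted_fraction = planted_fraction,
         n_analog_molecules = as.integer(n_analog_molecules),
         analog_shift = analog_shift,
         n_blanks = as.integer(n_blanks), n_qcs = as.integer(n_qcs),
         n_cell_line_files = as.integer(n_cell_line_files),
         noise = noise),
    class = "fixture_spec"
  )
}

rand_template <- function(precursor = stats::runif(1, 300, 1000),
                          n = sample(5:20, 1)) {
  mz <- sort(stats::runif(n, 50, precursor - 25))
  spectrum(precursor, mz, stats::runif(n, 10, 100))
}

apply_noise <- function(s, noise) {
  mz <- s$peaks[, "mz"]
  int <- s$peaks[, "intensity"]
  n <- length(mz)
  if (noise[["drop_prob"]] > 0 && n > 3L) {
    keep <- stats::runif(n) >= noise[["drop_prob"]]
    if (sum(keep) < 3L) keep[sample.int(n, 3L)] <- TRUE
    mz <- mz[keep]; int <- int[keep]
  }
  if (noise[["jitter_sd"]] > 0)
    mz <- mz + stats::rnorm(length(mz), 0, noise[["jitter_sd"]])
  if (noise[["decoy_rate"]] > 0) {
    extra <- stats::rpois(1, noise[["decoy_rate"]] * length(mz))
    if (extra > 0) {
      mz <- c(mz, stats::runif(extra, 50, s$precursor_mz - 25))
      int <- c(int, stats::runif(extra, 5, 30))
    }
  }
  spectrum(s$precursor_mz, mz, int, charge = s$charge,
           source_id = s$source_id, polarity = s$polarity)
}

analog_variant <- function(s, shift) {
  mz <- s$peaks[, "mz"]
  n <- length(mz)
  # shift a random subset of fragments (at least 2 shifted, 2 kept)
  sh <- stats::runif(n) < 0.5
  if (sum(sh) < 2L) sh[sample.int(n, 2L)] <- TRUE
  if (sum(!sh) < 2L) sh[sample(which(sh), 2L)] <- FALSE
  mz[sh] <- mz[sh] + shift
  spectrum(s$precursor_mz + shift, mz, s$peaks[, "intensity"])
}

#' Generate a synthetic reference repository with planted ground truth
#'
#' Builds the taxonomy, file metadata, lineage table, spectra and a
#' truth table recording every planted molecule occurrence. Each
#' planted molecule appears only in files of its producer species;
#' blanks share a media spectrum, QCs a QC-mix spectrum, and one "host"
#' molecule is planted in both a bacterial species and the human
#' cell-line files to exercise cell-line overlap detection. All
#' remaining scans are independent random decoy spectra.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `spectra` (list of [spectrum()], source ids
#'   `file_id#scan`), `records` (metadata data frame), `lineages`
#'   (named list), `fallback` (name-to-id map), `truth` (data frame:
#'   `molecule`, `file_id`, `scan`, `type`, `ncbi_id`), `templates`
#'   (named list of planted molecule spectra), `host_template`,
#'   `media_template`, `spec`.
#' @export
make_repository <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  next_id <- 100000L
  new_id <- function() {
    next_id <<- next_id + 1L
    next_id
  }
  lineages <- list()
  species <- data.frame(ncbi_id = integer(), name = character(),
                        genus = character(), domain = character(),
                        stringsAsFactors = FALSE)
  for (dom in names(spec$n_genera)) {
    base <- domain_lineage(dom)
    for (g in seq_len(spec$n_genera[[dom]])) {
      phy_id <- new_id()
      fam_id <- new_id()
      gen_id <- new_id()
      gtag <- sprintf("%s_genus_%02d", substr(dom, 1, 1), g)
      head <- rbind(base,
                    data.frame(rank = c("phylum", "family", "genus"),
                               name = c(sprintf("%s_phylum_%02d",
                                                substr(dom, 1, 1),
                                                (g - 1L) %/% 3L + 1L),
                                        sprintf("%s_family_%02d",
                                                substr(dom, 1, 1), g),
                                        gtag),
                               ncbi_id = c(phy_id, fam_id, gen_id),
                               stringsAsFactors = FALSE))
      for (s in seq_len(spec$n_species_per_genus)) {
        sp_id <- new_id()
        sp_name <- sprintf("%s species %d", gtag, s)
        lineages[[as.character(sp_id)]] <-
          rbind(head, data.frame(rank = "species", name = sp_name,
                                 ncbi_id = sp_id, stringsAsFactors = FALSE))
        species[nrow(species) + 1L, ] <- list(sp_id, sp_name, gtag, dom)
      }
    }
  }
  lineages[["9606"]] <- data.frame(
    rank = c("domain", "kingdom", "species"),
    name = c("Eukaryota", "Metazoa", "Homo sapiens"),
    ncbi_id = c(2759L, 33208L, 9606L), stringsAsFactors = FALSE)
  fallback <- stats::setNames(species$ncbi_id, species$name)

  # phylum ids repeat within a domain every 3 genera: regenerate heads
  # consistently by collapsing duplicate phylum names to one id
  lineages <- harmonize_lineages(lineages)

  templates <- lapply(seq_len(spec$n_molecules), function(i) rand_template())
  names(templates) <- sprintf("molecule_%02d", seq_len(spec$n_molecules))
  producer <- species$ncbi_id[seq_len(spec$n_molecules)]
  names(producer) <- names(templates)
  host_template <- rand_template()
  media_template <- rand_template()
  qc_template <- rand_template()
  host_producer <- species$ncbi_id[spec$n_molecules %% nrow(species) + 1L]

  records <- data.frame(massive_path = character(), file_id = character(),
                        dataset_id = character(),
                        taxon_name_submitted = character(),
                        taxon_name_alternative = character(),
                        ncbi_id = integer(), id_assignment = character(),
                        has_redu_metadata = logical(),
                        is_blank = logical(), is_qc = logical(),
                        stringsAsFactors = FALSE)
  add_record <- function(file_id, dataset_id, submitted, alternative,
                         ncbi_id, assignment = "automatic",
                         blank = FALSE, qc = FALSE) {
    records[nrow(records) + 1L, ] <<- list(
      paste0(dataset_id, "/peak/", file_id, ".mzML"), file_id, dataset_id,
      submitted, alternative, ncbi_id, assignment, TRUE, blank, qc)
  }

  spectra <- list()
  truth <- data.frame(molecule = character(), file_id = character(),
                      scan = integer(), type = character(),
                      ncbi_id = integer(), stringsAsFactors = FALSE)
  plant <- function(file_id, scan, s, molecule, type, ncbi_id) {
    s <- apply_noise(s, spec$noise)
    s$source_id <- sprintf("%s#%d", file_id, scan)
    spectra[[length(spectra) + 1L]] <<- s
    if (!is.null(molecule))
      truth[nrow(truth) + 1L, ] <<- list(molecule, file_id, scan, type,
                                         ncbi_id)
  }
  fill_file <- function(file_id, planted) {
    scan <- 0L
    for (p in planted) {
      scan <- scan + 1L
      plant(file_id, scan, p$s, p$molecule, p$type, p$ncbi_id)
    }
    while (scan < spec$spectra_per_file) {
      scan <- scan + 1L
      s <- rand_template()
      s$source_id <- sprintf("%s#%d", file_id, scan)
      spectra[[length(spectra) + 1L]] <<- s
    }
  }

  n_exact <- ceiling(spec$planted_fraction * spec$files_per_species)
  for (si in seq_len(nrow(species))) {
    sp <- species[si, ]
    dataset_id <- sprintf("MSV%06d", 100000L + si)
    mols <- names(producer)[producer == sp$ncbi_id]
    analog_mols <- intersect(mols, names(templates)[
      seq_len(spec$n_analog_molecules)])
    host_here <- sp$ncbi_id == host_producer
    for (k in seq_len(spec$files_per_species)) {
      file_id <- sprintf("%s_sp%02d_f%02d", dataset_id, si, k)
      planted <- list()
      for (m in mols) {
        if (k <= n_exact)
          planted <- c(planted, list(list(s = templates[[m]], molecule = m,
                                          type = "exact",
                                          ncbi_id = sp$ncbi_id)))
        else if (m %in% analog_mols && k <= n_exact + 2L)
          planted <- c(planted, list(list(
            s = analog_variant(templates[[m]], spec$analog_shift),
            molecule = m, type = "analog", ncbi_id = sp$ncbi_id)))
      }
      if (host_here && k <= n_exact)
        planted <- c(planted, list(list(s = host_template,
                                        molecule = "host_molecule",
                                        type = "exact",
                                        ncbi_id = sp$ncbi_id)))
      # one record exercises the closest-taxon name fallback
      if (si == 1L && k == 1L)
        add_record(file_id, dataset_id, paste(sp$name, "strain X"),
                   sp$name, NA_integer_, "manual")
      else
        add_record(file_id, dataset_id, sp$name, "", sp$ncbi_id)
      fill_file(file_id, planted)
    }
  }
  blank_ds <- "MSV200001"
  for (k in seq_len(spec$n_blanks)) {
    file_id <- sprintf("%s_blank_f%02d", blank_ds, k)
    add_record(file_id, blank_ds, "media blank", "", NA_integer_,
               blank = TRUE)
    fill_file(file_id, list(list(s = media_template, molecule = "media",
                                 type = "blank", ncbi_id = NA_integer_)))
  }
  qc_ds <- "MSV200002"
  for (k in seq_len(spec$n_qcs)) {
    file_id <- sprintf("%s_qc_f%02d", qc_ds, k)
    add_record(file_id, qc_ds, "QC mix", "", NA_integer_, qc = TRUE)
    fill_file(file_id, list(list(s = qc_template, molecule = "qc_mix",
                                 type = "qc", ncbi_id = NA_integer_)))
  }
  cell_ds <- "MSV200003"
  cell_names <- c("HeLa", "HEK293")
  for (k in seq_len(spec$n_cell_line_files)) {
    file_id <- sprintf("%s_cell_f%02d", cell_ds, k)
    add_record(file_id, cell_ds, cell_names[(k - 1L) %% 2L + 1L], "",
               NCBI_HOMO_SAPIENS, "manual")
    fill_file(file_id, list(list(s = host_template,
                                 molecule = "host_molecule",
                                 type = "exact", ncbi_id = NCBI_HOMO_SAPIENS)))
  }
  records <- validate_metadata(records)
  list(spectra = spectra, records = records, lineages = lineages,
       fallback = fallback, truth = truth, templates = templates,
       producer = producer, host_template = host_template,
       host_producer = host_producer, media_template = media_template,
       spec = spec)
}

# collapse taxa that share (rank, name) within a lineage set onto one id
harmonize_lineages <- function(lineages) {
  seen <- new.env(parent = emptyenv())
  for (key in names(lineages)) {
    lin <- lineages[[key]]
    for (j in seq_len(nrow(lin))) {
      k <- paste(lin$rank[j], lin$name[j], sep = "\r")
      if (is.null(seen[[k]])) seen[[k]] <- lin$ncbi_id[j]
      lin$ncbi_id[j] <- seen[[k]]
    }
    lineages[[key]] <- lin
  }
  lineages
}

#' Build the search index of a synthetic repository
#' @param repo A [make_repository()] result.
#' @return A [build_index()] object over all repository spectra.
#' @export
repository_index <- function(repo) {
  build_index(repo$spectra, records = repo$records)
}

#' Build the taxonomic tree of a synthetic repository
#' @param repo A [make_repository()] result.
#' @return A [build_taxon_tree()] object.
#' @export
repository_tree <- function(repo) {
  lin <- resolve_taxa(repo$records, repo$lineages, repo$fallback)
  build_taxon_tree(repo$records, lin)
}

#' Write a synthetic repository to disk
#'
#' One MGF per reference file under `dir/spectra/`, the metadata table
#' as `dir/metadata.csv`, and the lineage table as `dir/lineages.tsv`
#' — the on-disk layout the command-line interface consumes.
#'
#' @param repo A [make_repository()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_repository <- function(repo, dir) {
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE, recursive = TRUE)
  file_of <- sub("#[0-9]+$", "", vapply(repo$spectra,
                                        function(s) s$source_id,
                                        character(1)))
  for (fid in unique(file_of)) {
    write_mgf(repo$spectra[file_of == fid],
              file.path(spec_dir, paste0(fid, ".mgf")))
  }
  md <- repo$records
  utils::write.table(md, file.path(dir, "metadata.csv"), sep = ",",
                     quote = TRUE, row.names = FALSE, na = "")
  write_lineage_table(repo$lineages, file.path(dir, "lineages.tsv"))
  invisible(dir)
}
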