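#' The ten metadata columns of a reference file table
#' @keywords internal
METADATA_COLUMNS <- c("massive_path", "file_id", "dataset_id",
                      "taxon_name_submitted", "taxon_name_alternative",
                      "ncbi_id", "id_assignment", "has_redu_metadata",
                      "is_blank", "is_qc")

# Taxonomic ranks retained in the tree, coarse to fine. The domain /
# superkingdom level is kept as the anchor of the three domains of
# life; finer intermediate ranks (tribe, section, ...) are dropped and
# their files re-attach to the nearest kept ancestor.
KEPT_RANKS <- c("domain", "superkingdom", "kingdom", "phylum", "class",
                "order", "family", "genus", "subgenus", "species",
                "subspecies", "varietas", "strain")
RANK_LEVEL <- stats::setNames(
  c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11), KEPT_RANKS)
SPECIAL_RANKS <- c("root", "blank", "qc", "cell_line")
RANK_SORT <- c(root = -1, RANK_LEVEL, blank = 98, qc = 99, cell_line = 100)

NCBI_HOMO_SAPIENS <- 9606
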