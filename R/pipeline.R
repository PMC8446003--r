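#' Prepare a prey table for screening
#'
#' Applies the pre-network filters to one site-fraction series of the
#' general community table and returns the relative-abundance prey series:
#' OTUs must exceed `min_reads` summed reads over the series, gram-positive
#' prey are removed, and abundances are relativized to each sample's total
#' sequencing effort of the complete table (so filtering does not change
#' the denominators).
#'
#' @param table raw-counts `otu_tbl` for one site and fraction, with
#'   taxonomy attached.
#' @param min_reads series read threshold (strictly-greater filter).
#' @param taxonomy taxonomy tibble; defaults to the one attached to
#'   `table`.
#' @return relative-mode `otu_tbl` of surviving prey-candidate OTUs.
#' @export
prepare_prey_table <- function(table, min_reads = 10,
                               taxonomy = attr(table, "taxonomy")) {
  stop_if_not_otu(table)
  kept <- table %>%
    filter_min_reads(threshold = min_reads) %>%
    filter_gram_positive(taxonomy = taxonomy) %>%
    filter_guild("prey_candidate")
  rel <- relativize(table)
  restore_otu(filter(as_tibble(rel), .data$otu_id %in% unique(kept$otu_id)), rel)
}

#' Prepare a predator table for screening
#'
#' For a dedicated predator-amplicon pool: filters poorly represented
#' predator OTUs (`> min_reads` reads over the series) and relativizes
#' within the pool.
#'
#' @param table raw-counts `otu_tbl` of one predator pool (one site and
#'   fraction).
#' @param min_reads series read threshold.
#' @return relative-mode `otu_tbl` of surviving predator OTUs.
#' @export
prepare_predator_table <- function(table, min_reads = 10) {
  stop_if_not_otu(table)
  kept <- filter_min_reads(table, threshold = min_reads)
  rel <- relativize(table)
  restore_otu(filter(as_tibble(rel), .data$otu_id %in% unique(kept$otu_id)), rel)
}
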