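#' Read an OTU table from TSV files
#'
#' Counts are tab-separated with samples in rows: the header row holds OTU
#' ids, the first column sample ids. Metadata is keyed by `sample_id` with
#' columns `site`, `fraction`, `date` and optionally `temperature`.
#' Taxonomy is a two-column TSV (`otu_id`, semicolon-delimited SILVA-style
#' lineage); guilds are assigned from the order rank (Bdellovibrionales ->
#' `predator_bd`, Bacteriovoracales -> `predator_bx`, anything else ->
#' `prey_candidate`).
#'
#' @param counts_path,taxonomy_path,metadata_path file paths.
#' @return an `otu_tbl` in raw-counts mode with the parsed taxonomy attached
#'   as an attribute.
#' @export
read_otu_table <- function(counts_path, taxonomy_path, metadata_path) {
  raw <- readr::read_tsv(counts_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  sample_ids <- raw[[1]]
  check_unique(sample_ids, "sample")
  check_unique(names(raw)[-1], "OTU")
  counts <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1,
                   dimnames = list(sample_ids, names(raw)[-1]))
  for (j in seq_len(ncol(raw) - 1)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric count in %s at row %d, column '%s': '%s'",
                    counts_path, bad[1] + 1, names(raw)[j + 1], raw[[j + 1]][bad[1]]))
    }
    counts[, j] <- v
  }
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    sample_id = readr::col_character(), site = readr::col_character(),
    fraction = readr::col_character(), date = readr::col_date(),
    .default = readr::col_double()), progress = FALSE)
  taxonomy <- read_taxonomy(taxonomy_path)
  guilds <- assign_guilds(taxonomy)
  otu_table(counts, meta, guilds = guilds, taxonomy = taxonomy, mode = "raw_counts")
}

#' Read a two-column taxonomy TSV
#'
#' @param path TSV with columns `otu_id` and `lineage` (semicolon-delimited
#'   ranks, domain first). Unnamed ranks are filled as `"unclassified"`.
#' @return tibble with columns `otu_id`, `lineage`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  names(tx)[1:2] <- c("otu_id", "lineage")
  check_unique(tx$otu_id, "OTU")
  parse_taxonomy(tx$lineage, tx$otu_id)
}

#' Parse semicolon-delimited lineages into rank columns
#'
#' @param lineage character vector of SILVA-style lineages
#'   (`"Bacteria;Proteobacteria;...;Genus"`).
#' @param otu_id OTU ids, same length.
#' @return tibble with one row per OTU and rank columns domain..genus;
#'   missing ranks are `"unclassified"`.
#' @export
parse_taxonomy <- function(lineage, otu_id) {
  if (any(!nzchar(trimws(lineage)))) abort("empty lineage string")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("\\(\\d+\\)$", "", p)  # strip bootstrap confidences
    p[p == "" | is.na(p)] <- "unclassified"
    length(p) <- length(ranks)
    p[is.na(p)] <- "unclassified"
    p
  }, character(length(ranks))))
  colnames(mat) <- ranks
  dplyr::bind_cols(tibble(otu_id = otu_id, lineage = lineage), as_tibble(mat))
}

#' Assign predator/prey guilds from taxonomy
#'
#' @param taxonomy tibble from [read_taxonomy()] / [parse_taxonomy()].
#' @return named character vector otu_id -> guild.
#' @export
assign_guilds <- function(taxonomy) {
  guild <- dplyr::case_when(
    taxonomy$order == "Bdellovibrionales" ~ "predator_bd",
    taxonomy$order == "Bacteriovoracales" ~ "predator_bx",
    TRUE ~ "prey_candidate"
  )
  setNames(guild, taxonomy$otu_id)
}

#' Write an OTU table back to TSV files
#'
#' Inverse of [read_otu_table()]: a round trip reproduces the table.
#'
#' @param table an `otu_tbl`.
#' @param counts_path,taxonomy_path,metadata_path output paths
#'   (`taxonomy_path` may be `NULL` when no taxonomy is attached).
#' @return `table`, invisibly.
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path = NULL,
                            metadata_path) {
  stop_if_not_otu(table)
  m <- otu_matrix(table)
  readr::write_tsv(
    dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m)),
    counts_path, progress = FALSE)
  readr::write_tsv(sample_info(table), metadata_path, progress = FALSE)
  tx <- attr(table, "taxonomy")
  if (!is.null(taxonomy_path) && !is.null(tx)) {
    readr::write_tsv(tx[, c("otu_id", "lineage")], taxonomy_path, progress = FALSE)
  }
  invisible(table)
}
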