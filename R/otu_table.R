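#' Build an OTU table
#'
#' The universal currency of the pipeline: a long tidy tibble with one row
#' per (sample, OTU) cell, carrying the sample metadata (site, fraction,
#' sampling date, optional temperature) and the OTU guild alongside the
#' count. Guilds separate the two predatory clades, Bdellovibrionales
#' (`predator_bd`) and Bacteriovoracales (`predator_bx`), from candidate
#' gram-negative prey (`prey_candidate`).
#'
#' @param counts numeric matrix, samples in rows (rownames = sample ids),
#'   OTUs in columns (colnames = OTU ids); non-negative.
#' @param sample_meta data frame with columns `sample_id`, `site`,
#'   `fraction` (`"floc"` or `"liquor"`), `date` (ISO-8601 string or Date)
#'   and optionally `temperature` (deg C).
#' @param guilds named character vector mapping every OTU id to one of
#'   `"predator_bd"`, `"predator_bx"`, `"prey_candidate"`; or `NULL`, in
#'   which case all OTUs are prey candidates.
#' @param taxonomy optional taxonomy tibble (see [read_taxonomy()]); kept as
#'   an attribute and used by [filter_gram_positive()] and [assign_guilds()].
#' @param mode `"raw_counts"` or `"relative"`.
#' @return an `otu_tbl`: a tibble with columns `sample_id`, `otu_id`,
#'   `count`, `site`, `fraction`, `date`, `temperature`, `guild`, with
#'   attributes `mode` and (optionally) `taxonomy`.
#' @export
otu_table <- function(counts, sample_meta, guilds = NULL, taxonomy = NULL,
                      mode = c("raw_counts", "relative")) {
  mode <- match.arg(mode)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs sample ids as rownames and OTU ids as colnames")
  }
  sample_meta <- as_tibble(sample_meta)
  if (!"temperature" %in% names(sample_meta)) sample_meta$temperature <- NA_real_
  check_unique(rownames(counts), "sample")
  check_unique(colnames(counts), "OTU")
  check_unique(sample_meta$sample_id, "sample")
  missing <- setdiff(rownames(counts), sample_meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples present in counts but absent from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(guilds)) {
    guilds <- setNames(rep("prey_candidate", ncol(counts)), colnames(counts))
  }
  no_guild <- setdiff(colnames(counts), names(guilds))
  if (length(no_guild) > 0) {
    abort(paste0("OTUs without a guild label: ",
                 paste(head(no_guild, 5), collapse = ", ")))
  }
  bad <- setdiff(unique(guilds), c("predator_bd", "predator_bx", "prey_candidate"))
  if (length(bad) > 0) abort(paste0("unknown guild: ", paste(bad, collapse = ", ")))
  if (any(counts < 0)) abort("negative counts are not allowed")
  sample_meta$date <- as.Date(sample_meta$date)
  long <- tibble(
    sample_id = rep(rownames(counts), times = ncol(counts)),
    otu_id = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts)
  ) %>%
    left_join(sample_meta[, c("sample_id", "site", "fraction", "date", "temperature")],
              by = "sample_id") %>%
    mutate(guild = unname(guilds[.data$otu_id])) %>%
    arrange(.data$date, .data$sample_id, .data$otu_id)
  new_otu_tbl(long, mode = mode, taxonomy = taxonomy)
}

new_otu_tbl <- function(df, mode, taxonomy = NULL) {
  out <- as_tibble(df)
  attr(out, "mode") <- mode
  attr(out, "taxonomy") <- taxonomy
  class(out) <- c("otu_tbl", class(tibble()))
  out
}

#' Check OTU-table invariants
#'
#' Errors unless counts are non-negative, ids unique per cell, and — for a
#' complete relative-mode table — every sample sums to 1 within 1e-9.
#' Guild-subset tables of a relative table legitimately sum below 1 and are
#' validated with `complete = FALSE`.
#'
#' @param x an `otu_tbl`.
#' @param complete whether `x` is a complete community table.
#' @return `x`, invisibly.
#' @export
validate_otu_table <- function(x, complete = TRUE) {
  stop_if_not_otu(x)
  if (any(x$count < 0)) abort("negative counts")
  if (anyDuplicated(x[, c("sample_id", "otu_id")])) {
    abort("duplicated (sample, OTU) cells")
  }
  if (table_mode(x) == "relative" && complete) {
    tot <- tapply(x$count, x$sample_id, sum)
    if (any(abs(tot - 1) > 1e-9)) {
      abort("in relative mode every complete sample must sum to 1")
    }
  }
  invisible(x)
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicated ", what, " id: ", paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

# rebuild an otu_tbl after dplyr surgery, carrying attributes over
restore_otu <- function(df, template, mode = table_mode(template)) {
  new_otu_tbl(df, mode = mode, taxonomy = attr(template, "taxonomy"))
}

#' @export
print.otu_tbl <- function(x, ...) {
  cat("# OTU table (", table_mode(x), "): ",
      dplyr::n_distinct(x$sample_id), " samples x ",
      dplyr::n_distinct(x$otu_id), " OTUs\n", sep = "")
  NextMethod()
}

#' Table mode (`"raw_counts"` or `"relative"`)
#' @param x an `otu_tbl`.
#' @return a string.
#' @export
table_mode <- function(x) attr(x, "mode") %||% "raw_counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Samples-by-OTUs matrix view of an OTU table
#'
#' Rows are ordered by sampling date (ties broken by sample id), the sample
#' order every correlation in the pipeline relies on.
#'
#' @param x an `otu_tbl`.
#' @return numeric matrix, one row per sample in time order.
#' @export
otu_matrix <- function(x) {
  meta <- sample_info(x)
  otus <- sort(unique(x$otu_id))
  wide <- matrix(0, nrow = nrow(meta), ncol = length(otus),
                 dimnames = list(meta$sample_id, otus))
  wide[cbind(match(x$sample_id, meta$sample_id), match(x$otu_id, otus))] <- x$count
  wide
}

#' Per-sample metadata of an OTU table, in time order
#' @param x an `otu_tbl`.
#' @return tibble with one row per sample.
#' @export
sample_info <- function(x) {
  distinct(as_tibble(x)[, c("sample_id", "site", "fraction", "date", "temperature")]) %>%
    arrange(.data$date, .data$sample_id)
}

#' Per-OTU guild labels
#' @param x an `otu_tbl`.
#' @return tibble with columns `otu_id`, `guild`.
#' @export
otu_info <- function(x) {
  distinct(as_tibble(x)[, c("otu_id", "guild")]) %>% arrange(.data$otu_id)
}

#' Relativize counts to sampling effort
#'
#' Divides every count by its sample's total so each sample row sums to 1,
#' the form in which all downstream correlation and ordination operate.
#'
#' @param table an `otu_tbl` in raw-counts mode.
#' @return an `otu_tbl` in relative mode.
#' @export
relativize <- function(table) {
  stop_if_not_otu(table)
  if (table_mode(table) != "raw_counts") abort("input is already relative")
  tot <- tapply(table$count, table$sample_id, sum)
  zero <- names(tot)[tot <= 0]
  if (length(zero) > 0) {
    abort(paste0("samples with zero total reads cannot be relativized: ",
                 paste(zero, collapse = ", ")))
  }
  out <- as_tibble(table) %>%
    group_by(.data$sample_id) %>%
    mutate(count = .data$count / sum(.data$count)) %>%
    ungroup()
  restore_otu(out, table, mode = "relative")
}

#' Drop OTUs at or below a read-count threshold
#'
#' Retains OTUs whose reads summed over the full site-fraction time series
#' are strictly greater than `threshold` (default 10, i.e. "more than ten
#' reads"). Applied per series, so the table should already be restricted to
#' one site and fraction; set `per_sample = TRUE` for the stricter
#' per-sample variant.
#'
#' @param table an `otu_tbl` in raw-counts mode.
#' @param threshold read-count threshold; OTUs totalling exactly
#'   `threshold` reads are removed.
#' @param per_sample if `TRUE`, require `> threshold` reads in every sample
#'   rather than summed over the series.
#' @return filtered `otu_tbl`; the sample set is unchanged.
#' @export
filter_min_reads <- function(table, threshold = 10, per_sample = FALSE) {
  stop_if_not_otu(table)
  if (table_mode(table) != "raw_counts") {
    abort("the read filter is defined on raw counts, not relative abundances")
  }
  if (per_sample) {
    keep <- as_tibble(table) %>%
      group_by(.data$otu_id) %>%
      summarise(ok = all(.data$count > threshold)) %>%
      filter(.data$ok) %>%
      pull(.data$otu_id)
  } else {
    tot <- tapply(table$count, table$otu_id, sum)
    keep <- names(tot)[tot > threshold]
  }
  restore_otu(filter(as_tibble(table), .data$otu_id %in% keep), table)
}

#' Remove gram-positive prey candidates
#'
#' Obligate epibiotic/periplasmic predators of the Bdellovibrio-and-like
#' group attack gram-negative cells only, so prey candidates affiliated with
#' the gram-positive phyla Actinobacteria and Firmicutes are removed before
#' screening to limit spurious correlations. Predator OTUs are never
#' removed; prey with unresolved phylum are conservatively retained.
#'
#' @param table an `otu_tbl`.
#' @param taxonomy taxonomy tibble with columns `otu_id`, `phylum` (see
#'   [read_taxonomy()]); defaults to the taxonomy attached to `table`.
#' @param phyla character vector of phyla to remove.
#' @return filtered `otu_tbl`.
#' @export
filter_gram_positive <- function(table, taxonomy = attr(table, "taxonomy"),
                                 phyla = c("Actinobacteria", "Firmicutes")) {
  stop_if_not_otu(table)
  if (is.null(taxonomy)) abort("no taxonomy available; pass `taxonomy`")
  gram_pos <- taxonomy$otu_id[taxonomy$phylum %in% phyla]
  info <- otu_info(table)
  drop <- intersect(gram_pos, info$otu_id[info$guild == "prey_candidate"])
  restore_otu(filter(as_tibble(table), !.data$otu_id %in% drop), table)
}

#' Split an OTU table by metadata keys
#'
#' Partitions samples by site and/or fraction; each returned table keeps its
#' time ordering. Empty groups are never emitted.
#'
#' @param table an `otu_tbl`.
#' @param keys subset of `c("site", "fraction")`.
#' @return named list of `otu_tbl` (names like `"SH.floc"`).
#' @export
split_by_group <- function(table, keys = c("site", "fraction")) {
  stop_if_not_otu(table)
  if (!all(keys %in% c("site", "fraction"))) {
    abort("`keys` must be a subset of c(\"site\", \"fraction\")")
  }
  df <- as_tibble(table)
  key <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), restore_otu, template = table)
}

stop_if_not_otu <- function(x) {
  if (!inherits(x, "otu_tbl")) abort("expected an `otu_tbl` (see `otu_table()`)")
  invisible(x)
}

#' Keep only the given guilds
#' @param table an `otu_tbl`.
#' @param guilds guild labels to keep.
#' @return filtered `otu_tbl`.
#' @export
filter_guild <- function(table, guilds) {
  stop_if_not_otu(table)
  restore_otu(filter(as_tibble(table), .data$guild %in% guilds), table)
}
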