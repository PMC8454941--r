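# TSV/YAML input-output for all external formats. TSVs are tab-separated UTF-8
# with a header row; missing cells are errors, never silent zeros.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort_format(paste("file not found:", path))
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "", quote = "")
}

#' Read an OTU read-count table and its sample metadata
#'
#' The count TSV has OTUs as rows and samples as columns with the OTU id in the
#' first column (the common usearch `otutab` layout); a transposed dialect with
#' samples as rows is auto-detected when the first header cell is `sample_id`.
#' The sidecar metadata TSV maps `sample_id` to `site_id`, `replicate` and
#' `role`.
#'
#' @param path count-table TSV
#' @param meta_path sample-metadata TSV
#' @return a [read_count_matrix()] object
#' @export
read_count_tsv <- function(path, meta_path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2) abort_format("count table needs an id column plus at least one sample")
  id_col <- names(tab)[1]
  if (anyNA(tab)) {
    miss <- which(is.na(as.matrix(tab)), arr.ind = TRUE)[1, ]
    abort_format(sprintf("missing cell in count table at row %d, column '%s' (missing cells must be written as 0)",
                         miss[1], names(tab)[miss[2]]))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (identical(id_col, "sample_id")) m <- t(m)  # transposed dialect
  meta <- read_tsv_strict(meta_path)
  read_count_matrix(m, meta)
}

#' Write an OTU read-count table and sample metadata to TSV
#'
#' Inverse of [read_count_tsv()]; `read_count_tsv(write_count_tsv(x))` is
#' structurally identical to `x`.
#' @param x `ReadCountMatrix`
#' @param path,meta_path output TSV paths
#' @return `x`, invisibly
#' @export
write_count_tsv <- function(x, path, meta_path) {
  df <- data.frame(otu_id = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(x)
}

#' Read an indicator-taxon reference list
#'
#' Accepts the packaged TSV layout (columns `name`, `rank`, `phylum`,
#' `higher_group`, `gi_value`, `gi_min_abundance`) or a YAML file with an
#' `entries` list carrying the same fields.
#' @param path TSV or YAML file
#' @return an [indicator_list()] data.frame
#' @export
read_indicator_list <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    entries <- y$entries %||% y
    if (length(entries) == 0) return(indicator_list(empty_indicator_df()))
    df <- do.call(rbind, lapply(entries, function(e) {
      data.frame(name = e$name, rank = e$rank, phylum = e$phylum,
                 higher_group = e$higher_group %||% e$rank,
                 gi_value = e$gi_value %||% NA_integer_,
                 gi_min_abundance = e$gi_min_abundance %||% 3L,
                 stringsAsFactors = FALSE)
    }))
    return(indicator_list(df))
  }
  tab <- tryCatch(read_tsv_strict(path), error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) return(indicator_list(empty_indicator_df()))
  indicator_list(tab)
}

empty_indicator_df <- function() {
  data.frame(name = character(), rank = character(), phylum = character(),
             higher_group = character(), gi_value = integer(),
             gi_min_abundance = integer(), stringsAsFactors = FALSE)
}

#' The packaged 145-entry indicator reference
#'
#' A synthetic stand-in for the official Swiss IBCH indicator table: 145
#' freshwater macroinvertebrate indicator taxa (families, except Porifera,
#' Bryozoa and Cnidaria at phylum rank) with IBGN-style indicator-group values
#' and abundance minima. GI values and minima are editable defaults meant to be
#' replaced by the official table where available.
#' @return an [indicator_list()] with 145 entries
#' @export
default_indicator_list <- function() {
  read_indicator_list(system.file("extdata", "ibch_indicator_taxa_synthetic.tsv",
                                  package = "ednaIBCH", mustWork = TRUE))
}

#' Read an OTU taxonomy table
#'
#' TSV with `otu_id` plus the ranks `phylum`, `class`, `order`, `family`,
#' `genus`, `species` (blank = unassigned). The lowest assigned rank is
#' recomputed from the rank columns.
#' @param path TSV file
#' @return data.frame of class `TaxonomyAssignment`
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- read_tsv_strict(path)
  taxonomy_assignment(tab)
}

RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Validate a taxonomy table and derive the lowest assigned rank
#' @param df data.frame with `otu_id` and rank columns
#' @return data.frame of class `TaxonomyAssignment`
#' @export
taxonomy_assignment <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"otu_id" %in% names(df)) abort_validation("taxonomy needs an otu_id column")
  for (r in RANKS) if (!r %in% names(df)) df[[r]] <- NA_character_
  # consistent-prefix check: no rank assigned below an unassigned one
  rk <- as.matrix(df[, RANKS])
  assigned <- !is.na(rk) & rk != ""
  gap <- apply(assigned, 1L, function(a) {
    hi <- which(a)
    length(hi) > 0 && any(!a[seq_len(max(hi))])
  })
  if (any(gap))
    abort_validation(paste("taxonomy has a rank gap (e.g. species without genus) for OTU:",
                           df$otu_id[gap][1]))
  low <- apply(assigned, 1L, function(a) if (any(a)) RANKS[max(which(a))] else NA_character_)
  df$lowest_assigned_rank <- low
  class(df) <- c("TaxonomyAssignment", "data.frame")
  df
}

#' Link OTUs to indicator taxa
#'
#' An OTU maps to an indicator taxon when its annotation at that taxon's rank
#' (family, or phylum for the phylum-rank entries) equals the taxon name.
#' @param tax `TaxonomyAssignment`
#' @param indicators `IndicatorList`
#' @return `tax` with an `indicator_taxon` column (NA for non-target OTUs)
#' @export
assign_indicators <- function(tax, indicators) {
  fam_ind <- indicators$name[indicators$rank == "family"]
  phy_ind <- indicators$name[indicators$rank == "phylum"]
  it <- ifelse(!is.na(tax$family) & tax$family %in% fam_ind, tax$family,
        ifelse(!is.na(tax$phylum) & tax$phylum %in% phy_ind, tax$phylum,
               NA_character_))
  tax$indicator_taxon <- it
  tax
}

#' Read kick-net communities from a long-format TSV
#'
#' Columns `site_id`, `taxon`, `count`; one community per site. Taxa are
#' validated against the indicator list; unknown taxa are an error listing the
#' offending rows.
#' @param path TSV file
#' @param indicators `IndicatorList`
#' @return named list of [kicknet_community()] objects, one per site
#' @export
read_kicknet_tsv <- function(path, indicators) {
  tab <- read_tsv_strict(path)
  need <- c("site_id", "taxon", "count")
  if (!all(need %in% names(tab)))
    abort_format(paste("kick-net TSV needs columns:", paste(need, collapse = ", ")))
  unknown <- !(tab$taxon %in% indicators$name)
  if (any(unknown))
    abort_validation(paste("unknown indicator taxa in kick-net rows:",
                           paste(which(unknown), collapse = ", "),
                           "(", paste(unique(tab$taxon[unknown]), collapse = ", "), ")"))
  out <- lapply(split(tab, tab$site_id), function(d)
    kicknet_community(d$site_id[1], stats::setNames(d$count, d$taxon), indicators))
  out[unique(tab$site_id)]
}

#' Write kick-net communities to a long-format TSV
#' @param communities list of `KicknetCommunity`
#' @param path output TSV
#' @return `communities`, invisibly
#' @export
write_kicknet_tsv <- function(communities, path) {
  rows <- do.call(rbind, lapply(communities, function(cm) {
    if (length(cm$counts) == 0) return(NULL)
    data.frame(site_id = cm$site_id, taxon = names(cm$counts),
               count = unname(cm$counts), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(communities)
}
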