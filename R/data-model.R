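#' Construct a replicated OTU read-count matrix
#'
#' The central eDNA container: an OTU x sample matrix of sequencing read counts
#' together with per-sample metadata. Field samples carry a site identifier and
#' a replicate index (filter replicates within a site); negative and positive
#' controls carry neither.
#'
#' @param counts integer matrix, OTUs as rows and samples as columns, with
#'   dimnames giving OTU and sample identifiers.
#' @param meta data.frame with columns `sample_id`, `site_id`, `replicate`,
#'   `role` (one of `"field"`, `"negative_control"`, `"positive_control"`).
#'   `site_id`/`replicate` must be `NA` exactly for control samples.
#' @return object of class `ReadCountMatrix`
#' @export
read_count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_validation("count matrix must have OTU rownames and sample colnames")
  storage.mode(counts) <- "numeric"
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_format(sprintf(
      "counts must be non-negative integers; first offending cell: OTU '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_id", "replicate", "role")
  if (!all(need %in% names(meta)))
    abort_validation(paste("sample metadata must have columns:", paste(need, collapse = ", ")))
  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta) > 0)
    abort_validation(paste("samples missing from metadata:", paste(missing_meta, collapse = ", ")))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  ok_roles <- c("field", "negative_control", "positive_control")
  if (!all(meta$role %in% ok_roles))
    abort_validation(paste("sample role must be one of:", paste(ok_roles, collapse = ", ")))
  fld <- meta$role == "field"
  if (!any(fld)) abort_validation("at least one field sample is required")
  if (anyNA(meta$site_id[fld]) || anyNA(meta$replicate[fld]))
    abort_validation("every field sample needs site_id and replicate")
  key <- paste(meta$site_id[fld], meta$replicate[fld])
  if (anyDuplicated(key))
    abort_validation(paste("duplicate (site, replicate) among field samples:",
                           key[duplicated(key)][1]))
  meta$replicate <- as.integer(meta$replicate)
  structure(list(counts = counts, meta = meta), class = "ReadCountMatrix")
}

#' @export
print.ReadCountMatrix <- function(x, ...) {
  tab <- table(x$meta$role)
  cat(sprintf("ReadCountMatrix: %d OTUs x %d samples (%d field, %d neg ctrl, %d pos ctrl), %d sites\n",
              nrow(x$counts), ncol(x$counts),
              tab["field"], tab["negative_control"] %ifna% 0L, tab["positive_control"] %ifna% 0L,
              length(unique(stats::na.omit(x$meta$site_id)))))
  invisible(x)
}
`%ifna%` <- function(a, b) if (is.na(a)) b else a

#' Identifiers of field samples for one site
#' @keywords internal
site_samples <- function(x, site) {
  x$meta$sample_id[x$meta$role == "field" & !is.na(x$meta$site_id) & x$meta$site_id == site]
}

#' Replicate-consistency filter configuration
#'
#' @param k minimum number of replicates an OTU must be detected in
#' @param n number of filter replicates per site in the design
#' @param threshold_strategy `"max_in_controls"` (per-OTU read subtraction of
#'   the maximum control count) or `"proportional"` (detection minimum from the
#'   control read fraction)
#' @param pooling how replicate reads are combined for retained OTUs
#' @param controls which control roles feed the thresholds
#' @param min_sample_depth field samples with fewer total reads are dropped
#'   before filtering (0 = keep all)
#' @return a `FilterConfig` list
#' @export
filter_config <- function(k = 2L, n = 4L,
                          threshold_strategy = c("max_in_controls", "proportional"),
                          pooling = c("sum", "mean"),
                          controls = c("both", "negative_only"),
                          min_sample_depth = 0L) {
  threshold_strategy <- match.arg(threshold_strategy)
  pooling <- match.arg(pooling)
  controls <- match.arg(controls)
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(k) || is.na(n) || k < 1L || k > n)
    abort_config(sprintf("replicate filter requires 1 <= k <= n, got k = %d, n = %d", k, n))
  structure(list(k = k, n = n, threshold_strategy = threshold_strategy,
                 pooling = pooling, controls = controls,
                 min_sample_depth = as.integer(min_sample_depth)),
            class = "FilterConfig")
}

#' Construct a site-level detection table
#'
#' Product of the replicate-collapsing step: per (site, OTU) a presence flag
#' and the pooled read count of that OTU over the site's replicates.
#' @param presence logical site x OTU matrix
#' @param pooled_reads integer site x OTU matrix
#' @param config the `FilterConfig` that produced the table (provenance)
#' @return object of class `SiteDetectionTable`
#' @export
site_detection_table <- function(presence, pooled_reads, config = NULL) {
  presence <- as.matrix(presence); pooled_reads <- as.matrix(pooled_reads)
  if (!identical(dim(presence), dim(pooled_reads)))
    abort_validation("presence and pooled_reads must have identical dimensions")
  if (any(presence & pooled_reads <= 0) || any(!presence & pooled_reads != 0))
    abort_validation("presence must hold exactly where pooled_reads > 0")
  structure(list(presence = presence,
                 pooled_reads = pooled_reads,
                 site_ids = rownames(presence),
                 otu_ids = colnames(presence),
                 config = config),
            class = "SiteDetectionTable")
}

#' @export
print.SiteDetectionTable <- function(x, ...) {
  cat(sprintf("SiteDetectionTable: %d sites x %d OTUs, %d detections\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Construct a kick-net community
#'
#' Specimen counts of indicator taxa at one site, as sorted and counted from a
#' standardized kick-net sample.
#' @param site_id site identifier
#' @param counts named integer vector, names are indicator-taxon names
#' @param indicators optional `IndicatorList`; when given, taxon names are
#'   validated against it
#' @return object of class `KicknetCommunity`
#' @export
kicknet_community <- function(site_id, counts, indicators = NULL) {
  if (length(counts) && is.null(names(counts)))
    abort_validation("kick-net counts must be named by indicator taxon")
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (anyNA(counts) || any(counts < 0))
    abort_validation(sprintf("kick-net counts for site '%s' must be non-negative integers", site_id))
  if (anyDuplicated(names(counts)))
    abort_validation(sprintf("duplicate taxon in kick-net counts for site '%s'", site_id))
  if (!is.null(indicators)) {
    unknown <- setdiff(names(counts), indicators$name)
    if (length(unknown) > 0)
      abort_validation(sprintf("site '%s': taxa not in the indicator list: %s",
                               site_id, paste(unknown, collapse = ", ")))
  }
  structure(list(site_id = site_id, counts = counts), class = "KicknetCommunity")
}

#' Validate an indicator reference list
#'
#' @param df data.frame with columns `name`, `rank`, `phylum`, `higher_group`,
#'   `gi_value` (1-9 or NA = variety only), `gi_min_abundance` (>= 1)
#' @return data.frame of class `IndicatorList`
#' @export
indicator_list <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("name", "rank", "phylum", "higher_group", "gi_value", "gi_min_abundance")
  if (!all(need %in% names(df)))
    abort_validation(paste("indicator list needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$name))
    abort_validation(paste("duplicate indicator taxon:", df$name[duplicated(df$name)][1]))
  if (nrow(df) > 0 && !all(df$rank %in% c("family", "phylum")))
    abort_validation("indicator rank must be 'family' or 'phylum'")
  df$gi_value <- suppressWarnings(as.integer(df$gi_value))
  if (any(!is.na(df$gi_value) & (df$gi_value < 1L | df$gi_value > 9L)))
    abort_validation("gi_value must be in 1..9 or missing")
  df$gi_min_abundance <- as.integer(df$gi_min_abundance)
  if (nrow(df) > 0 && (anyNA(df$gi_min_abundance) || any(df$gi_min_abundance < 1L)))
    abort_validation("gi_min_abundance must be an integer >= 1")
  class(df) <- c("IndicatorList", "data.frame")
  df
}
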