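# Data-cleaning cascade: control-based per-OTU read thresholds, k-of-n
# replicate consistency, replicate pooling, and taxonomic restriction.

#' Compute per-OTU contamination thresholds from control samples
#'
#' Two strategies, reflecting the two plausible readings of control-based
#' cleaning: `max_in_controls` takes the maximum read count of each OTU over
#' all control samples (later subtracted from every field sample);
#' `proportional` takes the OTU's control-read fraction of its total reads
#' (later used as a per-sample detection minimum).
#'
#' @param x `ReadCountMatrix`
#' @param strategy `"max_in_controls"` or `"proportional"`
#' @param controls `"both"` (negative and positive) or `"negative_only"`
#' @return data.frame of class `OtuThresholds` (otu_id, threshold) with the
#'   strategy attached as attribute
#' @export
compute_otu_thresholds <- function(x, strategy = c("max_in_controls", "proportional"),
                                   controls = c("both", "negative_only")) {
  strategy <- tryCatch(match.arg(strategy), error = function(e)
    abort_config(paste("unknown threshold strategy:", strategy[1])))
  controls <- match.arg(controls)
  roles <- if (controls == "both") c("negative_control", "positive_control") else "negative_control"
  ctrl <- x$counts[, x$meta$role %in% roles, drop = FALSE]
  thr <- if (ncol(ctrl) == 0) {
    rep(0, nrow(x$counts))
  } else if (strategy == "max_in_controls") {
    apply(ctrl, 1L, max)
  } else {
    tot <- rowSums(x$counts)
    ifelse(tot == 0, 0, rowSums(ctrl) / tot)
  }
  structure(data.frame(otu_id = rownames(x$counts), threshold = unname(thr),
                       stringsAsFactors = FALSE),
            strategy = strategy, class = c("OtuThresholds", "data.frame"))
}

#' Apply contamination thresholds to a read-count matrix
#'
#' Under `max_in_controls` the threshold is subtracted from every field count
#' (floored at zero); under `proportional` a field count is kept only when it
#' reaches the OTU's fraction of that sample's total reads. Control columns are
#' zeroed after use, so downstream steps see cleaned field data only.
#'
#' @param x `ReadCountMatrix`
#' @param thresholds `OtuThresholds` covering every OTU in `x`
#' @return cleaned `ReadCountMatrix`
#' @export
apply_thresholds <- function(x, thresholds) {
  miss <- setdiff(rownames(x$counts), thresholds$otu_id)
  if (length(miss) > 0)
    abort_validation(paste("OTUs missing from thresholds:", paste(utils::head(miss, 5), collapse = ", ")))
  thr <- thresholds$threshold[match(rownames(x$counts), thresholds$otu_id)]
  strategy <- attr(thresholds, "strategy")
  counts <- x$counts
  fld <- x$meta$role == "field"
  if (strategy == "max_in_controls") {
    counts[, fld] <- pmax(0L, counts[, fld, drop = FALSE] - as.integer(round(thr)))
  } else if (strategy == "proportional") {
    sample_tot <- colSums(counts[, fld, drop = FALSE])
    minreads <- outer(thr, sample_tot)                # fraction_o * sample total
    keep <- counts[, fld, drop = FALSE] >= minreads
    counts[, fld] <- counts[, fld, drop = FALSE] * keep
  } else abort_config(paste("unknown threshold strategy:", strategy))
  counts[, !fld] <- 0L
  storage.mode(counts) <- "integer"
  read_count_matrix(counts, x$meta)
}

#' Drop field samples below a minimum read depth
#' @param x `ReadCountMatrix`
#' @param min_depth minimum total reads for a field sample to be kept
#' @return `ReadCountMatrix` without the weak samples
#' @export
drop_weak_samples <- function(x, min_depth) {
  if (min_depth <= 0) return(x)
  fld <- x$meta$role == "field"
  weak <- fld & colSums(x$counts) < min_depth
  if (any(weak)) {
    message(sprintf("dropping %d field sample(s) below %d reads", sum(weak), min_depth))
    x <- read_count_matrix(x$counts[, !weak, drop = FALSE], x$meta[!weak, , drop = FALSE])
  }
  x
}

#' Collapse filter replicates into site-level detections (k-of-n filter)
#'
#' An OTU is detected at a site when it has a nonzero count in at least
#' `config$k` of the site's replicates; pooled reads are the sum (or mean) of
#' the replicate counts of detected OTUs. Sites with fewer than `k` replicates
#' available cannot satisfy the rule and are excluded with a warning.
#'
#' @param x thresholded `ReadCountMatrix`
#' @param config [filter_config()]
#' @return `SiteDetectionTable` (sites x OTUs)
#' @export
collapse_replicates <- function(x, config) {
  if (!inherits(config, "FilterConfig")) abort_config("config must be a FilterConfig")
  x <- drop_weak_samples(x, config$min_sample_depth)
  meta <- x$meta[x$meta$role == "field", , drop = FALSE]
  sites <- unique(meta$site_id)
  n_rep <- table(meta$site_id)[sites]
  if (any(n_rep > config$n))
    abort_config(sprintf("site '%s' has %d replicates, more than the design n = %d",
                         sites[which.max(n_rep)], max(n_rep), config$n))
  drop <- n_rep < config$k
  if (any(drop)) {
    warning(sprintf("excluding %d site(s) with fewer than k = %d replicates: %s",
                    sum(drop), config$k, paste(sites[drop], collapse = ", ")))
    sites <- sites[!drop]
  }
  if (length(sites) == 0) abort_validation("no site has enough replicates")
  otus <- rownames(x$counts)
  presence <- matrix(FALSE, length(sites), length(otus), dimnames = list(sites, otus))
  pooled <- matrix(0L, length(sites), length(otus), dimnames = list(sites, otus))
  for (s in sites) {
    cols <- meta$sample_id[meta$site_id == s]
    sub <- x$counts[, cols, drop = FALSE]
    det <- rowSums(sub > 0) >= config$k
    pool <- if (config$pooling == "sum") rowSums(sub) else round_half_up(rowMeans(sub))
    presence[s, ] <- det
    pooled[s, ] <- as.integer(det * pool)
  }
  site_detection_table(presence, pooled, config)
}

subset_otus <- function(table, keep) {
  site_detection_table(table$presence[, keep, drop = FALSE],
                       table$pooled_reads[, keep, drop = FALSE],
                       table$config)
}

#' Restrict a detection table to indicator-assigned OTUs
#'
#' Keeps exactly the OTUs linked to an indicator taxon (the taxonomic filter of
#' the monitoring framework).
#' @param table `SiteDetectionTable`
#' @param tax `TaxonomyAssignment`
#' @param indicators `IndicatorList`
#' @return filtered `SiteDetectionTable`
#' @export
restrict_to_indicators <- function(table, tax, indicators) {
  if (!"indicator_taxon" %in% names(tax)) tax <- assign_indicators(tax, indicators)
  it <- tax$indicator_taxon[match(table$otu_ids, tax$otu_id)]
  subset_otus(table, !is.na(it))
}

#' The five phyla surveyed by the macroinvertebrate assessment
#' @export
ASSESSED_PHYLA <- c("Arthropoda", "Cnidaria", "Porifera", "Bryozoa", "Mollusca")

#' Restrict a detection table to OTUs of selected phyla
#'
#' Retains OTUs whose phylum annotation is in `phyla`, regardless of any deeper
#' assignment — the taxonomy-free feature set for index prediction.
#' @param table `SiteDetectionTable`
#' @param tax `TaxonomyAssignment`
#' @param phyla character vector of phylum names
#' @return filtered `SiteDetectionTable`
#' @export
restrict_to_phyla <- function(table, tax, phyla = ASSESSED_PHYLA) {
  ph <- tax$phylum[match(table$otu_ids, tax$otu_id)]
  subset_otus(table, !is.na(ph) & ph %in% phyla)
}

#' Stringency profile of the replicate-consistency filter
#'
#' Recomputes the site collapse for every detection stringency k = 1..n and
#' reports the mean pooled read number and mean OTU number per site — the
#' filtering profile used to choose a working stringency.
#'
#' @param x thresholded `ReadCountMatrix`
#' @param n replicates per site in the design
#' @param pooling replicate pooling passed through to [collapse_replicates()]
#' @return data.frame with columns `k`, `mean_reads_per_site`,
#'   `mean_otus_per_site`; means are non-increasing in `k`
#' @export
stringency_profile <- function(x, n = 4L, pooling = "sum") {
  rows <- lapply(seq_len(n), function(k) {
    tab <- collapse_replicates(x, filter_config(k = k, n = n, pooling = pooling))
    data.frame(k = k,
               mean_reads_per_site = mean(rowSums(tab$pooled_reads)),
               mean_otus_per_site = mean(rowSums(tab$presence)))
  })
  do.call(rbind, rows)
}
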