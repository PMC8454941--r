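# Alpha- and gamma-diversity comparison between kick-net and eDNA detections of
# indicator taxa: per-site richness, richness regression, paired tests, and
# pooled composition profiles by higher group.

#' Per-site indicator richness from eDNA detections
#'
#' Counts distinct indicator taxa per site; OTU multiplicity is collapsed, so a
#' taxon represented by several retained OTUs counts once.
#' @param table `SiteDetectionTable` (restricted to indicator OTUs or not; only
#'   OTUs with an indicator link are counted)
#' @param tax `TaxonomyAssignment` with `indicator_taxon` column
#' @return named integer vector, one entry per site
#' @export
edna_site_richness <- function(table, tax) {
  if (!"indicator_taxon" %in% names(tax))
    abort_validation("taxonomy must carry indicator_taxon (run assign_indicators)")
  it <- tax$indicator_taxon[match(table$otu_ids, tax$otu_id)]
  vapply(seq_along(table$site_ids), function(i) {
    length(unique(stats::na.omit(it[table$presence[i, ]])))
  }, integer(1)) |> stats::setNames(table$site_ids)
}

#' Per-site indicator richness from kick-net communities
#' @param communities list of `KicknetCommunity`
#' @return named integer vector (taxa with count >= 1)
#' @export
kicknet_site_richness <- function(communities) {
  vapply(communities, function(cm) sum(cm$counts >= 1L), integer(1)) |>
    stats::setNames(vapply(communities, `[[`, character(1), "site_id"))
}

#' Paired per-site richness of both methods
#' @param table indicator-restricted `SiteDetectionTable`
#' @param tax `TaxonomyAssignment` with indicator links
#' @param communities list of `KicknetCommunity`
#' @return data.frame site_id, kicknet_richness, edna_richness (sites present
#'   in both inputs)
#' @export
richness_table <- function(table, tax, communities) {
  kn <- kicknet_site_richness(communities)
  ed <- edna_site_richness(table, tax)
  sites <- intersect(names(kn), names(ed))
  data.frame(site_id = sites,
             kicknet_richness = unname(kn[sites]),
             edna_richness = unname(ed[sites]),
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares summary of one richness vector on another
#'
#' @param x predictor vector
#' @param y response vector
#' @return list of class `RegressionSummary`: slope, intercept, r_squared,
#'   adj_r_squared, p_value (two-sided slope test), n
#' @export
richness_regression <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  if (length(x) < 3) abort_validation("regression needs at least 3 paired observations")
  if (stats::var(x) == 0) abort_validation("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 p_value = s$coefficients[2, 4],
                 n = length(x)),
            class = "RegressionSummary")
}

#' Paired test for a systematic richness difference between methods
#'
#' Two-sided paired test on kicknet - edna differences. With all differences
#' zero the test statistic is degenerate; that case is reported as p = 1 with a
#' warning.
#' @param kicknet,edna per-site richness vectors, paired by position
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"` (signed-rank)
#' @return list: statistic, p_value, mean_difference, method, n
#' @export
paired_richness_test <- function(kicknet, edna, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(kicknet) != length(edna)) abort_validation("vectors must have equal length")
  d <- kicknet - edna
  if (all(d == d[1]) && stats::sd(d) == 0 && d[1] == 0) {
    warning("all paired differences are zero; degenerate test reported as p = 1")
    return(list(statistic = 0, p_value = 1, mean_difference = 0,
                method = method, n = length(d)))
  }
  ht <- if (method == "t") stats::t.test(kicknet, edna, paired = TRUE) else
    stats::wilcox.test(kicknet, edna, paired = TRUE, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_difference = mean(d), method = method, n = length(d))
}

#' Pooled (gamma) composition profiles per indicator higher group
#'
#' eDNA proportions are pooled indicator reads of the group over total pooled
#' indicator reads; kick-net proportions are specimen counts of the group over
#' total specimens — both pooled over all sites, so each method's proportions
#' sum to one.
#'
#' @param table indicator-restricted `SiteDetectionTable`
#' @param tax `TaxonomyAssignment` with indicator links
#' @param communities list of `KicknetCommunity`
#' @param indicators `IndicatorList` (supplies the higher-group labels)
#' @return long data.frame: group, method (`"edna"`/`"kicknet"`), proportion
#' @export
composition_profiles <- function(table, tax, communities, indicators) {
  hg_of <- stats::setNames(indicators$higher_group, indicators$name)
  it <- tax$indicator_taxon[match(table$otu_ids, tax$otu_id)]
  keep <- !is.na(it)
  edna_reads <- colSums(table$pooled_reads[, keep, drop = FALSE])
  edna_by_grp <- tapply(edna_reads, hg_of[it[keep]], sum)
  kn_all <- unlist(lapply(communities, `[[`, "counts"))
  kn_by_grp <- tapply(unname(kn_all), hg_of[sub("^.*\\.", "", names(kn_all))], sum)
  if (sum(edna_by_grp) == 0 || sum(kn_by_grp, na.rm = TRUE) == 0)
    abort_validation("cannot form composition proportions from zero total reads/counts")
  groups <- sort(unique(c(names(edna_by_grp), names(kn_by_grp))))
  prop <- function(v) {
    out <- stats::setNames(rep(0, length(groups)), groups)
    out[names(v)] <- v / sum(v)
    out
  }
  data.frame(group = rep(groups, 2),
             method = rep(c("edna", "kicknet"), each = length(groups)),
             proportion = c(prop(edna_by_grp), prop(kn_by_grp[!is.na(kn_by_grp)])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank concordance of two composition profiles
#'
#' Dense ranks by descending proportion per method, plus Spearman's rho with
#' tie correction.
#' @param profiles long data.frame from [composition_profiles()] with exactly
#'   two methods over the same group universe
#' @return list: `table` (group, proportions and dense ranks per method),
#'   `rho`
#' @export
rank_concordance <- function(profiles) {
  methods <- unique(profiles$method)
  if (length(methods) != 2) abort_validation("rank concordance needs exactly two methods")
  wide <- merge(profiles[profiles$method == methods[1], c("group", "proportion")],
                profiles[profiles$method == methods[2], c("group", "proportion")],
                by = "group", suffixes = paste0("_", methods))
  dense_rank <- function(p) match(p, sort(unique(p), decreasing = TRUE))
  wide[[paste0("rank_", methods[1])]] <- dense_rank(wide[[2]])
  wide[[paste0("rank_", methods[2])]] <- dense_rank(wide[[3]])
  rho <- stats::cor(wide[[2]], wide[[3]], method = "spearman")
  list(table = wide, rho = rho)
}
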