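# IBCH macroinvertebrate biotic index: variety class (taxon richness) x
# indicator group (sensitivity of the best qualifying taxon) -> 0-20 score ->
# five ecological-state categories.

IBCH_CATEGORIES <- c("bad", "unsatisfactory", "moderate", "good", "very good")

#' IBCH scoring configuration
#'
#' The official Swiss lookup tables are not distributed with this package; the
#' default configuration is a documented, structurally faithful stand-in that
#' can be replaced wholesale: uniform-width variety bins (`ceiling(richness /
#' variety_bin_width)` capped at `max_variety_class`), a formula-generated
#' score table `min(GI + CV - 1, score_max)`, and equal-width category
#' quintiles of the 0-20 scale.
#'
#' @param variety_bin_width taxa per variety class (default 4)
#' @param max_variety_class cap on the variety class CV (default 14)
#' @param score_max top of the index scale (default 20)
#' @param score_table optional integer matrix (9 GI rows x CV columns)
#'   overriding the generated table; must be non-decreasing along both axes
#' @param category_bounds data.frame `label`, `lower`, `upper`: five ordered
#'   intervals partitioning `0..score_max`
#' @return an `IbchConfig` list
#' @export
ibch_config <- function(variety_bin_width = 4L, max_variety_class = 14L,
                        score_max = 20L, score_table = NULL,
                        category_bounds = NULL) {
  if (is.null(score_table)) {
    score_table <- outer(1:9, seq_len(max_variety_class),
                         function(gi, cv) pmin(gi + cv - 1L, score_max))
    dimnames(score_table) <- list(GI = 1:9, CV = seq_len(max_variety_class))
  }
  if (any(score_table < 0 | score_table > score_max))
    abort_config(sprintf("score table values must lie in 0..%d", score_max))
  if (any(apply(score_table, 1L, diff) < 0) || any(apply(score_table, 2L, diff) < 0))
    abort_config("score table must be non-decreasing along GI and CV")
  if (is.null(category_bounds)) {
    # near-equal quintiles of the scale; on 0-20: 0-4 / 5-8 / 9-12 / 13-16 / 17-20
    up <- if (score_max == 20L) c(4L, 8L, 12L, 16L, 20L) else
      round((1:5) * (score_max + 1) / 5) - 1
    category_bounds <- data.frame(label = IBCH_CATEGORIES,
                                  lower = c(0, utils::head(up, 4) + 1),
                                  upper = up)
  }
  if (nrow(category_bounds) != 5)
    abort_config("exactly five ecological-state categories are required")
  covered <- unlist(Map(seq, category_bounds$lower, category_bounds$upper))
  if (!identical(sort(covered), 0:score_max))
    abort_config("category bounds must partition the score range without gaps or overlap")
  structure(list(variety_bin_width = as.integer(variety_bin_width),
                 max_variety_class = as.integer(max_variety_class),
                 score_max = as.integer(score_max),
                 score_table = score_table,
                 category_bounds = category_bounds),
            class = "IbchConfig")
}

#' Variety class from indicator richness
#'
#' @param richness number of indicator taxa present (count >= 1); vectorized
#' @param config [ibch_config()]
#' @return integer CV in 1..max class, or 0 when richness is 0
#' @export
variety_class <- function(richness, config = ibch_config()) {
  if (any(richness < 0)) abort_validation("richness must be >= 0")
  as.integer(ifelse(richness == 0, 0L,
                    pmin(ceiling(richness / config$variety_bin_width),
                         config$max_variety_class)))
}

#' Indicator group of a community
#'
#' The GI is the highest indicator-group value among taxa whose specimen count
#' reaches their abundance minimum; 0 when no taxon qualifies.
#' @param community `KicknetCommunity`
#' @param indicators `IndicatorList`
#' @return integer GI in 0..9
#' @export
indicator_group <- function(community, indicators) {
  if (length(community$counts) == 0) return(0L)
  idx <- match(names(community$counts), indicators$name)
  if (anyNA(idx))
    abort_validation(paste("community taxa missing from indicator list:",
                           paste(names(community$counts)[is.na(idx)], collapse = ", ")))
  gi <- indicators$gi_value[idx]
  qualifies <- !is.na(gi) & community$counts >= indicators$gi_min_abundance[idx]
  if (!any(qualifies)) return(0L)
  as.integer(max(gi[qualifies]))
}

#' Score one kick-net community with the IBCH index
#'
#' @param community `KicknetCommunity`
#' @param config [ibch_config()]
#' @param indicators `IndicatorList`
#' @return one-row data.frame: site_id, richness, variety_class,
#'   indicator_group, score, category
#' @export
ibch_score <- function(community, config = ibch_config(),
                       indicators = default_indicator_list()) {
  richness <- sum(community$counts >= 1)
  cv <- variety_class(richness, config)
  gi <- indicator_group(community, indicators)
  score <- if (gi == 0L || cv == 0L) 0L else config$score_table[gi, cv]
  data.frame(site_id = community$site_id, richness = richness,
             variety_class = cv, indicator_group = gi,
             score = as.integer(score),
             category = classify_score(score, config),
             stringsAsFactors = FALSE)
}

#' Score every site of a kick-net survey
#' @param communities list of `KicknetCommunity`
#' @inheritParams ibch_score
#' @return data.frame with one row per site
#' @export
ibch_index <- function(communities, config = ibch_config(),
                       indicators = default_indicator_list()) {
  out <- do.call(rbind, lapply(communities, ibch_score, config = config,
                               indicators = indicators))
  rownames(out) <- NULL
  out
}

#' Map an index score to its ecological-state category
#'
#' @param score integer score(s) within the configured scale
#' @param config [ibch_config()]
#' @return character category label(s)
#' @export
classify_score <- function(score, config = ibch_config()) {
  if (any(score < 0 | score > config$score_max))
    abort_validation(sprintf("score outside 0..%d", config$score_max))
  b <- config$category_bounds
  b$label[findInterval(score, b$lower)]
}
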