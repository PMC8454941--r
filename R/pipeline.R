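# End-to-end orchestration: simulate -> filter -> score -> compare -> predict,
# under one global seed fanned out to per-stage seeds, producing a single
# serializable run report.

#' Assemble a full run configuration
#'
#' Validates all stage configurations up front, so an inconsistent setting
#' (e.g. k > n) fails before any computation.
#' @param seed global integer seed; per-stage seeds are derived from it
#' @param synthetic [synthetic_config()]; its seed is overridden by the
#'   derived simulate-stage seed
#' @param filter [filter_config()]
#' @param ibch [ibch_config()]
#' @param rf_grid optional hyperparameter grid data.frame; `NULL` uses the
#'   protocol defaults (mtry = n/3, node size 3, 500 trees) without tuning
#' @param prediction_scheme forest prediction scheme, see [rf_config()]
#' @param outdir optional output directory for stage TSV/JSON artifacts
#' @return a `RunConfig` list
#' @export
run_config <- function(seed, synthetic = NULL, filter = filter_config(),
                       ibch = ibch_config(), rf_grid = NULL,
                       prediction_scheme = "leave_one_out", outdir = NULL) {
  if (missing(seed) || is.null(seed)) abort_config("a global seed is required")
  if (is.null(synthetic))
    synthetic <- synthetic_config(seed = stage_seed(seed, "simulate"))
  if (!inherits(filter, "FilterConfig")) abort_config("filter must be a FilterConfig")
  if (!inherits(ibch, "IbchConfig")) abort_config("ibch must be an IbchConfig")
  structure(list(seed = as.integer(seed), synthetic = synthetic, filter = filter,
                 ibch = ibch, rf_grid = rf_grid,
                 prediction_scheme = prediction_scheme, outdir = outdir),
            class = "RunConfig")
}

#' Run the full assessment pipeline
#'
#' Stages, in order: generate the paired synthetic dataset; clean the eDNA
#' table (control thresholds, k-of-n replicate filter); score kick-net
#' communities with the IBCH index; compare alpha/gamma diversity between
#' methods; predict the index from OTU presence/absence with a leave-one-out
#' random forest and evaluate agreement (against the kick-net scores and
#' against the latent truth). Identical configuration and seed reproduce the
#' report exactly.
#'
#' @param config a [run_config()]
#' @return a `RunReport` list (serializable via [serialize_run_report()]);
#'   stage wall-clock times are attached as the `"timing"` attribute and per
#'   site predictions as the `"detail"` attribute
#' @export
run_all <- function(config) {
  if (!inherits(config, "RunConfig")) abort_config("config must be a RunConfig")
  timing <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  indicators <- default_indicator_list()

  syn <- config$synthetic
  syn$seed <- stage_seed(config$seed, "simulate")
  ds <- tick("simulate", generate_dataset(syn, indicators))

  thr <- compute_otu_thresholds(ds$reads, config$filter$threshold_strategy,
                                config$filter$controls)
  cleaned <- apply_thresholds(ds$reads, thr)
  detections <- tick("filter", collapse_replicates(cleaned, config$filter))
  message(sprintf("thresholds computed for %d OTUs (%d nonzero)",
                  nrow(thr), sum(thr$threshold > 0)))
  indicator_tab <- restrict_to_indicators(detections, ds$taxonomy, indicators)
  phyla_tab <- restrict_to_phyla(detections, ds$taxonomy)
  message(sprintf("OTUs retained: %d after replicate filter, %d in assessed phyla, %d indicator-assigned",
                  sum(colSums(detections$presence) > 0),
                  ncol(phyla_tab$presence), ncol(indicator_tab$presence)))

  ibch <- tick("ibch", ibch_index(ds$kicknet, config$ibch, indicators))

  div <- tick("diversity", {
    rt <- richness_table(indicator_tab, ds$taxonomy, ds$kicknet)
    comp <- composition_profiles(indicator_tab, ds$taxonomy, ds$kicknet, indicators)
    list(richness = rt,
         regression_edna_on_kicknet = richness_regression(rt$kicknet_richness, rt$edna_richness),
         regression_kicknet_on_edna = richness_regression(rt$edna_richness, rt$kicknet_richness),
         paired_test = paired_richness_test(rt$kicknet_richness, rt$edna_richness),
         composition = comp,
         concordance = rank_concordance(comp))
  })

  pred <- tick("predict", {
    feats <- build_presence_features(phyla_tab)
    rf_seed <- stage_seed(config$seed, "predict")
    cfg <- if (!is.null(config$rf_grid)) {
      tune_hyperparameters(feats, ibch$score, config$rf_grid, seed = rf_seed)
    } else rf_config(seed = rf_seed)
    cfg$prediction_scheme <- config$prediction_scheme
    obs <- ibch$score[match(rownames(feats), ibch$site_id)]
    p_obs <- predict_scores(feats, obs, cfg)
    truth_q <- ds$truth$quality[rownames(feats)]
    p_truth <- predict_scores(feats, truth_q, cfg)
    list(config = cfg, n_features = ncol(feats),
         vs_kicknet = evaluate_predictions(obs, p_obs, config$ibch),
         vs_truth = evaluate_predictions(truth_q, p_truth, config$ibch))
  })

  report <- structure(list(
    config = list(seed = config$seed,
                  n_sites = syn$n_sites, n_rep = syn$n_rep,
                  filter_k = config$filter$k, filter_n = config$filter$n,
                  threshold_strategy = config$filter$threshold_strategy,
                  prediction_scheme = config$prediction_scheme),
    stage_counts = list(
      samples_in = ncol(ds$reads$counts),
      field_samples = sum(ds$reads$meta$role == "field"),
      otus_in = nrow(ds$reads$counts),
      sites = nrow(detections$presence),
      otus_detected = sum(colSums(detections$presence) > 0),
      otus_assessed_phyla = ncol(phyla_tab$presence),
      otus_indicator = ncol(indicator_tab$presence),
      rf_features = pred$n_features,
      sites_scored = nrow(ibch)),
    richness = list(
      kicknet_mean = mean(div$richness$kicknet_richness),
      kicknet_range = range(div$richness$kicknet_richness),
      edna_mean = mean(div$richness$edna_richness),
      edna_range = range(div$richness$edna_richness),
      regression_edna_on_kicknet = unclass(div$regression_edna_on_kicknet),
      regression_kicknet_on_edna = unclass(div$regression_kicknet_on_edna),
      paired_test = div$paired_test),
    composition = div$composition,
    concordance_rho = div$concordance$rho,
    ibch = list(score_mean = mean(ibch$score), score_range = range(ibch$score),
                category_counts = as.list(table(factor(ibch$category,
                                                       config$ibch$category_bounds$label)))),
    prediction = list(
      ntrees = pred$config$ntrees,
      mtry = pred$config$mtry %||% "n_features/3",
      min_node_size = pred$config$min_node_size,
      vs_kicknet = evaluation_summary(pred$vs_kicknet),
      vs_truth = evaluation_summary(pred$vs_truth))),
    class = "RunReport")
  attr(report, "timing") <- timing
  attr(report, "detail") <- list(dataset = ds, detections = detections,
                                 indicator_tab = indicator_tab,
                                 phyla_tab = phyla_tab, ibch = ibch,
                                 diversity = div, prediction = pred)
  if (!is.null(config$outdir)) write_run_outputs(report, config$outdir)
  report
}

evaluation_summary <- function(ev) {
  list(adj_r_squared = ev$adj_r_squared, p_value = ev$p_value,
       kappa = ev$kappa, kappa_band = ev$kappa_band,
       pct_exact_category = ev$pct_exact_category,
       pct_within_one_category = ev$pct_within_one_category,
       deviation_histogram = as.list(ev$deviation_histogram))
}

#' Serialize a run report to canonical JSON
#'
#' Wall-clock timings and large per-site detail are attributes, not report
#' fields, so reports from identical configurations and seeds serialize to
#' byte-identical JSON.
#' @param report a `RunReport`
#' @return JSON string
#' @export
serialize_run_report <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_run_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(serialize_run_report(report), file.path(outdir, "run_report.json"))
  d <- attr(report, "detail")
  utils::write.table(d$ibch, file.path(outdir, "ibch_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$diversity$richness, file.path(outdir, "richness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$diversity$composition, file.path(outdir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$prediction$vs_kicknet$per_site,
                     file.path(outdir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
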