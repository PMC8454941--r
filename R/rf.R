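# Taxonomy-free index prediction: OTU presence/absence features -> random
# forest regression (ranger) with seeded grid search, iterative per-site
# prediction, and agreement evaluation (adjusted R^2, Cohen's kappa, category
# deviations).

#' Random-forest configuration
#'
#' Defaults follow the protocol used for the biotic-index prediction: 500
#' trees, minimum node size 3, and mtry = floor(n_features / 3) unless set
#' explicitly.
#' @param ntrees number of trees
#' @param mtry variables tried per split; `NULL` = floor(n_features / 3)
#' @param min_node_size minimal terminal node size
#' @param prediction_scheme `"leave_one_out"` (refit without each site, fully
#'   out-of-sample) or `"out_of_bag"` (single fit, per-site OOB mean)
#' @param seed mandatory integer seed
#' @return an `RfConfig` list
#' @export
rf_config <- function(ntrees = 500L, mtry = NULL, min_node_size = 3L,
                      prediction_scheme = c("leave_one_out", "out_of_bag"),
                      seed = NULL) {
  prediction_scheme <- tryCatch(match.arg(prediction_scheme), error = function(e)
    abort_config(paste("unknown prediction scheme:", prediction_scheme[1])))
  if (is.null(seed)) abort_config("an RNG seed is mandatory for forest fitting")
  if (ntrees < 1) abort_config("ntrees must be >= 1")
  structure(list(ntrees = as.integer(ntrees),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 prediction_scheme = prediction_scheme,
                 seed = as.integer(seed)),
            class = "RfConfig")
}

#' Binary presence/absence feature matrix from site detections
#'
#' Columns without variance across sites carry no information for the forest
#' and are dropped (count reported via `message`).
#' @param table `SiteDetectionTable`, typically restricted to the five
#'   assessed phyla
#' @return numeric site x OTU matrix with entries in \{0, 1\}
#' @export
build_presence_features <- function(table) {
  if (nrow(table$presence) < 2) abort_validation("need at least 2 sites to build features")
  feats <- table$presence * 1
  keep <- apply(feats, 2L, function(v) length(unique(v)) > 1)
  if (sum(!keep) > 0)
    message(sprintf("dropping %d zero-variance feature(s)", sum(!keep)))
  if (!any(keep)) abort_validation("no informative features")
  feats[, keep, drop = FALSE]
}

#' Default hyperparameter grid
#'
#' mtry candidates n/5, n/3, n/2 (so the protocol's optimum n/3 is inside the
#' grid), node sizes 3/5/10, 500 trees.
#' @param n_features number of feature columns
#' @return data.frame grid with columns mtry, min_node_size, ntrees
#' @export
default_rf_grid <- function(n_features) {
  expand.grid(mtry = unique(pmax(1L, floor(n_features / c(5, 3, 2)))),
              min_node_size = c(3L, 5L, 10L),
              ntrees = 500L)
}

#' Seeded grid search for forest hyperparameters
#'
#' Selects the grid cell minimizing 5-fold cross-validated RMSE; ties break
#' toward smaller mtry, then fewer trees, then smaller node size. Cells with
#' mtry exceeding the feature count are skipped with a warning.
#'
#' @param features binary site x OTU matrix
#' @param response numeric score vector (one per site)
#' @param grid data.frame with columns mtry, min_node_size, ntrees
#' @param seed integer seed governing fold assignment and tree growing
#' @param nfolds number of CV folds
#' @return an [rf_config()] with the selected values (leave-one-out scheme)
#' @export
tune_hyperparameters <- function(features, response, grid = default_rf_grid(ncol(features)),
                                 seed, nfolds = 5L) {
  if (nrow(grid) == 0) abort_config("hyperparameter grid is empty")
  valid <- grid$mtry <= ncol(features)
  if (any(!valid))
    warning(sprintf("skipping %d grid cell(s) with mtry > %d features",
                    sum(!valid), ncol(features)))
  grid <- grid[valid, , drop = FALSE]
  if (nrow(grid) == 0) abort_config("no valid grid cell (all mtry exceed the feature count)")
  n <- nrow(features)
  set.seed(seed)
  fold <- sample(rep(seq_len(nfolds), length.out = n))
  grid$cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    sq <- numeric(0)
    for (f in seq_len(nfolds)) {
      hold <- fold == f
      if (all(hold) || !any(hold)) next
      fit <- ranger::ranger(x = features[!hold, , drop = FALSE], y = response[!hold],
                            num.trees = grid$ntrees[g], mtry = grid$mtry[g],
                            min.node.size = grid$min_node_size[g],
                            seed = seed + f, num.threads = 1)
      pred <- stats::predict(fit, data = features[hold, , drop = FALSE])$predictions
      sq <- c(sq, (pred - response[hold])^2)
    }
    sqrt(mean(sq))
  }, numeric(1))
  best <- grid[order(grid$cv_rmse, grid$mtry, grid$ntrees, grid$min_node_size), ][1, ]
  cfg <- rf_config(ntrees = best$ntrees, mtry = best$mtry,
                   min_node_size = best$min_node_size, seed = seed)
  cfg$grid <- grid
  cfg
}

#' Iterative per-site prediction of the index score
#'
#' `leave_one_out`: for each site, a forest is fitted on the remaining sites
#' and predicts the held-out site — strictly out-of-sample. `out_of_bag`: one
#' forest, per-site OOB mean prediction. Predictions are continuous on the
#' score scale and, being averages of observed responses, never leave the
#' observed response range.
#'
#' @param features binary site x OTU matrix
#' @param response numeric score vector
#' @param config [rf_config()]
#' @return named numeric vector of predicted scores, one per site
#' @export
predict_scores <- function(features, response, config) {
  if (!inherits(config, "RfConfig")) abort_config("config must be an RfConfig")
  n <- nrow(features)
  if (length(response) != n) abort_validation("response length must match the site count")
  mtry <- config$mtry %||% max(1L, floor(ncol(features) / 3))
  if (mtry > ncol(features)) abort_config("mtry exceeds the number of features")
  preds <- if (config$prediction_scheme == "leave_one_out") {
    vapply(seq_len(n), function(i) {
      fit <- ranger::ranger(x = features[-i, , drop = FALSE], y = response[-i],
                            num.trees = config$ntrees, mtry = mtry,
                            min.node.size = config$min_node_size,
                            seed = config$seed + i, num.threads = 1)
      stats::predict(fit, data = features[i, , drop = FALSE])$predictions
    }, numeric(1))
  } else {
    fit <- ranger::ranger(x = features, y = response,
                          num.trees = config$ntrees, mtry = mtry,
                          min.node.size = config$min_node_size,
                          seed = config$seed, num.threads = 1)
    fit$predictions
  }
  stats::setNames(preds, rownames(features))
}

#' Cohen's kappa for two categorical labelings
#'
#' kappa = (p_o - p_e) / (1 - p_e) with observed agreement p_o and the
#' marginal-product expected agreement p_e. The degenerate case p_e = 1 (both
#' labelings constant and identical marginals) is defined as 1 when agreement
#' is perfect and 0 otherwise, with a warning.
#'
#' @param a,b equal-length category vectors over a shared label set
#' @return kappa in \[-1, 1\]
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) abort_validation("labelings must have equal length")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (1 - p_e < 1e-12) {
    warning("expected agreement is 1; kappa undefined, reporting 1 if agreement is perfect else 0")
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

KAPPA_BREAKS <- c(0.05, 0.20, 0.40, 0.55, 0.70, 0.85)
KAPPA_LABELS <- c("no agreement", "very poor", "poor", "fair", "good",
                  "very good", "excellent")

#' Verbal agreement band of a kappa value
#'
#' Bands: < 0.05 no agreement, 0.05-0.20 very poor, 0.20-0.40 poor, 0.40-0.55
#' fair, 0.55-0.70 good, 0.70-0.85 very good, 0.85-0.99 excellent (values in
#' \[0.99, 1) included), and exactly 1 perfect. Boundary values fall into the
#' lower band.
#' @param kappa numeric in \[-1, 1\]
#' @return band label
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1) abort_validation("kappa must lie in [-1, 1]")
  if (kappa == 1) return("perfect")
  KAPPA_LABELS[findInterval(kappa, KAPPA_BREAKS, left.open = TRUE) + 1L]
}

#' Evaluate predicted against observed index scores
#'
#' Fits the observed-on-predicted linear model (adjusted R^2, slope p-value),
#' maps both vectors to ecological-state categories (predictions rounded half
#' up to the nearest integer score first), and summarizes categorical
#' agreement: Cohen's kappa with its band, percent exact category matches,
#' percent within one category, and the signed category-deviation histogram.
#'
#' @param observed,predicted paired numeric score vectors
#' @param config [ibch_config()] supplying the category bounds
#' @return list of class `PredictionEvaluation`: `per_site` data.frame and the
#'   summary fields
#' @export
evaluate_predictions <- function(observed, predicted, config = ibch_config()) {
  if (length(observed) != length(predicted)) abort_validation("paired vectors required")
  if (length(observed) < 3) abort_validation("need at least 3 sites to evaluate")
  reg <- if (stats::var(predicted) == 0) {
    warning("constant predictions; regression fit undefined")
    list(adj_r_squared = NA_real_, p_value = NA_real_)
  } else richness_regression(predicted, observed)
  to_cat <- function(x) classify_score(
    pmin(pmax(round_half_up(x), 0L), config$score_max), config)
  obs_cat <- to_cat(observed)
  pred_cat <- to_cat(predicted)
  lev <- config$category_bounds$label
  dev <- match(pred_cat, lev) - match(obs_cat, lev)
  kap <- cohen_kappa(factor(obs_cat, lev), factor(pred_cat, lev))
  hist <- table(factor(dev, levels = sort(unique(c(0, dev))))) / length(dev) * 100
  structure(list(
    per_site = data.frame(observed = observed, predicted = predicted,
                          observed_category = obs_cat,
                          predicted_category = pred_cat,
                          category_deviation = dev,
                          stringsAsFactors = FALSE),
    adj_r_squared = reg$adj_r_squared,
    p_value = reg$p_value,
    kappa = kap,
    kappa_band = kappa_band(kap),
    pct_exact_category = mean(dev == 0) * 100,
    pct_within_one_category = mean(abs(dev) <= 1) * 100,
    deviation_histogram = hist,
    n = length(observed)),
    class = "PredictionEvaluation")
}

#' @export
print.PredictionEvaluation <- function(x, ...) {
  cat(sprintf(paste0("PredictionEvaluation over %d sites\n",
                     "  adj. R^2 = %.3f (p = %.3g)\n",
                     "  Cohen's kappa = %.3f (%s)\n",
                     "  exact category: %.1f%%; within one category: %.1f%%\n"),
              x$n, x$adj_r_squared, x$p_value, x$kappa, x$kappa_band,
              x$pct_exact_category, x$pct_within_one_category))
  invisible(x)
}
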