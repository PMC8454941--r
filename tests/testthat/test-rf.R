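make_features <- function(n_sites = 30, n_otu = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * n_otu, 1, 0.5) == 1, n_sites, n_otu,
              dimnames = list(sprintf("s%02d", 1:n_sites), sprintf("o%02d", 1:n_otu)))
  pooled <- matrix(0L, n_sites, n_otu, dimnames = dimnames(m))
  pooled[m] <- sample.int(100, sum(m), replace = TRUE)
  site_detection_table(m, pooled)
}

test_that("presence features are binary with uninformative columns dropped", {
  tab <- make_features()
  feats <- build_presence_features(tab)
  expect_true(all(feats %in% c(0, 1)))
  expect_lte(ncol(feats), ncol(tab$presence))
  expect_identical(feats["s01", "o01"], unname(tab$presence["s01", "o01"] * 1))

  allp <- site_detection_table(matrix(TRUE, 3, 2, dimnames = list(letters[1:3], c("x", "y"))),
                               matrix(5L, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))
  expect_error(suppressMessages(build_presence_features(allp)),
               "no informative features")
  one <- site_detection_table(matrix(c(TRUE), 1, 1, dimnames = list("a", "x")),
                              matrix(1L, 1, 1, dimnames = list("a", "x")))
  expect_error(build_presence_features(one), class = "ednaIBCH_validation_error")
})

test_that("grid search is deterministic, respects the grid, and skips invalid cells", {
  tab <- make_features(40, 15, seed = 2)
  feats <- build_presence_features(tab)
  set.seed(3)
  y <- 10 + 4 * feats[, 1] + rnorm(40, 0, 0.5)

  single <- data.frame(mtry = 4L, min_node_size = 5L, ntrees = 60L)
  cfg <- tune_hyperparameters(feats, y, single, seed = 7)
  expect_identical(cfg$mtry, 4L)
  expect_identical(cfg$min_node_size, 5L)
  expect_identical(cfg$ntrees, 60L)

  grid <- data.frame(mtry = c(3L, 5L, 99L), min_node_size = 3L, ntrees = 50L)
  expect_warning(cfg2 <- tune_hyperparameters(feats, y, grid, seed = 7), "mtry")
  expect_true(cfg2$mtry %in% c(3L, 5L))
  cfg3 <- suppressWarnings(tune_hyperparameters(feats, y, grid, seed = 7))
  expect_identical(cfg2$mtry, cfg3$mtry)
  expect_identical(cfg2$grid$cv_rmse, cfg3$grid$cv_rmse)

  allbad <- data.frame(mtry = 99L, min_node_size = 3L, ntrees = 50L)
  expect_error(suppressWarnings(tune_hyperparameters(feats, y, allbad, seed = 7)),
               class = "ednaIBCH_config_error")
})

test_that("cross-validated RMSE of pure noise approaches the response spread", {
  tab <- make_features(60, 20, seed = 4)
  feats <- build_presence_features(tab)
  set.seed(5)
  y <- rnorm(60, 12, 2)
  cfg <- tune_hyperparameters(feats, y, data.frame(mtry = 6L, min_node_size = 5L, ntrees = 200L),
                              seed = 11)
  expect_lt(abs(cfg$grid$cv_rmse[1] - sd(y)) / sd(y), 0.15)
})

test_that("leave-one-out predictions are seeded, bounded, and track strong signal", {
  tab <- make_features(50, 11, seed = 6)
  feats <- build_presence_features(tab)
  # response perfectly encoded by the first binary feature
  y <- c(8, 14)[feats[, 1] + 1]

  cfg <- rf_config(ntrees = 300, mtry = ncol(feats), seed = 21)
  p1 <- predict_scores(feats, y, cfg)
  p2 <- predict_scores(feats, y, cfg)
  expect_identical(p1, p2)
  expect_gte(mean(abs(p1 - y) <= 1.0), 0.9)
  expect_true(all(p1 >= min(y) & p1 <= max(y)))

  const <- predict_scores(feats, rep(13, 50), rf_config(ntrees = 50, seed = 1))
  expect_true(all(const == 13))

  oob <- predict_scores(feats, y, rf_config(ntrees = 300, mtry = ncol(feats),
                                            prediction_scheme = "out_of_bag", seed = 21))
  expect_gte(mean(abs(oob - y) <= 1.0), 0.9)
  expect_error(rf_config(prediction_scheme = "bogus"), class = "ednaIBCH_config_error")
})

test_that("Cohen's kappa matches the closed form and an independent library", {
  # p_o = 0.75, p_e = 0.5 -> kappa = 0.5, exactly
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B")), 0.5,
               tolerance = 1e-13)
  expect_equal(cohen_kappa(letters[1:5], letters[1:5]), 1)
  expect_error(cohen_kappa(1:3, 1:4), class = "ednaIBCH_validation_error")
  expect_warning(k <- cohen_kappa(rep("A", 4), rep("A", 4)), "undefined")
  expect_equal(k, 1)

  skip_if_not_installed("e1071")
  set.seed(12)
  for (i in 1:10) {
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(letters[1:4], 60, replace = TRUE)
    ref <- e1071::classAgreement(table(factor(a, letters[1:4]), factor(b, letters[1:4])))$kappa
    expect_equal(cohen_kappa(a, b), ref, tolerance = 1e-12)
  }
})

test_that("kappa is invariant under consistent relabeling", {
  set.seed(13)
  a <- sample(c("bad", "good", "very good"), 50, replace = TRUE)
  b <- sample(c("bad", "good", "very good"), 50, replace = TRUE)
  relab <- c(bad = "x", good = "y", `very good` = "z")
  expect_equal(cohen_kappa(a, b), cohen_kappa(relab[a], relab[b]))
})

test_that("kappa bands follow the published scale with boundaries in the lower band", {
  expect_identical(kappa_band(0.5), "fair")
  expect_identical(kappa_band(1), "perfect")
  expect_identical(kappa_band(0.02), "no agreement")
  expect_identical(kappa_band(0.05), "no agreement")
  expect_identical(kappa_band(0.20), "very poor")
  expect_identical(kappa_band(0.60), "good")
  expect_identical(kappa_band(0.995), "excellent")
  expect_identical(kappa_band(-0.3), "no agreement")
  expect_error(kappa_band(1.2), class = "ednaIBCH_validation_error")
})

test_that("prediction evaluation summarizes regression and category agreement", {
  obs <- c(6, 8, 11, 13, 15, 17, 9, 14)
  perfect <- evaluate_predictions(obs, obs)
  expect_equal(perfect$adj_r_squared, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$pct_exact_category, 100)
  expect_identical(perfect$kappa_band, "perfect")

  # shift every site one full category up: 0% exact, 100% within one
  obs2 <- c(5, 6, 7, 8, 10, 11)
  up <- obs2 + 4
  shifted <- evaluate_predictions(obs2, up)
  expect_equal(shifted$pct_exact_category, 0)
  expect_equal(shifted$pct_within_one_category, 100)
  expect_true(all(shifted$per_site$category_deviation == 1))
  expect_equal(sum(shifted$deviation_histogram), 100)

  expect_error(evaluate_predictions(1:2, 1:2), class = "ednaIBCH_validation_error")
})
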