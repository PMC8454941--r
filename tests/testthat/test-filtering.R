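toy_with_controls <- function() {
  m <- matrix(c(10, 12, 0, 8,  3, 5,
                4,  0,  0, 0,  0, 0,
                7,  9,  6, 11, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("o1", "o2", "o3"),
                              c("A_1", "A_2", "B_1", "B_2", "neg1", "pos1")))
  meta <- data.frame(sample_id = colnames(m),
                     site_id = c("A", "A", "B", "B", NA, NA),
                     replicate = c(1, 2, 1, 2, NA, NA),
                     role = c(rep("field", 4), "negative_control", "positive_control"))
  read_count_matrix(m, meta)
}

test_that("control thresholds: maximum over controls and control read fraction", {
  x <- toy_with_controls()
  thr <- compute_otu_thresholds(x, "max_in_controls")
  expect_equal(thr$threshold, c(5, 0, 0))   # o1 control reads {3,5} -> 5

  prop <- compute_otu_thresholds(x, "proportional")
  expect_equal(prop$threshold[1], 8 / 38)   # o1: controls 8 of 38 total
  expect_equal(prop$threshold[2], 0)

  neg_only <- compute_otu_thresholds(x, "max_in_controls", controls = "negative_only")
  expect_equal(neg_only$threshold, c(3, 0, 0))

  no_ctrl <- random_rcm(n_ctrl = 0)
  expect_true(all(compute_otu_thresholds(no_ctrl)$threshold == 0))

  expect_error(compute_otu_thresholds(x, "bogus"), class = "ednaIBCH_config_error")
})

test_that("threshold application subtracts (max) or gates (proportional) and zeroes controls", {
  x <- toy_with_controls()
  thr <- compute_otu_thresholds(x, "max_in_controls")
  y <- apply_thresholds(x, thr)
  expect_equal(unname(y$counts["o1", 1:4]), c(5L, 7L, 0L, 3L))  # minus 5, floored
  expect_equal(unname(y$counts["o3", 1:4]), c(7L, 9L, 6L, 11L)) # threshold 0: unchanged
  expect_true(all(y$counts[, 5:6] == 0))

  # hand-built proportional case: sample total 1000, fraction 0.1 -> cut at 100
  m <- matrix(c(120, 80, 880, 920, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), site_id = "A", replicate = 1:2,
                     role = "field")
  xp <- read_count_matrix(m, meta)
  pthr <- structure(data.frame(otu_id = c("t1", "t2", "t3"),
                               threshold = c(0.1, 0, 0)),
                    strategy = "proportional", class = c("OtuThresholds", "data.frame"))
  yp <- apply_thresholds(xp, pthr)
  expect_equal(unname(yp$counts["t1", ]), c(120L, 0L))  # 120 >= 100 kept; 80 < 100 dropped

  expect_error(apply_thresholds(x, thr[-1, ]), class = "ednaIBCH_validation_error")
})

test_that("thresholding never increases a field count", {
  set.seed(40)
  for (i in 1:20) {
    x <- random_rcm(n_ctrl = 2)
    fld <- x$meta$role == "field"
    for (strat in c("max_in_controls", "proportional")) {
      y <- apply_thresholds(x, compute_otu_thresholds(x, strat))
      expect_true(all(y$counts[, fld] <= x$counts[, fld]))
    }
  }
})

test_that("replicate collapse counts detections and pools reads as specified", {
  m <- matrix(c(0, 3, 7, 0), nrow = 1,
              dimnames = list("o1", c("A_1", "A_2", "A_3", "A_4")))
  meta <- data.frame(sample_id = colnames(m), site_id = "A", replicate = 1:4,
                     role = "field")
  x <- read_count_matrix(m, meta)
  t2 <- collapse_replicates(x, filter_config(k = 2, n = 4))
  expect_true(t2$presence["A", "o1"])
  expect_identical(t2$pooled_reads["A", "o1"], 10L)
  t3 <- collapse_replicates(x, filter_config(k = 3, n = 4))
  expect_false(t3$presence["A", "o1"])
  expect_identical(t3$pooled_reads["A", "o1"], 0L)
})

test_that("collapse matches the naive oracle and is nested across k", {
  set.seed(11)
  for (i in 1:25) {
    x <- random_rcm(n_otu = 8, n_site = 5, n_rep = 4)
    prev <- NULL
    for (k in 1:4) {
      got <- collapse_replicates(x, filter_config(k = k, n = 4))
      ref <- naive_collapse(x$counts, x$meta, k)
      expect_identical(got$presence, ref$presence)
      expect_identical(got$pooled_reads, ref$pooled)
      expect_true(all(got$pooled_reads[got$presence] > 0))
      expect_true(all(got$pooled_reads[!got$presence] == 0))
      if (!is.null(prev)) expect_true(all(prev$presence >= got$presence))
      prev <- got
    }
  }
})

test_that("sites without enough replicates are excluded with a warning", {
  x <- random_rcm(n_site = 3, n_rep = 4)
  keep <- !(x$meta$site_id %in% "st01" & x$meta$replicate > 1)
  y <- read_count_matrix(x$counts[, keep], x$meta[keep, ])
  expect_warning(tab <- collapse_replicates(y, filter_config(k = 2, n = 4)),
                 "st01")
  expect_identical(sort(rownames(tab$presence)), c("st02", "st03"))
  expect_error(filter_config(k = 5, n = 4), class = "ednaIBCH_config_error")
})

subset_table_to <- function(tab, otus) {
  site_detection_table(tab$presence[, otus, drop = FALSE],
                       tab$pooled_reads[, otus, drop = FALSE], tab$config)
}

test_that("taxonomic restriction keeps indicator OTUs and is idempotent", {
  ind <- default_indicator_list()
  tax <- taxonomy_assignment(data.frame(
    otu_id = c("o1", "o2", "o3"),
    phylum = c("Arthropoda", "Arthropoda", "Rotifera"),
    class = c("Insecta", "Insecta", NA),
    order = c("Ephemeroptera", "Diptera", NA),
    family = c("Baetidae", NA, NA), genus = NA, species = NA))
  presence <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 2, 3,
                     dimnames = list(c("A", "B"), c("o1", "o2", "o3")))
  pooled <- matrix(c(5L, 9L, 0L, 4L, 0L, 2L), 2, 3,
                   dimnames = dimnames(presence))
  tab <- site_detection_table(presence, pooled)

  r1 <- restrict_to_indicators(tab, tax, ind)
  expect_identical(r1$otu_ids, "o1")
  expect_identical(restrict_to_indicators(r1, tax, ind)$otu_ids, "o1")

  ph <- restrict_to_phyla(tab, tax)
  expect_setequal(ph$otu_ids, c("o1", "o2"))  # Rotifera out, family-less Arthropoda in
  expect_true(all(r1$otu_ids %in% ph$otu_ids))

  none <- restrict_to_indicators(subset_table_to(tab, "o3"), tax, ind)
  expect_identical(ncol(none$presence), 0L)
})

test_that("stringency profile is monotone and matches a hand-computed toy", {
  # one site, OTUs detected in 4, 2, and 1 of 4 replicates
  m <- matrix(c(2, 2, 2, 2,
                0, 3, 0, 3,
                5, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("A_", 1:4)))
  meta <- data.frame(sample_id = colnames(m), site_id = "A", replicate = 1:4,
                     role = "field")
  prof <- stringency_profile(read_count_matrix(m, meta), n = 4)
  expect_equal(prof$mean_otus_per_site, c(3, 2, 1, 1))
  expect_equal(prof$mean_reads_per_site, c(8 + 6 + 5, 8 + 6, 8, 8))

  set.seed(77)
  x <- random_rcm()
  p <- stringency_profile(x, n = 4)
  expect_true(all(diff(p$mean_otus_per_site) <= 0))
  expect_true(all(diff(p$mean_reads_per_site) <= 0))
  expect_equal(p$mean_otus_per_site[1],
               mean(rowSums(collapse_replicates(x, filter_config(1, 4))$presence)))
})
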