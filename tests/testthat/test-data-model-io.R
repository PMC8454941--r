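test_that("count table TSV round-trips and parses roles", {
  dir <- withr::local_tempdir()
  writeLines(c("otu_id\tA_1\tA_2\tneg1",
               "otu1\t5\t0\t1",
               "otu2\t2\t3\t0"), file.path(dir, "counts.tsv"))
  writeLines(c("sample_id\tsite_id\treplicate\trole",
               "A_1\tA\t1\tfield",
               "A_2\tA\t2\tfield",
               "neg1\t\t\tnegative_control"), file.path(dir, "meta.tsv"))
  x <- read_count_tsv(file.path(dir, "counts.tsv"), file.path(dir, "meta.tsv"))
  expect_identical(dim(x$counts), c(2L, 3L))
  expect_identical(x$meta$role, c("field", "field", "negative_control"))
  expect_identical(x$counts["otu1", "A_1"], 5L)

  write_count_tsv(x, file.path(dir, "c2.tsv"), file.path(dir, "m2.tsv"))
  y <- read_count_tsv(file.path(dir, "c2.tsv"), file.path(dir, "m2.tsv"))
  expect_identical(x$counts, y$counts)
  expect_identical(x$meta, y$meta)

  set.seed(1)
  z <- random_rcm(n_ctrl = 2)
  write_count_tsv(z, file.path(dir, "c3.tsv"), file.path(dir, "m3.tsv"))
  z2 <- read_count_tsv(file.path(dir, "c3.tsv"), file.path(dir, "m3.tsv"))
  expect_identical(z$counts, z2$counts)
})

test_that("malformed count input raises typed errors naming the offender", {
  dir <- withr::local_tempdir()
  writeLines(c("otu_id\tA_1\tA_2", "otu1\t5\t-1"), file.path(dir, "counts.tsv"))
  writeLines(c("sample_id\tsite_id\treplicate\trole",
               "A_1\tA\t1\tfield", "A_2\tA\t2\tfield"), file.path(dir, "meta.tsv"))
  err <- expect_error(
    read_count_tsv(file.path(dir, "counts.tsv"), file.path(dir, "meta.tsv")),
    class = "ednaIBCH_format_error")
  expect_match(conditionMessage(err), "otu1")
  expect_match(conditionMessage(err), "A_2")

  writeLines(c("otu_id\tA_1\tA_2", "otu1\t5\t"), file.path(dir, "gap.tsv"))
  expect_error(read_count_tsv(file.path(dir, "gap.tsv"), file.path(dir, "meta.tsv")),
               class = "ednaIBCH_format_error")

  writeLines(c("sample_id\tsite_id\treplicate\trole", "A_1\tA\t1\tfield"),
             file.path(dir, "meta_short.tsv"))
  writeLines(c("otu_id\tA_1\tA_2", "otu1\t5\t2"), file.path(dir, "ok.tsv"))
  expect_error(read_count_tsv(file.path(dir, "ok.tsv"), file.path(dir, "meta_short.tsv")),
               class = "ednaIBCH_validation_error")
})

test_that("field samples require unique site/replicate identity", {
  m <- matrix(1L, 1, 2, dimnames = list("o1", c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), site_id = "A",
                     replicate = 1L, role = "field")
  expect_error(read_count_matrix(m, meta), class = "ednaIBCH_validation_error")
  meta$replicate <- 1:2
  expect_s3_class(read_count_matrix(m, meta), "ReadCountMatrix")
})

test_that("packaged indicator reference loads with 145 validated entries", {
  ind <- default_indicator_list()
  expect_identical(nrow(ind), 145L)
  expect_true(all(ind$rank %in% c("family", "phylum")))
  expect_setequal(ind$name[ind$rank == "phylum"], c("Porifera", "Bryozoa", "Cnidaria"))
  expect_true(all(is.na(ind$gi_value) | (ind$gi_value >= 1 & ind$gi_value <= 9)))
})

test_that("indicator list rejects duplicates and bad ranks, accepts empty", {
  ind <- default_indicator_list()
  dup <- rbind(ind, ind[ind$name == "Baetidae", ])
  expect_error(indicator_list(dup), class = "ednaIBCH_validation_error")
  bad <- ind; bad$rank[1] <- "genus"
  expect_error(indicator_list(bad), class = "ednaIBCH_validation_error")

  dir <- withr::local_tempdir()
  file.create(file.path(dir, "empty.tsv"))
  expect_identical(nrow(read_indicator_list(file.path(dir, "empty.tsv"))), 0L)
})

test_that("indicator list reads from YAML", {
  dir <- withr::local_tempdir()
  writeLines(c("entries:",
               "  - {name: Baetidae, rank: family, phylum: Arthropoda, higher_group: Ephemeroptera, gi_value: 2, gi_min_abundance: 10}",
               "  - {name: Porifera, rank: phylum, phylum: Porifera, higher_group: Porifera}"),
             file.path(dir, "ind.yaml"))
  ind <- read_indicator_list(file.path(dir, "ind.yaml"))
  expect_identical(nrow(ind), 2L)
  expect_true(is.na(ind$gi_value[2]))
})

test_that("kick-net TSV reading validates taxa and keeps zero counts", {
  ind <- default_indicator_list()
  dir <- withr::local_tempdir()
  writeLines(c("site_id\ttaxon\tcount",
               "A\tBaetidae\t12", "A\tGammaridae\t0", "A\tPerlidae\t3",
               "B\tBaetidae\t1", "B\tChironomidae\t40", "B\tPerlidae\t2"),
             file.path(dir, "kick.tsv"))
  kn <- read_kicknet_tsv(file.path(dir, "kick.tsv"), ind)
  expect_length(kn, 2)
  expect_identical(kn$A$counts[["Gammaridae"]], 0L)

  write_kicknet_tsv(kn, file.path(dir, "kick2.tsv"))
  kn2 <- read_kicknet_tsv(file.path(dir, "kick2.tsv"), ind)
  expect_identical(kn2$B$counts, kn$B$counts)

  writeLines(c("site_id\ttaxon\tcount", "A\tNotATaxon\t5"), file.path(dir, "bad.tsv"))
  err <- expect_error(read_kicknet_tsv(file.path(dir, "bad.tsv"), ind),
                      class = "ednaIBCH_validation_error")
  expect_match(conditionMessage(err), "NotATaxon")
})

test_that("taxonomy validation enforces a consistent rank prefix", {
  ok <- data.frame(otu_id = "o1", phylum = "Arthropoda", class = "Insecta",
                   order = "Diptera", family = "Chironomidae",
                   genus = NA, species = NA)
  tax <- taxonomy_assignment(ok)
  expect_identical(tax$lowest_assigned_rank, "family")
  gap <- data.frame(otu_id = "o2", phylum = "Arthropoda", class = NA, order = NA,
                    family = NA, genus = NA, species = "Baetis alpinus")
  expect_error(taxonomy_assignment(gap), class = "ednaIBCH_validation_error")
})

test_that("indicator assignment matches family and phylum ranks only", {
  ind <- default_indicator_list()
  tax <- taxonomy_assignment(data.frame(
    otu_id = c("o1", "o2", "o3"),
    phylum = c("Arthropoda", "Cnidaria", "Rotifera"),
    class = c("Insecta", NA, NA), order = c("Ephemeroptera", NA, NA),
    family = c("Baetidae", NA, NA), genus = NA, species = NA))
  tax <- assign_indicators(tax, ind)
  expect_identical(tax$indicator_taxon, c("Baetidae", "Cnidaria", NA))
})
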