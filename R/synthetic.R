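#' Configuration for the paired eDNA / kick-net simulator
#'
#' The generator draws a latent ecological-quality score per site on the IBCH
#' 0-20 scale and lets it drive both data types: taxon occupancy rises
#' logistically in (quality - taxon sensitivity); kick-net counts are
#' zero-truncated negative-binomial thinned by an imperfect detection
#' probability; each indicator taxon spawns one to five OTUs whose reads appear
#' in a replicate with an independent per-replicate detection probability; a
#' heavy non-target OTU load fills the remaining sequencing depth; and controls
#' receive low-level contamination reads.
#'
#' Defaults emulate the national monitoring design the package targets: 92
#' sites with 4 filter replicates each, 145 indicator taxa, markedly lower
#' per-site indicator detection by eDNA than by kick-net, and log-normal
#' per-sample read depth (scaled-down mean 20,000 reads).
#'
#' @param n_sites number of river sites
#' @param n_rep filter replicates per site
#' @param n_indicator_taxa indicator taxa drawn from the reference list
#' @param n_nontarget_otus non-target OTUs (non-indicator amplification load)
#' @param otus_per_taxon_probs probabilities for 1..5 OTUs per indicator taxon
#' @param quality_mean,quality_sd latent site quality: truncated normal on
#'   \[0, 20\]
#' @param sensitivity_range taxon sensitivity thresholds, uniform on this range
#'   of the quality scale (taxa with high thresholds occur only at high-quality
#'   sites)
#' @param sensitivity_scale logistic scale linking quality minus sensitivity to
#'   occurrence probability (smaller = sharper occupancy thresholds)
#' @param kicknet_detection_prob probability an occurring taxon is captured by
#'   the kick-net sample
#' @param kicknet_mu,kicknet_size negative-binomial mean/size for specimen
#'   counts of captured taxa (zero-truncated)
#' @param edna_replicate_detection_prob probability an OTU of an occurring
#'   taxon is detected in one filter replicate
#' @param read_depth_meanlog,read_depth_sdlog log-normal per-sample read depth
#' @param contamination_rate expected fraction of OTUs leaking low-level reads
#'   into each control sample
#' @param contamination_weighted if `TRUE`, leak probability is proportional to
#'   OTU abundance instead of uniform
#' @param n_neg_controls,n_pos_controls control samples in the run
#' @param nontarget_occupancy_shape Beta shape parameters for per-OTU
#'   non-target site-occupancy probabilities
#' @param nontarget_in_phyla_frac fraction of non-target OTUs annotated within
#'   the five macroinvertebrate phyla used by the prediction module
#' @param seed mandatory integer seed; the same config and seed reproduce the
#'   dataset exactly
#' @return a validated `SyntheticConfig` list
#' @export
synthetic_config <- function(n_sites = 92L, n_rep = 4L,
                             n_indicator_taxa = 145L,
                             n_nontarget_otus = 1500L,
                             otus_per_taxon_probs = c(0.70, 0.20, 0.05, 0.03, 0.02),
                             quality_mean = 13.3, quality_sd = 2,
                             sensitivity_range = c(10, 30),
                             sensitivity_scale = 1.5,
                             kicknet_detection_prob = 0.9,
                             kicknet_mu = 20, kicknet_size = 0.8,
                             edna_replicate_detection_prob = 0.45,
                             read_depth_meanlog = log(20000) - 0.5^2 / 2,
                             read_depth_sdlog = 0.5,
                             contamination_rate = 0.02,
                             contamination_weighted = FALSE,
                             n_neg_controls = 4L, n_pos_controls = 2L,
                             nontarget_occupancy_shape = c(2, 6),
                             nontarget_in_phyla_frac = 1 / 3,
                             seed = NULL) {
  if (is.null(seed)) abort_config("a seed is mandatory for synthetic generation")
  if (n_sites < 1 || n_indicator_taxa < 1)
    abort_config("need at least one site and one indicator taxon")
  if (n_rep < 1) abort_config("n_rep must be >= 1")
  probs <- c(kicknet_detection_prob, edna_replicate_detection_prob,
             contamination_rate, nontarget_in_phyla_frac)
  if (any(probs < 0 | probs > 1)) abort_config("probabilities must lie in [0, 1]")
  if (length(otus_per_taxon_probs) != 5 || abs(sum(otus_per_taxon_probs) - 1) > 1e-9)
    abort_config("otus_per_taxon_probs must be 5 probabilities summing to 1")
  structure(as.list(environment()), class = "SyntheticConfig")
}

# classes used to fill taxonomy rows for indicator families
HIGHER_GROUP_CLASS <- c(
  Ephemeroptera = "Insecta", Plecoptera = "Insecta", Trichoptera = "Insecta",
  Coleoptera = "Insecta", Diptera = "Insecta", Heteroptera = "Insecta",
  Odonata = "Insecta", Megaloptera = "Insecta", Neuroptera = "Insecta",
  Lepidoptera = "Insecta", Crustacea = "Malacostraca", Hydracarina = "Arachnida",
  Gastropoda = "Gastropoda", Bivalvia = "Bivalvia", Hirudinea = "Clitellata",
  Oligochaeta = "Clitellata", Tricladida = "Rhabditophora",
  Nematomorpha = "Gordioida", Nemertea = "Enopla")

#' Generate a paired eDNA / kick-net dataset with known ground truth
#'
#' @param config a [synthetic_config()]
#' @param indicators indicator reference list; defaults to the packaged
#'   145-entry table
#' @return list with elements `reads` (`ReadCountMatrix` incl. controls),
#'   `taxonomy` (`TaxonomyAssignment` with `indicator_taxon` links),
#'   `kicknet` (list of `KicknetCommunity`), and `truth` (`LatentTruth`:
#'   per-site quality, true occupancy, OTU-to-taxon map, drawn read depths)
#' @export
generate_dataset <- function(config, indicators = default_indicator_list()) {
  if (!inherits(config, "SyntheticConfig")) abort_config("config must be a SyntheticConfig")
  if (config$n_indicator_taxa > nrow(indicators))
    abort_config(sprintf("indicator list has %d entries, %d requested",
                         nrow(indicators), config$n_indicator_taxa))
  ind <- indicators[seq_len(config$n_indicator_taxa), , drop = FALSE]
  set.seed(config$seed)
  ns <- config$n_sites; nr <- config$n_rep; nt <- nrow(ind)
  site_ids <- sprintf("site_%03d", seq_len(ns))

  # latent quality: truncated normal on [0, 20] via inverse CDF
  lo <- stats::pnorm(0, config$quality_mean, config$quality_sd)
  hi <- stats::pnorm(20, config$quality_mean, config$quality_sd)
  quality <- stats::qnorm(stats::runif(ns, lo, hi), config$quality_mean, config$quality_sd)
  names(quality) <- site_ids

  # occupancy: logistic in (quality - sensitivity)
  sens <- stats::runif(nt, config$sensitivity_range[1], config$sensitivity_range[2])
  names(sens) <- ind$name
  p_occ <- stats::plogis(outer(quality, sens, "-") / config$sensitivity_scale)
  occupancy <- matrix(stats::runif(ns * nt) < p_occ, ns, nt,
                      dimnames = list(site_ids, ind$name))

  # kick-net: imperfect capture, zero-truncated negative-binomial counts
  kicknet <- vector("list", ns)
  names(kicknet) <- site_ids
  for (i in seq_len(ns)) {
    occ <- which(occupancy[i, ])
    cap <- occ[stats::runif(length(occ)) < config$kicknet_detection_prob]
    cnt <- if (length(cap)) ztnbinom(length(cap), config$kicknet_mu, config$kicknet_size) else integer(0)
    kicknet[[i]] <- kicknet_community(site_ids[i],
                                      stats::setNames(cnt, ind$name[cap]), ind)
  }

  # OTU inventory: indicator OTUs (1-5 per taxon) + non-target load
  m_per_taxon <- sample(1:5, nt, replace = TRUE, prob = config$otus_per_taxon_probs)
  otu_taxon <- rep(ind$name, m_per_taxon)
  n_ind_otu <- length(otu_taxon)
  nn <- config$n_nontarget_otus
  otu_ids <- sprintf("OTU_%05d", seq_len(n_ind_otu + nn))
  ind_otu_ids <- otu_ids[seq_len(n_ind_otu)]
  nt_otu_ids <- otu_ids[n_ind_otu + seq_len(nn)]
  names(otu_taxon) <- ind_otu_ids

  taxonomy <- build_synthetic_taxonomy(ind, otu_taxon, nt_otu_ids, config)
  taxonomy <- assign_indicators(taxonomy, ind)

  # non-target occupancy: per-OTU Beta occupancy probability, quality-independent
  p_nt <- stats::rbeta(nn, config$nontarget_occupancy_shape[1],
                       config$nontarget_occupancy_shape[2])
  occ_nt <- matrix(stats::runif(ns * nn) < rep(p_nt, each = ns), ns, nn,
                   dimnames = list(site_ids, nt_otu_ids))

  # base abundance profile; indicator OTUs get higher read coverage
  abund <- stats::setNames(stats::rlnorm(length(otu_ids), 0, 1.5), otu_ids)
  abund[ind_otu_ids] <- abund[ind_otu_ids] * exp(1)

  # field samples: per-replicate detection, multinomial read allocation
  taxon_idx <- match(otu_taxon, ind$name)
  field_ids <- as.vector(t(outer(seq_len(ns), seq_len(nr),
                                 function(i, r) sprintf("%s_R%d", site_ids[i], r))))
  depth <- stats::setNames(pmax(1, round(stats::rlnorm(
    ns * nr, config$read_depth_meanlog, config$read_depth_sdlog))), field_ids)
  counts <- matrix(0L, length(otu_ids), ns * nr,
                   dimnames = list(otu_ids, field_ids))
  p_e <- config$edna_replicate_detection_prob
  col <- 0L
  for (i in seq_len(ns)) {
    occ_ind_otu <- occupancy[i, taxon_idx]            # OTU-level occupancy via parent taxon
    occ_nt_otu <- occ_nt[i, ]
    for (r in seq_len(nr)) {
      col <- col + 1L
      det <- c(occ_ind_otu & stats::runif(n_ind_otu) < p_e,
               occ_nt_otu & stats::runif(nn) < p_e)
      nd <- sum(det)
      if (nd == 0L) next
      d <- max(depth[col], nd)
      w <- abund[det] * exp(stats::rnorm(nd, 0, 0.5))
      counts[det, col] <- 1L + as.integer(stats::rmultinom(1, d - nd, w))
      depth[col] <- d
    }
  }

  # controls: low-level contamination leaks, <= 1% of an OTU's mean field count
  ctrl_ids <- c(if (config$n_neg_controls > 0) sprintf("NEG_%02d", seq_len(config$n_neg_controls)),
                if (config$n_pos_controls > 0) sprintf("POS_%02d", seq_len(config$n_pos_controls)))
  ctrl_counts <- matrix(0L, length(otu_ids), length(ctrl_ids),
                        dimnames = list(otu_ids, ctrl_ids))
  if (length(ctrl_ids) > 0 && config$contamination_rate > 0) {
    mean_field <- rowMeans(counts)
    leak_p <- if (config$contamination_weighted) {
      pmin(1, config$contamination_rate * abund / mean(abund))
    } else rep(config$contamination_rate, length(otu_ids))
    for (j in seq_along(ctrl_ids)) {
      leak <- stats::runif(length(otu_ids)) < leak_p
      cap <- pmax(1, floor(0.01 * mean_field[leak]))
      ctrl_counts[leak, j] <- as.integer(pmax(1L, ceiling(stats::runif(sum(leak)) * cap)))
    }
  }

  all_counts <- cbind(counts, ctrl_counts)
  meta <- data.frame(
    sample_id = colnames(all_counts),
    site_id = c(rep(site_ids, each = nr), rep(NA_character_, length(ctrl_ids))),
    replicate = c(rep(seq_len(nr), ns), rep(NA_integer_, length(ctrl_ids))),
    role = c(rep("field", ns * nr),
             rep("negative_control", config$n_neg_controls),
             rep("positive_control", config$n_pos_controls)),
    stringsAsFactors = FALSE)
  reads <- read_count_matrix(all_counts, meta)

  truth <- structure(list(quality = quality, occupancy = occupancy,
                          sensitivity = sens, otu_taxon = otu_taxon,
                          read_depth = depth, config = config),
                     class = "LatentTruth")
  list(reads = reads, taxonomy = taxonomy, kicknet = kicknet, truth = truth)
}

# zero-truncated negative binomial via inverse-CDF conditioning on > 0
ztnbinom <- function(n, mu, size) {
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, p0, 1)
  as.integer(stats::qnbinom(u, mu = mu, size = size))
}

build_synthetic_taxonomy <- function(ind, otu_taxon, nt_otu_ids, config) {
  ind_rows <- ind[match(otu_taxon, ind$name), ]
  fam_rank <- ind_rows$rank == "family"
  tax_ind <- data.frame(
    otu_id = names(otu_taxon),
    phylum = ind_rows$phylum,
    class = ifelse(fam_rank, unname(HIGHER_GROUP_CLASS[ind_rows$higher_group]), NA_character_),
    order = ifelse(fam_rank, ind_rows$higher_group, NA_character_),
    family = ifelse(fam_rank, ind_rows$name, NA_character_),
    genus = NA_character_, species = NA_character_,
    stringsAsFactors = FALSE)
  nn <- length(nt_otu_ids)
  n_in <- round(nn * config$nontarget_in_phyla_frac)
  # non-target OTUs inside the five assessed phyla get made-up non-indicator
  # families (or none), never the three phylum-rank indicator phyla
  in_phy <- sample(c("Arthropoda", "Mollusca"), n_in, replace = TRUE, prob = c(0.8, 0.2))
  in_cls <- ifelse(in_phy == "Arthropoda", "Insecta", "Gastropoda")
  in_ord <- ifelse(in_phy == "Arthropoda", "Diptera", "Littorinimorpha")
  in_fam <- ifelse(stats::runif(n_in) < 0.5,
                   sprintf("NontargetFam%03d", sample.int(200, n_in, replace = TRUE)),
                   NA_character_)
  in_ord[is.na(in_fam)] <- NA_character_  # keep rank prefix consistent at class level
  out_phy <- sample(c("Rotifera", "Chordata", "Nematoda", "Bacillariophyta", "Ascomycota"),
                    nn - n_in, replace = TRUE)
  tax_nt <- data.frame(
    otu_id = nt_otu_ids,
    phylum = c(in_phy, out_phy),
    class = c(in_cls, rep(NA_character_, nn - n_in)),
    order = c(in_ord, rep(NA_character_, nn - n_in)),
    family = c(in_fam, rep(NA_character_, nn - n_in)),
    genus = NA_character_, species = NA_character_,
    stringsAsFactors = FALSE)
  taxonomy_assignment(rbind(tax_ind, tax_nt))
}

#' Tabulate the generator's ground truth
#'
#' @param truth `LatentTruth` from [generate_dataset()]
#' @return data.frame with per-site latent quality and true indicator richness
#'   (occupancy row sums)
#' @export
truth_summary <- function(truth) {
  data.frame(site_id = names(truth$quality),
             quality = unname(truth$quality),
             true_richness = unname(rowSums(truth$occupancy)),
             stringsAsFactors = FALSE)
}
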