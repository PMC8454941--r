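# Independent oracles and small fixture builders. The oracles deliberately
# share no code with the package implementations.

# naive replicate collapse: explicit per-(site, OTU) loops
naive_collapse <- function(counts, meta, k, pooling = "sum") {
  meta <- meta[meta$role == "field", ]
  sites <- unique(meta$site_id)
  otus <- rownames(counts)
  presence <- matrix(FALSE, length(sites), length(otus), dimnames = list(sites, otus))
  pooled <- matrix(0L, length(sites), length(otus), dimnames = list(sites, otus))
  for (s in sites) {
    cols <- meta$sample_id[meta$site_id == s]
    for (o in otus) {
      ndet <- 0L; tot <- 0L
      for (cc in cols) {
        v <- counts[o, cc]
        if (v > 0) ndet <- ndet + 1L
        tot <- tot + v
      }
      if (ndet >= k) {
        presence[s, o] <- TRUE
        pooled[s, o] <- if (pooling == "sum") tot else as.integer(floor(tot / length(cols) + 0.5))
      }
    }
  }
  list(presence = presence, pooled = pooled)
}

# naive IBCH scorer: explicit nested lookups, no shared helpers
naive_ibch_score <- function(counts, ind_df, bin_width = 4, max_cv = 14, smax = 20) {
  rich <- 0L
  for (v in counts) if (v >= 1) rich <- rich + 1L
  cv <- 0L
  if (rich > 0) {
    cv <- 1L
    while (cv * bin_width < rich && cv < max_cv) cv <- cv + 1L
  }
  gi <- 0L
  for (tx in names(counts)) {
    row <- ind_df[ind_df$name == tx, ]
    if (nrow(row) == 1 && !is.na(row$gi_value) && counts[[tx]] >= row$gi_min_abundance &&
        row$gi_value > gi) gi <- row$gi_value
  }
  if (gi == 0L || cv == 0L) return(0L)
  s <- gi + cv - 1L
  if (s > smax) s <- smax
  as.integer(s)
}

# random small replicated count matrix (field samples only + optional controls)
random_rcm <- function(n_otu = 8, n_site = 5, n_rep = 4, n_ctrl = 0, max_count = 20) {
  ids <- sprintf("otu%02d", seq_len(n_otu))
  sites <- sprintf("st%02d", seq_len(n_site))
  samp <- as.vector(outer(seq_len(n_rep), sites, function(r, s) paste0(s, "_", r)))
  ctrl <- if (n_ctrl > 0) sprintf("neg%02d", seq_len(n_ctrl)) else character(0)
  m <- matrix(rbinom(n_otu * (length(samp) + n_ctrl), max_count, 0.25) *
                rbinom(n_otu * (length(samp) + n_ctrl), 1, 0.5),
              n_otu, length(samp) + n_ctrl,
              dimnames = list(ids, c(samp, ctrl)))
  meta <- data.frame(
    sample_id = c(samp, ctrl),
    site_id = c(rep(sites, each = n_rep), rep(NA, n_ctrl)),
    replicate = c(rep(seq_len(n_rep), n_site), rep(NA, n_ctrl)),
    role = c(rep("field", length(samp)), rep("negative_control", n_ctrl)),
    stringsAsFactors = FALSE)
  read_count_matrix(m, meta)
}

# random kick-net community over the packaged indicator list
random_community <- function(ind, n_taxa = 10, site = "s1", max_count = 30) {
  taxa <- sample(ind$name, n_taxa)
  kicknet_community(site, stats::setNames(sample.int(max_count, n_taxa, replace = TRUE), taxa), ind)
}

# small fast synthetic configuration for structural tests
small_syn <- function(seed, ...) {
  synthetic_config(n_sites = 12L, n_rep = 4L, n_nontarget_otus = 150L, seed = seed, ...)
}
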