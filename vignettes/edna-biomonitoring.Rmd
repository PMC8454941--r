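---
title: "From eDNA reads to river status: filtering, the IBCH index, and taxonomy-free prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From eDNA reads to river status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regulatory river biomonitoring scores the ecological state of a site from its
benthic macroinvertebrate community. The Swiss IBCH protocol does this from
kick-net samples: specimens are sorted into 145 pre-defined indicator taxa
(families, except Porifera, Bryozoa and Cnidaria, which count at phylum
level), and the site receives an integer score from 0 to 20 that is binned
into five status categories from "bad" to "very good". Environmental DNA
(eDNA) metabarcoding of stream water offers a cheaper survey of the same
fauna, but it yields OTU read counts, not specimen counts, so the index
cannot be computed directly from eDNA. This package implements the full
comparison workflow: cleaning a replicated eDNA OTU table, scoring kick-net
communities with the IBCH engine, predicting the score from OTU
presence/absence with a random forest, and quantifying how well the two
routes agree.

## eDNA cleaning cascade

Raw OTU tables carry contamination and stochastic detections. Two control-based
threshold strategies are provided because the cleaning rule used in routine
practice can be read two ways:

* `max_in_controls` (default): for each OTU, the maximum read count observed
  in any negative or positive control is subtracted from every field sample,
  flooring at zero. This treats control reads as an additive contamination
  level.
* `proportional`: the OTU's control-read share of its total reads defines a
  per-sample detection minimum (`fraction * sample total`); weaker
  observations are zeroed. This treats control reads as a rate.

Neither reading is asserted as the authoritative rule; both are exposed as
named configuration, and the default is the subtraction reading. Positive
controls contribute to thresholds by default (a `negative_only` switch
exists) because cleaning against both control types is the conservative
choice when positive-control template can cross-contaminate.

The replicate-consistency filter then requires an OTU to be detected (nonzero
after thresholding) in at least *k* of the *n* = 4 filter replicates of a
site; retained OTUs get the **sum** of their replicate reads (mean pooling is
available but non-default, since site depth is conventionally reported over
pooled replicates). Detection sets are nested across *k* by construction, and
`stringency_profile()` tabulates mean reads and mean OTUs per site for
*k* = 1..4; the workflow uses *k* = 2 as its working stringency. Sites with
fewer than *k* replicates cannot satisfy the rule and are excluded with a
warning rather than rescaling *k*, because the design fixes *n* = 4.
A minimum per-sample read depth is available (`min_sample_depth`) but
defaults to 0, i.e. off, as no principled cutoff is fixed by the protocol.

Taxonomic restriction comes in two flavours used for different purposes:
`restrict_to_indicators()` keeps only OTUs linked to one of the 145 indicator
taxa (used for like-for-like diversity comparisons), while
`restrict_to_phyla()` keeps every OTU in the five assessed phyla —
Arthropoda, Cnidaria, Porifera, Bryozoa, Mollusca — regardless of deeper
assignment (used as the taxonomy-free feature set for prediction, which
deliberately includes OTUs the traditional index ignores).

## The IBCH engine

The index combines two ordinal components:

* **Variety class (CV)**: derived from the number of indicator taxa present.
* **Indicator group (GI)**: the sensitivity value (1-9) of the most
  pollution-intolerant taxon whose specimen count reaches its abundance
  minimum; 0 when none qualifies.

The official Swiss lookup tables (variety bins, the GI x CV score table, GI
values and abundance minima per taxon) are not redistributed here. The engine
therefore ships a documented, structurally faithful default that is plain
configuration and can be replaced wholesale by the official tables without
code changes:

* CV = `ceiling(richness / 4)`, capped at class 14, with CV = 0 for an empty
  community;
* score = `min(GI + CV - 1, 20)`, and 0 whenever GI = 0 or CV = 0 — this
  reproduces the 0-20 range and the monotonicity of the real table (score
  never decreases in either component);
* GI values in the packaged reference follow the IBGN-style sensitivity
  ordering (stoneflies highest, oligochaetes and chironomids lowest), with
  abundance minima of 3 specimens (10 for the most tolerant groups);
* categories are near-equal quintiles of the scale: bad 0-4, unsatisfactory
  5-8, moderate 9-12, good 13-16, very good 17-20.

The packaged indicator reference
(`inst/extdata/ibch_indicator_taxa_synthetic.tsv`, loaded by
`default_indicator_list()`) lists 145 real European freshwater
macroinvertebrate taxa; the `synthetic` in the filename marks that its GI
columns are generated defaults, not the official values. The published scale
is stated as 0-20 in the method description while score distributions are
sometimes displayed from 5 upward; the engine keeps the full 0-20 range and
leaves any narrower display range to configuration.

eDNA data never enter `ibch_score()` directly: read counts cannot be
translated into specimen counts, so the only eDNA route to the index is the
prediction module.

## Diversity comparison

Alpha diversity is compared as per-site indicator richness, with OTU
multiplicity collapsed (a taxon detected via three OTUs counts once). The
systematic eDNA detection deficit is tested with a two-sided paired t-test by
default (the design is paired by site; a Wilcoxon signed-rank option exists
because richness differences need not be normal). Gamma composition pools
all sites before forming proportions — reads (or specimens) in a higher group
over total indicator reads (or specimens) — so each method's proportions sum
to one; using total indicator reads rather than all reads in the denominator
is an interpretation choice that makes the group shares comparable across
methods, and the per-group dense ranks plus Spearman's rho (tie-corrected)
summarize concordance.

Because it is not fixed which richness vector was regressed on which in
comparable studies, `run_all()` reports both regression directions.

## Taxonomy-free prediction

Features are OTU presence/absence over the phylum-restricted table;
zero-variance columns are dropped. The forest protocol is: 500 trees, minimum
node size 3, `mtry = floor(n_features / 3)`, fitted with `ranger`. The grid
search (`mtry` in n/5, n/3, n/2; node size 3, 5, 10; 500 trees) minimizes
5-fold cross-validated RMSE with seeded fold assignment; ties break toward
smaller `mtry`, then fewer trees, then smaller node size. Five-fold CV was
chosen over out-of-bag error for tuning because it scores every candidate on
strictly held-out sites under one shared fold split.

"Predicted for every sample iteratively" is implemented as leave-one-out by
default — for each site the forest is refit on the remaining sites — because
it is strictly out-of-sample; per-site out-of-bag prediction is available as
a faster alternative. Predictions are continuous (a regression forest, not a
classifier), then rounded half-up to integer scores for categorization,
since categories are integer intervals. Tree averaging keeps predictions
inside the observed response range, which also narrows their distribution
relative to the observations — a known property worth remembering when the
extreme categories are rare in the training data.

Agreement is evaluated by the observed-on-predicted linear model (adjusted
R^2 and slope p-value), unweighted Cohen's kappa on the categories with the
conventional verbal bands (boundary values fall to the lower band; values in
[0.99, 1) are "excellent", exactly 1 is "perfect"), the percentage of exact
category matches, the percentage within one category, and the signed
category-deviation histogram. A linear-weighted kappa is deliberately not
the default.

## The synthetic-data generator

There is no public paired dataset at this scale, so the generator is a
first-class module with known ground truth. Its latent structure is the
minimal one supporting the workflow's inference claims:

* site quality `q_i` *is* the true score on the 0-20 scale (truncated normal,
  mean 13.3, sd 2 — centred on realistic national survey score
  distributions), so recovery tests have an unambiguous target;
* taxon `j` occurs at site `i` with probability
  `plogis((q_i - t_j) / 1.5)`, with sensitivities `t_j ~ U(10, 30)`; the
  range spans and exceeds the quality range so that community composition
  changes smoothly along the quality gradient and, in expectation, a site of
  average quality hosts roughly 25 of the 145 taxa — matching per-site
  kick-net richness around the low twenties after imperfect capture;
* kick-net counts: occurring taxa are captured with probability 0.9 and
  counted with a zero-truncated negative binomial (mean 20, size 0.8 —
  overdispersed, as specimen counts are);
* each indicator taxon spawns 1-5 OTUs (mostly one; mean about 1.4, giving
  around 205 indicator OTUs); an OTU of an occurring taxon is detected in a
  replicate with probability 0.45, independently across replicates — no
  spatial DNA-transport model, since within-site replicate correlation is
  left at zero;
* 1500 non-target OTUs (one third annotated inside the assessed phyla, the
  rest outside) occur independently of quality with Beta(2, 6) per-OTU
  occupancy, emulating the heavy non-target amplification load of degenerate
  COI primers;
* per-sample read depth is log-normal (scaled-down mean 20,000); reads are
  allocated to detected OTUs by a multinomial over log-normal abundance
  weights with every detected OTU guaranteed at least one read, so column
  sums equal the drawn depth exactly;
* each control sample receives contamination reads for an expected 2% of
  OTUs, at most 1% of the OTU's mean field count each; contamination is
  uniform across OTUs by default (the simplest adversary for the threshold
  filter), with an abundance-weighted switch.

What the generator does **not** emulate: PCR and primer bias, chimeras,
sequence-level error, upstream DNA transport, and taxon-specific DNA
shedding differences. Passing tests on synthetic data therefore demonstrate
that the workflow's statistics behave as designed under a known truth — not
that eDNA field data will achieve any particular agreement level.

## Determinism and numerical choices

Every stochastic step takes a seed. `run_all()` fans one global seed out to
per-stage seeds via a fixed hash of the stage name, so a stage re-run in
isolation reproduces its slice of the full run, and two runs with the same
seed serialize to byte-identical JSON reports; stage wall-clock times are
kept out of the serialized report (as an attribute) for exactly that reason.
Forests run single-threaded with explicit `ranger` seeds. Degenerate cases
are defined rather than left to fail: all-zero paired differences report
p = 1 with a warning; expected agreement of 1 makes kappa 1 (perfect
agreement) or 0, with a warning; constant predictions skip the regression
with a warning; an empty community scores 0 ("bad").

## Problem sizes

The shipped tests and the acceptance script run the full study scale — 92
sites, 4 replicates, 145 indicator taxa, about 1700 OTUs — for the
end-to-end checks, and small randomized instances (5 sites x 8 OTUs x 4
replicates; communities of up to 30 taxa) for the brute-force oracle
comparisons, with 200-1000 repetitions per property. A complete test run
takes a few minutes on one CPU, dominated by the leave-one-out forests.

## Limitations

The IBCH tables shipped are stand-ins: scores from the default configuration
are structurally but not numerically the official index. The forest transfers
whatever biases the training response carries; it cannot exceed the range of
observed scores, and sparse coverage of extreme categories limits what the
category-agreement statistics can show there. The generator's independence
assumptions (replicates, non-target occupancy) are simplifications; real
data violate them in ways that typically *reduce* effective replication.
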