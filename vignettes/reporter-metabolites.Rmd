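---
title: "Reporter metabolite analysis: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter metabolite analysis: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reporterMet)
```

## The model

A genome-scale metabolic network induces a neighborhood structure on
transcription: the genes encoding the enzymes around one metabolite tend
to be co-regulated, so a coordinated but individually modest expression
change can be invisible gene-by-gene yet clear in aggregate. Reporter
metabolite scoring formalizes this. For a metabolite with $k$ neighbor
enzymes (enzymes catalyzing a reaction that uses the metabolite as
substrate or product — direction plays no role):

$$Z_i = \Phi^{-1}(1 - p_i), \qquad
  Z_m = \frac{1}{\sqrt{k}} \sum_{i=1}^{k} Z_i, \qquad
  Z_m^{corr} = \frac{Z_m - \mu_k}{\sigma_k}, \qquad
  p_m = 1 - \Phi(Z_m^{corr}),$$

where $p_i$ is the differential-expression p-value assigned to enzyme
$i$, and $\mu_k, \sigma_k$ are the mean and standard deviation of $Z_m$
over random size-$k$ enzyme sets drawn from the network. Metabolites with
$p_m \le 0.05$ are called reporters (the boundary is inclusive).

Three modeling commitments deserve emphasis:

* **GPR collapse by minimum p.** An enzyme complex (AND) or isozyme group
  (OR) is scored by its most significantly changed gene. We apply the
  minimum over *all* genes of the association regardless of the boolean
  structure; the AND/OR tree is retained on the network object purely as
  provenance. The rationale is that one strongly responsive transcript is
  evidence of regulation at that reaction whichever boolean role it plays,
  and it makes the score insensitive to how curators nested the rule.
* **Enzyme identity is the gene set, not the reaction.** Two reactions
  around one metabolite sharing an identical gene association contribute
  one enzyme unit, so a single transcript signal is never counted twice
  (`dedup = FALSE` restores per-reaction counting for sensitivity
  analysis). The background pool is the network-wide collection of
  distinct scored enzyme units under the same rule.
* **The background is the network as observed.** Enzyme sets are sampled
  from all scored enzyme units — including any true signal present — because
  the null being asked is "is this neighborhood more coordinated than a
  random set of enzymes from *this* experiment", not "from an idealized
  null network". Sets are drawn without replacement within a set, with
  replacement across sets.

The per-$k$ normalization of the aggregate ($1/\sqrt{k}$) is immaterial:
because $\mu_k$ and $\sigma_k$ are computed under the same aggregation,
any fixed per-$k$ scaling cancels in $Z_m^{corr}$ (a unit test asserts
this). It is kept because it makes raw aggregates comparable across $k$
in diagnostics.

### Numerical choices

* `p_to_z()` clamps p-values into $[10^{-15}, 1 - 10^{-15}]$ before the
  inverse-normal transform, so $p = 1$ maps to a large negative but
  finite Z rather than $-\infty$; the clamped tails are evaluated at the
  clamp point itself so both ends are exact.
* `background_stats()` enumerates all $\binom{n}{k}$ subsets exactly
  whenever that count is at most `exhaustive_limit` (default 200,000) and
  reports the **population** SD — the enumeration *is* the null
  distribution. Monte-Carlo (default 10,000 sets) reports the sample SD.
  One seeded stream is consumed in ascending-$k$ order, so results are
  bit-reproducible for a given seed.
* A degenerate background ($\sigma_k = 0$, e.g. all enzyme Z identical or
  a one-enzyme network) defines the corrected score as 0 (p = 0.5) with a
  warning rather than failing.
* Ties in the output table are broken by metabolite id, making the sorted
  table deterministic.

## Differential expression and probe summarization

`differential_expression()` implements the empirical-Bayes moderated
t-test: per-probe variances are shrunk toward a common prior estimated by
moment matching on the log sample variances (delegated to
`limma::squeezeVar()`, which performs exactly this digamma/trigamma
matching), and the statistic is referenced to a t distribution with
$d + d_0$ degrees of freedom. The `d0` argument exposes the prior
strength for calibration work: `d0 = 0` reproduces the ordinary t-test
and `d0 = Inf` the fully pooled statistic, both covered by closed-form
tests; the default estimate is cross-checked against `limma::eBayes()`.
A Welch unequal-variance option is available, and precomputed gene-score
tables can bypass the module entirely, since real studies bring their own
DE stack. P-values are two-sided; direction is carried separately as the
sign of the log fold-change.

Probes map to genes through an optional rank tier (mirroring
probe-set rankings on commercial arrays): only the best (minimal) tier is
used, one probe is copied through, several are combined by the median of
p-values and of log fold-changes. With no tier annotation every probe is
tier 1 and the rule degenerates to the plain median. A log fold-change of
exactly 0 tie-breaks deterministically to "down" with a warning.

One consequence worth knowing: medians of 2–3 p-values are not uniform
under the null (the mean of two uniforms is triangular), so *gene-level*
null p-values deviate slightly from uniformity by construction. The
calibration guarantee — and the package's calibration tests — apply to
the per-probe p-values; the reporter statistic is unaffected because its
background correction is computed from the same gene-level scores.

## Motif enrichment

Promoters are the strand-oriented $-800..+200$ window around the TSS
(`extract_promoters()` does the coordinate arithmetic from a genome +
TSS table; soft-masked lowercase bases become `N`). For every reporter
metabolite, the up- and the down-regulated neighbor gene sets are tested
independently when they contain at least 5 genes; the direction of each
neighbor enzyme is that of its minimum-p gene.

Scanning: each window on both strands scores
$\sum_j \log f_j(b_j) / bg(b_j \mid \text{context})$ with column
frequencies from counts + 0.25 pseudocount per cell and a 2nd-order
Markov background with add-one pseudocounts trained on the background
(non-set) promoters. Windows containing `N` score $-\infty$. A promoter
is a hit when its best window reaches 70% of the matrix's maximum
achievable score against the background's stationary composition — the
per-matrix reading of a "70% of maximum" threshold; when that maximum is
not positive the fraction is taken on the range-normalized score, and a
`threshold_mode = "observed-best"` option thresholds on the best score
observed in the dataset instead.

Enrichment is per-sequence presence/absence: the 2×2 table of the gene
set versus all other metabolic genes is tested with the one-tailed
Fisher exact test (an exact hypergeometric upper tail, no mid-p), and
q-values are computed per gene set across motifs — the unit at which
enrichment is reported per reporter metabolite — with a pooled mode
available. $\pi_0$ is estimated on the $\lambda = 0.05..0.95$ grid with
cubic-smoothing-spline extrapolation to $\lambda = 1$, falling back to
the single-point estimate at $\lambda = 0.5$ below 100 p-values; with
$\pi_0 = 1$ the q-values coincide with Benjamini–Hochberg, which a test
asserts exactly.

## Cross-contrast comparison and phenotypes

Reporter sets of two contrasts are compared by Jaccard distance (the
fraction of non-overlapping reporters; two empty sets are at distance 0
by convention, with a message). Contrast trees use average-linkage
agglomerative clustering on the pairwise distance matrix — average
linkage because the distance is a set overlap with no ultrametric
guarantee, and single/complete are available flags. Dendrograms are
serialized as Newick.

"Centroid expression" of a metabolite is the per-sample mean of its
neighbor genes' z-scored expression (standardization per gene over all
samples; a raw-mean mode exists). All neighbor genes are used regardless
of direction — the directional filtering used for motif sets is not
applied here, keeping the centroid a property of the neighborhood rather
than of one contrast. Pearson correlation with a phenotype is reported
per group and pooled, with the usual t transform for the two-sided
p-value; groups with fewer than 3 paired observations or zero variance
are marked not computable.

## The synthetic-data generator

`simulate_dataset()` produces every input format the pipeline reads, plus
a truth file. What it emulates, and what it does not:

* **Network.** Metabolite connectivity weights follow a truncated power
  law (exponent `degree_power = 2.2`) scaled to a mean degree of 6, so a
  few hub metabolites attach to dozens of reactions — the cofactor
  (ATP/NAD) pattern — while the median metabolite attaches to a few.
  Reactions average 2–3 participants; 8% are gene-less
  (transport/spontaneous); gene-associated reactions carry a single gene
  (70%), an AND complex or an OR isozyme pair/triple (15% each). Genes
  are dealt from a shuffled stack, so each gene belongs to essentially
  one reaction, as most metabolic genes do.
* **Planted signal.** `n_planted_reporters = 5` metabolites with 5–15
  neighbor enzyme units get a coherent shift: 80% of their neighbor genes
  move by `effect_size = 1.5` baseline SDs (1.5 log2 units at the
  default `baseline_sd = 1`) in the case group, with one sign per
  metabolite. The degree window excludes the dominant hubs deliberately:
  planting the one metabolite that touches a third of the network would
  amount to a global expression shift, which is a different (and
  degenerate) detection problem. Expression is
  `N(baseline, probe_sd = 0.4)` per probe, 1–3 probes per gene
  (probabilities 0.6/0.3/0.1), 10 samples per group.
* **Promoters.** Sampled from an order-2 Markov model trained on a seeded
  random genome with mild AT bias. Target genes receive one motif
  instance drawn from the PFM columns with probability
  `motif_plant_rate = 0.9`, on a random strand at a uniform offset;
  draws are rejection-sampled to score at least 75% of the matrix
  maximum, because a planted "site" the scanner's own 70% definition
  would not recognize does not model a functional binding site. 5% of
  bases are masked to `N` in runs of 10 that never overlap the planted
  instance. Ten decoy matrices are emitted by shuffling the true matrix's
  columns — same information content, different motif — which makes
  specificity a real test. The promoters are also embedded in a synthetic
  chromosome with a TSS table so the coordinate-extraction path can be
  exercised end to end.
* **Not emulated:** RMA-level probe intensity physics, cross-hybridizing
  probes, correlated biological replicates, repeat structure or GC
  isochores in promoters, and operon-like shared promoters. Passing the
  recovery tests therefore demonstrates the statistics and the plumbing
  under the assumed structure, not performance on real arrays or real
  genomes.

## Problem sizes and determinism

The test-suite and acceptance runs use a 50-metabolite / 120-reaction /
150-gene network (200 metabolites and 2,000 genes for null calibration),
10,000 background samples, five seeds for recovery and twenty for motif
specificity — sizes at which every stage finishes in seconds while the
Monte-Carlo and exhaustive backgrounds remain distinguishable from each
other only within stated tolerances. All randomness flows from explicit
seeds: identical configuration plus seed reproduces every output file
byte for byte.

## Known limitations

* The SBML reader targets the fbc gene-product association and the legacy
  `GENE_ASSOCIATION` notes dialects; exotic encodings fall back to an
  empty association rather than being guessed.
* With very few scored enzymes the background becomes degenerate and the
  affected metabolites are reported at p = 0.5 rather than being
  excluded; the warning should be taken seriously on small networks.
* $\pi_0$ estimation below 100 p-values uses the single-$\lambda$
  fallback and is conservative when signal is dense.
* Reporter p-values are deliberately not multiplicity-corrected — the
  statistic's consumers rank metabolites and read the 0.05 call as a
  screening threshold, and the background correction already standardizes
  against the network-wide null.
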