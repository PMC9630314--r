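---
title: "Gene-network similarity: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-network similarity: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsig)
```

## The problem

Tumor antigens such as B7-H3 (CD276) are candidate therapy targets in
metastatic castration-resistant prostate cancer, and a central question is
which regulatory programs such a gene travels with — for instance whether
its co-expression network converges on the androgen-receptor (AR) axis.
Public expression cohorts cannot be pooled naively: they are profiled on
different platforms and shipped in different units, and single-gene
correlations are noisy. This package implements a pipeline that (i)
harmonizes cohorts to a common per-sample scale, (ii) compares genes by
their whole co-expression *networks* rather than by single pairwise
correlations, and (iii) corroborates network findings with preranked
enrichment, single-cell positivity, and classical association statistics.

## Normalization to pseudo-TPM

Units are converted per declared tag: FPKM samples are rescaled so each
column sums to $10^6$ (which is exactly the FPKM→TPM map up to the common
per-sample constant), and RSEM transcript fractions are multiplied by
$10^6$. Cohorts are then merged on the *exact, case-sensitive*
intersection of gene symbols and every sample is rescaled again to a total
of $10^6$ — "pseudo-TPM". Rescaling after row subsetting is deliberate:
it is the only order under which post-merge column sums can equal $10^6$,
and it redistributes the expression mass of the genes dropped by the
intersection. Consequences worth knowing:

- **Conservation.** Every pseudo-TPM column sums to $10^6$ within
  $10^{-6}$ relative tolerance (tested on random mixed-unit fixtures).
- **Order preservation.** Unit conversion and rescaling are strictly
  monotone within a sample, so gene rank order never changes.
- **Closure.** Forcing a constant column total makes the matrix
  compositional: when one block of genes goes up, everything else must go
  down. See "What the violin control actually shows" below.
- Zero-total samples are hard errors, never silently dropped — dropping
  would change $n$ without a trace.
- No alias resolution is attempted on gene symbols; exact matching is the
  only reproducible default.
- The median's 95% CI in `summarize_gene()` is a percentile bootstrap
  (2000 resamples, seeded); displays of per-cohort medians commonly quote
  such a CI without naming a method, and the percentile bootstrap is the
  assumption-free default.

## The second-order network similarity

Stage one computes each gene's *network*: its vector of correlations to
every other gene across samples. The default is Pearson on
$\log_2(\text{pseudo-TPM}+1)$ — TPM-scale data are strongly right-skewed
and the log stabilizes variance; both the method (`pearson`/`spearman`)
and the transform (`log2p1`/`none`) are configurable and recorded, since
nothing forces one choice.

Stage two correlates the networks themselves: for genes $i$ and $j$,

$$S_{ij} = \mathrm{cor}\!\left(C_{i,-\{i,j\}},\; C_{j,-\{i,j\}}\right),$$

the Pearson correlation of the two correlation profiles with *both*
self-positions excluded. The exclusion matters: $C_{ii}=C_{jj}=1$
structurally, and leaving those entries in would inflate every pairwise
similarity. "Serial correlations" here therefore means exactly two serial
passes — correlation over samples, then correlation over profiles — which
is the reading consistent with a similarity score bounded in $[-1, 1]$
where 1 means near-identical networks.

Numerical notes:

- $S$ is computed with a closed-form vectorized identity (one matrix
  product plus rank-one corrections for the excluded positions). The test
  suite holds it to within $10^{-10}$ of an exhaustive double-loop
  recomputation on every fixture up to 30 genes.
- Zero-variance genes have undefined correlations; they are flagged `NA`
  in stage one and excluded (with a logged count) before stage two. Pairs
  whose profile becomes constant after exclusion get `NA`, never an
  imputed value.
- Results are clamped to $[-1,1]$ and symmetrized
  ($S \leftarrow (S+S^\top)/2$) to remove float noise; the diagonal is set
  to 1 by construction.
- Correctness is maintained at desk scale (≤ ~3,000 genes, where the
  $G \times G$ product is cheap); no blocking/streaming is attempted
  beyond that.

### Signatures, violins, embedding

The *network signature* of a query is every gene with
$S[\text{query},\cdot] \ge 0.7$ — the query itself included, since its
self-similarity is 1 and the definition makes no exclusion. 0.7 is the
conventional tight-signature cut and is a parameter. Members are sorted by
score, ties broken lexicographically, so output order is deterministic.

`signature_distribution()` returns a test gene's similarities to all
signature members with median/quartile/range summaries — the numbers
behind a violin comparison. `signature_overlap()` adds Jaccard and
overlap-coefficient metrics, an explicit quantification of what violins
show visually (no standard numeric definition of "violin overlap" exists,
so both classical set metrics are reported).

`embed_networks()` feeds each gene's full similarity row to UMAP
(`uwot`). Defaults `n_neighbors = 15`, `min_dist = 0.1`, Euclidean metric,
seed 42 — standard UMAP defaults, all recorded in the result, since no
parameter set is canonical for this use. Single-threaded SGD keeps
coordinates bit-reproducible for a given seed.

### What the violin control actually shows

On synthetic data with a planted module under TPM closure, a background
gene's violin median against the module signature is not merely below the
0.7 threshold — it is strongly *negative* (around −0.7). This is the
compositional closure effect: the module's shared factor moves the column
totals, so background genes acquire a small systematic anticorrelation
with module genes, and the profile correlation *concentrates* that
systematic structure into a large negative similarity. The negative
control therefore separates even more sharply than a "near zero" intuition
suggests. On real data, where no gene block dominates the total, the
effect is far weaker. The planted-module tests assert the direction and
the threshold (background median < 0.7 in 20/20 replicates; module recall
≥ 7/8 in ≥ 18/20), not a "near zero" value.

## Preranked enrichment

`rank_profile()` builds the query's association profile: per cohort, the
correlation of the query with every gene common to all cohorts, averaged
per gene across cohorts, sorted descending with lexicographic
tie-breaking. The alternative construction — ranking genes by mean
expression across cohorts, with no reference to the query — is also
implemented (`profile_mode = "mean_expression"`). Both readings of "a
profile obtained by averaging across datasets" are defensible; the
correlation profile is the default because it is the one that measures
association *with the query*, which is what the enrichment question asks.
Neither is asserted to be "the" published construction.

`enrichment_score()` is the weighted Kolmogorov–Smirnov running sum: hits
add $|s|^p$ normalized by the set's total weight ($p = 1$ by default, the
standard), misses subtract $1/(N-N_h)$, and the ES is the
maximum-magnitude deviation. The implementation is held to $10^{-12}$
against a step-by-step oracle on every 3-gene subset of a 10-gene list,
and cross-checked against `fgsea::calcGseaStat` to $10^{-10}$.

The null in `nes_and_fdr()` is **gene-label permutation**: random sets of
the same size drawn from the profile's universe. Preranked input has no
sample phenotype to permute, so this is the only available null. NES
divides ES by the mean magnitude of same-sign null ES (per set size);
nominal p is the plain same-sign tail fraction; FDR q is the classical
ratio of null-to-observed NES tail fractions, clipped to $[0,1]$. With a
fixed seed, every number is reproducible. Calibration is tested: on a
structureless profile, ~5% of random sets reach p ≤ 0.05; on a planted
module (ρ = 0.9), the true set clears NES ≥ 1.4 with q ≤ 0.05 in ≥ 18/20
replicates at 1000 permutations. The 1.4 cutoff in `filter_results()` is
the conventional tabulation threshold for oncogenic-signature scans and is
a parameter, not a constant.

One property worth recording: "promoting a hit never lowers a positive
ES" is a theorem only for the *unweighted* statistic ($p = 0$). With
$p = 1$ it is false — on scores $10..1$, the set at ranks $\{1,2,10\}$ has
ES $0.95$, but moving the rank-10 hit to rank 5 gives $0.76$, because the
promoted hit's larger weight dilutes the top hits' share of the total. The
property test therefore pins the $p = 0$ case, and the $p = 1$ case is
pinned by the exhaustive oracle instead.

If every hit in a set has score exactly zero (possible on degenerate
profiles), hit weights fall back to equal weights with a message rather
than dividing by zero.

## Single-cell positivity

A cell is positive for a marker iff its raw count exceeds zero — "absolute
count values", no normalization, no imputation. The floor is configurable
(`min_count`), and raising it can only shrink the positive set (tested).
Fractions are integer arithmetic with a single final division;
`percent_1dp` is the percent rounded to one decimal, the resolution such
figures are quoted at. Note a display subtlety: a quoted percent at one
decimal does not always pin down an integer count — 38.5% of 83 cells
would be 31.955, and the closest realizable count (32/83) displays as
38.6% under half-up rounding.

## The synthetic-data generator

The generator exists so every downstream stage has a ground truth:

- **Planted modules** use a latent-factor Gaussian copula:
  $z_g = \sqrt{\rho}\, f + \sqrt{1-\rho}\,\varepsilon_g$ on the log scale,
  then $x_g = 2^{\mu + \sigma z_g}$. This controls the target correlation
  ρ and the heavy-tailed (log-normal) marginal *independently* — a direct
  multivariate-normal construction on the raw scale could not hold both.
  The default log-scale SD (0.5) is modest, so exponentiation attenuates
  the realized Pearson correlation only slightly; the Monte-Carlo test
  (20 replicates at n = 500) bounds the mean deviation from ρ below 0.05.
- **Background genes** are independent log-normals with log2-means drawn
  uniformly on [1, 7] — roughly the dynamic range of bulk expression. The
  default background correlation is exactly zero *on the latent scale*;
  after TPM closure a small compositional dependence appears, as it does
  in real TPM data.
- **Units**: TPM columns are rescaled to $10^6$, RSEM fractions to 1, and
  FPKM columns are multiplied by log-normal per-sample depth factors so
  that FPKM input genuinely exercises the conversion step.
- **Single-cell counts**: detection is Bernoulli per gene and cell, and a
  detected entry is $1 + \mathrm{Poisson}(\lambda - 1)$ — so "detected"
  means *exactly* count > 0 and the positivity rule has no edge cases. The
  per-gene positive fraction is unbiased for the specified detection
  fraction.
- **Gene sets**: one set per planted module (its exact member list) plus
  uniform random decoys — a ground-truth stand-in for an
  oncogenic-signature collection.

Deliberately **not** emulated: copy-number structure, tumor purity,
batch/platform effects beyond unit heterogeneity, mean–variance coupling
of counts, doublets or ambient RNA. Passing tests therefore demonstrate
that the algorithms recover the statistical structure they assume, not
that any biological claim about real cohorts is reproduced; real-data
conclusions still require the real cohorts.

## Problem sizes and determinism

The test-suite fixtures are sized for a laptop: planted cohorts of 48–68
genes × 500 samples, similarity oracles up to 30 genes × 50 samples,
enrichment at 1000 permutations over universes of 68–300 genes, and
single-cell recovery at 10,000 cells. Every stochastic step flows through
an explicit seed (generators carry one in their spec; permutation and
bootstrap functions take one), and each generator is a pure function of
spec + seed, so all reported numbers are bit-reproducible. The
`scripts/acceptance.R` entry point regenerates all headline quantities
from a single command-line seed.

## Known limitations

- The similarity matrix is dense $G \times G$; at the ~19k-gene scale of
  a full transcriptome it requires the corresponding memory (and the
  closed-form identity still applies), but this package only asserts
  correctness at desk scale.
- Cross-cohort pooling without batch correction confounds between-cohort
  mean shifts with correlation; for that reason per-cohort correlation
  (then averaging) is used for profiles, and within-cohort samples for
  marker-independence checks. No batch correction is performed anywhere.
- Fisher's odds ratio is reported as the sample odds ratio $(ad)/(bc)$,
  not the conditional MLE; the p-value is the standard "sum of
  probabilities ≤ observed" two-sided definition.
- `percent_1dp` uses R's round-half-even at the margin (see the 38.5 vs
  38.6 note above); the exact fraction is always reported alongside.
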