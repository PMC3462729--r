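---
title: "Measuring gene-set consistency in expression compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gene-set consistency in expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsconsistency)
```

## The problem

Most statistical analyses of expression data lean on *gene sets*: named
groups of genes sharing an annotation (a GO term, a KEGG map, a predicted
operon, a SEED subsystem, scenario or path, or any user-defined grouping).
Set-level methods — differential-expression gene-set analysis, on/off
calling, clustering, co-expression network inference — all implicitly assume
the genes in a set behave similarly. When they do not, the set-level signal
is diluted and statistical power is lost. A natural question, for any
annotation source, is therefore: *how consistently do the genes of its sets
actually behave across a compendium of arrays?*

gsconsistency quantifies this with seven per-set metrics, each tied to one
of the three ways expression data is commonly analyzed, and provides the
comparison machinery to contrast annotation sources across set sizes and
organisms, plus a synthetic compendium generator with an analytic
ground-truth so the whole pipeline is testable without external data.

All expression input is assumed to be normalized, log2-scale values (the
RMA output convention), genes in rows, arrays in columns. The package never
re-logs.

## The seven metrics

Write $e_{k,i}$ for the log2 expression of gene $i$ on array $k$, $n$ for
the number of set members with expression data, and $P$ for the number of
arrays.

**Differential expression spread.** For an array pair $(k, l)$, the
differential values $d_i = e_{k,i} - e_{l,i}$ are log ratios; their sample
standard deviation over the set, $s_{N,(k,l)}$, measures how much the set's
genes disagree about the contrast between the two arrays. `s_mean_diff` and
`s_median_diff` are the mean and median of $s_{N,(k,l)}$ over array pairs.
Smaller is more consistent. Because compendia can have hundreds of arrays
(hundreds of thousands of pairs), the pair set is subsampled: by default 100
distinct unordered pairs, drawn uniformly without replacement, one shared
sample per matrix. When $P(P-1)/2 \le 100$ the enumeration is exhaustive and
flagged as such. Sampling without replacement keeps the estimator a plain
mean over a uniform subset, hence unbiased for the exhaustive value; the
package's tests verify this calibration directly.

**Absolute expression spread.** For each array $k$, $s_{N,k}$ is the sample
standard deviation of the $n$ member values on that array; `s_mean_exp` and
`s_median_exp` summarize over all $P$ arrays (no subsampling — one value per
array is cheap). Small values mean the members sit at similar levels, the
property exploited by on/off calling and rank-ordered absolute-expression
analyses. Note that a set can be perfectly co-regulated yet have large
absolute spread, if members track each other at different baseline levels;
the two metric classes are deliberately not redundant.

**Pairwise correlation.** `corr_mean` and `corr_median` summarize the
Pearson correlation $r_{i,j}$ over all $\binom{n}{2}$ member pairs, computed
across all arrays. Larger is more consistent. Sets with more than 50
measured genes are first reduced to a seeded uniform subsample of 50 genes;
one subsample is shared by both summaries. A zero-variance gene has no
defined correlation with anything, so pairs involving one are excluded; if
every pair is excluded the summaries are flagged missing (`NA`), never
imputed.

**PC1 variance fraction.** `pc1` treats the members as variables and the
arrays as observations, forms the $n \times n$ sample covariance matrix
(genes centered, not scaled), and reports $\lambda_1 / \sum_j \lambda_j$ —
the fraction of total variance captured by the first principal component. It
rewards sets driven by a *single* shared profile, not merely high average
pairwise correlation. It is computed on the full set, with no gene
subsampling by default; a cap exists for pathologically large sets but is
off. When defined, $1/n \le \mathrm{pc1} \le 1$; a set with zero total
variance has no defined PC1.

Conventions shared by all metrics: sample standard deviations and
covariances use the $n-1$ denominator; the median of an even-length list is
the mean of the two central values; pair orientation is fixed $k < l$ (the
SD is orientation-invariant regardless); metrics are carried at full double
precision and rounded only for display.

## Estimator reproducibility

All randomness flows from one master integer seed. The array-pair sample is
drawn once per matrix. Each set's 50-gene subsample uses a stream seeded
from the master seed plus a stable polynomial hash of `source:set_id`, so
adding or removing sets never changes another set's subsample, and a records
table is byte-identical across reruns. Seeded draws are isolated from the
caller's RNG state.

## Building and filtering collections

For hierarchy-organized vocabularies (the GO's three DAGs being the model
case), `propagate_hierarchy()` builds each term's set as the union of its
direct annotations and those of all descendant terms, taking the hierarchy
as a child-to-parent edge list. Parent sets are therefore supersets of their
children's. Terms whose propagated set is empty are omitted. A parent and
child can end up with identical gene sets; both are kept — deduplication
would silently change set counts per source, which the comparison analyses
report. Cycles are rejected with the offending terms named.

`filter_to_matrix()` applies the defining eligibility rule: a set is
analyzed only if at least two of its genes have expression data, after
intersecting with the matrix's gene universe. `restrict_to_universe()`
supports reduced analyses (e.g. "only sets containing metabolic-pathway
genes"): by default it is a *membership* filter — a set survives if it
intersects the universe, and its contents are untouched, because the
reduction narrows which sets are analyzed, not what they contain. An
explicit `trim = TRUE` intersects instead. `overlap_report()` quantifies how
much a source's sets share genes (percent of covered genes in two or more
sets) and how much of the measured genome a source covers; the coverage
denominator is the measured-gene universe, since unmeasured genes cannot
contribute to any metric.

## Comparing sources

`summarize_by_source()` averages each metric over all sets within a source
and ranks sources per metric, direction-aware: rank 1 is the smallest mean
for spread metrics and the largest for correlation/PC1 metrics. Ranks use
full-precision means; exact ties (measure zero on real data) break
alphabetically for determinism. `metric_correlations()` gives the 7×7
Pearson table across sets, complete-case so every entry shares one row
basis. Mean/median variants of a class are near-collinear on symmetric
data and diverge under heavy tails — the generator's t-residual option
exists to exercise exactly that.

`size_stratified_profile()` reports per-source mean metric values across
set-size bins, suppressing (source, bin) cells with fewer than 20 sets so
sparse strata do not produce noisy means. The default binning uses exact
sizes 2–20 and then (20,30], (30,50], (50,100], (100,∞): set-size
distributions are heavily concentrated at small sizes, where exact-size
resolution is informative, and long-tailed above, where only coarse bins
retain 20 sets. The binning is configurable.

`fit_nested_models()` quantifies how much of a metric's variation is
attributable to source once set size and organism are controlled: four OLS
models — source; + log10 size; + organism; + all interactions — with
treatment-coded factors. $r^2 = 1 - SSE/SST$ (defined as 0 for a constant
response) is non-decreasing across the nest, and the model-4 gain over
model 3 measures combination-specific structure beyond main effects.
Per-coefficient t-test p-values are reported raw, with no multiplicity
adjustment — the fits are descriptive decompositions, not a screening
procedure. With a single organism in the records, organism terms are
dropped with a warning rather than failing on a rank-deficient design.
`size_variance_decomposition()` answers the complementary bookkeeping
question — whether set size is driven by source or by organism — via two
one-way regressions of log10 size.

## The synthetic generator

`generate_synthetic()` draws each set from a single-factor Gaussian block
model:

$$ g_i(a) = \mu_i + \lambda f_s(a) + \varepsilon_i(a), \qquad
   f_s \sim N(0,1), \; \varepsilon \sim (0, \sigma^2), $$

with one latent factor $f_s$ per set and the loading chosen from the target
within-set correlation $\rho$ by the closed form
$\lambda^2 / (\lambda^2 + \sigma^2) = \rho$. A single factor rather than an
arbitrary correlation matrix is a deliberate choice: the closed form makes
$\rho$ an analytic oracle — the expected pairwise Pearson correlation *and*
the expected behavior of PC1 are known, so parameter-recovery tests have an
exact target rather than a simulated one.

Defaults, chosen once to emulate an RMA-summarized bacterial compendium:
per-gene baselines $\mu_i$ around a grand mean of 7 log2 units with SD 2
across genes (typical spread of RMA baseline levels), residual SD
$\sigma = 0.5$ across arrays, 40 arrays, and three sources whose target
correlations (0.9 / 0.5 / 0.1) mirror the ordering observed between
operon-derived, pathway-derived and broad-ontology sets in real compendia.
`offset_spread` adds extra within-set baseline dispersion, reproducing the
"co-regulated but at different levels" scenario: it inflates the absolute
spread metrics while leaving correlations untouched in expectation.
`noise_df` switches residuals to a variance-rescaled t distribution (the
rescaling preserves the $\rho$ closed form) to create the heavy tails that
separate mean- from median-based metrics. An optional per-array shift
emulates condition structure; within-array spread metrics are invariant to
it by construction.

What the generator does **not** emulate: probe-level artifacts and
normalization residue, intensity-dependent variance, batch or platform
structure, overlapping and nested sets as real ontologies produce them
(overlap is grafted on separately by `make_overlapping_collection()`), and
non-Gaussian marginal shapes beyond the symmetric-t option. Passing tests
on synthetic data therefore demonstrate correctness of the estimators and
the qualitative behavior of the metrics under controlled correlation
structure — not that any particular real annotation source will score well.

## Test and verification scale

The package's tests verify every metric against independent explicit-loop
brute-force implementations (tolerance $10^{-10}$) on random fixtures of
2–8 genes by 3–20 arrays, sizes at which exhaustive enumeration is exact
and fast. Calibration checks run at moderate scale chosen for tight Monte
Carlo error at interactive runtimes: 200 sets of 10 genes on 40 arrays for
correlation recovery at each $\rho$; 20 seeded replicates for source-rank
agreement; 50 seeds of 100-pair samples against the exhaustive 435 pairs of
a 30-array compendium; 150 independent $\rho = 0.9$ blocks aggregated into
sets of 10–80 genes for the size-dilution trend.

## Numerical notes

Per-column standard deviations use explicit two-pass centering, stable for
near-constant columns. PC1 uses the Gram-matrix identity — the nonzero
eigenvalues of the $n \times n$ covariance equal those of the $P \times P$
Gram matrix of centered data — computing the eigendecomposition on the
smaller side, and divides by the trace (exactly $\sum \lambda$) rather than
a re-summed spectrum. Degenerate inputs resolve as: all-constant set → PC1
and correlations `NA`, spreads 0; single zero-variance member → excluded
pairwise from correlations only; `NA` metrics propagate through summaries
by per-metric exclusion (and complete-case for the 7×7 table), never as
zeros.

## Limitations

Consistency is a statistical-power proxy, not biological truth: a source
can score high by grouping trivially co-transcribed genes while carrying
little functional information, and a functionally coherent set can score
low on absolute spread simply because its members express at different
levels. Cross-source conclusions require the sources to be evaluated on the
same organism and matrix — the package shares one pair sample per matrix
for exactly that reason — and metric values are not comparable across
matrices with very different array counts without attention to the
correlation estimator's $P$-dependent bias.
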