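---
title: "Methods: from germplasm screening to candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from germplasm screening to candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipnet)
```

`ipnet` chains six analysis stages into a pipeline that nominates
candidate genes for seed inositol phosphate (IP) metabolism. This
vignette explains the model behind each stage, the tunable parameters
and why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and the design decisions taken where
the methodology was genuinely open.

## 1. Germplasm screening with the Q statistic

For two inbred lines with seed phytic acid phosphorus contents $x_i$ and
$x_j$ (mg per g of seed), the contrast statistic is

$$Q = \left|\log_2 (x_i / x_j)\right|.$$

$Q$ is dimensionless, symmetric, and invariant to rescaling both
contents — so unit changes or a common environmental shift cancel. The
screening threshold $Q > 0.58 \approx \log_2 1.5$ demands at least a
1.5-fold contrast.

*Stability across environments.* The screen requires (a) $Q$ above the
threshold in every environment where both lines were measured, and (b) a
one-sample, one-sided t-test of the per-environment $Q$ values against
the threshold with $p < 0.05$. Interpretation (b) is a design decision:
the verbal description of the stability test admits several readings
(test across environments, against a threshold, or between raw
contents); we test whether the mean $Q$ significantly exceeds the
cutoff, which combines naturally with the per-environment gate and
reproduces the intended outcome — pairs with a consistent ~2-fold
contrast in all environments are retained, unstable or weak contrasts
are not. When the per-environment $Q$ values are exactly constant the t
statistic is undefined; the test degenerates to the threshold comparison
($p$ of 0 or 1), a documented tie-break rather than an error.

Pairs are evaluated either over an explicit candidate pairing (e.g. a
declared high-IP6 × low-IP6 partition) or over all unordered pairs; the
quadratic all-pairs enumeration warns above 1000 lines. No outlier
removal is applied: any rule for discarding "abnormal" content values is
a curation step upstream of this package.

## 2. Expression statistics

**RPKM.** $\mathrm{RPKM}_{gs} = c_{gs} / (m_s \cdot \ell_g)$ with
$c_{gs}$ the read count, $m_s$ the sample's mapped reads in millions and
$\ell_g$ the exon length in kilobases. The formula is linear in counts,
which the tests exercise by splitting a library in half.

**Gene filter.** Genes with more than `max_bad = 3` entries that are
missing *or zero* are removed (strict inequality: exactly three bad
entries survive). Missing and zero are treated identically because a
zero in these tables is typically a non-measurement.

**Differential expression.** The decision gate is fold change ≥ 2 and
Benjamini–Hochberg FDR < 0.01. The p-value comes from a two-sided exact
negative-binomial test on the two group sums, conditional on their
total: group sums are modelled as NB with means scaled by the summed
size factors and size $n_j/\alpha$, where the gene-wise dispersion
$\alpha$ is a pooled method-of-moments estimate
$(\widehat{\mathrm{var}} - \bar q)/\bar q^2$ floored at $10^{-8}$ (the
floor keeps the Poisson limit numerically stable). This is a deliberate
simplification of shrinkage-based DE machinery: with the FC/FDR gate
doing the decision work, the test only needs to be approximately
calibrated, which the null suite verifies (≤ 2% of genes called at
FDR < 0.01 under the global null). Fold changes use library-size
normalised group means with a symmetric pseudo-count of 0.5. Library
size is the total mapped count — consistent with the RPKM definition —
rather than median-of-ratios.

## 3. Weighted co-expression network

**Correlation.** Spearman by default (Pearson on within-gene average
ranks), computed blockwise with `max_block_size = 3500` genes per block
for memory control; blockwise and whole-matrix results are identical to
machine precision (tested). Zero-variance genes are excluded with a
warning. At least 4 samples are required; below that rank correlations
are degenerate.

**Soft threshold.** Unsigned adjacency $a_{ij} = |\rho_{ij}|^\beta$.
Two ways of choosing $\beta$ are provided:

* `pick_soft_threshold()` — the scale-free criterion: smallest candidate
  $\beta$ whose connectivity distribution fits a power law with
  $R^2 \ge 0.8$ in a log–log regression over 10 connectivity bins,
  with the sign convention that an *increasing* fit counts as zero
  (a scale-free degree distribution must decay). If no candidate
  reaches the target the conventional power 6 is returned with a
  warning.
* `default_beta()` — the sample-size rule of thumb for unsigned
  networks: 9 below 20 samples, 8 for 20–30, 7 for 30–40, 6 above 40.

The recovery benchmarks and the pipeline demonstration use
`default_beta()`. The reason is structural: expression with a few
strongly co-regulated modules over a noise background is *not*
scale-free, and the $R^2 \ge 0.8$ criterion is then either unreachable
or first reached at extreme powers (β ≈ 16–18 in our benchmarks) that
suppress genuine module adjacency along with the noise. The sample-size
convention reflects what the criterion is actually for — lifting the
adjacency of real co-expression above the correlation noise floor,
which rises as samples get scarce — and recovers planted modules
reliably. Both routes remain available; `run_pipeline()` accepts
`beta = "auto"` or any fixed power.

**Topological overlap and modules.**
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i,k_j) + 1 - a_{ij})$ with zero-diagonal adjacency and
$k_i = \sum_u a_{iu}$; the unit diagonal is set afterwards. Modules are
branches of an average-linkage tree on $1-\mathrm{TOM}$ cut statically
at `cut_height = 0.99` with `min_module_size = 30`; smaller branches are
"grey" (unassigned). The static cut is a deliberate simplification of
the dynamic tree-cut family: deterministic, easy to reason about, and
adequate for well-separated modules — at the price of occasionally
admitting background genes whose chance correlation with a module
survives the soft threshold (visible at small sample sizes; a sharper
$\beta$ suppresses it). Exact ties in the dissimilarity can leave
numerically non-monotone merge heights; these are made monotone before
cutting. Modules are named from a fixed colour vocabulary in decreasing
size order (ties broken by lowest gene index), so names are
deterministic.

**Eigengenes and metabolite selection.** A module eigengene is the
first left singular vector of the gene-standardised module submatrix,
scaled to unit variance and oriented so it correlates non-negatively
with the module's mean profile (sign conventions of PCA are otherwise
arbitrary). Module–metabolite records use Pearson correlation with the
t approximation $t = r\sqrt{(n-2)/(1-r^2)}$, $df = n-2$; a record is
selected iff $|r| > 0.8$ **and** $p < 0.01$, both strict — a
correlation of exactly 0.8 is not selected, which the bundled
nine-record example exercises (it yields exactly six distinct modules).
Metabolite samples are aligned to expression samples by explicit
`sample_id` matching; mismatches are an error naming the offending ids,
never a silent positional join.

**Network export.** Edges are exported where the similarity (TOM)
*strictly exceeds* `export_threshold = 0.5` — the "network output
threshold". The same strict rule defines "guide-correlated genes" in
the candidate screen, keeping the two uses consistent.

## 4. Power-graph compression

A power node is a gene set; a power edge $(S,T)$ asserts that every
$S$–$T$ pair is an original edge (for $S = T$, that $S$ is a clique).
Compression is greedy: candidate sets are all branches of an
average-linkage clustering of the nodes by Jaccard similarity of their
neighbourhoods; among candidate set pairs forming complete bicliques
(or sets forming cliques), the one abstracting the most not-yet-covered
edges is committed, subject to the power-node family remaining laminar
(pairwise disjoint or nested), until no candidate abstracts at least
two edges. Remaining edges stay residual. Exact minimum power graphs
are NP-hard; this greedy edge-coverage heuristic is deterministic (ties
broken by the lexicographically smallest combined gene set) and lossless
by construction — `pg_decompress()` reproduces the original edge set
exactly, which the test suite verifies on random and structured graphs.

The compression ratio is defined as the fraction of original edges
eliminated: $1 - (\#\text{power edges} + \#\text{residual edges}) /
\#\text{original edges}$ ($K_{5,5}$: $1 - 1/25 = 0.96$). Note that even
a path compresses (its internal star abstracts two edges, ratio 0.5);
only graphs in which no two edges share an abstractable pattern — e.g.
disjoint edges — have ratio 0. An optional `min_degree` pre-filter
removes low-connectivity nodes before compression; the default keeps
all nodes since no principled cutoff is available.

## 5. Candidate screening

Three mandatory principles, evaluated per non-guide gene:

1. **Shared hub** — some top-`k` hub (degree or Maximal Clique
   Centrality, $\mathrm{MCC}(v)=\sum_{C \ni v}(|C|-1)!$ over maximal
   cliques) is adjacent to both the gene and at least one guide. "Key
   node" has no formal definition in the source methodology; common
   adjacency to a top hub (default `top_hubs = 10`, degree) is the
   operationalisation here.
2. **Distance** — BFS hop distance to the nearest guide strictly
   below 4.
3. **Power node** — the gene shares a *committed power node* with at
   least one other non-guide gene whose edge weight to a guide strictly
   exceeds the export threshold. We deliberately read "co-regulated
   genes … in power nodes" as co-membership in a committed set: the
   looser cross-endpoint reading (gene in $S$, correlate in $T$)
   collapses into the shared-hub criterion whenever hub stars compress,
   and would leave the third principle with no independent content.

Passing genes are ranked by bonus count (preferred domain among
IPR011611 / IPR005337 / IPR027417; differential expression) descending,
then guide distance ascending, then maximum edge weight to a guide
descending, then gene id — a total order, so screening is deterministic.
Bonuses are preferences, not gates, mirroring the "considered optimal
if" role they play in the methodology.

Note an interaction worth knowing: a gene satisfying the shared-hub
principle is automatically within distance 2 of a guide, so the
distance gate only excludes genes independently of the hub gate when
hub and distance evidence disagree — the screening benchmark therefore
plants decoys that violate one principle while satisfying the others as
far as the geometry allows.

## 6. miRNA target scoring

Duplexes are scored per aligned position (miRNA position $i$ against
site position $L+1-i$, both sequences 5'→3'): Watson–Crick match 0, G:U
wobble 0.5, any other mismatch 1, penalties doubled at miRNA positions
2–13. A target is predicted when the score is *strictly* below 4: two
core mismatches score exactly $2\times(1\times 2)=4$ and are rejected.
The additive penalty scheme is the plant-tool convention; the
alternative "ratio" reading of match/mismatch scoring is incompatible
with an integer-4 threshold and was not adopted. Only ungapped windows
are scored (`scan_targets()` slides the miRNA over every transcript
window; coordinates are 0-based half-open); gapped alignment is out of
scope. T and U are interchangeable on input. Expression
anticorrelation between miRNA and target is reported as plain Pearson r
with no gate — supporting evidence, not a filter.

## The synthetic-data generators

All generators are pure functions of their arguments including the
seed.

* **Expression** uses a single latent factor per module:
  $x_g = b + a f_m + \sqrt{1-a^2}\,\varepsilon$, $\varepsilon$ i.i.d.
  standard normal, factor standardised. This is the minimal generator
  of block-correlated expression and makes eigengene recovery
  analytically interpretable (the eigengene estimates $f_m$). The
  baseline $b = 8$ (log2-like units) keeps values positive in practice.
  Defaults: 2 genotypes × 3 stages × 2 replicates = 12 samples — the
  replicate count is a required, defaulted parameter because the
  emulated design does not pin it down.
* **Metabolites** are generated against the module *factors*, not the
  estimated eigengenes, so recovery error honestly includes eigengene
  estimation error. Negative target correlations are allowed.
* **Counts** are negative binomial with gene means log-uniform on
  [10, 1000] (spanning the dynamic range without zero-inflation
  machinery); `dispersion = 0` is the Poisson limit. Planted DE genes
  multiply the group-2 mean by the fold change.
* **Germplasm panels** plant high/low line pairs differing by
  $\log_2(\text{ratio})$ with per-line per-environment log2 noise, plus
  a shared environment effect that cancels in Q.
* **miRNA duplexes** start from an exact reverse complement and apply a
  controlled number of core mismatches, tail mismatches and tail G:U
  wobbles, recording the implied score as truth.
* **The candidate benchmark** is a fixed topology (two bicliques, two
  hubs, a guide, one true candidate, per-principle decoys and a
  bonus-free competitor) with seed-jittered labels and weights.
* **The pipeline preset** (`simulate_pipeline_inputs()`) uses three
  40-gene modules at loading 0.98. The high loading is deliberate: the
  export threshold 0.5 is a fixed constant of the method, and the
  preset must emulate the regime in which that constant is meaningful —
  module networks dense at TOM > 0.5, as in the tightly co-regulated
  printed sub-networks the pipeline is patterned on. Metabolites track
  module factors at $\pm 0.95$, within the published range of
  module–metabolite correlations.

What the generators do **not** emulate: library-size artefacts and
batch effects, zero inflation, overlapping or nested modules,
correlated background structure, genotype×environment interaction
beyond a shared environment shift, and gapped miRNA duplexes. Passing
recovery tests therefore demonstrates correctness of the algorithms
under their stated model, not robustness to every pathology of real
kernel data.

## Problem sizes and numerical choices

The validation suites run at desk scale, chosen to finish in minutes
while keeping every estimate stable: module recovery uses 5 modules ×
50 genes + 350 background over 24 samples (5 seeds); module–metabolite
recovery 2 modules over 20 samples (10 seeds); DE calibration 2000
genes × 10 null seeds; power-graph round-trips 100 random 30-node
graphs plus structured families; germplasm screening 20 seeded panels.
Correlations are clamped to [−1, 1] before powering; TOM is clamped to
[0, 1]; dispersion estimates are floored at $10^{-8}$; merge heights
are made monotone before static cutting; all rank ties use average
ranks; all ordering ties break lexicographically.

## Known limitations

* The static tree cut admits hitchhiker background genes near the cut
  height at small sample sizes (see §3); dynamic tree cutting and
  eigengene-based module merging are out of scope.
* The exact NB test enumerates the conditional distribution of the
  group sums; for very deep libraries (sums ≫ 10^5) a normal
  approximation would be preferable. At the package's intended desk
  scale enumeration is exact and fast.
* Greedy power-graph compression is near-optimal, not optimal; its
  ratios are data-dependent and no external ratio is asserted.
* Candidate screening operates on the thresholded export network; hop
  distances on the full correlation network would differ. This choice
  is exposed rather than hidden: the screen takes whatever edge list it
  is given.
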