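---
title: "Models and methods behind methmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmir)
```

# Scope

`methmir` implements an integrated epigenomic comparison of two donor
groups (cases labelled `AD`, controls `HC`) in a sorted T-cell
population: per-CpG differential DNA methylation on the M-value scale
with empirical-Bayes variance moderation, collapse of nearby probes into
differentially methylated regions (DMRs), differential miRNA expression,
an integrated miRNA–CpG Spearman correlation network with community
detection and antagonistic-community identification, methylation–mRNA
coupling, comparative-Ct qPCR statistics, and gene-set
over-representation. A synthetic-data generator with a planted truth
record allows every stage to be benchmarked for recovery.

The package starts from normalized matrices. Raw-array processing (IDAT
parsing, within-array normalization, probe-chemistry correction) is out
of scope; SNP-overlap flags are an input annotation column, never
computed.

# Differential analysis

Methylation is analysed on the M scale, $M = \log_2\beta/(1-\beta)$,
where variances are closer to constant across the methylation range;
$M > 1$ indicates a methylated site and $M < -1$ a demethylated one.
`beta_to_m()` errors outside $(0,1)$ by default; clipping at
$\varepsilon = 10^{-6}$ is opt-in, because silently clipped boundary
values usually indicate an upstream problem.

Each feature $g$ (CpG or miRNA) is fit by ordinary least squares under
`y ~ group + age`, with `HC` the reference level, so the group
coefficient is the case-minus-control difference (`logfc`). The
moderated statistic follows the standard hierarchical model: residual
variances $s_g^2$ on $d_g$ degrees of freedom are shrunk toward a prior
$(d_0, s_0^2)$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
t_g = \frac{\widehat\beta_g}{\tilde s_g \sqrt{v_g}},$$

with $v_g$ the unscaled variance of the contrast and $t_g$ referred to a
t distribution on $d_0 + d_g$ df. The prior is estimated by moment
matching on $\log s_g^2$: the mean and excess variance of
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ determine $s_0^2$ and
$d_0$ through a Newton inversion of the trigamma function. When the
empirical spread of $e_g$ does not exceed its chi-square sampling floor
the prior df is infinite and all features share $s_0^2$; estimates above
$10^6$ are treated as infinite. At $d_0 = 0$ the procedure reduces
exactly to the classical covariate-adjusted t-test, which the test suite
verifies to $10^{-10}$, and the whole moderation path is cross-checked
against an independent reference implementation.

Two modelling notes:

* **Subject blocking.** A `subject` term is only honored when it is
  estimable — i.e. when at least one subject contributes samples to more
  than one design cell. With one sample per subject (the single-cell-
  population case) the term is confounded with group and is dropped with
  a warning rather than silently absorbed.
* **Age** is carried as a covariate by default. The generator simulates
  ages Uniform(20, 60) with a zero true slope, so the covariate is
  exercised without being confounded with group.

Multiple testing uses Benjamini–Hochberg step-up adjustment
(`bh_adjust()`, delegating to `stats::p.adjust`), applied separately
within each feature family (methylation; miRNA), mirroring per-platform
analyses. Features with missing values are fitted on their complete
samples; a feature whose residual df falls below 1 is reported untested
rather than imputed.

# DMR collapse

Probes are chained per chromosome by single linkage: consecutive sorted
probes join one cluster iff their gap is at most `maxgap` (default
500 bp). The distance rule is the only clustering criterion, so the
result is deterministic and order-invariant; the suite checks it against
a brute-force connected-components oracle. Each cluster is scored with

* `mean_logfc`: unweighted mean probe effect,
* `p_region`: Stouffer combination of signed probe z-scores,
  $Z = \sum_i \mathrm{sign}(\mathrm{logfc}_i)\, z_i / \sqrt n$ with
  $z_i = \Phi^{-1}(1 - p_i/2)$,

so probes pulling in opposite directions cancel rather than reinforce
(clusters with opposite signs are additionally flagged heterogeneous;
Fisher's unsigned combination is selectable). BH correction runs across
all candidate clusters; called regions need `p_bh < alpha` and at least
`min_probes` probes (default 2). Coordinates are 1-based inclusive with
`width = max(pos) - min(pos) + 1`; conversion to 0-based half-open
intervals happens only in BED export. The 500 bp default is the
conventional array DMR gap and is consistent with the widths of the
bundled reference regions (up to 1910 bp across 23 probes); it is
exposed as a parameter because the underlying choice is not uniquely
determined.

# The integrated network

The network stage takes the full miRNA set plus the CpGs selected by the
differential FDR rule (`select_top_differential`, default BH < 0.1 —
the operational form of "top varying probes"). After removing
zero-variance features, all feature pairs receive a Spearman rank
correlation (average ranks for ties, pairwise-complete samples, at
least 5 shared samples), a two-sided p from the t approximation on
$n-2$ df, and a joint BH FDR over all tested pairs (one family, with no
stratification). Edges are retained at $|\rho| > 0.75$ and FDR
$< 0.001$; the community graph keeps only positive edges, weighted by
$\rho$, while the full signed table is kept for the antagonism scan.

Communities come from Leiden modularity optimization (igraph), with a
mandatory seed, resolution 1 by default, and five seeded restarts
keeping the highest-modularity partition — the local-moving phase is
stochastic and restarts guard against local optima. Determinism under a
fixed seed matters more here than matching any particular community
count. The suite requires the partition to reach the exhaustive-search
modularity maximum on a battery of graphs with up to 8 nodes, where
enumeration of all set partitions is feasible.

**Antagonistic communities.** For every community pair the scan
summarises all cross-community signed correlations (median $\rho$,
fraction negative) and flags a pair iff the median is at or below
−0.5 *and* a seeded node-label permutation test (default 1000 shuffles)
gives $p < 0.01$. The permutation null conditions on the partition
sizes and the observed correlation matrix. One degenerate case is worth
knowing: if the graph consists of *only* two perfectly mirrored
communities, most label shuffles also produce a cross-median of −1, so
the permutation p cannot become extreme and the flag is withheld — the
test needs at least one other community (or noise) to anchor the null.
This is intended behavior of a label-permutation test, not a defect of
the rule. The concrete median-plus-permutation rule is this package's
own operationalization of "antagonistic feature relationships"; the
threshold is exposed.

**Recapitulation.** Per community, the package counts members called
significantly up or down per layer and tests over-representation by a
one-sided hypergeometric test against the partitioned nodes of that
layer, BH-corrected over all (community, layer, direction) cells.

# Coupling and qPCR

Comparative-Ct quantities follow one convention throughout:
$\Delta C_t = C_t^{\mathrm{reference}} - C_t^{\mathrm{target}}$, so
larger $\Delta C_t$ means more transcript and fold change is
$2^{\Delta C_t}$; the same orientation is applied to the mRNA reference
gene. Group comparisons of $\Delta C_t$ use unpaired two-sided t-tests,
equal-variance by default (similar group sizes), Welch behind a flag.

The methylation–expression coupling reports a pooled Spearman
correlation, per-group Spearman correlations with BH adjustment over
the within-group family, and a per-group OLS regression
$\Delta C_t \sim M$ with slope ($\Delta C_t$ per M-unit), $R^2$, and
F-test p. Groups with fewer than 4 paired samples are marked
unavailable rather than fitted.

# Over-representation

Queries are unions of miRNA target genes (and, in community mode, genes
annotated to member CpGs, with slash-separated annotations split into
symbols). The test is the one-sided hypergeometric upper tail
*including* the observed overlap, against an explicit background —
defaulting to all possible targets plus CpG-annotated genes, never
silently the whole genome. Odds ratios use a Haldane 0.5 correction on
zero margins. Redundancy among significant sets is collapsed by a
greedy pass in ascending-p order (ties broken by set id): a set is kept
iff its member Jaccard similarity with every kept set is below 0.5.
This overlap-based rule deliberately replaces ontology-graph semantic
similarity and will differ from it on sets that are semantically close
but share few members.

# The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_study()` draws all
layers from one seed with per-stage sub-streams, so outputs are
bit-reproducible. What the defaults emulate, and why:

* **Design**: 10 cases vs 9 controls, male, ages Uniform(20, 60) with
  zero age effect; 2000 CpG probes (enough for stable variance-prior
  estimation and realistic multiplicity while keeping a full pipeline
  run in seconds) and 455 miRNAs, of which 10 are up- and 6
  down-regulated in cases.
* **Methylation baseline**: bimodal probe means around ±2 on the M
  scale (methylated/demethylated poles), residual noise sd 0.5.
* **Planted DMPs**: 30 singleton probes with signed effects drawn from
  |effect| in [0.46, 3.23] (the observed effect range on the M scale),
  75% hypomethylated in cases.
* **Planted DMRs**: 3 runs of 4 probes sharing one negative effect in
  [1.0, 2.0], placed at gaps below the 500 bp distance rule; background
  probes are spaced beyond the rule, so planted runs are the only
  multi-probe clusters by construction. Passing DMR tests therefore
  shows correct clustering and scoring, not robustness to accidental
  probe crowding.
* **Communities**: 4 latent standard-normal factors; members load with
  1.2 (±10%) and member noise sd 0.5, giving expected within-community
  Spearman correlations near 0.84, comfortably above the 0.75 edge
  rule. The designated pair (1, 2) is mirrored
  ($f_2 = -f_1 + \varepsilon$) and its factor carries a group shift of
  2, so members of community 1 are coordinately higher in cases, members
  of community 2 lower — the antagonistic pair recapitulates the group
  contrast, and its CpG members clear the FDR < 0.1 network filter. The
  up/down miRNAs are the miRNA members of this pair (plus an explicit
  log2 shift of ±1), which reproduces the observed pattern of one
  community containing all upregulated miRNAs.
* **Coupled probe**: one CpG is hypomethylated in cases
  (M ~ N(−2.2, 0.8) vs N(−0.8, 0.5)); within cases its gene's
  $\Delta C_t$ follows $a - 3M + \varepsilon$ with residual sd 0.4
  (design $R^2 \approx 0.97$, expected within-case Spearman near
  −0.95), while in controls $\Delta C_t$ is independent of M. Only 7
  controls carry qPCR values, emulating partial validation coverage.
  The slope and noise were set from the printed within-case targets
  (slope below −2.5, $R^2$ above 0.82, strongly negative rank
  correlation). A side effect of the steep slope is a wide case-group
  $\Delta C_t$ spread, so the two-group $\Delta C_t$ t-test on this
  gene is not reliably significant at these sample sizes.

What the generator does **not** emulate: probe-type chemistry, batch
and position effects, cell-composition heterogeneity, count-like miRNA
noise, or any dependence between the methylation noise and the mean.
The methylation noise model is Normal on the M scale — the standard
assumption behind moderated-t analyses, adopted here as an explicit
choice. Recovery results on this generator therefore demonstrate
algorithmic correctness under the stated model, not performance on raw
array data.

The truth record lists every planted quantity (DMP ids and effects, DMR
probe sets, miRNA directions, community assignment, the antagonistic
pair, the coupled probe), and `score_recovery()` turns a pipeline run
into sensitivity / false-discovery / Jaccard / adjusted-Rand /
flag-correctness metrics. When scoring antagonism flags, detected
communities are mapped to planted ones by majority membership; flagged
pairs involving clusters of planted differential features outside the
two factor communities are ignored rather than counted as errors,
because the shared group shift makes such pairs genuinely
anti-correlated.

# Numerical choices and degenerate inputs

* Zero-variance features are removed before rank-correlation (Spearman
  is undefined on constants); "null variance" means exactly zero, not
  near-zero.
* Correlations of ±1 get p = 0 under the t approximation.
* `estimate_prior` needs at least 10 positive residual variances and
  errors when all variances are zero; single-probe regions keep their
  probe's p; empty graphs yield empty partitions; empty queries skip
  enrichment.
* All seeds are plain 32-bit integers; every stochastic routine
  (generator, Leiden, permutations) takes an explicit seed.

# Known limitations

* DMR p-values assume independent probe statistics within a cluster;
  spatial correlation between neighboring probes would make Stouffer
  anticonservative. The bundled reference regions are reproduced as
  fixtures, not recomputed, since the underlying per-sample data are
  not public.
* The antagonism permutation test conditions on the detected partition
  and does not propagate community-detection uncertainty.
* The enrichment redundancy filter is member-overlap-based, not
  semantic.
* With ~19 samples, Spearman edge p-values from the t approximation are
  approximate; the joint FDR < 0.001 rule keeps the retained graph
  conservative.
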