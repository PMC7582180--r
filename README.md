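# methmir

Integrated differential DNA methylation and miRNA network analysis for
two-group comparisons of sorted T-cell populations — written for
epigenomics analysts who have normalized feature-by-sample matrices (CpG
M-values or β-values, log2 miRNA expression), a sample sheet, and probe
annotation, and who want a reproducible, testable pipeline from
differential calling through network integration, with a synthetic
benchmark that knows its own ground truth.

## What it computes

**Differential methylation / expression.** Per feature *g*, an OLS fit of
`y ~ group + age` (reference level `HC`, so `logfc` is the AD − HC
difference on the analysis scale) with empirical-Bayes variance
moderation: residual variances *s²g* on *dg* df are shrunk toward a
moment-matched prior (*d₀*, *s₀²*),

    s̃²g = (d₀·s₀² + dg·s²g) / (d₀ + dg),   tg = logfc / (s̃g·√vg),

with *tg* on *d₀ + dg* df and Benjamini–Hochberg control per feature
family. At *d₀* = 0 this is exactly the classical covariate-adjusted
t-test.

**DMRs.** Probes chained per chromosome at gaps ≤ 500 bp (single
linkage), each cluster scored by mean `logfc` and a signed Stouffer
combination of probe z-scores, BH-corrected across candidate regions.

**Network.** All-pairs Spearman correlations (tie-aware, pairwise
complete) over the full miRNA set plus the CpGs at differential
FDR < 0.1; edges kept at |ρ| > 0.75 and joint FDR < 0.001; Leiden
modularity communities on the positive graph (seeded, with restarts);
antagonistic community pairs flagged when the median signed
cross-community ρ ≤ −0.5 with a permutation p < 0.01; per-community
hypergeometric enrichment of up/down differential members.

**Integration.** Comparative-Ct statistics (ΔCt = reference − target;
fold = 2^ΔCt; unpaired t-tests) and per-group methylation–expression
coupling: Spearman correlations and OLS `ΔCt ~ M` with slope, R², and
F-test p.

**Enrichment.** One-sided hypergeometric over-representation of
miRNA-target / CpG-gene queries against an explicit background, with a
greedy Jaccard redundancy collapse.

**Synthetic benchmark.** `sim_config()` / `simulate_study()` generate the
full study (10 AD vs 9 HC; 2000 CpGs; 455 miRNAs with 10 up / 6 down;
planted DMPs spanning |logfc| 0.46–3.23; 3 planted DMRs; 4 latent
communities with one group-linked antagonistic pair; one
expression-coupled CpG) plus a truth record, and `score_recovery()`
measures how much of it the pipeline got back.

The package also bundles reference tables of 49 differentially
methylated probes and 7 hypomethylated regions from circulating
CD4+CLA+ T cells of adult atopic dermatitis patients versus healthy
controls (`load_cla_dmps()`, `load_cla_dmrs()`), used in worked
examples and tests.

## Worked example

```r
library(methmir)

study <- simulate_study(sim_config(seed = 7))
study
#> Synthetic study: 2000 CpG probes x 19 samples; 455 miRNAs (seed 7)
#>   planted: 30 DMPs, 3 DMRs, 10 up / 6 down miRNAs, 4 communities

run <- run_pipeline(study)
run
#> Pipeline run (seed 7)
#>                    stage    n
#>             probes_input 2000
#>  probes_after_snp_filter 1904
#>            probes_tested 1904
#>              dmps_called   90
#>           dmr_candidates 1895
#>              dmrs_called    3
#>            mirnas_tested  455
#>            mirnas_called   17
#>             network_cpgs  105
#>   network_edges_retained 1084
#>              communities    8
```

90 CpGs pass BH < 0.05 (the 30 planted DMPs, the 12 DMR probes, the
coupled probe, and the group-shifted community members), all 3 planted
regions are called with no false regions, and 17 miRNAs are significant
(the 16 planted plus one). Scoring against the planted truth:

```r
round(score_recovery(run), 3)
#>   dmp_sensitivity dmp_fdp dmr_jaccard mirna_direction_accuracy community_ari
#> 1               1   0.078           1                        1          0.99
#>   antagonism_correct case_rho case_slope case_r2 slope_error control_slope_p
#> 1                  1   -0.988     -2.704   0.993       0.296           0.152
#>   pooled_rho
#> 1     -0.917
```

Every strongly planted DMP is recovered with a realized false-discovery
proportion of 0.078; communities are recovered at adjusted Rand 0.99 and
the planted anti-correlated pair is the one flagged; within cases the
coupled probe shows Spearman ρ = −0.99 with a fitted slope of −2.7 ΔCt
per M-unit (R² = 0.99), while the control-group slope is not significant
(p = 0.15) — the case-only coupling the pipeline is designed to detect.

Individual stages are plain functions on matrices and data frames:

```r
dt <- diff_test(study$meth, study$sample_sheet)
dt
#> Differential table: 2000 features, 2000 tested, 90 at BH p < 0.05
#>   prior: d0 = 11.15608  s0^2 = 0.2484
#>    feature_id     logfc     t_mod df_total            p         p_bh direction
#> 17   cgs00017  2.984097  13.71776 27.15608 9.958465e-14 1.991693e-10         1
#> 38   cgs00038 -2.697440 -13.07462 27.15608 3.108509e-13 3.108509e-10        -1
#> ...
dmrs <- find_dmrs(dt, study$annotation)
```

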