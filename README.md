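# partpgs

Partitioned polygenic scores and mechanistic clustering for
type 2 diabetes–hypertension comorbidity.

## The problem

Type 2 diabetes (T2D) and hypertension co-occur far beyond chance, but a
single genome-wide genetic correlation cannot say *why*: distinct
biological mechanisms (adiposity, vascular dysfunction, beta-cell failure,
…) push on both disease risks with different signs and strengths.
`partpgs` dissects this heterogeneity from GWAS summary statistics and
evaluates the result in an individual-level cohort:

1. **z-score matrix** — for variant *j* and trait *i*, the clustering
   feature is *Z<sub>ij</sub>* = β<sub>ij</sub>/s<sub>ij</sub>, aligned to
   the T2D risk allele, with LD-proxy substitution (r² > 0.6),
   a strict 20% row-missingness filter, iterative random-forest
   imputation, and per-trait winsorization at 2 SD.
2. **Mechanistic clusters** — Ward (ward.D2) hierarchical clustering on
   Euclidean distance, cut at **half the maximum merge height**; cluster
   interpretation through the regression
   E(Z<sub>ij</sub>) = Σ<sub>k</sub> α<sub>ik</sub> C<sub>kj</sub>;
   soft-clustering cross-check by ARD Bayesian NMF with the weight > 0.75
   assignment rule.
3. **Colocalization** — Wakefield approximate Bayes factors over ±100 kb
   regions (100–1000 variants, MHC excluded), single-causal-variant
   posteriors PP.H0–PP.H4; a call requires PP.H4 > 0.8 and PP.H3 < 0.5;
   tissue-specific counting per index variant.
4. **Regulatory enrichment** — Firth bias-reduced logistic regression of
   cluster membership on exon/UTR annotations and cell-type peak
   membership, tested by the penalized likelihood-ratio (model fitted
   with and without the focal cell-type coefficient), Bonferroni across
   all (cluster × cell type) tests (0.05/222 ≈ 2.25×10⁻⁴ for the
   222-cell-type atlas).
5. **Partitioned PGS risk** — unweighted risk-allele counts per cluster;
   covariate-adjusted associations (age, sex, array, PC1–6); top-decile
   relative risk with the published CI form
   exp[ln RR ± 1.96 √(1/N<sub>cases,cluster</sub> −
   1/N<sub>cases,overall</sub>)]; dominant-cluster (top-33% percentile
   rank) survival stratification from first to second diagnosis; and a
   Bonferroni-corrected complication outcome scan (0.05/645 ≈ 7.75×10⁻⁵
   at the full outcome taxonomy).

Every input the pipeline consumes can be generated synthetically with
planted ground truth (`simulate_*` functions), so recovery of the planted
structure is a testable property. See `vignettes/methods.Rmd` for the
models, assumptions and design choices.

## Worked example

```r
library(partpgs)

gw <- simulate_gwas_matrix(k = 3, n_traits = 12,
                           snvs_per_cluster = c(60, 40, 30),
                           signature_scale = 5, noise_sd = 1,
                           missing_rate = 0.05, seed = 42)
zm <- build_zmatrix(gw$catalog, gw$trait_tables)
zm <- filter_missingness(zm)   # drops rows > 20% missing
zm <- impute_rf(zm, seed = 42) # regression-forest imputation
zm <- truncate_z(zm)           # 2-SD winsorization per trait
cut <- cut_half_max(ward_dendrogram(zm))
cut$k
#> [1] 3
table(cut$assignment)
#>  1  2  3
#> 60 39 30
adjusted_rand_index(cut$assignment,
                    gw$truth$cluster_of[names(cut$assignment)])
#> [1] 1
```

The half-max cut recovers the three planted clusters exactly (one variant
row was lost to the missingness filter). Scoring a simulated cohort with
each cluster's partitioned PGS and taking top-decile relative risks for
the T2D-like disease:

```r
co <- simulate_cohort(n = 5000, gw$catalog, gw$truth,
                      prevalence_d1 = 0.10, seed = 43)
profile <- partitioned_pgs(co$dosages, cut$assignment)
for (k in colnames(profile)) {
  grp <- top_fraction_group(profile[, k], 0.10)
  rr <- relative_risk(grp, co$cohort$disease1 == 1)
  cat(sprintf("%s: RR = %.2f [%.2f, %.2f]\n",
              k, rr$rr, rr$ci_low, rr$ci_high))
}
#> cluster1: RR = 0.50 [0.35, 0.71]
#> cluster2: RR = 2.15 [1.82, 2.53]
#> cluster3: RR = 1.86 [1.61, 2.15]
```

Cluster 1 is the planted *inverse* mechanism (its variants lower the
T2D-like liability while raising blood pressure): its top decile carries
half the population risk, while the risk-increasing clusters roughly
double it.

## Pipeline CLI

Each stage is a subcommand writing TSVs into a shared output directory:

```sh
Rscript inst/cli/partpgs simulate --outdir out --seed 1
Rscript inst/cli/partpgs zmatrix  --outdir out
Rscript inst/cli/partpgs cluster  --outdir out
# ... coloc, enrich, pgs, survive, scan, report
```

or from R: `run_pipeline("out", default_config(seed = 1))`. Outputs are
deterministic given the config seed; the config is echoed into the output
directory as `config.yaml`.

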