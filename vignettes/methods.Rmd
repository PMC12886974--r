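---
title: "Partitioned polygenic scores and mechanistic clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned polygenic scores and mechanistic clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Type 2 diabetes (T2D) and hypertension co-occur far more often than chance
predicts, yet a single genome-wide genetic correlation hides the fact that
different biological mechanisms push on both diseases in different ways —
some variants raise both risks through adiposity, others through vascular
dysfunction, and some even pull the two risks in opposite directions.
`partpgs` implements a pipeline that dissects this heterogeneity from GWAS
summary statistics: it groups trait-associated variants into mechanistic
clusters, characterises each cluster's regulatory and tissue context, and
converts each cluster into a *partitioned polygenic score* (PGS) whose
risk stratification can be evaluated in an individual-level cohort.

Everything runs on synthetic data with planted ground truth; the
generators emulate the statistical structure the analysis assumes so that
recovery of that structure is a testable property.

# The z-score matrix

For variant $j$ and trait $i$ the clustering feature is
$Z_{ij} = \beta_{ij} / s_{ij}$, the GWAS effect divided by its standard
error, with every record first aligned to the variant's T2D-risk-increasing
allele (alignment flips the beta sign, swaps alleles and complements the
allele frequency; it is an involution). A sample-size-adjusted variant
$\beta_{ij}/(s_{ij}\sqrt{N_j})$ is available as a sensitivity option: the
unadjusted score weights large-study traits more and is the default because
it privileges high-confidence associations.

The matrix build order is fixed: align, substitute LD proxies
($r^2 > 0.6$ within 500 kb) for variants missing from a trait's GWAS,
drop variants with more than 20% missing cells (strictly greater — a row
at exactly 20% stays), impute the remainder, then winsorize. Imputation is
a missForest-style scheme around regression forests: columns are visited
in ascending missingness order, each regressed on all others over its
observed rows, and sweeps repeat until the summed squared change of the
imputed values increases (10 sweeps maximum; 100 trees; fixed seed;
observed cells are never modified). Winsorization clips each cell to
within two standard deviations of its column mean, computed *after*
imputation on the full column. We read "truncation" as clipping rather
than row removal: removing rows would shrink the variant set, which
contradicts downstream cluster sizes that account for every variant.
Whether the column statistics should be computed before or after
imputation is genuinely open; after-imputation is our declared choice and
it is the one consistent with the stated processing order.

Palindromic (A/T, C/G) variants are aligned trusting the reported alleles,
with a logged warning when the allele frequency is in [0.4, 0.6]; dropping
them would alter the catalog.

# Hard clustering and the half-max cut

Variants are clustered by Ward's method on Euclidean distances
(`hclust(method = "ward.D2")`, the criterion in which each merge minimizes
the increase of within-cluster variance; heights are monotone). The number
of clusters is set by cutting the dendrogram at **half of its maximum
merge height**: every merge above the cut is severed and the surviving
subtrees are the clusters, labelled in decreasing size order. The wording
of this rule admits other readings (e.g. half of the maximum *pairwise
row* distance), but only the merge-height reading defines a tree cut, so
that is the implemented one.

Cluster interpretation uses the regression
$E(Z_{ij}) = \sum_k \alpha_{ik} C_{kj}$ where $C_{kj}$ indicates hard
membership; with disjoint indicators and no intercept, $\alpha_{ik}$ is
exactly the mean z of cluster $k$ for trait $i$, and two-sided t-tests on
the coefficients give the heat-map p-values.

As a sensitivity cross-check a Bayesian non-negative matrix factorization
(bNMF) with automatic relevance determination provides *soft* weights.
The signed matrix is embedded by column doubling (positive and negative
parts of each trait column), and ARD places a shared per-component
relevance on both factors with an inverse-gamma hyperprior; MAP fitting
uses multiplicative updates. Two numerical choices matter and are frozen:
the noise variance is floored at 1% of the mean squared data value during
the ARD phase (otherwise a superfluous-rank exact fit drives the noise to
zero, the penalty vanishes and nothing is pruned), and pruned solutions
are polished with unpenalized updates. The effective rank is the modal
rank over 10 seeded restarts. Variants are hard-assignable from soft
weights when the row-normalized weight exceeds 0.75. Hard/soft agreement
is tested per cluster by a deviance (likelihood-ratio) test of membership
on the weight columns; because row-normalized weights sum to one, a
full-rank column subset is used, and separable fits fall back to the
package's Firth engine with a flag.

# Colocalization

For each index variant the ±100 kb region is intersected between the GWAS
and eQTL tables (inclusive bounds, alleles harmonized), QC requires 100 to
1000 variants inclusive, and the MHC (chr6:25–35 Mb) is excluded. Each
variant's evidence is the Wakefield approximate Bayes factor
$\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \tfrac12 z^2\frac{W}{V+W}$
with $V = s^2$, $W$ the prior effect variance and $z = \beta/s$. Under the
single-causal-variant assumption the five hypothesis evidences (H0 none,
H1/H2 one trait, H3 two distinct causal variants, H4 one shared) are
assembled with per-variant priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$ and prior effect sd 0.2 for both traits — the
documented defaults of the standard tool for this analysis, overridable
in the config. All sums use log-sum-exp accumulation: at $|z| \approx 40$
raw ABFs overflow doubles. A region is *called* when PP.H4 > 0.8 and
PP.H3 < 0.5 and QC passed. An index variant counts as *tissue-specific*
for a tissue when that tissue holds its only called colocalization.

# Cell-type regulatory enrichment

The background set aggregates panel variants within 50 kb of any
clustered variant, LD-pruned to $r^2 < 0.2$ and deduplicated, minus the
clustered variants. For a focal cluster the model is a Firth bias-reduced
logistic regression of membership on exon/3'UTR/5'UTR indicators plus all
cell-type peak-membership columns. The test fits the model twice — free,
and with the focal cell type's coefficient constrained to zero — and
compares twice the penalized log-likelihood difference to $\chi^2_1$.
The constrained fit keeps the *full* model's Jeffreys penalty (the
penalized likelihood-ratio construction); using the reduced-model penalty
instead inflates the statistic by a penalty offset unrelated to fit, and
the suite verifies the implemented test holds its nominal type-I rate
empirically rather than assuming it. Background variants from other
clusters are labelled 0 for the focal test and other clusters' variants
are excluded, so cross-cluster contamination cannot bias the contrast.
Significance is Bonferroni at $\alpha$ over the number of
(cluster × cell type) tests; with 222 cell types alone the threshold is
$0.05/222 \approx 2.25\times10^{-4}$.

The Firth engine itself is iteratively reweighted scoring with the
hat-value score correction and step-halving on the penalized likelihood;
convergence at max |score| < 1e-6 or 50 iterations. It is cross-checked
against an independent numeric maximizer of the penalized likelihood in
the tests.

# Partitioned scores and risk

Blood pressure phenotypes average repeated readings and add 15 mmHg
(SBP) / 10 mmHg (DBP) for medicated individuals; hypertension is defined
on the *raw* means (SBP ≥ 150, DBP ≥ 90, or medication) — medication is a
separate criterion there, so adjusting first would double-count it.

Weighted scores follow pruning-and-thresholding: LD-independent,
genome-wide-significant variants with external GWAS effect weights.
Partitioned scores are unweighted risk-allele counts per cluster
(bounded by $[0, 2n_k]$); missing dosages are imputed at $2\times$EAF.
Associations adjust for age, sex, genotyping array and six genetic PCs.

Top-fraction risk groups take scores strictly above the empirical
$1-f$ quantile, with ties at the cut included. The relative risk of a
subgroup is its case prevalence over the overall prevalence; its 95% CI is
implemented verbatim as published,
$\exp[\ln RR \pm 1.96\sqrt{1/N_{cases,cluster} - 1/N_{cases,overall}}]$ —
note the minus sign under the radical, which degenerates to a width-zero
interval when the group is the whole cohort. Because that form is unusual
for an RR interval, the conventional log-RR interval is available behind
`ci_style = "standard"`.

Dominant-cluster assignment compares *percentile ranks*, not raw scores —
clusters have different variant counts, so raw unweighted scores are not
comparable — and assigns an individual to their top-ranked cluster if that
rank is in the top 33%; exact ties go to the larger cluster. Survival uses
time from first diagnosis (of either disease) to the second; single-disease
individuals are censored at follow-up end, and same-day dual diagnoses are
excluded (zero durations break the Cox partial likelihood). Cumulative
hazards are Nelson–Aalen/Breslow with log-scale 95% bands. The
complication scan runs the logistic association per (cluster, outcome)
pair, skipping outcomes with fewer than 10 cases, Bonferroni-corrected
across clusters × outcome categories; with 5 clusters and the full
129-category taxonomy the threshold is $0.05/645 \approx
7.75\times10^{-5}$, which is one way of resolving the printed threshold's
undocumented test count; the operation takes the count explicitly so
either convention is expressible.

# What the synthetic generators emulate

* **Reference panel** — block-LD dosages: within a block all variants
  share an allele frequency and each haplotype allele copies its left
  neighbour with probability $\rho$ (AR(1) adjacent correlation), blocks
  independent. Default 300 samples, blocks of 4 at $\rho = 0.8$, allele
  frequencies in [0.05, 0.5]. Not emulated: realistic human LD maps,
  ancestry structure, imputation uncertainty.
* **GWAS matrix** — K = 5 planted signatures over 45 traits and cluster
  sizes 215/353/137/287/312, mirroring the scale of the real catalog.
  Signatures are disjoint trait blocks of magnitude 5 (one cluster
  sign-inverted, emulating an inverse-comorbidity mechanism) with unit
  z noise and 10% MCAR missingness; about half the records are stored on
  the flipped allele orientation to exercise alignment. Block magnitude
  and noise were calibrated once so that the planted structure is
  recoverable (signature separation at least 3 × noise × √T) and then
  frozen.
* **Cohort** — 10,000 individuals; probit liability for the T2D-like
  disease (target prevalence 8%; the threshold is solved from the realized
  linear predictor, so empirical prevalence fluctuates around the target);
  linear SBP/DBP with per-cluster effects; medication probability rising
  in true SBP; hypertension by the package's own rule; ordered diagnosis
  dates with the second-diagnosis waiting time shortened by genetic
  burden; six complication outcomes with planted per-cluster log-odds
  including one protective cluster (−0.35 per SD on the renal outcome).
* **eQTL regions** — marginal z-scores from the standard LD-convolved
  model $z \sim N(R_{\cdot c}\,\lambda, R)$ under each colocalization
  hypothesis (same causal variant, distant causal variants, one-trait,
  none), default 300 variants at effect 8.
* **Peak atlases** — per (cell type, variant) Bernoulli peak membership at
  a 10% background rate, raised 3-fold for planted (cell type, cluster)
  pairs.

Passing tests on these generators show the *procedures* recover planted
structure under the stated models; they do not show that real GWAS data
satisfy those models (no horizontal pleiotropy adjudication, no multi-
causal-variant colocalization, no realistic LD).

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere; BED is converted on read.
* TSV with "." for missing; floats at 15 significant digits so round
  trips hold to 12.
* LD pruning is greedy by ascending origin-GWAS p-value (ties by
  position) — the original ordering is unstated; keeping the most
  significant signal matches field practice. Variants absent from the
  panel are retained un-prunable with a warning rather than silently
  dropped.
* Degenerate cases are first-class: zero-variance dosages give NA with a
  warning (distinct from r² = 0); constant enrichment columns give a
  flagged non-informative result; all-tied score vectors select the whole
  cohort with a warning; a zero-case subgroup gives RR = 0 with an
  undefined, flagged CI.
* Problem sizes in the test-suite calibrations (100 colocalization
  replicates per hypothesis, 1000 null likelihood-ratio simulations,
  5000-individual survival simulations) were chosen as the smallest runs
  at which the binomial/Monte-Carlo error is well inside each check's
  acceptance band.

# Known limitations

The single-causal-variant assumption in colocalization, the absence of an
MR-based sensitivity clustering, winsorization as the reading of
"truncation", and the as-printed RR interval are all faithful
re-implementations of the published procedure, not endorsements; each has
a documented escape hatch or flagged alternative where feasible. The bNMF
hyperpriors and restart count are frozen package defaults because no
published values exist for them.
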