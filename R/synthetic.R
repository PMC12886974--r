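# Seeded generators for every input the pipeline consumes, each emitting
# its planted ground truth so recovery can be tested downstream.

#' Simulate a block-LD genotype reference panel
#'
#' Dosages are sums of two haplotypes generated by a within-block copying
#' chain: within a block each variant shares the block's allele frequency
#' and each haplotype allele copies its left neighbour with probability
#' `rho`, giving adjacent-variant dosage correlation rho (AR(1) decay with
#' distance); across blocks variants are independent. Variants sit on one
#' chromosome at fixed spacing.
#'
#' @param n_samples number of panel individuals (>= 50).
#' @param n_variants total variants (last block may be short).
#' @param block_size variants per LD block.
#' @param rho within-block adjacent correlation, in \[0, 1).
#' @param maf_range interval the per-block allele frequency is drawn from.
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @param spacing_bp distance between adjacent variants.
#' @return list with `dosages` (variants x samples), `chrom`, `pos`, `maf`
#'   (named by variant), `block` (block index per variant).
#' @export
simulate_reference_panel <- function(n_samples = 500L, n_variants = 1000L,
                                     block_size = 20L, rho = 0.8,
                                     maf_range = c(0.05, 0.5), seed = 1L,
                                     chrom = "1", spacing_bp = 5000L) {
  if (rho >= 1 || rho < 0) stop("rho must lie in [0, 1)")
  if (n_samples < 50) stop("n_samples must be >= 50")
  set.seed(seed)
  n_hap <- 2L * n_samples
  ids <- sprintf("pv%05d", seq_len(n_variants))
  blocks <- ceiling(seq_len(n_variants) / block_size)
  dos <- matrix(0L, n_variants, n_samples,
                dimnames = list(ids, sprintf("s%04d", seq_len(n_samples))))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    f <- stats::runif(1, maf_range[1], maf_range[2])
    hap <- matrix(0L, length(idx), n_hap)
    hap[1, ] <- stats::rbinom(n_hap, 1, f)
    if (length(idx) > 1) {
      for (t in 2:length(idx)) {
        copy <- stats::rbinom(n_hap, 1, rho)
        fresh <- stats::rbinom(n_hap, 1, f)
        hap[t, ] <- copy * hap[t - 1, ] + (1L - copy) * fresh
      }
    }
    dos[idx, ] <- hap[, seq_len(n_samples), drop = FALSE] +
      hap[, n_samples + seq_len(n_samples), drop = FALSE]
  }
  storage.mode(dos) <- "double"
  list(dosages = dos,
       chrom = stats::setNames(rep(chrom, n_variants), ids),
       pos = stats::setNames(as.integer(seq_len(n_variants)) * spacing_bp,
                             ids),
       maf = stats::setNames(rep(NA_real_, n_variants), ids),
       block = stats::setNames(blocks, ids))
}

default_signatures <- function(k, n_traits, signature_scale) {
  block <- floor(n_traits / k)
  S <- matrix(0, k, n_traits)
  for (i in seq_len(k)) {
    idx <- ((i - 1) * block + 1):(i * block)
    # one inverse-effect cluster: its signature points the other way
    S[i, idx] <- signature_scale * (if (i == 1) -1 else 1)
  }
  S
}

#' Simulate multi-trait GWAS summary statistics with planted clusters
#'
#' Plants K mechanistic signatures (disjoint trait blocks, one with
#' inverted sign) and generates, per trait, a summary-statistics table in
#' which each variant's risk-allele-aligned z equals its cluster signature
#' plus Gaussian noise; beta/se pairs are reconstructed with se = 1/sqrt(N)
#' so beta/se = z. About half the variants are stored on the opposite
#' allele orientation (beta negated, alleles swapped, EAF complemented) to
#' exercise alignment. Cells go missing completely at random at
#' `missing_rate`.
#'
#' @param k number of planted clusters (>= 1).
#' @param n_traits number of traits (first four are named T2D, SBP, DBP,
#'   PP; the rest endophenotypes).
#' @param snvs_per_cluster integer vector of cluster sizes (each >= 2).
#' @param signature_scale magnitude of the planted signature entries.
#' @param noise_sd z-score noise standard deviation.
#' @param missing_rate MCAR cell missingness, in \[0, 1).
#' @param gwas_n per-trait sample size (scalar or length `n_traits`).
#' @param seed integer seed.
#' @param panel optional reference panel; catalog variants are then taken
#'   from the panel grid (first variant of successive blocks) so LD
#'   operations can find them.
#' @param separation_multiple signatures must be at least this multiple of
#'   `noise_sd * sqrt(n_traits)` apart (warning otherwise).
#' @return list with `trait_tables` (named list of `sumstats`), `catalog`
#'   (`variant_catalog` with `p` priority column), `truth` (list:
#'   `cluster_of`, `signatures`, `eaf`).
#' @export
simulate_gwas_matrix <- function(k = 5L, n_traits = 45L,
                                 snvs_per_cluster = c(215L, 353L, 137L,
                                                      287L, 312L),
                                 signature_scale = 5, noise_sd = 1,
                                 missing_rate = 0.10, gwas_n = 100000L,
                                 seed = 1L, panel = NULL,
                                 separation_multiple = 3) {
  if (k < 1) stop("k must be >= 1")
  if (length(snvs_per_cluster) != k) stop("need one size per cluster")
  if (any(snvs_per_cluster < 2)) stop("cluster sizes must be >= 2")
  if (missing_rate >= 1 || missing_rate < 0) stop("missing_rate in [0, 1)")
  set.seed(seed)
  n_var <- sum(snvs_per_cluster)
  traits <- c("T2D", "SBP", "DBP", "PP",
              sprintf("endo%02d", seq_len(max(0, n_traits - 4)) + 4))
  traits <- traits[seq_len(n_traits)]
  S <- default_signatures(k, n_traits, signature_scale)
  if (k > 1) {
    dmin <- min(stats::dist(S))
    if (dmin < separation_multiple * noise_sd * sqrt(n_traits))
      warning(sprintf(
        "signature separation %.2f below %g * noise_sd * sqrt(T) = %.2f",
        dmin, separation_multiple,
        separation_multiple * noise_sd * sqrt(n_traits)))
  }
  cluster_of <- rep(seq_len(k), snvs_per_cluster)
  if (!is.null(panel)) {
    firsts <- rownames(panel$dosages)[!duplicated(panel$block)]
    if (length(firsts) < n_var)
      stop("panel has too few LD blocks for the requested variant count")
    ids <- firsts[seq_len(n_var)]
    chroms <- unname(panel$chrom[ids])
    poss <- unname(panel$pos[ids])
  } else {
    ids <- sprintf("rs%05d", seq_len(n_var))
    chroms <- rep("1", n_var)
    poss <- as.integer(seq_len(n_var)) * 50000L
  }
  eaf <- stats::runif(n_var, 0.10, 0.90)
  flip <- stats::rbinom(n_var, 1, 0.5) == 1
  z_true <- S[cluster_of, , drop = FALSE] +
    matrix(stats::rnorm(n_var * n_traits, 0, noise_sd), n_var, n_traits)
  rownames(z_true) <- ids
  colnames(z_true) <- traits
  gwas_n <- rep_len(gwas_n, n_traits)
  origin <- c("T2D", "SBP", "DBP", "PP")[1 + (cluster_of - 1) %% 4]
  trait_tables <- list()
  catalog_p <- rep(NA_real_, n_var)
  for (ti in seq_along(traits)) {
    se <- 1 / sqrt(gwas_n[ti])
    z <- z_true[, ti]
    beta_aligned <- z * se
    tab <- data.frame(
      variant_id = ids, chrom = chroms, pos = poss,
      effect_allele = ifelse(flip, "G", "A"),
      other_allele = ifelse(flip, "A", "G"),
      beta = ifelse(flip, -beta_aligned, beta_aligned),
      se = se, p = 2 * stats::pnorm(-abs(z)),
      n = gwas_n[ti],
      eaf = ifelse(flip, 1 - eaf, eaf),
      stringsAsFactors = FALSE)
    keep <- stats::runif(n_var) >= missing_rate
    trait_tables[[traits[ti]]] <- as_sumstats(tab[keep, , drop = FALSE],
                                              stage = "simulate")
    hit <- origin == traits[ti]
    catalog_p[hit] <- tab$p[hit]
  }
  catalog_p[is.na(catalog_p)] <- 2 * stats::pnorm(-abs(z_true[cbind(
    seq_len(n_var), match(origin, traits))]))[is.na(catalog_p)]
  catalog <- as_catalog(data.frame(
    variant_id = ids, chrom = chroms, pos = poss,
    origin_trait = origin, risk_allele = "A", p = catalog_p,
    stringsAsFactors = FALSE))
  list(trait_tables = trait_tables, catalog = catalog,
       truth = list(cluster_of = stats::setNames(cluster_of, ids),
                    signatures = S, eaf = stats::setNames(eaf, ids),
                    traits = traits))
}

default_cohort_effects <- function(k, outcome_names) {
  d1 <- rep_len(c(-0.20, 0.40, 0.30, 0.30, 0.25), k)
  sbp <- rep_len(c(4, 1, 3, 2, 1), k)
  dbp <- rep_len(c(2.5, 0.5, 2, 1.5, 0.5), k)
  comp <- matrix(0, k, length(outcome_names),
                 dimnames = list(NULL, outcome_names))
  if (k >= 2 && "circulatory" %in% outcome_names)
    comp[2, "circulatory"] <- 0.35
  if (k >= 5 && "renal" %in% outcome_names)
    comp[5, "renal"] <- -0.35          # planted protective cluster
  if ("metabolic" %in% outcome_names)
    comp[1, "metabolic"] <- 0.30
  list(d1 = d1, sbp = sbp, dbp = dbp, comp = comp)
}

#' Simulate an individual-level cohort with cluster-specific liabilities
#'
#' Dosages at the catalog variants are independent binomials at the
#' planted allele frequencies (risk-allele aligned). Disease 1 (T2D-like)
#' follows a probit liability model with per-cluster genetic effects (on
#' standardized partitioned scores) plus age and sex terms; SBP/DBP are
#' linear with per-cluster effects and noise; the medication flag's
#' probability increases with true blood pressure; disease 2
#' (hypertension-like) follows the SBP >= 150 / DBP >= 90 / medication
#' rule on the raw reading means. Individuals with both diseases receive
#' two ordered diagnosis dates, the waiting time to the second diagnosis
#' shortened by the total genetic burden; complications are Bernoulli with
#' planted per-cluster log-odds including one protective cluster.
#'
#' @param n cohort size (>= 1000).
#' @param catalog `variant_catalog` of scored variants.
#' @param truth truth list from [simulate_gwas_matrix()] (`cluster_of`,
#'   `eaf`).
#' @param prevalence_d1 target disease-1 prevalence.
#' @param effects optional effect list (`d1`, `sbp`, `dbp`, `comp`);
#'   defaults planted as documented.
#' @param seed integer seed.
#' @return list with `cohort` (data.frame), `dosages` (individuals x
#'   variants), `truth` (effects, cluster_of, outcome names).
#' @export
simulate_cohort <- function(n = 10000L, catalog, truth,
                            prevalence_d1 = 0.08, effects = NULL,
                            seed = 1L) {
  if (n < 1000) stop("n must be >= 1000")
  set.seed(seed)
  ids <- catalog$variant_id
  k <- max(truth$cluster_of)
  eaf <- truth$eaf[ids]
  dos <- vapply(eaf, function(f) stats::rbinom(n, 2, f),
                numeric(n))
  colnames(dos) <- ids
  rownames(dos) <- sprintf("i%06d", seq_len(n))
  outcome_names <- c("circulatory", "renal", "neuro", "eye",
                     "metabolic", "respiratory")
  if (is.null(effects)) effects <- default_cohort_effects(k, outcome_names)
  profile <- partitioned_pgs(dos, truth$cluster_of[ids])
  g_std <- scale(profile)
  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1, 0.5)
  arr <- stats::rbinom(n, 1, 0.5)
  pcs <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("pc", 1:6)))
  lin1 <- drop(g_std %*% effects$d1) + 0.30 * (age - 55) / 10 + 0.20 * sex
  if (prevalence_d1 <= 0 || prevalence_d1 >= 1)
    stop("unattainable disease-1 prevalence target: ", prevalence_d1)
  thr <- tryCatch(stats::uniroot(function(t)
    mean(stats::pnorm(lin1 - t)) - prevalence_d1,
    lower = min(lin1) - 10, upper = max(lin1) + 10)$root,
    error = function(e)
      stop("unattainable disease-1 prevalence target: ",
           conditionMessage(e)))
  disease1 <- (lin1 + stats::rnorm(n)) > thr
  sbp_true <- 125 + drop(g_std %*% effects$sbp) + 0.45 * (age - 55) +
    4 * sex + stats::rnorm(n, 0, 12)
  dbp_true <- 78 + drop(g_std %*% effects$dbp) + 0.15 * (age - 55) +
    2 * sex + stats::rnorm(n, 0, 8)
  bp_med <- stats::rbinom(n, 1, 0.85 * stats::plogis((sbp_true - 155) / 8))
  sbp1 <- sbp_true + stats::rnorm(n, 0, 3)
  sbp2 <- sbp_true + stats::rnorm(n, 0, 3)
  dbp1 <- dbp_true + stats::rnorm(n, 0, 3)
  dbp2 <- dbp_true + stats::rnorm(n, 0, 3)
  disease2 <- define_hypertension((sbp1 + sbp2) / 2, (dbp1 + dbp2) / 2,
                                  bp_med == 1)
  followup_end <- rep(6000L, n)
  first_day <- ifelse(disease1 | disease2,
                      round(stats::runif(n, 500, 3000)), NA_integer_)
  burden <- rowSums(g_std %*% diag(pmax(effects$d1, 0), k, k))
  gap <- 1 + round(stats::rexp(n, rate = exp(0.4 * burden) / 900))
  second_day <- pmin(first_day + gap, followup_end)
  both <- disease1 & disease2
  d1_first <- stats::rbinom(n, 1, 0.5) == 1
  diag1_day <- ifelse(disease1, ifelse(both & !d1_first, second_day,
                                       first_day), NA_integer_)
  diag2_day <- ifelse(disease2, ifelse(both & d1_first, second_day,
                                       first_day), NA_integer_)
  comp <- matrix(0L, n, length(outcome_names),
                 dimnames = list(rownames(dos), outcome_names))
  for (oc in seq_along(outcome_names)) {
    lo <- stats::qlogis(0.10) + drop(g_std %*% effects$comp[, oc]) +
      0.20 * (age - 55) / 10
    comp[, oc] <- stats::rbinom(n, 1, stats::plogis(lo))
  }
  cohort <- data.frame(
    id = rownames(dos), age = age, sex = sex, array = arr, pcs,
    sbp1 = sbp1, sbp2 = sbp2, dbp1 = dbp1, dbp2 = dbp2,
    bp_med = bp_med, disease1 = as.integer(disease1),
    disease2 = as.integer(disease2),
    diag1_day = as.integer(diag1_day), diag2_day = as.integer(diag2_day),
    followup_end_day = followup_end,
    comp, stringsAsFactors = FALSE)
  list(cohort = cohort, dosages = dos,
       truth = list(effects = effects,
                    cluster_of = truth$cluster_of[ids],
                    outcome_names = outcome_names,
                    d1_threshold = thr))
}

#' Simulate one paired GWAS/eQTL region under a colocalization hypothesis
#'
#' Marginal z-scores follow the standard LD-convolved model: with AR(1)
#' correlation R between variants and a causal variant c of
#' non-centrality `effect_z`, E\[z\] = R\[, c\] * effect_z and
#' z ~ N(E\[z\], R). H4 plants the same causal variant in both traits; H3
#' two distant causal variants; H1/H2 one trait only; H0 none.
#'
#' @param scenario one of "H0" ... "H4".
#' @param n_snps number of variants, in \[3, 2000\].
#' @param ld_rho adjacent-variant correlation of the AR(1) LD structure.
#' @param effect_z causal non-centrality.
#' @param n GWAS/eQTL sample size (sets se = 1/sqrt(n)).
#' @param seed integer seed.
#' @param chrom,center region location.
#' @param spacing_bp distance between adjacent variants.
#' @param region_id prefix for variant ids.
#' @return list with `gwas`, `eqtl` (`sumstats` over the same variants),
#'   `scenario`, `causal` (ids or NULL per trait), `index_variant`.
#' @export
simulate_eqtl_region <- function(scenario = c("H0", "H1", "H2", "H3", "H4"),
                                 n_snps = 300L, ld_rho = 0.9,
                                 effect_z = 8, n = 10000L, seed = 1L,
                                 chrom = "2", center = 50000000L,
                                 spacing_bp = 500L, region_id = "reg") {
  scenario <- match.arg(scenario)
  if (n_snps < 3 || n_snps > 2000) stop("n_snps must lie in [3, 2000]")
  if (ld_rho >= 1 || ld_rho < 0) stop("ld_rho must lie in [0, 1)")
  set.seed(seed)
  idx <- seq_len(n_snps)
  R <- ld_rho^abs(outer(idx, idx, "-"))
  L <- chol(R)
  mid <- ceiling(n_snps / 2)
  c1 <- c2 <- NULL
  if (scenario == "H4") c1 <- c2 <- mid
  if (scenario == "H3") { c1 <- max(1, round(n_snps / 6))
                          c2 <- min(n_snps, round(5 * n_snps / 6)) }
  if (scenario == "H1") c1 <- mid
  if (scenario == "H2") c2 <- mid
  draw_z <- function(causal) {
    mu <- if (is.null(causal)) rep(0, n_snps) else R[, causal] * effect_z
    mu + drop(crossprod(L, stats::rnorm(n_snps)))
  }
  z1 <- draw_z(c1)
  z2 <- draw_z(c2)
  ids <- sprintf("%s_v%04d", region_id, idx)
  pos <- as.integer(center + (idx - mid) * spacing_bp)
  eaf <- stats::runif(n_snps, 0.05, 0.95)
  mk <- function(z) as_sumstats(data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    beta = z / sqrt(n), se = 1 / sqrt(n),
    p = 2 * stats::pnorm(-abs(z)), n = n, eaf = eaf,
    stringsAsFactors = FALSE), stage = "simulate")
  list(gwas = mk(z1), eqtl = mk(z2), scenario = scenario,
       causal = list(gwas = if (!is.null(c1)) ids[c1],
                     eqtl = if (!is.null(c2)) ids[c2]),
       index_variant = ids[if (!is.null(c1)) c1 else mid])
}

#' Simulate a cell-type peak atlas with planted enrichment
#'
#' For every (cell type, variant) pair the variant is covered by a peak
#' with probability `background_rate`, raised to `background_rate * fold`
#' when the variant belongs to a cluster planted as enriched in that cell
#' type. Peaks are +-100 bp intervals around covered variants. Exon/UTR
#' annotations are sprinkled independently.
#'
#' @param catalog `variant_catalog` with a `cluster` column (clustered
#'   variants).
#' @param background data.frame `variant_id`, `chrom`, `pos` (background
#'   variants; always at background rate).
#' @param cell_types number of cell types (named ct1, ct2, ...).
#' @param enriched_pairs data.frame with `cell_type`, `cluster` columns.
#' @param fold enrichment fold (>= 1).
#' @param background_rate baseline in-peak probability.
#' @param annotation_rate per-annotation sprinkle probability.
#' @param seed integer seed.
#' @return list with `peaks` (named list of interval data.frames),
#'   `annotations` (list exon/utr3/utr5), `truth` (enriched_pairs).
#' @export
simulate_peak_atlas <- function(catalog, background, cell_types = 6L,
                                enriched_pairs = data.frame(
                                  cell_type = c("ct1", "ct2"),
                                  cluster = c(1, 3)),
                                fold = 3, background_rate = 0.10,
                                annotation_rate = 0.03, seed = 1L) {
  if (fold < 1) stop("fold must be >= 1")
  if (background_rate * fold > 1)
    stop("background_rate * fold exceeds 1: not a probability")
  set.seed(seed)
  all_v <- rbind(
    data.frame(variant_id = catalog$variant_id, chrom = catalog$chrom,
               pos = catalog$pos, cluster = catalog$cluster,
               stringsAsFactors = FALSE),
    data.frame(variant_id = background$variant_id, chrom = background$chrom,
               pos = background$pos, cluster = NA,
               stringsAsFactors = FALSE))
  ct_names <- paste0("ct", seq_len(cell_types))
  peaks <- list()
  for (ct in ct_names) {
    enr_clusters <- enriched_pairs$cluster[enriched_pairs$cell_type == ct]
    rate <- ifelse(!is.na(all_v$cluster) & all_v$cluster %in% enr_clusters,
                   background_rate * fold, background_rate)
    inpeak <- stats::rbinom(nrow(all_v), 1, rate) == 1
    peaks[[ct]] <- data.frame(chrom = all_v$chrom[inpeak],
                              start = all_v$pos[inpeak] - 100L,
                              end = all_v$pos[inpeak] + 100L,
                              stringsAsFactors = FALSE)
  }
  annotations <- lapply(c(exon = 1, utr3 = 2, utr5 = 3), function(dummy) {
    hit <- stats::rbinom(nrow(all_v), 1, annotation_rate) == 1
    data.frame(chrom = all_v$chrom[hit],
               start = all_v$pos[hit] - 50L,
               end = all_v$pos[hit] + 50L,
               stringsAsFactors = FALSE)
  })
  list(peaks = peaks, annotations = annotations,
       truth = list(enriched_pairs = enriched_pairs,
                    background_rate = background_rate, fold = fold))
}
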