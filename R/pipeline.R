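# Stage-per-subcommand pipeline. Every stage reads only files written by
# earlier stages (plus config) and writes TSVs with documented schemas, so
# the chain is re-runnable and deterministic given the config seed.

stage_paths <- function(outdir) {
  list(config = file.path(outdir, "config.yaml"),
       panel = file.path(outdir, "panel.tsv"),
       catalog = file.path(outdir, "catalog.tsv"),
       sumstats_dir = file.path(outdir, "sumstats"),
       cohort = file.path(outdir, "cohort.tsv"),
       cohort_dosages = file.path(outdir, "cohort_dosages.tsv"),
       regions_dir = file.path(outdir, "regions"),
       region_index = file.path(outdir, "region_index.tsv"),
       peaks_dir = file.path(outdir, "peaks"),
       truth_dir = file.path(outdir, "truth"),
       zmatrix = file.path(outdir, "zmatrix.tsv"),
       proxies = file.path(outdir, "proxies.tsv"),
       clusters = file.path(outdir, "clusters.tsv"),
       assoc = file.path(outdir, "cluster_trait_assoc.tsv"),
       soft = file.path(outdir, "soft_weights.tsv"),
       hardsoft = file.path(outdir, "hard_soft_tests.tsv"),
       coloc = file.path(outdir, "coloc.tsv"),
       tissue_counts = file.path(outdir, "tissue_counts.tsv"),
       enrichment = file.path(outdir, "enrichment.tsv"),
       pgs = file.path(outdir, "pgs.tsv"),
       pgs_assoc = file.path(outdir, "pgs_assoc.tsv"),
       rr = file.path(outdir, "rr.tsv"),
       survival = file.path(outdir, "survival.tsv"),
       hazard = file.path(outdir, "hazard_ratios.tsv"),
       cumhaz = file.path(outdir, "cumhaz.tsv"),
       scan = file.path(outdir, "scan.tsv"),
       report = file.path(outdir, "report.tsv"))
}

#' Generate every synthetic input for the pipeline
#'
#' Writes the reference panel, variant catalog, per-trait summary
#' statistics, cohort (phenotypes plus dosages), paired GWAS/eQTL
#' colocalization regions with an index file, cell-type peak BEDs with
#' annotation BEDs, the planted-truth tables (under `truth/`, consumed only
#' by tests), and an echo of the configuration.
#'
#' @param outdir output directory (created if needed).
#' @param cfg `partpgs_config`.
#' @return `outdir`, invisibly.
#' @export
stage_simulate <- function(outdir, cfg = default_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- stage_paths(outdir)
  syn <- cfg$synthetic
  for (d in c(p$sumstats_dir, p$regions_dir, p$peaks_dir, p$truth_dir))
    dir.create(d, showWarnings = FALSE)
  n_var <- sum(syn$snvs_per_cluster)
  panel <- simulate_reference_panel(
    n_samples = syn$panel_n, n_variants = n_var * syn$panel_block_size,
    block_size = syn$panel_block_size, rho = syn$panel_rho,
    maf_range = syn$maf_range, seed = cfg$seed)
  write_dosages(panel, p$panel)
  gw <- simulate_gwas_matrix(
    k = syn$k, n_traits = syn$n_traits,
    snvs_per_cluster = syn$snvs_per_cluster,
    signature_scale = syn$signature_scale, noise_sd = syn$noise_sd,
    missing_rate = syn$missing_rate, gwas_n = syn$gwas_n,
    seed = cfg$seed + 1L, panel = panel)
  write_tsv(gw$catalog, p$catalog)
  for (tr in names(gw$trait_tables))
    write_sumstats(gw$trait_tables[[tr]],
                   file.path(p$sumstats_dir, paste0(tr, ".tsv")))
  write_tsv(data.frame(variant_id = names(gw$truth$cluster_of),
                       true_cluster = unname(gw$truth$cluster_of),
                       eaf = unname(gw$truth$eaf)),
            file.path(p$truth_dir, "clusters.tsv"))
  co <- simulate_cohort(n = syn$cohort_n, catalog = gw$catalog,
                        truth = gw$truth,
                        prevalence_d1 = syn$disease1_prevalence,
                        seed = cfg$seed + 2L)
  write_tsv(co$cohort, p$cohort)
  write_dosages(list(dosages = t(co$dosages),
                     chrom = stats::setNames(gw$catalog$chrom,
                                             gw$catalog$variant_id),
                     pos = stats::setNames(gw$catalog$pos,
                                           gw$catalog$variant_id)),
               p$cohort_dosages)
  comp_truth <- as.data.frame(co$truth$effects$comp)
  comp_truth <- cbind(data.frame(cluster = seq_len(nrow(comp_truth)),
                                 d1 = co$truth$effects$d1,
                                 sbp = co$truth$effects$sbp,
                                 dbp = co$truth$effects$dbp), comp_truth)
  write_tsv(comp_truth, file.path(p$truth_dir, "cohort_effects.tsv"))
  scenarios <- rep(c("H4", "H3", "H0", "H4", "H1"),
                   length.out = 10L)
  tissues <- paste0("tissue", seq_len(syn$n_eqtl_tissues))
  idx_rows <- list()
  reg_i <- 0L
  for (ri in seq_along(scenarios)) {
    for (tj in seq_along(tissues)) {
      reg_i <- reg_i + 1L
      rid <- sprintf("reg%02d", ri)
      sim <- simulate_eqtl_region(
        scenario = scenarios[ri], n_snps = syn$eqtl_n_snps,
        ld_rho = syn$eqtl_ld_rho, effect_z = syn$eqtl_effect_z,
        seed = cfg$seed + 100L + reg_i, chrom = "2",
        center = 10000000L * ri, region_id = paste0(rid, tissues[tj]))
      write_sumstats(sim$gwas, file.path(
        p$regions_dir, sprintf("%s_%s_gwas.tsv", rid, tissues[tj])))
      write_sumstats(sim$eqtl, file.path(
        p$regions_dir, sprintf("%s_%s_eqtl.tsv", rid, tissues[tj])))
      idx_rows[[reg_i]] <- data.frame(
        region = rid, tissue = tissues[tj],
        index_variant = sim$index_variant, scenario = sim$scenario,
        stringsAsFactors = FALSE)
    }
  }
  idx <- do.call(rbind, idx_rows)
  write_tsv(idx[, c("region", "tissue", "index_variant")], p$region_index)
  write_tsv(idx, file.path(p$truth_dir, "coloc_scenarios.tsv"))
  clustered_catalog <- gw$catalog
  clustered_catalog$cluster <- unname(gw$truth$cluster_of[
    clustered_catalog$variant_id])
  bg_ids <- setdiff(rownames(panel$dosages), gw$catalog$variant_id)
  bg <- data.frame(variant_id = bg_ids,
                   chrom = unname(panel$chrom[bg_ids]),
                   pos = unname(panel$pos[bg_ids]))
  atlas <- simulate_peak_atlas(
    clustered_catalog, bg, cell_types = syn$n_cell_types,
    fold = syn$peak_fold, background_rate = syn$peak_background_rate,
    seed = cfg$seed + 3L)
  for (ct in names(atlas$peaks))
    write_bed(atlas$peaks[[ct]], file.path(p$peaks_dir,
                                           paste0(ct, ".bed")))
  for (ann in names(atlas$annotations))
    write_bed(atlas$annotations[[ann]],
              file.path(outdir, paste0("annotations_", ann, ".bed")))
  write_tsv(atlas$truth$enriched_pairs,
            file.path(p$truth_dir, "enriched_pairs.tsv"))
  write_config(cfg, p$config)
  invisible(outdir)
}

#' Build, filter, impute and winsorize the z-score matrix
#'
#' Reads the catalog, per-trait summary statistics and panel; LD-prunes
#' the catalog; assembles the risk-allele-aligned z matrix with proxy
#' substitution; applies the missingness filter, random-forest imputation
#' and per-column winsorization; writes `zmatrix.tsv` and `proxies.tsv`.
#'
#' @param outdir pipeline directory holding the simulate stage outputs.
#' @param cfg `partpgs_config`.
#' @return the final `zmatrix`, invisibly.
#' @export
stage_zmatrix <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  if (!file.exists(p$catalog))
    stop("no catalog found in ", outdir, "; run the simulate stage first")
  catalog <- read_catalog(p$catalog)
  panel <- read_dosages(p$panel)
  files <- list.files(p$sumstats_dir, pattern = "\\.tsv$",
                      full.names = TRUE)
  trait_tables <- stats::setNames(lapply(files, read_sumstats),
                                  sub("\\.tsv$", "", basename(files)))
  catalog <- prune_independent(catalog, panel, r2_max = cfg$ld_prune_r2)
  zm <- build_zmatrix(catalog, trait_tables, panel = panel,
                      proxy_r2 = cfg$proxy_r2,
                      proxy_window_bp = cfg$proxy_window_bp)
  zm <- filter_missingness(zm, max_frac = cfg$missingness_max)
  zm <- impute_rf(zm, max_iter = cfg$rf_max_iter,
                  n_trees = cfg$rf_n_trees, seed = cfg$seed)
  zm <- truncate_z(zm, k_sd = cfg$truncation_sd)
  write_zmatrix(zm, p$zmatrix)
  write_tsv(zm$proxies, p$proxies)
  invisible(zm)
}

#' Cluster the z matrix and interpret the clusters
#'
#' Ward dendrogram, half-max cut, cluster-trait regression, bNMF soft
#' clustering and the hard/soft comparison tests. Writes `clusters.tsv`,
#' `cluster_trait_assoc.tsv`, `soft_weights.tsv`, `hard_soft_tests.tsv`.
#'
#' @param outdir pipeline directory with `zmatrix.tsv`.
#' @param cfg `partpgs_config`.
#' @param soft run the bNMF comparison (disable to save time).
#' @return list with the hard solution and (optionally) the soft one,
#'   invisibly.
#' @export
stage_cluster <- function(outdir, cfg = default_config(), soft = TRUE) {
  p <- stage_paths(outdir)
  if (!file.exists(p$zmatrix))
    stop("no z matrix found in ", outdir, "; run the zmatrix stage first")
  zm <- read_zmatrix(p$zmatrix)
  catalog <- read_catalog(p$catalog)
  hc <- ward_dendrogram(zm)
  cut <- cut_half_max(hc)
  reg <- cluster_trait_regression(zm, cut$assignment)
  cl_df <- data.frame(variant_id = names(cut$assignment),
                      cluster = unname(cut$assignment))
  cl_df$origin_trait <- catalog$origin_trait[
    match(cl_df$variant_id, catalog$variant_id)]
  write_tsv(cl_df, p$clusters)
  assoc <- do.call(rbind, lapply(colnames(reg$alpha), function(k)
    data.frame(trait = rownames(reg$alpha), cluster = k,
               alpha = reg$alpha[, k], p = reg$alpha_p[, k],
               row.names = NULL)))
  write_tsv(assoc, p$assoc)
  out <- list(linkage = hc, k = cut$k, cut_height = cut$cut_height,
              assignment = cut$assignment, alpha = reg$alpha,
              alpha_p = reg$alpha_p)
  if (soft) {
    bn <- bnmf_soft_cluster(zm, k_max = cfg$bnmf_k_max,
                            n_restarts = cfg$bnmf_n_restarts,
                            seed = cfg$seed)
    sw <- data.frame(variant_id = rownames(bn$variant_weights),
                     bn$variant_weights, check.names = FALSE)
    write_tsv(sw, p$soft)
    cmp <- compare_hard_soft(cut$assignment, bn$variant_weights)
    write_tsv(cmp$deviance_tests, p$hardsoft)
    out$soft <- bn
    out$hard_soft <- cmp
  }
  invisible(out)
}

#' Colocalization over all simulated region/tissue pairs
#'
#' For each entry of `region_index.tsv`: build the +-100 kb region around
#' the index variant from the paired GWAS/eQTL tables, apply the
#' 100-1000-variant QC, compute the five posteriors and the call rule.
#' Index variants in the MHC are excluded up front. Writes `coloc.tsv` and
#' `tissue_counts.tsv`.
#'
#' @param outdir pipeline directory with the simulate stage outputs.
#' @param cfg `partpgs_config`.
#' @return the coloc results data.frame, invisibly.
#' @export
stage_coloc <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  if (!file.exists(p$region_index))
    stop("no region index found in ", outdir,
         "; run the simulate stage first")
  idx <- read_tsv(p$region_index)
  rows <- list()
  for (i in seq_len(nrow(idx))) {
    gwas <- read_sumstats(file.path(
      p$regions_dir, sprintf("%s_%s_gwas.tsv", idx$region[i],
                             idx$tissue[i])))
    eqtl <- read_sumstats(file.path(
      p$regions_dir, sprintf("%s_%s_eqtl.tsv", idx$region[i],
                             idx$tissue[i])))
    iv <- idx$index_variant[i]
    ivm <- match(iv, gwas$variant_id)
    if (!is.na(ivm)) {
      in_mhc <- sub("^chr", "", gwas$chrom[ivm]) ==
        sub("^chr", "", cfg$mhc$chrom) &&
        gwas$pos[ivm] >= cfg$mhc$start && gwas$pos[ivm] <= cfg$mhc$end
      if (in_mhc) next
    }
    reg <- build_region(iv, gwas, eqtl,
                        half_window = cfg$coloc_halfwindow_bp)
    qc <- !reg$flagged && region_qc(reg, cfg$region_min_snps,
                                    cfg$region_max_snps)
    pp <- if (nrow(reg$gwas) > 0)
      coloc_posteriors(reg, p1 = cfg$coloc_p1, p2 = cfg$coloc_p2,
                       p12 = cfg$coloc_p12,
                       prior_sds = unname(cfg$coloc_prior_sd))
    else data.frame(n_snps = 0L, pp_h0 = NA, pp_h1 = NA, pp_h2 = NA,
                    pp_h3 = NA, pp_h4 = NA)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(region = idx$region[i], tissue = idx$tissue[i],
                 index_variant = iv), pp,
      data.frame(qc_pass = qc,
                 called = call_colocalization(pp, qc, cfg$pp_h4_min,
                                              cfg$pp_h3_max)))
  }
  res <- do.call(rbind, rows)
  write_tsv(res, p$coloc)
  counts <- tissue_specific_counts(res)
  write_tsv(counts$per_tissue, p$tissue_counts)
  invisible(res)
}

#' Cell-type regulatory enrichment of each cluster
#'
#' Aggregates the LD-pruned background around the clustered variants, then
#' runs the Firth likelihood-ratio enrichment test for every
#' (cluster, cell type) pair at the Bonferroni threshold over all pairs.
#' Writes `enrichment.tsv`.
#'
#' @param outdir pipeline directory with clusters and peak BEDs.
#' @param cfg `partpgs_config`.
#' @return the enrichment data.frame, invisibly.
#' @export
stage_enrich <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  if (!file.exists(p$clusters))
    stop("no clusters found in ", outdir, "; run the cluster stage first")
  clusters <- read_tsv(p$clusters)
  catalog <- read_catalog(p$catalog)
  catalog$cluster <- clusters$cluster[match(catalog$variant_id,
                                            clusters$variant_id)]
  catalog <- catalog[!is.na(catalog$cluster), , drop = FALSE]
  panel <- read_dosages(p$panel)
  bg <- build_background(catalog, panel,
                         window_bp = cfg$background_window_bp,
                         r2_max = cfg$ld_prune_r2)
  peak_files <- list.files(p$peaks_dir, pattern = "\\.bed$",
                           full.names = TRUE)
  peaks <- stats::setNames(lapply(peak_files, read_bed),
                           sub("\\.bed$", "", basename(peak_files)))
  annotations <- list()
  for (ann in c("exon", "utr3", "utr5")) {
    f <- file.path(outdir, paste0("annotations_", ann, ".bed"))
    if (file.exists(f)) annotations[[ann]] <- read_bed(f)
  }
  ks <- sort(unique(catalog$cluster))
  n_tests <- length(ks) * length(peaks)
  rows <- list()
  for (k in ks) {
    tab <- build_enrichment_table(catalog, k, bg, peaks, annotations)
    for (ct in names(peaks)) {
      r <- enrichment_lr_test(tab, ct, n_tests = n_tests,
                              alpha = cfg$enrich_alpha)
      rows[[length(rows) + 1L]] <- cbind(data.frame(cluster = k), r)
    }
  }
  res <- do.call(rbind, rows)
  write_tsv(res, p$enrichment)
  invisible(res)
}

#' Polygenic scores, associations and top-decile relative risk
#'
#' Computes weighted (P+T, GWAS-significant pruned variants with T2D/SBP
#' weights) and cluster-partitioned unweighted scores, the covariate-
#' adjusted reciprocal associations, the comorbidity case definition
#' (disease 1 plus hypertension from raw BP means/medication), and the
#' top-decile relative risk per cluster. Writes `pgs.tsv`,
#' `pgs_assoc.tsv`, `rr.tsv`.
#'
#' @param outdir pipeline directory with cohort and clusters.
#' @param cfg `partpgs_config`.
#' @return list with profile, associations and RR table, invisibly.
#' @export
stage_pgs <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  if (!file.exists(p$clusters))
    stop("no clusters found in ", outdir, "; run the cluster stage first")
  clusters <- read_tsv(p$clusters)
  cohort <- read_tsv(p$cohort)
  dos <- t(read_dosages(p$cohort_dosages)$dosages)
  assignment <- stats::setNames(clusters$cluster, clusters$variant_id)
  catalog <- read_catalog(p$catalog)
  profile <- partitioned_pgs(dos, assignment)
  covars <- cohort[, c("age", "sex", "array", paste0("pc", 1:6))]
  bp <- prepare_bp_cohort(cohort, med_adjust = cfg$med_adjust)
  htn <- define_hypertension(bp$sbp_raw, bp$dbp_raw, cohort$bp_med == 1,
                             sbp_cut = cfg$htn_sbp, dbp_cut = cfg$htn_dbp)
  comorbid <- cohort$disease1 == 1 & htn
  pgs_df <- data.frame(id = cohort$id, profile, check.names = FALSE)
  weights <- list()
  for (tr in c("T2D", "SBP")) {
    f <- file.path(p$sumstats_dir, paste0(tr, ".tsv"))
    if (!file.exists(f)) next
    ss <- read_sumstats(f)
    sig <- ss[ss$p < 5e-8 & ss$variant_id %in% clusters$variant_id, ,
              drop = FALSE]
    w <- numeric(nrow(sig))
    for (i in seq_len(nrow(sig))) {
      rec <- align_to_risk_allele(
        sig[i, ], catalog$risk_allele[match(sig$variant_id[i],
                                            catalog$variant_id)])
      w[i] <- rec$beta
    }
    weights[[tr]] <- stats::setNames(w, sig$variant_id)
    pgs_df[[paste0("pgs_", tr)]] <- weighted_pgs(dos, weights[[tr]])
  }
  write_tsv(pgs_df, p$pgs)
  assoc_rows <- list()
  add_assoc <- function(score_name, score, pheno_name, pheno, family) {
    a <- pgs_association(score, pheno, covars, family)
    assoc_rows[[length(assoc_rows) + 1L]] <<- cbind(
      data.frame(score = score_name, phenotype = pheno_name,
                 family = family), a)
  }
  for (tr in names(weights)) {
    s <- pgs_df[[paste0("pgs_", tr)]]
    add_assoc(paste0("pgs_", tr), s, "disease1", cohort$disease1,
              "logistic")
    add_assoc(paste0("pgs_", tr), s, "sbp", bp$sbp, "linear")
    add_assoc(paste0("pgs_", tr), s, "hypertension", as.integer(htn),
              "logistic")
  }
  for (k in colnames(profile)) {
    add_assoc(k, profile[, k], "comorbidity", as.integer(comorbid),
              "logistic")
  }
  assoc <- do.call(rbind, assoc_rows)
  write_tsv(assoc, p$pgs_assoc)
  rr_rows <- list()
  for (fr in cfg$top_fractions) {
    for (k in colnames(profile)) {
      grp <- top_fraction_group(profile[, k], fr)
      rr <- relative_risk(grp, comorbid, ci_style = cfg$rr_ci_style)
      rr_rows[[length(rr_rows) + 1L]] <- cbind(
        data.frame(cluster = k, fraction = fr), rr)
    }
  }
  rr_tab <- do.call(rbind, rr_rows)
  write_tsv(rr_tab, p$rr)
  invisible(list(profile = profile, assoc = assoc, rr = rr_tab,
                 comorbid = comorbid))
}

# vectorized BP preparation over a cohort table with two readings each
prepare_bp_cohort <- function(cohort, med_adjust = c(sbp = 15, dbp = 10)) {
  sbp_raw <- rowMeans(cohort[, c("sbp1", "sbp2")])
  dbp_raw <- rowMeans(cohort[, c("dbp1", "dbp2")])
  med <- cohort$bp_med == 1
  list(sbp = sbp_raw + ifelse(med, med_adjust[[1]], 0),
       dbp = dbp_raw + ifelse(med, med_adjust[[2]], 0),
       sbp_raw = sbp_raw, dbp_raw = dbp_raw)
}

#' Survival stratification by dominant cluster
#'
#' Assigns individuals to their dominant cluster (top-33% percentile-rank
#' rule), fits the Cox model of time from first to second diagnosis on the
#' group factor (unassigned individuals are the reference) and writes
#' `survival.tsv`, `hazard_ratios.tsv`, `cumhaz.tsv`.
#'
#' @param outdir pipeline directory with pgs stage outputs.
#' @param cfg `partpgs_config`.
#' @return the [comorbidity_survival()] result, invisibly.
#' @export
stage_survive <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  if (!file.exists(p$pgs))
    stop("no PGS profile found in ", outdir, "; run the pgs stage first")
  pgs_df <- read_tsv(p$pgs)
  cohort <- read_tsv(p$cohort)
  clusters <- read_tsv(p$clusters)
  k_cols <- grep("^cluster", names(pgs_df), value = TRUE)
  profile <- as.matrix(pgs_df[, k_cols, drop = FALSE])
  rownames(profile) <- pgs_df$id
  sizes <- table(paste0("cluster", clusters$cluster))
  grp <- assign_dominant_cluster(profile,
                                 fraction = max(cfg$top_fractions),
                                 cluster_sizes = sizes[k_cols])
  grp[is.na(grp)] <- "unassigned"
  grp <- factor(grp, levels = c("unassigned", k_cols))
  surv <- comorbidity_survival(cohort, grp)
  write_tsv(surv$data, p$survival)
  if (!is.null(surv$hazard_ratios)) write_tsv(surv$hazard_ratios, p$hazard)
  write_tsv(surv$cumhaz, p$cumhaz)
  invisible(surv)
}

#' Scan complication outcomes against partitioned scores
#'
#' Logistic association of every outcome category column (`circulatory`,
#' `renal`, ...) on every cluster's partitioned score with the standard
#' covariates, Bonferroni-corrected. Writes `scan.tsv`.
#'
#' @param outdir pipeline directory with pgs stage outputs.
#' @param cfg `partpgs_config`.
#' @return the scan data.frame, invisibly.
#' @export
stage_scan <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  if (!file.exists(p$pgs))
    stop("no PGS profile found in ", outdir, "; run the pgs stage first")
  pgs_df <- read_tsv(p$pgs)
  cohort <- read_tsv(p$cohort)
  k_cols <- grep("^cluster", names(pgs_df), value = TRUE)
  profile <- as.matrix(pgs_df[, k_cols, drop = FALSE])
  outcome_cols <- c("circulatory", "renal", "neuro", "eye", "metabolic",
                    "respiratory")
  outcome_cols <- intersect(outcome_cols, names(cohort))
  covars <- cohort[, c("age", "sex", "array", paste0("pc", 1:6))]
  res <- complication_scan(profile, cohort[, outcome_cols, drop = FALSE],
                           covars, alpha = cfg$scan_alpha,
                           min_cases = cfg$scan_min_cases)
  res$threshold <- attr(res, "threshold")
  write_tsv(res, p$scan)
  invisible(res)
}

#' Summarize the pipeline's headline numbers
#'
#' Collects cluster count and sizes, colocalization call counts,
#' significant enrichment pairs, per-cluster top-decile relative risks,
#' hazard ratios and significant complication associations into
#' `report.tsv` (one `metric`/`value` pair per row).
#'
#' @param outdir pipeline directory.
#' @param cfg `partpgs_config`.
#' @return the report data.frame, invisibly.
#' @export
stage_report <- function(outdir, cfg = default_config()) {
  p <- stage_paths(outdir)
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = as.character(value))
  if (file.exists(p$clusters)) {
    cl <- read_tsv(p$clusters)
    add("k", length(unique(cl$cluster)))
    sz <- sort(table(cl$cluster), decreasing = TRUE)
    add("cluster_sizes", paste(sz, collapse = "/"))
  }
  if (file.exists(p$coloc)) {
    co <- read_tsv(p$coloc)
    add("n_coloc_called", sum(co$called))
    add("n_coloc_tested", nrow(co))
  }
  if (file.exists(p$enrichment)) {
    en <- read_tsv(p$enrichment)
    add("n_enriched_pairs", sum(en$significant, na.rm = TRUE))
  }
  if (file.exists(p$rr)) {
    rr <- read_tsv(p$rr)
    top10 <- rr[rr$fraction == 0.10, ]
    for (i in seq_len(nrow(top10)))
      add(paste0("rr_top10_", top10$cluster[i]),
          sprintf("%.3f", top10$rr[i]))
  }
  if (file.exists(p$hazard)) {
    hr <- read_tsv(p$hazard)
    for (i in seq_len(nrow(hr)))
      add(paste0("hr_", hr$group[i]), sprintf("%.3f", hr$hr[i]))
  }
  if (file.exists(p$scan)) {
    sc <- read_tsv(p$scan)
    add("n_scan_significant", sum(sc$significant, na.rm = TRUE))
  }
  rep <- do.call(rbind, rows)
  write_tsv(rep, p$report)
  invisible(rep)
}

#' Run the full pipeline
#'
#' All stages in order: simulate, zmatrix, cluster, coloc, enrich, pgs,
#' survive, scan, report.
#'
#' @param outdir output directory.
#' @param cfg `partpgs_config`.
#' @param soft run the bNMF comparison in the cluster stage.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(outdir, cfg = default_config(), soft = TRUE) {
  stage_simulate(outdir, cfg)
  stage_zmatrix(outdir, cfg)
  stage_cluster(outdir, cfg, soft = soft)
  stage_coloc(outdir, cfg)
  stage_enrich(outdir, cfg)
  stage_pgs(outdir, cfg)
  stage_survive(outdir, cfg)
  stage_scan(outdir, cfg)
  stage_report(outdir, cfg)
  invisible(outdir)
}

#' Command-line entry point
#'
#' `run_cli(c("<subcommand>", flags...))` with subcommands `simulate`,
#' `zmatrix`, `cluster`, `coloc`, `enrich`, `pgs`, `survive`, `scan`,
#' `report` and global flags `--config <yaml>`, `--seed <int>`,
#' `--outdir <dir>` (default "."). Unknown subcommands print usage and
#' return a nonzero status. A thin Rscript wrapper is installed at
#' `system.file("cli", "partpgs", package = "partpgs")`.
#'
#' @param argv character vector of arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(argv) {
  usage <- paste(
    "usage: partpgs <subcommand> [--config file.yaml] [--seed N]",
    "[--outdir dir]\n  subcommands: simulate zmatrix cluster coloc",
    "enrich pgs survive scan report")
  stages <- list(simulate = stage_simulate, zmatrix = stage_zmatrix,
                 cluster = stage_cluster, coloc = stage_coloc,
                 enrich = stage_enrich, pgs = stage_pgs,
                 survive = stage_survive, scan = stage_scan,
                 report = stage_report)
  if (length(argv) == 0 || !argv[1] %in% names(stages)) {
    message(usage)
    return(invisible(1L))
  }
  sub <- argv[1]
  argv <- argv[-1]
  grab <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 0) return(default)
    if (i[1] == length(argv)) stop("flag ", flag, " needs a value")
    argv[i[1] + 1L]
  }
  status <- tryCatch({
    outdir <- grab("--outdir", ".")
    cfg_path <- grab("--config")
    seed <- grab("--seed")
    cfg <- if (!is.null(cfg_path)) read_config(cfg_path) else {
      echoed <- file.path(outdir, "config.yaml")
      if (sub != "simulate" && file.exists(echoed)) read_config(echoed)
      else default_config()
    }
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    stages[[sub]](outdir, cfg)
    0L
  }, error = function(e) {
    message("partpgs ", sub, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
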