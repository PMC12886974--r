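test_that("reference panel honours the block-AR(1) LD structure", {
  pan0 <- simulate_reference_panel(n_samples = 500, n_variants = 60,
                                   block_size = 1, rho = 0, seed = 5)
  r2s <- c()
  for (i in seq(1, 59, by = 2))
    r2s <- c(r2s, ld_r2(pan0$dosages[i, ], pan0$dosages[i + 1, ]))
  expect_lte(mean(r2s), 3 / 500 + 0.02)

  pan <- simulate_reference_panel(n_samples = 500, n_variants = 100,
                                  block_size = 10, rho = 0.95, seed = 6)
  adj <- c()
  for (i in 1:99) {
    if (pan$block[i] == pan$block[i + 1])
      adj <- c(adj, ld_r2(pan$dosages[i, ], pan$dosages[i + 1, ]))
  }
  expect_gt(mean(adj), 0.6)
  # across blocks: independent
  cross <- c()
  for (i in which(diff(pan$block) == 1))
    cross <- c(cross, ld_r2(pan$dosages[i, ], pan$dosages[i + 1, ]))
  expect_lt(mean(cross), 0.05)

  pan2 <- simulate_reference_panel(n_samples = 500, n_variants = 100,
                                   block_size = 10, rho = 0.95, seed = 6)
  expect_identical(pan$dosages, pan2$dosages)
  expect_error(simulate_reference_panel(rho = 1), "rho")
  expect_error(simulate_reference_panel(n_samples = 10), "50")
})

test_that("planted GWAS matrix meets its noiseless, missingness and K = 1
           contracts", {
  gw0 <- simulate_gwas_matrix(k = 2, n_traits = 10,
                              snvs_per_cluster = c(4, 4),
                              signature_scale = 4, noise_sd = 0,
                              missing_rate = 0, seed = 3)
  z <- build_zmatrix(gw0$catalog, gw0$trait_tables)$z
  for (v in rownames(z))
    expect_equal(unname(z[v, ]),
                 unname(gw0$truth$signatures[gw0$truth$cluster_of[[v]], ]),
                 tolerance = 1e-9)

  gw <- simulate_gwas_matrix(seed = 4)
  n_var <- length(gw$truth$cluster_of)
  n_cells <- n_var * 45
  n_obs <- sum(vapply(gw$trait_tables, nrow, integer(1)))
  frac_missing <- 1 - n_obs / n_cells
  expect_gt(frac_missing, 0.09)
  expect_lt(frac_missing, 0.11)

  one <- simulate_gwas_matrix(k = 1, n_traits = 6,
                              snvs_per_cluster = 5L,
                              signature_scale = 3, noise_sd = 0.4,
                              missing_rate = 0, seed = 8)
  z1 <- build_zmatrix(one$catalog, one$trait_tables)$z
  spread <- apply(z1, 2, sd)
  expect_true(all(spread < 3 * 0.4))
  expect_error(simulate_gwas_matrix(missing_rate = 1), "missing_rate")
  expect_error(simulate_gwas_matrix(k = 2, snvs_per_cluster = c(2, 1)),
               ">= 2")
})

test_that("cohort generator: null genetic effects give null associations,
           planted effects are recovered, prevalence is on target", {
  gw <- simulate_gwas_matrix(k = 3, n_traits = 9,
                             snvs_per_cluster = c(40, 40, 40),
                             signature_scale = 5, noise_sd = 1,
                             missing_rate = 0, seed = 14)
  null_eff <- list(d1 = rep(0, 3), sbp = rep(0, 3), dbp = rep(0, 3),
                   comp = matrix(0, 3, 6,
                                 dimnames = list(NULL,
                                   c("circulatory", "renal", "neuro",
                                     "eye", "metabolic", "respiratory"))))
  co0 <- simulate_cohort(n = 10000, gw$catalog, gw$truth,
                         prevalence_d1 = 0.10, effects = null_eff,
                         seed = 15)
  prof <- partitioned_pgs(co0$dosages, co0$truth$cluster_of)
  covars <- co0$cohort[, c("age", "sex", "array", paste0("pc", 1:6))]
  a0 <- pgs_association(prof[, 1], co0$cohort$disease1, covars,
                        "logistic")
  expect_lt(abs(a0$z), 3)
  expect_lt(abs(mean(co0$cohort$disease1) - 0.10),
            2 * sqrt(0.1 * 0.9 / 10000))

  co1 <- simulate_cohort(n = 10000, gw$catalog, gw$truth,
                         prevalence_d1 = 0.10, seed = 16)
  prof1 <- partitioned_pgs(co1$dosages, co1$truth$cluster_of)
  a1 <- pgs_association(scale(prof1[, 2]), co1$cohort$disease1,
                        co1$cohort[, c("age", "sex", "array",
                                       paste0("pc", 1:6))], "logistic")
  expect_gt(a1$estimate, 1)       # planted positive cluster-2 effect
  expect_lt(a1$p, 1e-4)
  expect_error(simulate_cohort(n = 10000, gw$catalog, gw$truth,
                               prevalence_d1 = 1.5, seed = 1),
               "unattainable")
  expect_error(simulate_cohort(n = 10, gw$catalog, gw$truth),
               "1000")
})

test_that("eQTL region generator plants the stated causal configuration", {
  h0 <- simulate_eqtl_region("H0", n_snps = 100, effect_z = 8, seed = 21)
  expect_lt(max(abs(h0$gwas$beta / h0$gwas$se)), 5)
  expect_lt(max(abs(h0$eqtl$beta / h0$eqtl$se)), 5)

  h4 <- simulate_eqtl_region("H4", n_snps = 300, effect_z = 8, seed = 22)
  expect_equal(h4$causal$gwas, h4$causal$eqtl)
  pp <- coloc_posteriors(list(gwas = h4$gwas, eqtl = h4$eqtl))
  expect_gt(pp$pp_h4, 0.8)

  h3 <- simulate_eqtl_region("H3", n_snps = 300, effect_z = 8, seed = 23)
  expect_false(h3$causal$gwas == h3$causal$eqtl)
  pp3 <- coloc_posteriors(list(gwas = h3$gwas, eqtl = h3$eqtl))
  expect_gt(pp3$pp_h3, 0.5)

  again <- simulate_eqtl_region("H4", n_snps = 300, effect_z = 8,
                                seed = 22)
  expect_identical(again$gwas$beta, h4$gwas$beta)
  expect_error(simulate_eqtl_region("H4", n_snps = 2), "n_snps")
})

test_that("peak atlas plants enrichment at the requested fold and stays at
           background elsewhere", {
  set.seed(25)
  catal <- make_catalog(sprintf("c%03d", 1:300),
                        pos = seq(10000, by = 5000, length.out = 300))
  catal$cluster <- rep(1:3, each = 100)
  bg <- data.frame(variant_id = sprintf("b%03d", 1:500), chrom = "1",
                   pos = seq(2e6, by = 5000, length.out = 500))
  atlas <- simulate_peak_atlas(catal, bg, cell_types = 4,
                               enriched_pairs = data.frame(
                                 cell_type = "ct1", cluster = 1),
                               fold = 3, background_rate = 0.10,
                               seed = 26)
  member <- function(ct, chrom, pos)
    mean(in_intervals(chrom, pos, atlas$peaks[[ct]]))
  rate_fg <- member("ct1", catal$chrom[catal$cluster == 1],
                    catal$pos[catal$cluster == 1])
  rate_other <- member("ct1", catal$chrom[catal$cluster != 1],
                       catal$pos[catal$cluster != 1])
  rate_bg <- member("ct2", bg$chrom, bg$pos)
  expect_gt(rate_fg, 0.2)
  se2 <- 2 * sqrt(0.1 * 0.9 / 200)
  expect_lt(abs(rate_other - 0.10), se2)
  expect_lt(abs(rate_bg - 0.10), 2 * sqrt(0.1 * 0.9 / 500))
  expect_error(simulate_peak_atlas(catal, bg, fold = 20,
                                   background_rate = 0.1),
               "probability")
  expect_error(simulate_peak_atlas(catal, bg, fold = 0.5), "fold")
})

test_that("a null peak atlas yields calibrated enrichment tests", {
  set.seed(27)
  catal <- make_catalog(sprintf("c%03d", 1:200),
                        pos = seq(10000, by = 5000, length.out = 200))
  catal$cluster <- rep(1:2, each = 100)
  bg <- data.frame(variant_id = sprintf("b%03d", 1:600), chrom = "1",
                   pos = seq(2e6, by = 5000, length.out = 600))
  ps <- c()
  for (s in 1:5) {
    atlas <- simulate_peak_atlas(catal, bg, cell_types = 4,
                                 enriched_pairs = data.frame(
                                   cell_type = character(0),
                                   cluster = integer(0)),
                                 fold = 1, background_rate = 0.10,
                                 seed = 30 + s)
    tab <- build_enrichment_table(catal, 1, bg, atlas$peaks,
                                  atlas$annotations)
    for (ct in names(atlas$peaks))
      ps <- c(ps, enrichment_lr_test(tab, ct)$p)
  }
  expect_gt(mean(ps), 0.25)
  expect_lte(sum(ps < 0.05), 4)
})
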