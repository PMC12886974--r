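test_that("z-scores are beta/se with the sample-size-adjusted variant", {
  expect_equal(zscore(0.10, 0.05), 2.0)
  expect_equal(zscore(0, 0.3), 0)
  expect_error(zscore(0.1, 0), "se")
  expect_equal(zscore_size_adjusted(0.10, 0.05, 100), 0.2)
  expect_equal(zscore_size_adjusted(0.1, 0.02, 1), zscore(0.1, 0.02))
  expect_equal(zscore_size_adjusted(0.1, 0.02, 50),
               zscore_size_adjusted(0.1, 0.02, 100) * sqrt(2))
  expect_error(zscore_size_adjusted(0.1, 0.02, 0), "n")
})

test_that("risk-allele alignment flips sign, swaps alleles, is involutive", {
  rec <- as_sumstats(make_sumstats_df(1, beta = 0.2))[1, ]
  expect_identical(align_to_risk_allele(rec, "A"), rec)
  flipped <- align_to_risk_allele(rec, "G")
  expect_equal(flipped$beta, -0.2)
  expect_equal(flipped$effect_allele, "G")
  expect_equal(flipped$other_allele, "A")
  expect_equal(flipped$eaf, 1 - rec$eaf)
  expect_equal(align_to_risk_allele(flipped, "A"), rec)
  expect_error(align_to_risk_allele(rec, "T"), "neither")
})

test_that("noiseless matrix build recovers planted signatures exactly", {
  gw <- simulate_gwas_matrix(k = 3, n_traits = 12,
                             snvs_per_cluster = c(5, 5, 5),
                             signature_scale = 4, noise_sd = 0,
                             missing_rate = 0, seed = 2)
  zm <- build_zmatrix(gw$catalog, gw$trait_tables)
  expect_false(any(is.na(zm$z)))
  for (v in rownames(zm$z)) {
    k <- gw$truth$cluster_of[[v]]
    expect_equal(unname(zm$z[v, ]), unname(gw$truth$signatures[k, ]),
                 tolerance = 1e-9)
  }
  expect_true(all(zm$mask == "observed"))
})

test_that("global beta sign flip flips every z (alignment disabled)", {
  gw <- simulate_gwas_matrix(k = 2, n_traits = 8,
                             snvs_per_cluster = c(4, 4),
                             signature_scale = 3, noise_sd = 0.5,
                             missing_rate = 0, seed = 5)
  neg <- lapply(gw$trait_tables, function(t) { t$beta <- -t$beta; t })
  z1 <- build_zmatrix(gw$catalog, gw$trait_tables, align = FALSE)$z
  z2 <- build_zmatrix(gw$catalog, neg, align = FALSE)$z
  expect_equal(z2, -z1)
})

test_that("missingness filter removes rows strictly above the threshold", {
  z <- matrix(rnorm(3 * 45), 3, 45,
              dimnames = list(paste0("v", 1:3), paste0("t", 1:45)))
  z[1, 1:10] <- NA          # 22.2% missing -> removed
  z[2, 1:9] <- NA           # 20.0% missing -> retained (strict rule)
  zm <- structure(list(z = z, mask = ifelse(is.na(z), "missing",
                                            "observed"),
                       catalog = make_catalog(rownames(z))),
                  class = "zmatrix")
  out <- suppressMessages(filter_missingness(zm, max_frac = 0.20))
  expect_setequal(rownames(out$z), c("v2", "v3"))
  expect_equal(attr(out, "removed"), "v1")
})

test_that("random-forest imputation preserves observed cells and beats
           column-mean imputation on a planted low-rank matrix", {
  set.seed(21)
  W <- matrix(runif(200 * 2, 0, 2), 200, 2)
  H <- matrix(runif(2 * 10, 0, 2), 2, 10)
  full <- W %*% H + matrix(rnorm(2000, 0, 0.05), 200, 10)
  dimnames(full) <- list(paste0("v", 1:200), paste0("t", 1:10))
  mask <- matrix(runif(2000) < 0.10, 200, 10)
  z <- full; z[mask] <- NA
  zm <- structure(list(z = z, mask = ifelse(is.na(z), "missing",
                                            "observed"),
                       catalog = make_catalog(rownames(z))),
                  class = "zmatrix")
  imp <- suppressMessages(impute_rf(zm, seed = 9))
  expect_false(any(is.na(imp$z)))
  expect_identical(imp$z[!mask], full[!mask])
  expect_true(all(imp$mask[mask] == "imputed"))
  rf_rmse <- sqrt(mean((imp$z[mask] - full[mask])^2))
  cm <- z
  for (j in 1:10) cm[mask[, j], j] <- mean(z[, j], na.rm = TRUE)
  mean_rmse <- sqrt(mean((cm[mask] - full[mask])^2))
  expect_lt(rf_rmse, mean_rmse)

  # no-missing input returned unchanged
  zm_full <- structure(list(z = full,
                            mask = matrix("observed", 200, 10,
                                          dimnames = dimnames(full)),
                            catalog = NULL), class = "zmatrix")
  expect_identical(suppressMessages(impute_rf(zm_full))$z, full)
})

test_that("winsorization clips to post-hoc column bounds only", {
  vals <- c(rep(0, 10), 30, -30)
  z <- cbind(a = vals, b = rnorm(12, 0, 0.5))
  rownames(z) <- paste0("v", 1:12)
  zm <- structure(list(z = z,
                       mask = matrix("observed", 12, 2,
                                     dimnames = dimnames(z))),
                  class = "zmatrix")
  out <- suppressMessages(truncate_z(zm, k_sd = 2))
  bound <- mean(vals) + 2 * sd(vals)
  expect_equal(out$z["v11", "a"], bound)
  expect_equal(out$z["v12", "a"], -bound)
  expect_true(out$truncated["v11", "a"])
  expect_equal(sum(out$truncated[, "a"]), 2)
  # definitional post-condition on every column
  for (j in 1:2) {
    mu <- mean(z[, j]); s <- sd(z[, j])
    expect_true(all(abs(out$z[, j] - mu) <= 2 * s + 1e-12))
  }
  # a column with one mild outlier is untouched: bounds use post-hoc stats
  v2 <- c(0, 0, 0, 0, 20)
  zm2 <- structure(list(z = cbind(a = v2),
                        mask = matrix("observed", 5, 1)),
                   class = "zmatrix")
  expect_equal(suppressMessages(truncate_z(zm2))$z[, "a"], v2)
  expect_error(truncate_z(structure(list(z = cbind(a = c(1, NA))),
                                    class = "zmatrix")), "impute")
})

test_that("z matrix TSV round trip preserves values and mask", {
  gw <- simulate_gwas_matrix(k = 2, n_traits = 6,
                             snvs_per_cluster = c(3, 3),
                             signature_scale = 3, noise_sd = 0.3,
                             missing_rate = 0, seed = 7)
  zm <- build_zmatrix(gw$catalog, gw$trait_tables)
  path <- tempfile(fileext = ".tsv")
  write_zmatrix(zm, path)
  back <- read_zmatrix(path)
  expect_equal(back$z, zm$z, tolerance = 1e-12)
  expect_equal(back$mask, zm$mask)
})
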