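test_that("Ward dendrogram merges nearest groups first, monotone heights", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hc <- ward_dendrogram(m)
  expect_equal(hc$height[1], 0)
  m2 <- matrix(c(0, 1, 10), ncol = 1)
  hc2 <- ward_dendrogram(m2)
  # first merge joins leaves 1 and 2 (points 0 and 1), matching the Ward
  # objective enumerated over all merge orders for three 1-D points
  expect_setequal(-hc2$merge[1, ], c(1, 2))
  set.seed(13)
  hc3 <- ward_dendrogram(matrix(rnorm(100), 20, 5))
  expect_true(all(diff(hc3$height) >= -1e-12))
  expect_error(ward_dendrogram(rbind(c(1, NA), c(0, 0))), "impute")
  expect_error(ward_dendrogram(matrix(1, 1, 3)), "2 rows")
})

test_that("half-max cut severs merges above half the top height", {
  fake <- structure(list(merge = rbind(c(-1, -2), c(-3, -4), c(1, 2)),
                         height = c(1, 2, 10), order = 1:4,
                         labels = paste0("v", 1:4),
                         method = "ward.D2"),
                    class = "hclust")
  cut <- cut_half_max(fake)
  expect_equal(cut$cut_height, 5)
  expect_equal(cut$k, 2)
  expect_equal(unname(cut$assignment[c("v1", "v2")]),
               unname(cut$assignment[c("v2", "v1")]))
  expect_false(cut$assignment[["v1"]] == cut$assignment[["v3"]])

  # all heights equal: the cut at h/2 severs everything
  flat <- structure(list(merge = rbind(c(-1, -2), c(-3, -4), c(1, 2)),
                         height = c(3, 3, 3), order = 1:4,
                         labels = paste0("v", 1:4),
                         method = "ward.D2"),
                    class = "hclust")
  expect_equal(cut_half_max(flat)$k, 4)
})

test_that("cluster labels are ordered by descending size and row order
           does not change memberships", {
  gw <- simulate_gwas_matrix(k = 3, n_traits = 12,
                             snvs_per_cluster = c(10, 6, 3),
                             signature_scale = 5, noise_sd = 0.5,
                             missing_rate = 0, seed = 31)
  z <- build_zmatrix(gw$catalog, gw$trait_tables)$z
  cut <- cut_half_max(ward_dendrogram(z))
  sizes <- table(cut$assignment)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  perm <- sample(nrow(z))
  cut2 <- cut_half_max(ward_dendrogram(z[perm, ]))
  expect_equal(cut$k, cut2$k)
  for (k in seq_len(cut$k)) {
    expect_setequal(names(cut$assignment)[cut$assignment == k],
                    names(cut2$assignment)[cut2$assignment == k])
  }
})

test_that("cluster-trait regression coefficients are cluster means with
           calibrated t-tests", {
  z <- cbind(t1 = c(1, 3, 10, 14))
  rownames(z) <- paste0("v", 1:4)
  assign1 <- setNames(c(1, 1, 2, 2), rownames(z))
  reg <- cluster_trait_regression(z, assign1)
  expect_equal(unname(reg$alpha["t1", ]), c(2, 12))
  one <- cluster_trait_regression(z, setNames(rep(1, 4), rownames(z)))
  expect_equal(unname(one$alpha["t1", 1]), mean(z))

  # null calibration: pure-noise columns give ~5% of p below 0.05
  set.seed(17)
  ps <- replicate(400, {
    zz <- cbind(x = rnorm(30))
    rownames(zz) <- paste0("v", 1:30)
    a <- setNames(rep(1:3, each = 10), rownames(zz))
    cluster_trait_regression(zz, a)$alpha_p
  })
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("adjusted Rand index matches a hand-computed contingency case", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  # contingency 2/1/0/3: sum_ij C2 = 4; sum_a = 6, sum_b = 7, C(6,2) = 15
  # ARI = (4 - 6*7/15) / ((6+7)/2 - 6*7/15)
  expect_equal(adjusted_rand_index(a, b), (4 - 2.8) / (6.5 - 2.8),
               tolerance = 1e-12)
})

test_that("ARD bNMF recovers an exact nonnegative rank-2 factorization", {
  set.seed(23)
  W0 <- matrix(runif(30 * 2, 0.2, 2), 30, 2)
  H0 <- matrix(runif(2 * 8, 0.2, 2), 2, 8)
  A <- W0 %*% H0
  # feed the signed interface a matrix whose positive part is A
  dimnames(A) <- list(paste0("v", 1:30), paste0("t", 1:8))
  fit <- bnmf_soft_cluster(A, k_max = 6, n_restarts = 6, seed = 3)
  expect_equal(fit$k, 2)
  recon <- fit$variant_weights_raw %*% t(fit$trait_weights_signed)
  rel_err <- sqrt(sum((cbind(A, 0 * A) - recon)^2) / sum(A^2))
  expect_lt(rel_err, 1e-3)
  expect_true(all(fit$variant_weights >= 0))
  expect_true(all(fit$trait_weights >= 0))
})

test_that("soft assignment applies the 0.75 normalized-weight rule", {
  w <- rbind(v1 = c(8, 1, 1), v2 = c(4, 3, 3), v3 = c(0, 0, 0))
  out <- soft_assignment(w, min_weight = 0.75)
  expect_equal(out[["v1"]], 1L)
  expect_true(is.na(out[["v2"]]))
  expect_true(is.na(out[["v3"]]))
})

test_that("hard/soft comparison detects one-hot concordance and stays
           calibrated under independence", {
  set.seed(29)
  assign1 <- setNames(rep(1:3, each = 20), paste0("v", 1:60))
  onehot <- sapply(1:3, function(k) as.numeric(assign1 == k))
  rownames(onehot) <- names(assign1)
  cmp <- compare_hard_soft(assign1, onehot)
  expect_true(all(cmp$deviance_tests$separable))
  expect_true(all(cmp$deviance_tests$p < 1e-6))

  ps <- replicate(60, {
    w <- matrix(runif(60 * 3), 60, 3,
                dimnames = list(names(assign1), NULL))
    compare_hard_soft(assign1, w)$deviance_tests$p
  })
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.3)

  tw <- matrix(runif(24), 8, 3, dimnames = list(paste0("t", 1:8), NULL))
  cmp2 <- compare_hard_soft(assign1, onehot, trait_weights_a = tw,
                            trait_weights_b = tw)
  expect_equal(unname(diag(cmp2$trait_cor)), rep(1, 3))
  cmp3 <- compare_hard_soft(assign1, onehot, other_assignment = assign1)
  expect_lt(cmp3$independence$p.value, 1e-10)
})
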