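test_that("blood-pressure preparation averages readings and applies the
           medication offsets", {
  expect_equal(prepare_bp(c(140, 150), c(80, 90), FALSE)$sbp, 145)
  med <- prepare_bp(135, 85, TRUE)
  raw <- prepare_bp(135, 85, FALSE)
  expect_equal(med$sbp - raw$sbp, 15)
  expect_equal(med$dbp - raw$dbp, 10)
  expect_equal(med$pp, med$sbp - med$dbp)
  expect_equal(med$sbp_raw, 135)
  expect_error(prepare_bp(numeric(0), 80, FALSE), "readings")
})

test_that("hypertension rule: SBP >= 150 or DBP >= 90 or medication", {
  expect_false(define_hypertension(149, 89, FALSE))
  expect_true(define_hypertension(150, 80, FALSE))
  expect_true(define_hypertension(120, 90, FALSE))
  expect_true(define_hypertension(120, 70, TRUE))
  expect_true(is.na(define_hypertension(NA, NA, NA)))
})

test_that("weighted PGS sums weight x dosage with 2EAF fallback and the
           allele-flip identity", {
  dos <- matrix(c(0, 1, 2, 2, 0, 1), 3, 2,
                dimnames = list(paste0("i", 1:3), c("v1", "v2")))
  expect_equal(weighted_pgs(dos * 0, c(v1 = 0.3, v2 = -0.1)), rep(0, 3),
               ignore_attr = TRUE)
  expect_equal(unname(weighted_pgs(dos, c(v1 = 0.3), "v1")),
               c(0, 0.3, 0.6))
  # flipping orientation: -w * (2 - d) + 2w == w * d
  flipped <- dos
  flipped[, "v1"] <- 2 - dos[, "v1"]
  s1 <- weighted_pgs(dos, c(v1 = 0.3), "v1")
  s2 <- weighted_pgs(flipped, c(v1 = -0.3), "v1") + 2 * 0.3
  expect_equal(s1, s2)
  s3 <- suppressMessages(weighted_pgs(dos, c(v1 = 0.3, v3 = 0.5),
                                      eaf = c(v3 = 0.25)))
  expect_equal(unname(s3), unname(s1) + 0.5 * 2 * 0.25)
  expect_error(weighted_pgs(dos, c(v3 = 0.5)), "no dosage")
})

test_that("partitioned PGS counts risk alleles per cluster additively", {
  dos <- matrix(c(0, 1, 2, 2, 2, 2, 1, 0, 2), 3, 3,
                dimnames = list(paste0("i", 1:3), paste0("v", 1:3)))
  assign1 <- c(v1 = 1, v2 = 1, v3 = 2)
  prof <- partitioned_pgs(dos, assign1)
  expect_equal(unname(prof[, "cluster1"]), c(2, 3, 4))
  expect_equal(unname(prof[, "cluster2"]), c(1, 0, 2))
  expect_true(all(prof >= 0 & prof <= 2 * 2))
  # additivity over disjoint clusters
  merged <- partitioned_pgs(dos, c(v1 = 9, v2 = 9, v3 = 9))
  expect_equal(unname(merged[, 1]), unname(rowSums(prof)))
  expect_equal(unname(partitioned_pgs(dos * 0, assign1)[, 1]), rep(0, 3))
})

test_that("PGS association is calibrated under the null and recovers a
           planted log-OR with nominal coverage", {
  covars <- std_covariates(10000, seed = 61)
  set.seed(62)
  pgs <- rnorm(10000)
  y_null <- rbinom(10000, 1, 0.2)
  a <- pgs_association(pgs, y_null, covars, "logistic")
  expect_lt(abs(a$z), 3)

  set.seed(63)
  covered <- replicate(100, {
    n <- 2000
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1.5 + 0.2 * s))
    fit <- pgs_association(s, y, std_covariates(n, seed = NULL),
                           "logistic")
    fit$ci_low <= exp(0.2) && exp(0.2) <= fit$ci_high
  })
  expect_gte(sum(covered), 90)

  # affine invariance of the slope
  x <- rnorm(500)
  y <- x + rnorm(500)
  cv <- std_covariates(500, seed = 64)
  f1 <- pgs_association(x, y, cv, "linear")
  f2 <- pgs_association(x + 100, y, cv, "linear")
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-9)
})

test_that("top-fraction groups use the strict upper quantile with tie
           inclusion", {
  expect_equal(sum(top_fraction_group(1:10, 0.10)), 1)
  expect_true(top_fraction_group(1:10, 0.10)[10])
  expect_equal(sum(top_fraction_group(sample(1:1000), 0.10)), 100)
  expect_warning(grp <- top_fraction_group(rep(5, 20), 0.10), "equal")
  expect_true(all(grp))
})

test_that("relative risk reproduces the printed formula and its limits", {
  cases <- c(rep(TRUE, 50), rep(FALSE, 950))
  whole <- relative_risk(rep(TRUE, 1000), cases)
  expect_equal(whole$rr, 1)
  expect_equal(whole$ci_low, 1)
  expect_equal(whole$ci_high, 1)

  group <- c(rep(TRUE, 100), rep(FALSE, 900))
  cases2 <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 40), rep(FALSE, 860))
  rr <- relative_risk(group, cases2)
  expect_equal(rr$rr, 2.0)
  expect_equal(rr$ci_low, exp(log(2) - 1.96 * sqrt(1 / 10 - 1 / 50)),
               tolerance = 1e-12)
  expect_equal(rr$ci_high, exp(log(2) + 1.96 * sqrt(1 / 10 - 1 / 50)),
               tolerance = 1e-12)
  # doubling group cases at fixed prevalence narrows the interval
  group3 <- c(rep(TRUE, 200), rep(FALSE, 800))
  cases3 <- c(rep(TRUE, 20), rep(FALSE, 180), rep(TRUE, 30), rep(FALSE, 770))
  rr3 <- relative_risk(group3, cases3)
  expect_lt(rr3$ci_high / rr3$ci_low, rr$ci_high / rr$ci_low)

  none <- relative_risk(c(TRUE, TRUE, FALSE, FALSE),
                        c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(none$rr, 0)
  expect_true(none$flagged)

  std <- relative_risk(group, cases2, ci_style = "standard")
  expect_equal(std$ci_low,
               exp(log(2) - 1.96 * sqrt(1 / 10 - 1 / 100 + 1 / 50 - 1 / 1000)))
})

test_that("dominant-cluster assignment uses percentile ranks, the top-33%
           gate and the declared tie-break", {
  set.seed(67)
  prof <- cbind(cluster1 = rnorm(300), cluster2 = rnorm(300))
  rownames(prof) <- paste0("i", 1:300)
  out <- assign_dominant_cluster(prof, fraction = 0.33)
  ranks <- apply(prof, 2, rank) / 300
  top <- apply(ranks, 1, max) > 2 / 3
  expect_equal(unname(!is.na(out)), unname(top))
  idx <- which(!is.na(out))[1:20]
  expect_equal(unname(out[idx]),
               colnames(prof)[max.col(ranks[idx, ], "first")])
  # exact tie: the larger cluster wins
  tie <- cbind(cluster1 = c(1, 2, 3, 4), cluster2 = c(1, 2, 3, 4))
  rownames(tie) <- paste0("i", 1:4)
  out_tie <- assign_dominant_cluster(tie, fraction = 0.5,
                                     cluster_sizes = c(cluster1 = 10,
                                                       cluster2 = 99))
  expect_equal(unname(out_tie[4]), "cluster2")
})

test_that("comorbidity survival handles censoring, same-day exclusion and
           date-shift invariance", {
  n <- 200
  cohort <- data.frame(
    diag1_day = c(rep(1000L, 150), rep(NA, 50)),
    diag2_day = c(1000L + c(rep(300L, 100), rep(NA, 50)),
                  rep(2000L, 50)),
    followup_end_day = 5000L)
  cohort$diag2_day[1] <- 1000L            # same-day pair, must be excluded
  grp <- factor(rep(c("a", "b"), 100))
  surv <- suppressMessages(comorbidity_survival(cohort, grp))
  expect_equal(surv$n_excluded_same_day, 1)
  expect_equal(nrow(surv$data), 199)
  shifted <- cohort
  shifted$diag1_day <- shifted$diag1_day + 777L
  shifted$diag2_day <- shifted$diag2_day + 777L
  shifted$followup_end_day <- shifted$followup_end_day + 777L
  surv2 <- suppressMessages(comorbidity_survival(shifted, grp))
  expect_equal(surv2$cumhaz$cumhaz, surv$cumhaz$cumhaz)
  expect_equal(surv2$hazard_ratios$hr, surv$hazard_ratios$hr)

  # a group with no events has identically zero cumulative hazard
  cohort_ne <- data.frame(diag1_day = rep(100L, 60),
                          diag2_day = c(rep(400L, 30), rep(NA, 30)),
                          followup_end_day = 1000L)
  grp_ne <- factor(rep(c("ev", "none"), each = 30))
  s <- suppressWarnings(comorbidity_survival(cohort_ne, grp_ne))
  expect_true(all(s$cumhaz$cumhaz[s$cumhaz$group == "none"] == 0))

  bad <- data.frame(diag1_day = 100L, diag2_day = NA_integer_,
                    followup_end_day = 10L)
  expect_error(comorbidity_survival(bad, factor("a")), "negative")
})

test_that("complication scan skips sparse outcomes and records direction", {
  set.seed(71)
  n <- 1500
  prof <- cbind(cluster1 = rnorm(n), cluster2 = rnorm(n))
  outcomes <- data.frame(
    common = rbinom(n, 1, plogis(-2 + 0.5 * prof[, 1])),
    protective = rbinom(n, 1, plogis(-2 - 0.5 * prof[, 2])),
    rare = c(rep(1L, 5), rep(0L, n - 5)))
  covars <- std_covariates(n, seed = 72)
  res <- suppressMessages(complication_scan(prof, outcomes, covars))
  expect_false("rare" %in% res$outcome)
  r1 <- res[res$cluster == "cluster1" & res$outcome == "common", ]
  expect_gt(r1$or, 1)
  expect_equal(r1$direction, "risk")
  expect_true(r1$significant)
  r2 <- res[res$cluster == "cluster2" & res$outcome == "protective", ]
  expect_lt(r2$or, 1)
  expect_equal(r2$direction, "protective")
  expect_equal(attr(res, "threshold"),
               0.05 / (2 * ncol(outcomes)))
})
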