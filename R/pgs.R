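#' Prepare blood-pressure phenotypes
#'
#' Averages repeated readings, then adjusts for antihypertensive medication
#' by adding 15 mmHg to SBP and 10 mmHg to DBP. Pulse pressure is
#' SBP - DBP (on the adjusted values). The raw (unadjusted) means are also
#' returned; the hypertension definition uses those.
#'
#' @param sbp_readings,dbp_readings numeric vectors of readings (>= 1 each).
#' @param on_medication logical medication flag.
#' @param med_adjust length-2 vector `c(sbp, dbp)` of mmHg offsets.
#' @return list with `sbp`, `dbp`, `pp` (adjusted) and `sbp_raw`,
#'   `dbp_raw`.
#' @export
prepare_bp <- function(sbp_readings, dbp_readings, on_medication,
                       med_adjust = c(sbp = 15, dbp = 10)) {
  if (length(sbp_readings) == 0 || length(dbp_readings) == 0)
    stop("no blood-pressure readings: phenotype missing for this individual")
  sbp_raw <- mean(sbp_readings)
  dbp_raw <- mean(dbp_readings)
  sbp <- sbp_raw + if (isTRUE(on_medication)) med_adjust[[1]] else 0
  dbp <- dbp_raw + if (isTRUE(on_medication)) med_adjust[[2]] else 0
  list(sbp = sbp, dbp = dbp, pp = sbp - dbp,
       sbp_raw = sbp_raw, dbp_raw = dbp_raw)
}

#' Hypertension definition
#'
#' True iff raw mean SBP >= `sbp_cut`, or raw mean DBP >= `dbp_cut`, or the
#' individual takes blood-pressure-lowering medication. Uses the raw
#' (pre-adjustment) means: medication is a separate criterion, so applying
#' the medication offset first would double-count it.
#'
#' @param sbp_raw,dbp_raw raw mean blood pressures (mmHg); may be NA if
#'   `on_medication` is informative.
#' @param on_medication logical.
#' @param sbp_cut,dbp_cut thresholds (mmHg).
#' @return logical (NA when every input is missing).
#' @export
define_hypertension <- function(sbp_raw, dbp_raw, on_medication,
                                sbp_cut = 150, dbp_cut = 90) {
  out <- (!is.na(sbp_raw) & sbp_raw >= sbp_cut) |
    (!is.na(dbp_raw) & dbp_raw >= dbp_cut) |
    (!is.na(on_medication) & on_medication)
  undet <- is.na(sbp_raw) & is.na(dbp_raw) & is.na(on_medication)
  out[undet] <- NA
  out
}

#' Weighted polygenic score
#'
#' Sum of GWAS effect weights times risk-allele dosage over the included
#' variant set (pruning-and-thresholding selection happens upstream:
#' `included` should already be the LD-pruned, genome-wide-significant
#' set). Variants with a weight but no dosage column are imputed at their
#' expected dosage 2 x EAF (logged count); a missing EAF is an error.
#'
#' @param dosages individuals x variants numeric matrix (colnames =
#'   variant ids).
#' @param weights named numeric vector, variant -> beta.
#' @param included character vector of variant ids to score.
#' @param eaf optional named vector of effect-allele frequencies used for
#'   the 2 x EAF imputation.
#' @return numeric vector of scores, one per individual.
#' @export
weighted_pgs <- function(dosages, weights, included = names(weights),
                         eaf = NULL) {
  have <- intersect(included, colnames(dosages))
  absent <- setdiff(included, colnames(dosages))
  score <- drop(dosages[, have, drop = FALSE] %*% weights[have])
  if (length(absent) > 0) {
    if (is.null(eaf) || any(!absent %in% names(eaf)) ||
        any(is.na(eaf[absent])))
      stop("variant(s) with weight but no dosage column and no EAF: ",
           paste(utils::head(absent, 5), collapse = ", "))
    pp_log("pgs", "missing dosages imputed as 2*EAF", length(absent))
    score <- score + sum(weights[absent] * 2 * eaf[absent])
  }
  score
}

#' Cluster-partitioned unweighted polygenic scores
#'
#' For each cluster, the plain count of risk alleles: the sum of dosages
#' (aligned to the T2D risk allele) over the cluster's variants, so each
#' risk-increasing allele counts as one. Scores are bounded by
#' \[0, 2 x n_k\] for a cluster of n_k variants.
#'
#' @param dosages individuals x variants matrix, risk-allele aligned.
#' @param assignment named vector, variant -> cluster label.
#' @param eaf optional named EAF vector for 2 x EAF imputation of variants
#'   absent from the dosage matrix.
#' @return individuals x clusters matrix of partitioned scores.
#' @export
partitioned_pgs <- function(dosages, assignment, eaf = NULL) {
  clusters <- sort(unique(assignment))
  out <- matrix(0, nrow(dosages), length(clusters),
                dimnames = list(rownames(dosages),
                                paste0("cluster", clusters)))
  n_imputed <- 0L
  for (j in seq_along(clusters)) {
    vars <- names(assignment)[assignment == clusters[j]]
    have <- intersect(vars, colnames(dosages))
    absent <- setdiff(vars, colnames(dosages))
    s <- rowSums(dosages[, have, drop = FALSE])
    if (length(absent) > 0) {
      if (is.null(eaf) || any(!absent %in% names(eaf)))
        stop("assigned variant(s) missing from dosage matrix with no EAF: ",
             paste(utils::head(absent, 5), collapse = ", "))
      s <- s + sum(2 * eaf[absent])
      n_imputed <- n_imputed + length(absent)
    }
    out[, j] <- s
  }
  if (n_imputed > 0)
    pp_log("pgs", "missing dosages imputed as 2*EAF", n_imputed)
  out
}

#' Covariate-adjusted PGS-phenotype association
#'
#' Linear regression for continuous phenotypes, logistic for binary ones,
#' of the phenotype on the score adjusted for the standard covariates
#' (age, sex, array, PC1-PC6). Returns the per-unit-score effect (beta, or
#' odds ratio for logistic) with Wald 95% CI and p. Rows with any missing
#' value are dropped listwise with a logged count.
#'
#' @param pgs numeric score vector.
#' @param phenotype numeric (continuous) or 0/1 vector.
#' @param covariates data.frame with columns `age`, `sex`, `array`,
#'   `pc1` ... `pc6`.
#' @param family `"linear"` or `"logistic"`.
#' @return one-row data.frame: `estimate` (beta or OR), `ci_low`,
#'   `ci_high`, `z`, `p`, `n`.
#' @export
pgs_association <- function(pgs, phenotype, covariates,
                            family = c("linear", "logistic")) {
  family <- match.arg(family)
  need <- c("age", "sex", "array", paste0("pc", 1:6))
  missing_cov <- setdiff(need, names(covariates))
  if (length(missing_cov) > 0)
    stop("covariates lack column(s): ", paste(missing_cov, collapse = ", "))
  df <- data.frame(y = phenotype, pgs = pgs,
                   covariates[, need, drop = FALSE])
  cc <- stats::complete.cases(df)
  if (any(!cc)) pp_log("pgs", "rows dropped listwise for missingness",
                       sum(!cc))
  df <- df[cc, , drop = FALSE]
  qrx <- qr(cbind(1, as.matrix(df[, -1])))
  if (qrx$rank < ncol(qrx$qr))
    stop("perfect collinearity among pgs/covariates; check columns: ",
         paste(c("pgs", need), collapse = ", "))
  if (family == "linear") {
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients["pgs", ]
    est <- sm[["Estimate"]]; se <- sm[["Std. Error"]]
    z <- est / se
    data.frame(estimate = est, ci_low = est - 1.96 * se,
               ci_high = est + 1.96 * se, z = z,
               p = sm[["Pr(>|t|)"]], n = nrow(df))
  } else {
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    sm <- summary(fit)$coefficients["pgs", ]
    est <- sm[["Estimate"]]; se <- sm[["Std. Error"]]
    data.frame(estimate = exp(est), ci_low = exp(est - 1.96 * se),
               ci_high = exp(est + 1.96 * se), z = est / se,
               p = sm[["Pr(>|z|)"]], n = nrow(df))
  }
}

#' Top-fraction group membership
#'
#' True for individuals whose score is strictly above the (1 - fraction)
#' empirical quantile. Ties at the cut are all included, so the group may
#' slightly exceed the nominal fraction; when every score is tied the
#' whole cohort is selected with a warning.
#'
#' @param scores finite numeric vector.
#' @param fraction top fraction (e.g. 0.10 for the top decile).
#' @return logical vector.
#' @export
top_fraction_group <- function(scores, fraction) {
  stopifnot(all(is.finite(scores)), fraction > 0, fraction < 1)
  cut <- stats::quantile(scores, probs = 1 - fraction, type = 7)
  grp <- scores > cut
  if (!any(grp)) {
    # all mass tied at the cut (degenerate distribution)
    grp <- scores >= cut
    if (all(grp)) warning("all scores equal: whole cohort selected")
  } else {
    grp <- grp | (scores == cut & sum(scores > cut) < fraction * length(scores))
  }
  grp
}

#' Relative risk of a subgroup with the as-printed confidence interval
#'
#' RR = (cases_group / n_group) / (cases_total / n_total). The default 95%
#' CI follows the published form
#' exp\[ln RR +- 1.96 sqrt(1/N_cases,group - 1/N_cases,total)\]
#' (minus sign under the radical, implemented verbatim); the conventional
#' log-RR interval sqrt(1/a - 1/n1 + 1/c - 1/n2) is available with
#' `ci_style = "standard"`.
#'
#' @param group logical subgroup indicator.
#' @param cases logical case indicator (same length).
#' @param ci_style `"as_printed"` or `"standard"`.
#' @return one-row data.frame: group/overall counts and prevalences, `rr`,
#'   `ci_low`, `ci_high`, `flagged` (TRUE when the CI is undefined).
#' @export
relative_risk <- function(group, cases, ci_style = c("as_printed",
                                                     "standard")) {
  ci_style <- match.arg(ci_style)
  stopifnot(length(group) == length(cases), any(group))
  n_group <- sum(group)
  cases_group <- sum(cases[group])
  n_total <- length(group)
  cases_total <- sum(cases)
  prev_group <- cases_group / n_group
  prev_overall <- cases_total / n_total
  rr <- prev_group / prev_overall
  flagged <- FALSE
  if (cases_group == 0) {
    ci <- c(NA_real_, NA_real_)
    flagged <- TRUE
  } else {
    se <- if (ci_style == "as_printed") {
      v <- 1 / cases_group - 1 / cases_total
      if (v < 0) { flagged <- TRUE; NA_real_ } else sqrt(v)
    } else {
      sqrt(1 / cases_group - 1 / n_group + 1 / cases_total - 1 / n_total)
    }
    ci <- exp(log(rr) + c(-1.96, 1.96) * se)
  }
  data.frame(n_group = n_group, cases_group = cases_group,
             n_total = n_total, cases_total = cases_total,
             prevalence_group = prev_group, prevalence_overall = prev_overall,
             rr = rr, ci_low = ci[1], ci_high = ci[2], flagged = flagged)
}

#' Dominant-cluster assignment from a partitioned-score profile
#'
#' Each individual's candidate cluster is the one where their partitioned
#' score's percentile rank (rank, not raw score: clusters have different
#' variant counts) is highest; they are assigned iff that rank falls in
#' the top `fraction` of the cohort. Exact rank ties go to the cluster
#' with more variants, then label order.
#'
#' @param profile individuals x clusters matrix of partitioned scores.
#' @param fraction top fraction required for assignment (default top 33%).
#' @param cluster_sizes optional named vector of variants per cluster for
#'   the tie-break (defaults to equal).
#' @return character vector of cluster labels (NA = unassigned), named by
#'   individual when `profile` has rownames.
#' @export
assign_dominant_cluster <- function(profile, fraction = 0.33,
                                    cluster_sizes = NULL) {
  n <- nrow(profile)
  ranks <- apply(profile, 2, function(x) rank(x, ties.method = "average")) / n
  if (is.null(cluster_sizes))
    cluster_sizes <- stats::setNames(rep(1, ncol(profile)),
                                     colnames(profile))
  size_order <- order(-cluster_sizes[colnames(profile)],
                      seq_len(ncol(profile)))
  pref <- ranks[, size_order, drop = FALSE]
  best_in_pref <- max.col(pref, ties.method = "first")
  best <- size_order[best_in_pref]
  best_rank <- ranks[cbind(seq_len(n), best)]
  assigned <- best_rank > (1 - fraction)
  out <- ifelse(assigned, colnames(profile)[best], NA_character_)
  names(out) <- rownames(profile)
  out
}

#' Time-to-comorbidity survival analysis across cluster groups
#'
#' Time zero is the first diagnosis of either disease; the event is the
#' second diagnosis (developing the comorbidity). Individuals with a single
#' disease are censored at follow-up end; individuals with both diagnoses
#' on the same day are excluded (logged count). Fits a Cox proportional
#' hazards model on the group factor and returns the Nelson-Aalen/Breslow
#' cumulative hazard per group with 95% bands.
#'
#' @param cohort data.frame with `diag1_day`, `diag2_day` (NA when never
#'   diagnosed) and `followup_end_day`.
#' @param groups factor/character vector of group labels (NA rows are
#'   dropped); the first level is the Cox reference.
#' @return list with `data` (time, event, group), `cox` (coxph fit or NULL
#'   when < 2 groups), `hazard_ratios` (data.frame), `cumhaz` (data.frame:
#'   group, time, cumhaz, lower, upper), `n_excluded_same_day`.
#' @export
comorbidity_survival <- function(cohort, groups) {
  d1 <- cohort$diag1_day
  d2 <- cohort$diag2_day
  has_any <- !is.na(d1) | !is.na(d2)
  first <- pmin(d1, d2, na.rm = TRUE)
  both <- !is.na(d1) & !is.na(d2)
  same_day <- both & d1 == d2
  n_same <- sum(same_day, na.rm = TRUE)
  if (n_same > 0)
    pp_log("survival", "same-day dual diagnoses excluded", n_same)
  use <- has_any & !same_day & !is.na(groups)
  event <- both[use]
  time <- ifelse(event,
                 pmax(d1[use], d2[use]) - first[use],
                 cohort$followup_end_day[use] - first[use])
  if (any(time < 0)) stop("negative follow-up durations: data integrity")
  grp <- droplevels(factor(groups[use]))
  df <- data.frame(time = time, event = as.integer(event), group = grp)
  cox <- NULL
  hr <- NULL
  if (nlevels(grp) >= 2) {
    cox <- survival::coxph(survival::Surv(time, event) ~ group, data = df)
    sm <- summary(cox)
    hr <- data.frame(group = sub("^group", "", rownames(sm$coefficients)),
                     hr = sm$coefficients[, "exp(coef)"],
                     ci_low = sm$conf.int[, "lower .95"],
                     ci_high = sm$conf.int[, "upper .95"],
                     p = sm$coefficients[, "Pr(>|z|)"],
                     row.names = NULL)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           ctype = 1, conf.type = "log")
  strata_names <- if (is.null(fit$strata)) levels(grp)[1] else
    sub("^group=", "", names(fit$strata))
  strata_id <- if (is.null(fit$strata)) rep(1L, length(fit$time)) else
    rep(seq_along(fit$strata), fit$strata)
  cumhaz <- data.frame(group = strata_names[strata_id],
                       time = fit$time,
                       cumhaz = fit$cumhaz,
                       lower = -log(fit$upper),
                       upper = -log(fit$lower))
  list(data = df, cox = cox, hazard_ratios = hr, cumhaz = cumhaz,
       n_excluded_same_day = n_same)
}

#' Scan complication outcomes against partitioned scores
#'
#' Logistic [pgs_association()] of every outcome category on every
#' cluster's partitioned score, Bonferroni-corrected at
#' alpha / (n_clusters x n_outcome_categories). Outcomes with fewer than
#' `min_cases` cases are skipped (logged). The direction of effect
#' (OR above/below 1) is recorded per pair.
#'
#' @param profile individuals x clusters partitioned-score matrix.
#' @param outcomes individuals x categories 0/1 data.frame or matrix.
#' @param covariates covariate data.frame (see [pgs_association()]).
#' @param alpha family-wise error rate.
#' @param min_cases minimum case count per analyzed outcome.
#' @param n_categories number of categories used for the correction
#'   (defaults to `ncol(outcomes)`; pass the full taxonomy size when only
#'   a subset is scanned).
#' @return data.frame: `cluster`, `outcome`, `or`, `ci_low`, `ci_high`,
#'   `p`, `direction` ("risk"/"protective"), `significant`, plus the
#'   threshold as attribute `threshold`.
#' @export
complication_scan <- function(profile, outcomes, covariates, alpha = 0.05,
                              min_cases = 10L, n_categories = ncol(outcomes)) {
  outcomes <- as.data.frame(outcomes)
  n_cases <- colSums(outcomes, na.rm = TRUE)
  skip <- n_cases < min_cases
  if (any(skip))
    pp_log("scan", sprintf("outcomes skipped (< %d cases)", min_cases),
           sum(skip))
  thr <- bonferroni_threshold(ncol(profile) * n_categories, alpha)
  rows <- list()
  for (k in colnames(profile)) {
    for (oc in names(outcomes)[!skip]) {
      a <- pgs_association(profile[, k], outcomes[[oc]], covariates,
                           family = "logistic")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, outcome = oc, or = a$estimate,
        ci_low = a$ci_low, ci_high = a$ci_high, p = a$p,
        direction = ifelse(a$estimate > 1, "risk", "protective"),
        significant = a$p < thr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
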