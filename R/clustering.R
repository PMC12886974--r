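#' Ward hierarchical clustering of the z-score matrix
#'
#' Agglomerative clustering of variants (rows) on Euclidean distance with
#' the Ward.D2 criterion: each merge minimizes the increase in total
#' within-cluster variance, and merge heights are monotone non-decreasing.
#'
#' @param matrix `zmatrix` with no missing cells, or a plain numeric matrix.
#' @return An `hclust` object.
#' @export
ward_dendrogram <- function(matrix) {
  z <- if (inherits(matrix, "zmatrix")) matrix$z else as.matrix(matrix)
  if (nrow(z) < 2) stop("need at least 2 rows to cluster")
  if (any(is.na(z))) stop("matrix has missing cells: impute before clustering")
  stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
}

#' Cut the dendrogram at half its maximum merge height
#'
#' The cluster count is determined by severing every merge whose height
#' exceeds half the maximum merge height; the surviving subtrees are the
#' clusters. Cluster labels are integers ordered by descending cluster
#' size (1 = largest).
#'
#' @param linkage `hclust` object from [ward_dendrogram()].
#' @return list with `k`, `cut_height`, and `assignment` (named integer
#'   vector, variant -> cluster label).
#' @export
cut_half_max <- function(linkage) {
  stopifnot(inherits(linkage, "hclust"))
  cut_height <- max(linkage$height) / 2
  raw <- stats::cutree(linkage, h = cut_height)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  assignment <- relabel[as.character(raw)]
  names(assignment) <- names(raw)
  list(k = length(sizes), cut_height = cut_height,
       assignment = assignment)
}

#' Cluster-trait interpretation regression
#'
#' For each trait, ordinary least squares of the z column on the K disjoint
#' cluster-membership indicators without intercept. With disjoint
#' indicators the coefficient for cluster k equals the mean z of cluster k
#' for that trait; p-values are two-sided t-tests on the coefficients.
#'
#' @param matrix `zmatrix` (or numeric matrix) over the assigned variants.
#' @param assignment named vector, variant -> cluster.
#' @return list with `alpha` and `alpha_p`: trait x cluster matrices.
#' @export
cluster_trait_regression <- function(matrix, assignment) {
  z <- if (inherits(matrix, "zmatrix")) matrix$z else as.matrix(matrix)
  assignment <- assignment[rownames(z)]
  if (any(is.na(assignment))) stop("assignment missing for some variants")
  cl <- factor(assignment)
  if (any(table(cl) == 0)) stop("empty cluster in assignment")
  K <- nlevels(cl)
  traits <- colnames(z)
  alpha <- matrix(NA_real_, length(traits), K,
                  dimnames = list(traits, levels(cl)))
  alpha_p <- alpha
  X <- vapply(levels(cl), function(l) as.numeric(cl == l),
              numeric(length(cl)))
  for (i in seq_along(traits)) {
    fit <- stats::lm(z[, i] ~ 0 + X)
    sm <- summary(fit)$coefficients
    alpha[i, ] <- sm[, "Estimate"]
    alpha_p[i, ] <- sm[, "Pr(>|t|)"]
  }
  list(alpha = alpha, alpha_p = alpha_p)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Compare hard and soft cluster solutions
#'
#' Three diagnostics: (1) per hard cluster, a deviance (likelihood-ratio)
#' test of a logistic regression of the 0/1 membership on the soft weight
#' columns against the intercept-only model, chi-squared with df = number
#' of weight columns -- separable fits fall back to the package's Firth
#' penalized fit and are flagged; (2) Pearson correlation between matched
#' trait-weight vectors of the two solutions; (3) a contingency
#' chi-squared test of independence between two hard assignments.
#'
#' @param assignment named hard assignment (variant -> cluster).
#' @param soft_weights variant x component nonnegative weight matrix (same
#'   variants).
#' @param trait_weights_a,trait_weights_b optional trait x component weight
#'   matrices to correlate (matched by column position).
#' @param other_assignment optional second hard assignment for the
#'   independence test.
#' @return list with `deviance_tests` (data.frame: cluster, lr_stat, df, p,
#'   separable), `trait_cor` (matrix or NULL), `independence`
#'   (htest or NULL).
#' @export
compare_hard_soft <- function(assignment, soft_weights,
                              trait_weights_a = NULL,
                              trait_weights_b = NULL,
                              other_assignment = NULL) {
  ids <- intersect(names(assignment), rownames(soft_weights))
  if (length(ids) == 0) stop("no shared variants between solutions")
  assignment <- assignment[ids]
  W <- soft_weights[ids, , drop = FALSE]
  # row-normalized weights sum to 1 and are collinear with the intercept:
  # keep a full-rank subset of weight columns for the fits
  qrx <- qr(cbind(1, W))
  sel <- qrx$pivot[seq_len(qrx$rank)]
  W <- W[, sel[sel > 1] - 1, drop = FALSE]
  clusters <- sort(unique(assignment))
  res <- lapply(clusters, function(k) {
    y <- as.integer(assignment == k)
    if (all(y == 0) || all(y == 1)) {
      return(data.frame(cluster = k, lr_stat = NA_real_, df = ncol(W),
                        p = NA_real_, separable = NA,
                        note = "degenerate membership"))
    }
    df_fit <- as.data.frame(W)
    names(df_fit) <- paste0("w", seq_len(ncol(W)))
    full <- suppressWarnings(stats::glm(y ~ ., data = df_fit,
                                        family = stats::binomial()))
    null <- stats::glm(y ~ 1, family = stats::binomial())
    eps <- 1e-8
    separable <- any(full$fitted.values > 1 - eps) ||
      any(full$fitted.values < eps)
    if (separable) {
      X_full <- cbind(1, as.matrix(W))
      f_full <- firth_logistic(X_full, y)
      f_null <- firth_logistic(matrix(1, length(y), 1), y)
      lr <- 2 * (f_full$pll - f_null$pll)
    } else {
      lr <- null$deviance - full$deviance
    }
    data.frame(cluster = k, lr_stat = lr, df = ncol(W),
               p = stats::pchisq(lr, df = ncol(W), lower.tail = FALSE),
               separable = separable, note = "")
  })
  deviance_tests <- do.call(rbind, res)
  trait_cor <- NULL
  if (!is.null(trait_weights_a) && !is.null(trait_weights_b)) {
    shared <- intersect(rownames(trait_weights_a), rownames(trait_weights_b))
    trait_cor <- stats::cor(trait_weights_a[shared, , drop = FALSE],
                            trait_weights_b[shared, , drop = FALSE])
  }
  independence <- NULL
  if (!is.null(other_assignment)) {
    shared <- intersect(names(assignment), names(other_assignment))
    independence <- suppressWarnings(
      stats::chisq.test(table(assignment[shared], other_assignment[shared])))
  }
  list(deviance_tests = deviance_tests, trait_cor = trait_cor,
       independence = independence)
}

#' Hard-assign variants from soft weights
#'
#' A variant is assigned to the component carrying its maximum row-normalized
#' weight when that weight exceeds `min_weight`; otherwise unassigned (NA).
#'
#' @param soft_weights variant x component nonnegative matrix.
#' @param min_weight assignment floor on the normalized weight.
#' @return named integer vector (NA where unassigned).
#' @export
soft_assignment <- function(soft_weights, min_weight = 0.75) {
  rs <- rowSums(soft_weights)
  norm <- soft_weights / ifelse(rs == 0, 1, rs)
  best <- max.col(norm, ties.method = "first")
  w <- norm[cbind(seq_len(nrow(norm)), best)]
  out <- ifelse(w > min_weight, best, NA_integer_)
  stats::setNames(as.integer(out), rownames(soft_weights))
}
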