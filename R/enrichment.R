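#' Aggregate a background variant set around clustered variants
#'
#' Background = the union, over all clustered variants, of reference-panel
#' variants within `window_bp` either side, LD-pruned to pairwise
#' r-squared < `r2_max`, deduplicated, minus the clustered variants
#' themselves. Clustered variants with no panel neighbours contribute no
#' rows (one warning with the count).
#'
#' @param clustered `variant_catalog` of the clustered variants.
#' @param panel reference panel.
#' @param window_bp aggregation window either side of each clustered
#'   variant.
#' @param r2_max pruning ceiling for the background set.
#' @return data.frame `variant_id`, `chrom`, `pos` of background variants.
#' @export
build_background <- function(clustered, panel, window_bp = 50000L,
                             r2_max = 0.2) {
  ids <- rownames(panel$dosages)
  hit <- character(0)
  n_no_neighbours <- 0L
  for (i in seq_len(nrow(clustered))) {
    nb <- ids[panel$chrom[ids] == clustered$chrom[i] &
                abs(panel$pos[ids] - clustered$pos[i]) <= window_bp]
    nb <- setdiff(nb, clustered$variant_id)
    if (length(nb) == 0) n_no_neighbours <- n_no_neighbours + 1L
    hit <- c(hit, nb)
  }
  if (n_no_neighbours > 0)
    warning(sprintf("%d clustered variant(s) with no panel neighbours",
                    n_no_neighbours))
  hit <- unique(hit)
  if (length(hit) == 0) stop("empty background set")
  bg <- data.frame(variant_id = hit,
                   chrom = unname(panel$chrom[hit]),
                   pos = unname(panel$pos[hit]),
                   origin_trait = "T2D", risk_allele = "A",
                   stringsAsFactors = FALSE)
  bg <- as_catalog(bg)
  pruned <- prune_independent(bg, panel, r2_max = r2_max)
  pruned[, c("variant_id", "chrom", "pos")]
}

#' Build the enrichment design table for one focal cluster
#'
#' Rows are the focal cluster's variants (y = 1) plus the background
#' variants (y = 0); clustered variants of other clusters are excluded.
#' Columns: `exon`, `utr3`, `utr5` annotation indicators and one 0/1
#' peak-membership column per cell type, all filled by interval overlap.
#'
#' @param catalog `variant_catalog` with a `cluster` column.
#' @param focal_cluster cluster label to test.
#' @param background data.frame from [build_background()].
#' @param peaks named list of interval data.frames (1-based inclusive),
#'   one per cell type.
#' @param annotations list with interval data.frames `exon`, `utr3`,
#'   `utr5` (any may be missing; the column is then all zero).
#' @return data.frame with `variant_id`, `y`, `exon`, `utr3`, `utr5` and
#'   one column per cell type.
#' @export
build_enrichment_table <- function(catalog, focal_cluster, background,
                                   peaks, annotations = list()) {
  focal <- catalog[catalog$cluster == focal_cluster, , drop = FALSE]
  if (nrow(focal) == 0) stop("no variants in focal cluster ", focal_cluster)
  rows <- rbind(
    data.frame(variant_id = focal$variant_id, chrom = focal$chrom,
               pos = focal$pos, y = 1L, stringsAsFactors = FALSE),
    data.frame(variant_id = background$variant_id, chrom = background$chrom,
               pos = background$pos, y = 0L, stringsAsFactors = FALSE))
  rows <- rows[!duplicated(rows$variant_id), , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  for (ann in c("exon", "utr3", "utr5")) {
    iv <- if (!is.null(annotations[[ann]])) annotations[[ann]] else empty
    rows[[ann]] <- as.integer(in_intervals(rows$chrom, rows$pos, iv))
  }
  for (ct in names(peaks)) {
    rows[[ct]] <- as.integer(in_intervals(rows$chrom, rows$pos, peaks[[ct]]))
  }
  rownames(rows) <- NULL
  rows
}

#' Likelihood-ratio enrichment test for one cell type
#'
#' Fits the Firth logistic model of cluster membership on the annotation
#' indicators and all cell-type membership columns twice: once in full and
#' once with the focal cell type's coefficient constrained to zero. The
#' statistic is twice the penalized log-likelihood difference, compared to
#' chi-squared with 1 df. Constant (degenerate) focal columns give a
#' flagged, non-informative result. Columns other than the focal one that
#' are constant or collinear are silently dropped from both models (they
#' carry no information and would make the design rank-deficient).
#'
#' @param table design table from [build_enrichment_table()].
#' @param cell_type name of the focal cell-type column.
#' @param n_tests number of tests in the family (for the Bonferroni flag).
#' @param alpha family-wise error rate.
#' @return one-row data.frame: `cell_type`, `coef` (log fold enrichment),
#'   `lr_stat`, `p`, `significant`, `degenerate`.
#' @export
enrichment_lr_test <- function(table, cell_type, n_tests = 1L,
                               alpha = 0.05) {
  if (!cell_type %in% names(table))
    stop("cell-type column absent: ", cell_type)
  y <- table$y
  covar_names <- setdiff(names(table),
                         c("variant_id", "chrom", "pos", "y"))
  focal <- table[[cell_type]]
  if (length(unique(focal)) < 2) {
    return(data.frame(cell_type = cell_type, coef = NA_real_,
                      lr_stat = NA_real_, p = NA_real_,
                      significant = FALSE, degenerate = TRUE))
  }
  others <- setdiff(covar_names, cell_type)
  keep <- others[vapply(others, function(nm)
    length(unique(table[[nm]])) > 1, logical(1))]
  X_null <- cbind(`(Intercept)` = 1,
                  as.matrix(table[, keep, drop = FALSE]))
  qrn <- qr(X_null)
  X_null <- X_null[, qrn$pivot[seq_len(qrn$rank)], drop = FALSE]
  X_full <- cbind(X_null, focal)
  colnames(X_full)[ncol(X_full)] <- cell_type
  qrf <- qr(X_full)
  if (qrf$rank < ncol(X_full)) {
    # focal column collinear with retained covariates
    return(data.frame(cell_type = cell_type, coef = NA_real_,
                      lr_stat = NA_real_, p = NA_real_,
                      significant = FALSE, degenerate = TRUE))
  }
  fit_full <- firth_logistic(X_full, y)
  # null: focal coefficient constrained to zero under the full-model
  # penalty (the penalized likelihood-ratio construction)
  fit_null <- firth_logistic(X_null, y, penalty_X = X_full)
  lr <- max(0, 2 * (fit_full$pll - fit_null$pll))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  thr <- bonferroni_threshold(n_tests, alpha)
  data.frame(cell_type = cell_type,
             coef = unname(fit_full$coefficients[cell_type]),
             lr_stat = lr, p = p, significant = p < thr,
             degenerate = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests in the family, >= 1.
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}
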