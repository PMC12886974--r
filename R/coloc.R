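#' Wakefield log approximate Bayes factor
#'
#' For one variant's association estimate: with V = se^2, W = prior_sd^2 and
#' z = beta/se,
#' log ABF = 0.5 log(V / (V + W)) + 0.5 z^2 W / (V + W).
#' The ABF compares the alternative (true effect ~ N(0, W)) against the
#' point null.
#'
#' @param beta effect estimate.
#' @param se standard error, > 0.
#' @param prior_sd prior standard deviation of the true effect, >= 0.
#' @return log ABF (0 when `prior_sd` is 0).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(prior_sd < 0)) stop("prior_sd must be >= 0")
  V <- se^2
  W <- prior_sd^2
  z <- beta / se
  0.5 * log(V / (V + W)) + 0.5 * z^2 * W / (V + W)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Colocalization posteriors for one region
#'
#' Approximate-Bayes-factor colocalization under the single-causal-variant
#' assumption. Each variant gets a log ABF per trait; the five hypothesis
#' evidences are assembled with per-variant priors `p1` (trait 1 only),
#' `p2` (trait 2 only), `p12` (shared causal variant) and normalized:
#' H0 no association, H1/H2 one trait only, H3 two distinct causal
#' variants, H4 one shared causal variant. All accumulation is in log space.
#'
#' @param region list with `gwas` and `eqtl` `sumstats` tables over the same
#'   variant set (see [build_region()]), or any two aligned tables.
#' @param p1,p2,p12 per-variant prior probabilities.
#' @param prior_sds length-2 vector: prior effect sd for trait 1 and 2.
#' @return A one-row data.frame: `n_snps`, `pp_h0` ... `pp_h4`.
#' @export
coloc_posteriors <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sds = c(0.2, 0.2)) {
  g <- region$gwas
  e <- region$eqtl
  if (nrow(g) == 0) stop("empty region")
  if (!identical(g$variant_id, e$variant_id)) {
    diff <- union(setdiff(g$variant_id, e$variant_id),
                  setdiff(e$variant_id, g$variant_id))
    stop("variant sets differ between traits: ",
         paste(utils::head(diff, 5), collapse = ", "))
  }
  l1 <- log_abf(g$beta, g$se, prior_sds[1])
  l2 <- log_abf(e$beta, e$se, prior_sds[2])
  s1 <- logsumexp(l1)                 # sum_i ABF1_i
  s2 <- logsumexp(l2)                 # sum_j ABF2_j
  s12 <- logsumexp(l1 + l2)           # sum_i ABF1_i ABF2_i
  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
          h4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  data.frame(n_snps = nrow(g), pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]],
             pp_h2 = pp[["h2"]], pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]])
}

#' Build a colocalization region around an index variant
#'
#' Takes the variants within `half_window` bp of the index variant that are
#' present in both the GWAS and eQTL tables (intersection on variant id,
#' inclusive bounds), and harmonizes the eQTL effect direction onto the
#' GWAS effect allele (records whose alleles are swapped get their beta
#' sign flipped and eaf complemented; mismatching allele pairs are dropped
#' with a logged count).
#'
#' @param index_variant variant id present in the GWAS table.
#' @param gwas,eqtl `sumstats` tables.
#' @param half_window region half-width in bp.
#' @return list with `index_variant`, `gwas`, `eqtl` (aligned tables) and
#'   `flagged` (TRUE when the index variant is missing from either table,
#'   in which case the tables are empty).
#' @export
build_region <- function(index_variant, gwas, eqtl, half_window = 100000L) {
  ig <- match(index_variant, gwas$variant_id)
  if (is.na(ig) || !index_variant %in% eqtl$variant_id) {
    return(list(index_variant = index_variant,
                gwas = gwas[0, ], eqtl = eqtl[0, ], flagged = TRUE))
  }
  chrom <- gwas$chrom[ig]
  pos <- gwas$pos[ig]
  g <- gwas[gwas$chrom == chrom & abs(gwas$pos - pos) <= half_window, ,
            drop = FALSE]
  shared <- intersect(g$variant_id, eqtl$variant_id)
  g <- g[match(shared, g$variant_id), , drop = FALSE]
  e <- eqtl[match(shared, eqtl$variant_id), , drop = FALSE]
  same <- e$effect_allele == g$effect_allele & e$other_allele == g$other_allele
  swapped <- e$effect_allele == g$other_allele &
    e$other_allele == g$effect_allele
  if (any(swapped)) {
    e$beta[swapped] <- -e$beta[swapped]
    e$eaf[swapped] <- 1 - e$eaf[swapped]
    tmp <- e$effect_allele[swapped]
    e$effect_allele[swapped] <- e$other_allele[swapped]
    e$other_allele[swapped] <- tmp
  }
  bad <- !(same | swapped)
  if (any(bad)) {
    pp_log("coloc", "variants dropped for irreconcilable alleles", sum(bad))
    g <- g[!bad, , drop = FALSE]
    e <- e[!bad, , drop = FALSE]
  }
  rownames(g) <- rownames(e) <- NULL
  list(index_variant = index_variant, gwas = g, eqtl = e, flagged = FALSE)
}

#' Region QC: variant-count window
#'
#' A region is well-characterised when it holds between `min_snps` and
#' `max_snps` variants, bounds inclusive.
#'
#' @param region region list from [build_region()], or an integer count.
#' @param min_snps,max_snps inclusive bounds.
#' @return logical.
#' @export
region_qc <- function(region, min_snps = 100L, max_snps = 1000L) {
  n <- if (is.list(region)) nrow(region$gwas) else region
  n >= min_snps && n <= max_snps
}

#' Colocalization call rule
#'
#' Called when the shared-causal-variant posterior PP.H4 exceeds
#' `pp_h4_min`, the distinct-causal-variants posterior PP.H3 is below
#' `pp_h3_max`, and the region passed QC.
#'
#' @param pp one-row data.frame (or named vector) with `pp_h3`, `pp_h4`.
#' @param qc_pass region QC flag.
#' @param pp_h4_min,pp_h3_max call thresholds.
#' @return logical.
#' @export
call_colocalization <- function(pp, qc_pass = TRUE, pp_h4_min = 0.8,
                                pp_h3_max = 0.5) {
  h4 <- if (is.data.frame(pp)) pp$pp_h4 else pp[["pp_h4"]]
  h3 <- if (is.data.frame(pp)) pp$pp_h3 else pp[["pp_h3"]]
  isTRUE(h4 > pp_h4_min && h3 < pp_h3_max && qc_pass)
}

#' Exclude MHC-region variants from a catalog
#'
#' Removes variants inside the extended major histocompatibility complex
#' interval (default chr6:25,000,000-35,000,000, inclusive), whose extreme
#' LD confounds colocalization.
#'
#' @param catalog `variant_catalog`.
#' @param chrom,start,end interval (1-based inclusive).
#' @return Filtered catalog; removed count logged.
#' @export
exclude_mhc <- function(catalog, chrom = "6", start = 25000000L,
                        end = 35000000L) {
  chr <- sub("^chr", "", as.character(catalog$chrom))
  drop <- chr == sub("^chr", "", chrom) &
    catalog$pos >= start & catalog$pos <= end
  pp_log("coloc", "variants excluded in MHC region", sum(drop))
  out <- catalog[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tissue-specific colocalization counts
#'
#' An index variant contributes to a tissue's specific count iff its only
#' called colocalization across all tissues is in that tissue. Also returns
#' total called counts per tissue and, when a `cluster` column is present,
#' per (tissue, cluster).
#'
#' @param results data.frame with columns `index_variant`, `tissue`,
#'   `called` (logical) and optionally `cluster`; rows deduplicated by
#'   (index_variant, tissue).
#' @return list with `per_tissue` (tissue, n_called, n_specific) and
#'   `per_tissue_cluster` (or NULL).
#' @export
tissue_specific_counts <- function(results) {
  results <- results[!duplicated(results[, c("index_variant", "tissue")]), ,
                     drop = FALSE]
  called <- results[results$called, , drop = FALSE]
  n_tissues_per_variant <- table(called$index_variant)
  specific_variants <- names(n_tissues_per_variant)[n_tissues_per_variant == 1]
  tissues <- sort(unique(results$tissue))
  per_tissue <- data.frame(
    tissue = tissues,
    n_called = vapply(tissues, function(t)
      sum(called$tissue == t), integer(1)),
    n_specific = vapply(tissues, function(t)
      sum(called$tissue == t &
            called$index_variant %in% specific_variants), integer(1)),
    row.names = NULL)
  per_tissue_cluster <- NULL
  if ("cluster" %in% names(results) && nrow(called) > 0) {
    per_tissue_cluster <- as.data.frame(
      table(tissue = called$tissue, cluster = called$cluster),
      responseName = "n_called")
  }
  list(per_tissue = per_tissue, per_tissue_cluster = per_tissue_cluster)
}
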