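#' Squared dosage correlation between two variants
#'
#' Genotypic LD r-squared: the squared Pearson correlation of dosage
#' vectors across the reference-panel samples.
#'
#' @param dosages_a,dosages_b numeric dosage vectors of equal length >= 2.
#' @return r-squared in \[0, 1\]; `NA` (with a warning) if either vector has
#'   zero variance, which is distinct from true r-squared 0.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b), length(dosages_a) >= 2)
  va <- stats::var(dosages_a)
  vb <- stats::var(dosages_b)
  if (va == 0 || vb == 0) {
    warning("zero-variance dosage vector: LD r2 undefined")
    return(NA_real_)
  }
  stats::cor(dosages_a, dosages_b)^2
}

# pairwise r2 of a set of variants against themselves (or a second set),
# from the panel dosage matrix; variants absent from the panel give NA
panel_r2 <- function(panel, ids_a, ids_b = ids_a) {
  m <- panel$dosages
  out <- matrix(NA_real_, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
  in_a <- ids_a %in% rownames(m)
  in_b <- ids_b %in% rownames(m)
  if (any(in_a) && any(in_b)) {
    sub_a <- t(m[ids_a[in_a], , drop = FALSE])
    sub_b <- t(m[ids_b[in_b], , drop = FALSE])
    sd_a <- apply(sub_a, 2, stats::sd)
    sd_b <- apply(sub_b, 2, stats::sd)
    cc <- suppressWarnings(stats::cor(sub_a, sub_b))
    cc[sd_a == 0, ] <- NA_real_
    cc[, sd_b == 0] <- NA_real_
    out[in_a, in_b] <- cc^2
  }
  out
}

#' Greedy LD pruning of a variant catalog
#'
#' Keeps a subset in which no retained pair has panel r-squared at or above
#' `r2_max`. Greedy by priority: ascending origin-GWAS p-value when a `p`
#' column is present, ties (and absent p) broken by (chrom, pos). Variants
#' missing from the panel cannot be pruned and are retained with a warning.
#'
#' @param variants `variant_catalog` data.frame.
#' @param panel reference panel (list with `dosages`, `chrom`, `pos`).
#' @param r2_max pairwise r-squared ceiling (pairs at or above it conflict).
#' @return The retained catalog, with attribute `removed`: a data.frame of
#'   pruned variants and the retained variant that displaced each.
#' @export
prune_independent <- function(variants, panel, r2_max = 0.2) {
  n <- nrow(variants)
  if (n == 0) return(variants)
  p <- if ("p" %in% names(variants)) variants$p else rep(NA_real_, n)
  p[is.na(p)] <- Inf
  ord <- order(p, variants$chrom, variants$pos)
  in_panel <- variants$variant_id %in% rownames(panel$dosages)
  if (any(!in_panel))
    warning(sprintf("%d variant(s) absent from panel: retained un-prunable",
                    sum(!in_panel)))
  r2 <- panel_r2(panel, variants$variant_id)
  keep <- logical(n)
  removed_by <- character(0)
  removed_id <- character(0)
  for (i in ord) {
    if (!in_panel[i]) { keep[i] <- TRUE; next }
    conflict <- which(keep & in_panel &
                        !is.na(r2[i, variants$variant_id]) &
                        r2[i, variants$variant_id] >= r2_max)
    if (length(conflict) == 0) {
      keep[i] <- TRUE
    } else {
      removed_id <- c(removed_id, variants$variant_id[i])
      removed_by <- c(removed_by, variants$variant_id[conflict[1]])
    }
  }
  pp_log("prune", "variants removed by LD pruning", length(removed_id))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(variant_id = removed_id,
                                     displaced_by = removed_by,
                                     stringsAsFactors = FALSE)
  out
}

#' Find a high-LD proxy record for a variant absent from a trait's GWAS
#'
#' Searches the reference panel for the highest-r-squared variant within
#' `window_bp` of the target that is present in `trait_table` and exceeds
#' the `r2_min` floor (strict).
#'
#' @param target variant id (must be in the panel; if not, returns `NULL`
#'   with a warning).
#' @param trait_table `sumstats` table for the trait.
#' @param panel reference panel.
#' @param r2_min proxy r-squared floor (candidates must exceed it).
#' @param window_bp distance cap around the target position.
#' @return The proxy's `EffectRecord` row with extra columns `proxy_for` and
#'   `proxy_r2`, or `NULL` if no candidate qualifies.
#' @export
find_proxy <- function(target, trait_table, panel, r2_min = 0.6,
                       window_bp = 500000L) {
  if (!target %in% rownames(panel$dosages)) {
    warning(sprintf("proxy target %s absent from panel", target))
    return(NULL)
  }
  tchrom <- panel$chrom[[target]]
  tpos <- panel$pos[[target]]
  cand <- rownames(panel$dosages)
  cand <- cand[panel$chrom[cand] == tchrom &
                 abs(panel$pos[cand] - tpos) <= window_bp &
                 cand != target]
  cand <- cand[cand %in% trait_table$variant_id]
  if (length(cand) == 0) return(NULL)
  r2 <- panel_r2(panel, target, cand)[1, ]
  r2 <- r2[!is.na(r2) & r2 > r2_min]
  if (length(r2) == 0) return(NULL)
  best <- names(r2)[which.max(r2)]
  rec <- trait_table[trait_table$variant_id == best, , drop = FALSE]
  rec$proxy_for <- target
  rec$proxy_r2 <- max(r2)
  rec
}

#' Locus overlap between two variant sets
#'
#' A pair (a, b) overlaps when the variants lie within `window_bp` of each
#' other on the same chromosome, or when their panel LD r-squared exceeds
#' `r2_min` (strict). Each reported pair is annotated with which criterion
#' fired.
#'
#' @param set_a,set_b `variant_catalog` data.frames.
#' @param panel reference panel (used for the LD criterion; pairs absent
#'   from the panel are judged on distance only).
#' @param window_bp distance criterion, base pairs.
#' @param r2_min LD criterion floor.
#' @return data.frame of overlapping pairs: `variant_a`, `variant_b`,
#'   `distance_bp` (NA across chromosomes), `r2`, `by_distance`, `by_ld`.
#' @export
locus_overlap <- function(set_a, set_b, panel, window_bp = 500000L,
                          r2_min = 0.2) {
  r2 <- panel_r2(panel, set_a$variant_id, set_b$variant_id)
  rows <- list()
  for (i in seq_len(nrow(set_a))) {
    same_chr <- set_b$chrom == set_a$chrom[i]
    dist <- ifelse(same_chr, abs(set_b$pos - set_a$pos[i]), NA_integer_)
    by_dist <- same_chr & dist <= window_bp
    r2i <- r2[i, ]
    by_ld <- !is.na(r2i) & r2i > r2_min
    hit <- which(by_dist | by_ld)
    if (length(hit) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant_a = set_a$variant_id[i],
        variant_b = set_b$variant_id[hit],
        distance_bp = dist[hit],
        r2 = unname(r2i[hit]),
        by_distance = by_dist[hit],
        by_ld = by_ld[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(variant_a = character(0), variant_b = character(0),
                      distance_bp = integer(0), r2 = numeric(0),
                      by_distance = logical(0), by_ld = logical(0)))
  do.call(rbind, rows)
}
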