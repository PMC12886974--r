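#' Variant-trait z-score
#'
#' The association z-score of one variant with one trait: the GWAS effect
#' estimate divided by its standard error.
#'
#' @param beta effect estimate (trait units or log-odds).
#' @param se standard error, strictly positive.
#' @return `beta / se`.
#' @export
zscore <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0")
  beta / se
}

#' Sample-size-adjusted z-score
#'
#' Divides the plain z-score by the square root of the GWAS sample size,
#' down-weighting traits whose large N inflates z irrespective of effect
#' size. Used as a clustering sensitivity analysis, not the main matrix.
#'
#' @param beta,se as in [zscore()].
#' @param n GWAS sample size, >= 1.
#' @return `beta / (se * sqrt(n))`.
#' @export
zscore_size_adjusted <- function(beta, se, n) {
  if (any(n < 1)) stop("n must be >= 1")
  zscore(beta, se) / sqrt(n)
}

#' Align an effect record to a designated risk allele
#'
#' If the record's effect allele already is the risk allele the record is
#' returned unchanged; otherwise the beta sign is flipped, the alleles are
#' swapped and the effect-allele frequency becomes its complement. The
#' operation is an involution.
#'
#' @param record one-row `sumstats` data.frame.
#' @param risk_allele the allele to orient the effect to; must match one of
#'   the record's alleles.
#' @return The aligned record.
#' @export
align_to_risk_allele <- function(record, risk_allele) {
  risk_allele <- toupper(risk_allele)
  if (record$effect_allele == risk_allele) return(record)
  if (record$other_allele != risk_allele)
    stop(sprintf("risk allele %s matches neither record allele (%s/%s)",
                 risk_allele, record$effect_allele, record$other_allele))
  tmp <- record$effect_allele
  record$effect_allele <- record$other_allele
  record$other_allele <- tmp
  record$beta <- -record$beta
  if (!is.null(record$eaf) && !is.na(record$eaf))
    record$eaf <- 1 - record$eaf
  record
}

#' Assemble the risk-allele-aligned variant-by-trait z-score matrix
#'
#' For every catalog variant and every trait: take the trait's record if
#' present, otherwise search the reference panel for a high-LD proxy; align
#' the record (or proxy) to the variant's T2D risk allele (the proxy's own
#' alleles, trusting the reported orientation); store z = beta/se. Cells
#' with neither record nor proxy stay missing. Palindromic (A/T or C/G)
#' variants with ambiguous frequency (EAF in \[0.4, 0.6\]) are aligned as
#' reported, with one logged count.
#'
#' @param catalog `variant_catalog`.
#' @param trait_tables named list of `sumstats` tables, one per trait.
#' @param panel reference panel for proxy search (`NULL` disables proxies).
#' @param proxy_r2 proxy r-squared floor.
#' @param proxy_window_bp proxy search window.
#' @param size_adjusted divide z by sqrt(n) (sensitivity variant).
#' @param align set `FALSE` to skip risk-allele alignment (diagnostics only).
#' @return A `zmatrix` object: list with `z` (numeric matrix, rows =
#'   variants, cols = traits), `mask` (character matrix with entries
#'   observed/proxy/missing, later also imputed), `proxies` (provenance
#'   data.frame), `catalog`.
#' @export
build_zmatrix <- function(catalog, trait_tables, panel = NULL,
                          proxy_r2 = 0.6, proxy_window_bp = 500000L,
                          size_adjusted = FALSE, align = TRUE) {
  traits <- names(trait_tables)
  stopifnot(length(traits) > 0, !is.null(traits))
  nv <- nrow(catalog)
  z <- matrix(NA_real_, nv, length(traits),
              dimnames = list(catalog$variant_id, traits))
  mask <- matrix("missing", nv, length(traits),
                 dimnames = dimnames(z))
  proxies <- list()
  n_palindromic_ambiguous <- 0L
  for (tr in traits) {
    tab <- trait_tables[[tr]]
    idx <- match(catalog$variant_id, tab$variant_id)
    for (i in seq_len(nv)) {
      rec <- NULL
      state <- "missing"
      if (!is.na(idx[i])) {
        rec <- tab[idx[i], , drop = FALSE]
        state <- "observed"
      } else if (!is.null(panel)) {
        rec <- find_proxy(catalog$variant_id[i], tab, panel,
                          r2_min = proxy_r2, window_bp = proxy_window_bp)
        if (!is.null(rec)) {
          state <- "proxy"
          proxies[[length(proxies) + 1L]] <- data.frame(
            variant_id = catalog$variant_id[i], trait = tr,
            proxy_id = rec$variant_id, r2 = rec$proxy_r2,
            stringsAsFactors = FALSE)
        }
      }
      if (is.null(rec)) next
      if (align && state == "observed") {
        pal <- paste0(sort(c(rec$effect_allele, rec$other_allele)),
                      collapse = "") %in% c("AT", "CG")
        if (pal && !is.na(rec$eaf) && rec$eaf >= 0.4 && rec$eaf <= 0.6)
          n_palindromic_ambiguous <- n_palindromic_ambiguous + 1L
        rec <- align_to_risk_allele(rec, catalog$risk_allele[i])
      }
      z[i, tr] <- if (size_adjusted)
        zscore_size_adjusted(rec$beta, rec$se, rec$n)
      else zscore(rec$beta, rec$se)
      mask[i, tr] <- state
    }
  }
  if (n_palindromic_ambiguous > 0)
    pp_log("zmatrix", "palindromic variants with ambiguous EAF aligned as reported",
           n_palindromic_ambiguous)
  proxies <- if (length(proxies) > 0) do.call(rbind, proxies) else
    data.frame(variant_id = character(0), trait = character(0),
               proxy_id = character(0), r2 = numeric(0))
  structure(list(z = z, mask = mask, proxies = proxies, catalog = catalog),
            class = "zmatrix")
}

#' Drop variants with excessive missingness
#'
#' Removes rows whose fraction of missing cells is strictly greater than
#' `max_frac` (a row missing exactly the threshold fraction is retained).
#'
#' @param matrix `zmatrix` with proxies already substituted.
#' @param max_frac maximum tolerated missing fraction.
#' @return Filtered `zmatrix`; removed variant ids in attribute `removed`.
#' @export
filter_missingness <- function(matrix, max_frac = 0.20) {
  frac <- rowMeans(is.na(matrix$z))
  drop <- frac > max_frac
  pp_log("zmatrix", sprintf("variants removed for missingness > %g%%",
                            100 * max_frac), sum(drop))
  out <- matrix
  out$z <- matrix$z[!drop, , drop = FALSE]
  out$mask <- matrix$mask[!drop, , drop = FALSE]
  out$catalog <- matrix$catalog[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(matrix$z)[drop]
  out
}

#' Iterative random-forest imputation of missing z-scores
#'
#' missForest-style scheme: missing cells are initialized with column means;
#' columns are then visited in ascending missingness order, each fitted by a
#' regression forest on all other columns over its observed rows and its
#' missing rows predicted. Sweeps repeat until the summed squared change of
#' the imputed values increases (the previous sweep's values are kept) or
#' `max_iter` sweeps. Observed cells are never modified. Deterministic given
#' `seed`.
#'
#' @param matrix `zmatrix` after missingness filtering.
#' @param max_iter maximum sweeps.
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return `zmatrix` with no missing cells; imputed cells flagged "imputed"
#'   in the mask.
#' @export
impute_rf <- function(matrix, max_iter = 10L, n_trees = 100L, seed = 1L) {
  z <- matrix$z
  miss <- is.na(z)
  if (!any(miss)) return(matrix)
  if (any(colSums(!miss) == 0))
    stop("column(s) with no observed values cannot be imputed: ",
         paste(colnames(z)[colSums(!miss) == 0], collapse = ", "))
  col_means <- colMeans(z, na.rm = TRUE)
  for (j in seq_len(ncol(z))) z[miss[, j], j] <- col_means[j]
  visit <- order(colSums(miss))
  visit <- visit[colSums(miss)[visit] > 0]
  prev_delta <- Inf
  best <- z
  set.seed(seed)
  for (iter in seq_len(max_iter)) {
    z_old <- z
    for (j in visit) {
      obs <- !miss[, j]
      df <- as.data.frame(z[, -j, drop = FALSE])
      names(df) <- paste0("x", seq_len(ncol(df)))
      df$y <- z[, j]
      fit <- ranger::ranger(y ~ ., data = df[obs, , drop = FALSE],
                            num.trees = n_trees, num.threads = 1,
                            seed = seed + iter * 1000L + j)
      z[miss[, j], j] <- stats::predict(
        fit, df[miss[, j], , drop = FALSE])$predictions
    }
    delta <- sum((z[miss] - z_old[miss])^2)
    if (delta >= prev_delta) { z <- best; break }
    best <- z
    prev_delta <- delta
  }
  pp_log("zmatrix", "cells imputed by random forest", sum(miss))
  out <- matrix
  out$z <- z
  out$mask[miss] <- "imputed"
  out
}

#' Winsorize extreme z-scores per trait column
#'
#' For each trait column, computes the mean and standard deviation over all
#' rows (after imputation) and clips every cell to within `k_sd` standard
#' deviations of the column mean. Clipped cells are flagged. Values are
#' clipped, not rows removed, so the variant set is preserved.
#'
#' @param matrix fully imputed `zmatrix`.
#' @param k_sd truncation bound in column standard deviations.
#' @return `zmatrix` with `truncated` (logical matrix) and per-column
#'   `trunc_mean`/`trunc_sd` recorded.
#' @export
truncate_z <- function(matrix, k_sd = 2) {
  z <- matrix$z
  if (any(is.na(z))) stop("impute before truncation: matrix has missing cells")
  mu <- colMeans(z)
  sig <- apply(z, 2, stats::sd)
  clipped <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  for (j in seq_len(ncol(z))) {
    if (sig[j] == 0) {
      warning(sprintf("column %s has zero sd: left untouched", colnames(z)[j]))
      next
    }
    lo <- mu[j] - k_sd * sig[j]
    hi <- mu[j] + k_sd * sig[j]
    cj <- z[, j] < lo | z[, j] > hi
    z[, j] <- pmin(pmax(z[, j], lo), hi)
    clipped[, j] <- cj
  }
  pp_log("zmatrix", "cells winsorized", sum(clipped))
  out <- matrix
  out$z <- z
  out$truncated <- clipped
  out$trunc_mean <- mu
  out$trunc_sd <- sig
  out
}

#' Write / read a z-matrix as TSV
#'
#' One row per variant; trait columns hold z values, matching `mask.<trait>`
#' columns hold cell provenance.
#'
#' @param matrix `zmatrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_zmatrix <- function(matrix, path) {
  df <- data.frame(variant_id = rownames(matrix$z), check.names = FALSE)
  zdf <- as.data.frame(matrix$z, check.names = FALSE)
  mdf <- as.data.frame(matrix$mask, check.names = FALSE)
  names(mdf) <- paste0("mask.", names(mdf))
  write_tsv(cbind(df, zdf, mdf), path)
}

#' @rdname write_zmatrix
#' @param path TSV written by [write_zmatrix()].
#' @export
read_zmatrix <- function(path) {
  df <- read_tsv(path)
  mask_cols <- grep("^mask\\.", names(df), value = TRUE)
  traits <- setdiff(names(df), c("variant_id", mask_cols))
  z <- as.matrix(df[, traits, drop = FALSE])
  storage.mode(z) <- "double"
  rownames(z) <- df$variant_id
  mask <- as.matrix(df[, mask_cols, drop = FALSE])
  colnames(mask) <- sub("^mask\\.", "", mask_cols)
  rownames(mask) <- df$variant_id
  structure(list(z = z, mask = mask,
                 proxies = NULL, catalog = NULL), class = "zmatrix")
}
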