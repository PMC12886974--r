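# shared fixture builders (all data generated in code)

make_sumstats_df <- function(n = 3, chrom = "1", pos = NULL, beta = NULL,
                             se = NULL, ids = NULL) {
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(beta)) beta <- seq_len(n) / 10
  if (is.null(se)) se <- rep(0.05, n)
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(n))
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             effect_allele = "A", other_allele = "G",
             beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n = 10000L,
             eaf = rep(0.3, n), stringsAsFactors = FALSE)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  path
}

# panel from explicit dosage rows (variants x samples)
make_panel <- function(dosage_rows, chrom = NULL, pos = NULL) {
  m <- do.call(rbind, dosage_rows)
  ids <- names(dosage_rows)
  dimnames(m) <- list(ids, sprintf("s%03d", seq_len(ncol(m))))
  if (is.null(chrom)) chrom <- rep("1", length(ids))
  if (is.null(pos)) pos <- seq_along(ids) * 1000L
  list(dosages = m, chrom = setNames(chrom, ids),
       pos = setNames(as.integer(pos), ids))
}

make_catalog <- function(ids, chrom = "1", pos = NULL, p = NULL) {
  if (is.null(pos)) pos <- seq_along(ids) * 1000L
  df <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                   origin_trait = "T2D", risk_allele = "A",
                   stringsAsFactors = FALSE)
  if (!is.null(p)) df$p <- p
  as_catalog(df)
}

# dosage vector correlated with `a` at approximately the target r
correlated_dosages <- function(a, target_r, seed = 1) {
  set.seed(seed)
  n <- length(a)
  b <- a
  n_swap <- round((1 - target_r) * n / 1.3)
  idx <- sample(n, n_swap)
  b[idx] <- sample(0:2, n_swap, replace = TRUE)
  b
}

std_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5),
             array = rbinom(n, 1, 0.5),
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("pc", 1:6))))
}
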