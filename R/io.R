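#' Read GWAS summary statistics
#'
#' Reads a delimited text file of per-variant association records into a
#' typed summary-statistics table. The canonical columns are `variant_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`
#' and (optionally) `eaf`; `column_map` renames source headers onto these
#' (names = canonical, values = source header). Rows with missing or
#' non-numeric `beta` or `se`, or `se <= 0`, are rejected with one logged
#' count per rejection class. Alleles are uppercased.
#'
#' All coordinates in the package are 1-based inclusive. The on-disk dialect
#' is tab-separated with "." for missing values.
#'
#' @param path delimited text file with a header row.
#' @param column_map optional named character vector mapping canonical
#'   column names to the file's header names.
#' @return A `data.frame` of class `sumstats` with one row per variant.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c(".", "NA", ""),
                           colClasses = "character",
                           check.names = FALSE)
  canonical <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "beta", "se", "p", "n", "eaf")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      src <- column_map[[nm]]
      if (!src %in% names(raw))
        stop(sprintf("mapped column '%s' (for '%s') absent from %s",
                     src, nm, path))
      names(raw)[names(raw) == src] <- nm
    }
  }
  mandatory <- setdiff(canonical, "eaf")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0)
    stop(sprintf("summary statistics file %s lacks mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  as_sumstats(raw, stage = "read_sumstats")
}

#' Coerce a data.frame to a summary-statistics table
#'
#' Applies the typing and row-filtering rules of [read_sumstats()] to an
#' in-memory data.frame.
#'
#' @param df data.frame with the canonical columns.
#' @param stage label used in log lines.
#' @return A `sumstats` data.frame.
#' @export
as_sumstats <- function(df, stage = "as_sumstats") {
  df$pos <- as.integer(as.character(df$pos))
  df$chrom <- as.character(df$chrom)
  suppressWarnings({
    df$beta <- as.numeric(as.character(df$beta))
    df$se <- as.numeric(as.character(df$se))
    df$p <- as.numeric(as.character(df$p))
    df$n <- as.integer(as.character(df$n))
  })
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  suppressWarnings(df$eaf <- as.numeric(as.character(df$eaf)))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  bad <- is.na(df$beta) | is.na(df$se) | df$se <= 0
  if (any(bad)) pp_log(stage, "rows rejected (missing/invalid beta or se)",
                       sum(bad))
  df <- df[!bad, , drop = FALSE]
  dup <- duplicated(df$variant_id)
  if (any(dup)) {
    pp_log(stage, "duplicate variant_id rows dropped", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Write a summary-statistics table
#'
#' Tab-separated, "." for missing, numeric columns at full double precision
#' (15 significant digits) so a write-then-read round trip preserves floats
#' to at least 12 significant digits.
#'
#' @param table `sumstats` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  write_tsv(table, path)
}

# shared TSV writer: tabs, "." for NA, full float precision
write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          formatC(out[[nm]], digits = 15, format = "g"))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write %s: %s", path,
                                conditionMessage(ok)))
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    na.strings = c(".", "NA", ""), check.names = FALSE, ...)
}

#' Read a curated variant catalog
#'
#' Columns: `variant_id`, `chrom`, `pos`, `origin_trait` (one of T2D, SBP,
#' DBP, PP), `risk_allele` (the T2D-risk-increasing allele), optional
#' `cluster`, optional `p` (origin-GWAS p-value, used as pruning priority).
#'
#' @param path TSV file.
#' @return A `data.frame` of class `variant_catalog`.
#' @export
read_catalog <- function(path) {
  df <- read_tsv(path)
  as_catalog(df)
}

#' Coerce a data.frame to a variant catalog
#' @param df data.frame with catalog columns.
#' @return A `variant_catalog` data.frame.
#' @export
as_catalog <- function(df) {
  need <- c("variant_id", "chrom", "pos", "origin_trait", "risk_allele")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("catalog lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  ok <- df$origin_trait %in% c("T2D", "SBP", "DBP", "PP")
  if (!all(ok))
    stop(sprintf("origin_trait outside {T2D, SBP, DBP, PP} for %d variants",
                 sum(!ok)))
  df$pos <- as.integer(df$pos)
  df$chrom <- as.character(df$chrom)
  df$risk_allele <- toupper(as.character(df$risk_allele))
  rownames(df) <- NULL
  class(df) <- c("variant_catalog", "data.frame")
  df
}

#' Read a dosage matrix
#'
#' Variants x samples TSV: first three columns `variant_id`, `chrom`, `pos`,
#' then one numeric column per sample with dosages in \[0, 2\].
#'
#' @param path TSV file.
#' @return A list with `dosages` (numeric matrix, rownames = variant ids),
#'   `chrom` and `pos` vectors named by variant.
#' @export
read_dosages <- function(path) {
  df <- read_tsv(path)
  need <- c("variant_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("dosage file must start with variant_id, chrom, pos columns")
  samp_cols <- setdiff(names(df), need)
  m <- as.matrix(df[, samp_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$variant_id
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("dosages outside [0, 2] in ", path)
  list(dosages = m,
       chrom = stats::setNames(as.character(df$chrom), df$variant_id),
       pos = stats::setNames(as.integer(df$pos), df$variant_id))
}

#' Write a dosage matrix
#' @param panel list as returned by [read_dosages()] or
#'   [simulate_reference_panel()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(panel, path) {
  df <- data.frame(variant_id = rownames(panel$dosages),
                   chrom = unname(panel$chrom[rownames(panel$dosages)]),
                   pos = unname(panel$pos[rownames(panel$dosages)]),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(panel$dosages, check.names = FALSE))
  write_tsv(df, path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package-wide 1-based inclusive convention on read (`start + 1`, `end`).
#'
#' @param path BED file (3+ columns, no header).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` if a fourth column is present.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Write intervals as BED
#'
#' Converts from 1-based inclusive back to BED's 0-based half-open.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom,
                   as.integer(intervals$start) - 1L,
                   as.integer(intervals$end))
  if ("name" %in% names(intervals)) df$name <- intervals$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Membership of positions in intervals
#'
#' @param chrom,pos vectors of variant coordinates (1-based).
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return logical vector: position falls inside at least one interval.
#' @export
in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  if (nrow(intervals) == 0) return(out)
  by_chr <- split(intervals, intervals$chrom)
  for (cc in names(by_chr)) {
    idx <- which(chrom == cc)
    if (length(idx) == 0) next
    iv <- by_chr[[cc]]
    for (i in idx) {
      out[i] <- any(pos[i] >= iv$start & pos[i] <= iv$end)
    }
  }
  out
}
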