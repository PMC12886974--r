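#' Default run configuration
#'
#' Every tunable threshold of the pipeline, with its default. Values are
#' grouped by pipeline stage; synthetic-data generation parameters live under
#' `$synthetic`. All downstream stage functions accept individual arguments
#' whose defaults are drawn from this object, so a config file only needs to
#' list overrides.
#'
#' Key thresholds: LD pruning keeps variants with pairwise r-squared below
#' `ld_prune_r2`; proxies require r-squared above `proxy_r2`; z-matrix rows
#' with missing fraction above `missingness_max` are dropped; cells are
#' winsorized at `truncation_sd` column standard deviations; colocalization
#' regions span `coloc_halfwindow_bp` either side of the index variant and
#' must hold between `region_min_snps` and `region_max_snps` variants
#' (inclusive); a colocalization is called when PP.H4 exceeds `pp_h4_min` and
#' PP.H3 is below `pp_h3_max`; the MHC interval `mhc` is excluded; enrichment
#' background aggregates panel variants within `background_window_bp` of each
#' clustered variant; soft-cluster assignment requires normalized weight
#' above `soft_assign_weight`; risk groups use the `top_fractions`
#' percentile cuts; medicated blood pressure is adjusted by `med_adjust`
#' (mmHg); hypertension is SBP >= `htn_sbp` or DBP >= `htn_dbp` or
#' medication.
#'
#' @param seed integer seed used by every stochastic stage.
#' @return A named list of class `partpgs_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    ld_prune_r2 = 0.2,
    proxy_r2 = 0.6,
    proxy_window_bp = 500000L,
    overlap_window_bp = 500000L,
    overlap_r2 = 0.2,
    missingness_max = 0.20,
    truncation_sd = 2,
    rf_max_iter = 10L,
    rf_n_trees = 100L,
    coloc_halfwindow_bp = 100000L,
    region_min_snps = 100L,
    region_max_snps = 1000L,
    pp_h4_min = 0.8,
    pp_h3_max = 0.5,
    coloc_p1 = 1e-4,
    coloc_p2 = 1e-4,
    coloc_p12 = 1e-5,
    coloc_prior_sd = c(gwas = 0.2, eqtl = 0.2),
    mhc = list(chrom = "6", start = 25000000L, end = 35000000L),
    background_window_bp = 50000L,
    enrich_alpha = 0.05,
    soft_assign_weight = 0.75,
    bnmf_k_max = 8L,
    bnmf_n_restarts = 10L,
    top_fractions = c(0.10, 0.33),
    med_adjust = c(sbp = 15, dbp = 10),
    htn_sbp = 150,
    htn_dbp = 90,
    scan_alpha = 0.05,
    scan_min_cases = 10L,
    rr_ci_style = "as_printed",
    synthetic = list(
      k = 5L,
      n_traits = 45L,
      snvs_per_cluster = c(215L, 353L, 137L, 287L, 312L),
      signature_scale = 5,
      noise_sd = 1,
      missing_rate = 0.10,
      gwas_n = 100000L,
      panel_n = 300L,
      panel_block_size = 4L,
      panel_rho = 0.8,
      maf_range = c(0.05, 0.5),
      cohort_n = 10000L,
      disease1_prevalence = 0.08,
      disease2_prevalence = 0.25,
      n_cell_types = 6L,
      peak_background_rate = 0.10,
      peak_fold = 3,
      n_eqtl_tissues = 3L,
      eqtl_effect_z = 8,
      eqtl_n_snps = 300L,
      eqtl_ld_rho = 0.9
    )
  )
  class(cfg) <- c("partpgs_config", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults; anything absent keeps
#' its default value. Nested lists (e.g. `synthetic`) are merged field-wise.
#'
#' @param path YAML file.
#' @param base configuration to merge overrides into.
#' @return A `partpgs_config` list.
#' @export
read_config <- function(path, base = default_config()) {
  stopifnot(file.exists(path))
  over <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_cfg(unclass(base), over)
  validate_config(cfg)
  class(cfg) <- c("partpgs_config", "list")
  cfg
}

#' Write a configuration as YAML
#'
#' @param cfg configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  frac_fields <- c("ld_prune_r2", "proxy_r2", "missingness_max",
                   "pp_h4_min", "pp_h3_max", "soft_assign_weight")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("config field '%s' must lie in (0, 1), got %s", f, v))
  }
  if (any(cfg$top_fractions <= 0 | cfg$top_fractions >= 1))
    stop("top_fractions must lie in (0, 1)")
  win_fields <- c("proxy_window_bp", "overlap_window_bp",
                  "coloc_halfwindow_bp", "background_window_bp")
  for (f in win_fields) {
    if (cfg[[f]] <= 0) stop(sprintf("config field '%s' must be positive", f))
  }
  invisible(TRUE)
}

# one structured line per filtering-decision class, never per-row spam
pp_log <- function(stage, what, n, detail = NULL) {
  msg <- sprintf("[partpgs:%s] %s: %d", stage, what, n)
  if (!is.null(detail)) msg <- paste0(msg, " (", detail, ")")
  message(msg)
  invisible(msg)
}
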