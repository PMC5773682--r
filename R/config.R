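#' Analysis configuration
#'
#' Creates the flat configuration object that holds every threshold used by
#' the pipeline: the variant-QC filters, the LD-pruning and duplicate
#' detection cut-offs, the discovery-evaluation and meta-analysis
#' significance thresholds, the RPE stopping rule and binning limits, and
#' the eQTL overlap filters. All defaults are the pipeline's standard
#' operating values; any of them can be overridden by name.
#'
#' @param ... named overrides of the default values, e.g.
#'   `analysis_config(maf_min = 0.05)`.
#'
#' @return An object of class `fa_config`: a named list of thresholds.
#'
#' @details Key defaults:
#' * `call_rate_min = 0.99` (strict `>`), `maf_min = 0.01` (`>=`),
#'   `hwe_p_min = 1e-6` (strict `>`), `concordance_min = 0.90` (strict `>`):
#'   the four per-variant QC filters, each applied in *both* samplesets.
#' * `ld_prune_r2 = 0.2`: variants with pairwise dosage r^2 at or above this
#'   are pruned before PCA/IBD.
#' * `pi_hat_dup = 0.8`: PI_HAT above this flags a duplicate pair.
#' * `p_discovery_max = 1e-4`, `p_eval_max = 0.05`, `fdr_eval_max = 0.2`:
#'   the bi-directional discovery-evaluation rule.
#' * `effective_test_count = 411521`, `n_foods_tested = 27`,
#'   `p_nominal = 1.21e-7`, `p_strong = 4.4e-9`: significance tiers. The two
#'   P cut-offs are stored verbatim (as printed in the source analyses they
#'   mirror) rather than recomputed, so tier calls reproduce reported
#'   behaviour exactly.
#' * `min_cases_per_set = 100`: a food is analysed only with case count
#'   strictly greater than this in both samplesets.
#' * `rpe_locus_stop_p = 0.05`, `bin_min_expected = 5`,
#'   `hap_bin_min_freq = 0.01`: RPE stopping and binning rules.
#' * `ld_moderate = 0.5`, `ld_high = 0.8`: LD-class thresholds on dosage r^2
#'   and r2_equiv.
#' * `rss_min = 0.2`, `hgvd_r2_min = 0.1`: eQTL overlap filters.
#' * `ct_min = 0.5`: HLA call-threshold filter (strict `>`).
#' * `n_pcs = 2`: number of principal components used as GWAS covariates.
#'
#' @examples
#' cfg <- analysis_config()
#' cfg$p_nominal
#' analysis_config(maf_min = 0.05)$maf_min
#' @export
analysis_config <- function(...) {
  cfg <- list(
    call_rate_min = 0.99,
    maf_min = 0.01,
    hwe_p_min = 1e-6,
    concordance_min = 0.90,
    ld_prune_r2 = 0.2,
    ld_prune_window = 50L,
    ld_prune_step = 5L,
    pi_hat_dup = 0.8,
    p_discovery_max = 1e-4,
    p_eval_max = 0.05,
    fdr_eval_max = 0.2,
    fdr_universe = "per_direction",  # or "genome_wide"
    effective_test_count = 411521L,
    n_foods_tested = 27L,
    p_nominal = 1.21e-7,
    p_strong = 4.4e-9,
    min_cases_per_set = 100L,
    rpe_locus_stop_p = 0.05,
    rpe_allow_bin_removal = FALSE,
    bin_min_expected = 5,
    hap_bin_min_freq = 0.01,
    hap_count_mode = "hard",          # or "fractional"
    ld_moderate = 0.5,
    ld_high = 0.8,
    rss_min = 0.2,
    gtex_min_tissues = 10L,
    hgvd_r2_min = 0.1,
    ct_min = 0.5,
    n_pcs = 2L,
    pca_rounds = 3L,
    pca_outlier_sd = 6,
    hwe_test = "exact",               # or "chisq"
    gwas_max_iter = 25L,
    gwas_max_abs_beta = 20
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  .validate_config(cfg)
  structure(cfg, class = "fa_config")
}

.validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  stopifnot(
    in01(cfg$call_rate_min), in01(cfg$maf_min), in01(cfg$hwe_p_min),
    in01(cfg$concordance_min), in01(cfg$pi_hat_dup),
    in01(cfg$p_discovery_max), in01(cfg$p_eval_max), in01(cfg$fdr_eval_max),
    in01(cfg$p_nominal), in01(cfg$p_strong),
    in01(cfg$rpe_locus_stop_p), in01(cfg$hap_bin_min_freq),
    in01(cfg$rss_min), in01(cfg$hgvd_r2_min), in01(cfg$ct_min),
    cfg$ld_prune_r2 > 0, cfg$ld_prune_r2 <= 1,
    cfg$min_cases_per_set >= 0, cfg$bin_min_expected >= 0,
    cfg$n_pcs >= 1, cfg$pca_rounds >= 1
  )
  if (cfg$p_strong > cfg$p_nominal) {
    stop("p_strong must not exceed p_nominal")
  }
  invisible(cfg)
}

#' @export
print.fa_config <- function(x, ...) {
  cat("<fa_config> analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
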