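#' Dosage-correlation r-squared between two variants
#'
#' Squared Pearson correlation of alternate-allele dosages over
#' pairwise-complete subjects. Undefined (NA) when either vector is
#' constant or fewer than two complete pairs exist.
#'
#' @param geno an [fa_geno].
#' @param v1,v2 variant ids.
#' @return Scalar r-squared in [0, 1], or NA.
#' @export
dosage_r2 <- function(geno, v1, v2) {
  pair_r2(geno_dosage(geno, v1), geno_dosage(geno, v2))
}

#' The conditional-signal LD-equivalent statistic r2_equiv
#'
#' Quantifies how much of variant B's association signal is explained by
#' conditioning on a top variant A, on the -log10 P scale: with
#' `Z = -log10(P)`, `r2_equiv = (Z_B - Z_B|A) / Z_A`. A variant tested
#' against itself (where the conditional P is 1 by the collinearity
#' convention) scores exactly 1; conditioning that changes nothing scores 0.
#' Values are not clamped: conditioning that *increases* significance yields
#' a negative value. P-values of 0 are floored at 1e-320 before logs.
#'
#' @param p_top unconditional P of the top variant A.
#' @param p_b unconditional P of the tested variant B.
#' @param p_b_cond P of B after conditioning on A.
#' @return Scalar (vectorized over inputs).
#' @examples
#' r2_equiv(1e-10, 1e-8, 1e-2)  # (8 - 2) / 10 = 0.6
#' @export
r2_equiv <- function(p_top, p_b, p_b_cond) {
  if (any(c(p_top, p_b, p_b_cond) < 0, na.rm = TRUE) ||
      any(c(p_top, p_b, p_b_cond) > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  z_a <- -log10(floor_p(p_top))
  z_b <- -log10(floor_p(p_b))
  z_bc <- -log10(floor_p(p_b_cond))
  (z_b - z_bc) / z_a
}

#' LD metrics of every variant against a top variant
#'
#' Computes, for each tested variant, the dosage r-squared with the top
#' variant and the `r2_equiv` statistic from an unconditional and a
#' conditional GWAS run.
#'
#' @param geno an [fa_geno].
#' @param gwas unconditional [logistic_gwas()] result.
#' @param gwas_cond matching [conditional_gwas()] result, conditioned on
#'   `top`.
#' @param top id of the top variant.
#' @return data.frame `top_id, id, r2, r2_equiv`.
#' @export
ld_metrics <- function(geno, gwas, gwas_cond, top) {
  stopifnot(inherits(gwas, "fa_gwas"), inherits(gwas_cond, "fa_gwas"))
  rec <- gwas$records
  recc <- gwas_cond$records[match(rec$id, gwas_cond$records$id), ]
  p_top <- rec$p[match(top, rec$id)]
  if (is.na(p_top)) stop("top variant has no unconditional p-value: ", top)
  data.frame(
    top_id = top,
    id = rec$id,
    r2 = vapply(rec$id, function(v) dosage_r2(geno, top, v), numeric(1)),
    r2_equiv = r2_equiv(p_top, rec$p, recc$p),
    stringsAsFactors = FALSE
  )
}

#' Classify variants into moderate/high LD sets around a top variant
#'
#' Default (OR) rule: moderate LD when `r2 > ld_moderate` *or*
#' `r2_equiv > ld_moderate`; high LD when either exceeds `ld_high`. The
#' high set is a subset of the moderate set. Setting `rule = "equiv_only"`
#' classifies on `r2_equiv` alone.
#'
#' @param results data.frame from [ld_metrics()] (columns `id, r2,
#'   r2_equiv`).
#' @param config an [analysis_config()].
#' @param rule `"or"` (default) or `"equiv_only"`.
#' @return `results` with added logical columns `moderate` and `high`.
#' @export
ld_class <- function(results, config = analysis_config(), rule = c("or", "equiv_only")) {
  rule <- match.arg(rule)
  r2 <- ifelse(is.na(results$r2), -Inf, results$r2)
  re <- ifelse(is.na(results$r2_equiv), -Inf, results$r2_equiv)
  if (rule == "or") {
    results$moderate <- r2 > config$ld_moderate | re > config$ld_moderate
    results$high <- r2 > config$ld_high | re > config$ld_high
  } else {
    results$moderate <- re > config$ld_moderate
    results$high <- re > config$ld_high
  }
  results$moderate <- results$moderate | results$high
  results
}
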