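#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p P-values in [0, 1].
#' @return Adjusted values, monotone non-decreasing in `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Convert an odds ratio with 95% CI to log-odds and standard error
#'
#' `beta = ln(OR)`; `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`. A degenerate
#' interval (`hi == lo`) yields `se = 0` and is flagged.
#'
#' @param or,lo,hi odds ratio and its 95% confidence bounds
#'   (`0 < lo <= or <= hi`).
#' @return data.frame `beta, se, degenerate`.
#' @examples
#' or_ci_to_beta_se(1.70, 1.34, 2.14)
#' @export
or_ci_to_beta_se <- function(or, lo, hi) {
  if (any(lo <= 0) || any(lo > or + 1e-12) || any(or > hi + 1e-12)) {
    stop("need 0 < lo <= or <= hi")
  }
  data.frame(
    beta = log(or),
    se = (log(hi) - log(lo)) / (2 * 1.959964),
    degenerate = hi == lo
  )
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools two samplesets' log-odds estimates with weights `1/se^2`:
#' pooled beta `= sum(w b)/sum(w)`, pooled SE `= 1/sqrt(sum(w))`,
#' `z = beta/se`, and a two-sided normal P computed on the log scale so
#' extreme signals do not underflow. Also reports the pooled odds ratio with
#' its 95% CI (`exp(beta -+ 1.959964 se)`).
#'
#' @param beta1,se1,beta2,se2 per-set estimates (vectors allowed; both SEs
#'   must be positive).
#' @return data.frame `beta, se, z, p, neglog10_p, or, or_lo, or_hi`.
#' @examples
#' ivw_meta(log(1.5), 0.1, log(1.5), 0.1)  # pooled se = 0.1/sqrt(2)
#' @export
ivw_meta <- function(beta1, se1, beta2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0)) stop("standard errors must be positive")
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  beta <- (w1 * beta1 + w2 * beta2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  z <- beta / se
  data.frame(
    beta = beta, se = se, z = z,
    p = p_from_z(z),
    neglog10_p = neglog10_p_from_z(z),
    or = exp(beta),
    or_lo = exp(beta - 1.959964 * se),
    or_hi = exp(beta + 1.959964 * se)
  )
}

# Harmonize two record sets to a shared variant universe and effect allele.
# Flippable mismatches have beta negated; irreconcilable alleles error.
harmonize_records <- function(a, b) {
  common <- intersect(a$id, b$id)
  a <- a[match(common, a$id), , drop = FALSE]
  b <- b[match(common, b$id), , drop = FALSE]
  same <- a$effect_allele == b$effect_allele & a$other_allele == b$other_allele
  flip <- a$effect_allele == b$other_allele & a$other_allele == b$effect_allele
  bad <- !(same | flip)
  if (any(bad)) {
    stop("effect alleles cannot be harmonized for: ",
         paste(a$id[bad], collapse = ", "))
  }
  b$beta[flip] <- -b$beta[flip]
  b$effect_allele[flip] <- a$effect_allele[flip]
  b$other_allele[flip] <- a$other_allele[flip]
  list(a = a, b = b)
}

#' Bi-directional discovery-evaluation candidate selection
#'
#' A variant is a candidate when it achieves `P <= p_discovery_max` in one
#' sampleset (the discovery arm) and, in the other sampleset,
#' `P < p_eval_max` together with Benjamini-Hochberg FDR `< fdr_eval_max`;
#' both directions are searched and the union returned. The evaluation FDR
#' is computed, per direction, over the evaluation-arm P-values of exactly
#' those variants that passed discovery in the opposite arm
#' (`config$fdr_universe = "per_direction"`, the default) or over all
#' evaluation-arm P-values (`"genome_wide"`). Concordance of effect
#' direction is not required.
#'
#' @param rec_a,rec_b per-sampleset association records (data.frames with
#'   `id, effect_allele, other_allele, beta, p`).
#' @param config an [analysis_config()].
#' @return data.frame `id, direction, p_discovery, p_evaluation, fdr_evaluation`
#'   with `direction` in `"a_to_b"`/`"b_to_a"` (a variant discovered both
#'   ways appears once per direction).
#' @export
discovery_evaluation <- function(rec_a, rec_b, config = analysis_config()) {
  h <- harmonize_records(rec_a, rec_b)
  one_direction <- function(disc, eval_, label) {
    cand <- which(!is.na(disc$p) & disc$p <= config$p_discovery_max)
    if (!length(cand)) {
      return(data.frame(id = character(0), direction = character(0),
                        p_discovery = numeric(0), p_evaluation = numeric(0),
                        fdr_evaluation = numeric(0)))
    }
    p_eval <- eval_$p[cand]
    fdr <- if (identical(config$fdr_universe, "genome_wide")) {
      bh_fdr(eval_$p)[cand]
    } else {
      bh_fdr(p_eval)
    }
    pass <- !is.na(p_eval) & p_eval < config$p_eval_max &
      fdr < config$fdr_eval_max
    data.frame(
      id = disc$id[cand][pass], direction = rep(label, sum(pass)),
      p_discovery = disc$p[cand][pass],
      p_evaluation = p_eval[pass],
      fdr_evaluation = fdr[pass],
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    one_direction(h$a, h$b, "a_to_b"),
    one_direction(h$b, h$a, "b_to_a")
  )
  rownames(out) <- NULL
  out
}

#' Meta-analyse two samplesets' records
#'
#' Harmonizes effect alleles, pools by inverse variance, and returns one
#' meta record per shared variant with both per-set and pooled statistics.
#'
#' @inheritParams discovery_evaluation
#' @return data.frame with per-set `beta/se/p` columns, pooled `beta, se,
#'   z, p_meta, neglog10_p_meta, or_meta, or_lo, or_hi`.
#' @export
meta_analyse <- function(rec_a, rec_b) {
  h <- harmonize_records(rec_a, rec_b)
  ok <- !is.na(h$a$se) & !is.na(h$b$se) & h$a$se > 0 & h$b$se > 0
  a <- h$a[ok, , drop = FALSE]
  b <- h$b[ok, , drop = FALSE]
  m <- ivw_meta(a$beta, a$se, b$beta, b$se)
  data.frame(
    id = a$id, effect_allele = a$effect_allele,
    other_allele = a$other_allele,
    beta_a = a$beta, se_a = a$se, p_a = a$p,
    beta_b = b$beta, se_b = b$se, p_b = b$p,
    beta = m$beta, se = m$se, z = m$z,
    p_meta = m$p, neglog10_p_meta = m$neglog10_p,
    or_meta = m$or, or_lo = m$or_lo, or_hi = m$or_hi,
    stringsAsFactors = FALSE
  )
}

#' Call significance tiers for discovery-evaluation candidates
#'
#' Tiers apply only to discovery-evaluation survivors: a candidate is
#' `"strong"` when `p_meta < p_strong`, else `"nominal"` when
#' `p_meta < p_nominal`, else `"candidate"`. Non-candidates are `"none"`
#' regardless of `p_meta`.
#'
#' @param meta data.frame from [meta_analyse()].
#' @param candidates candidate variant ids (from [discovery_evaluation()]).
#' @param config an [analysis_config()].
#' @return Character vector of tiers aligned to `meta$id`.
#' @export
call_tiers <- function(meta, candidates, config = analysis_config()) {
  tier <- rep("none", nrow(meta))
  is_cand <- meta$id %in% candidates
  tier[is_cand] <- "candidate"
  tier[is_cand & meta$p_meta < config$p_nominal] <- "nominal"
  tier[is_cand & meta$p_meta < config$p_strong] <- "strong"
  tier
}
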