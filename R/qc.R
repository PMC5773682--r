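#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of Hardy-Weinberg proportions: conditional on the
#' observed allele counts, all heterozygote counts of matching parity are
#' enumerated and the P-value is the sum of the probabilities of every
#' configuration no more probable than the observed one (the classical
#' mid-p-free exact test). Probabilities are computed by the stable
#' ratio recurrence in the heterozygote count.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return Exact two-sided P-value in (0, 1].
#' @examples
#' hwe_exact_p(25, 50, 25)   # exact HWE proportions
#' hwe_exact_p(0, 100, 0)    # extreme heterozygote excess
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)

  # Heterozygote counts share the parity of the rare allele count.
  het_vals <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # Unnormalized probabilities via the ratio
  #   P(h + 2) / P(h) = (r - h)(c - h) / ((h + 2)(h + 1) ... ) with
  #   r = n_rare, hom_rare = (r - h)/2, hom_common = n - h - hom_rare.
  logp <- numeric(length(het_vals))
  for (i in seq_along(het_vals)[-1]) {
    h <- het_vals[i - 1]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    logp[i] <- logp[i - 1] +
      log(4) + log(hom_r) + log(hom_c) - log(h + 2) - log(h + 1)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, het_vals)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  max(min(sum(p[p <= obs * (1 + 1e-12)]), 1), .Machine$double.xmin)
}

# Chi-square 1-df HWE test, selectable through config$hwe_test.
hwe_chisq_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Per-variant quality control across both samplesets
#'
#' Computes, per variant and per sampleset, the call rate, minor allele
#' frequency and Hardy-Weinberg P-value, and (when duplicate pairs are
#' supplied) the duplicate-pair genotype concordance. A variant passes only
#' if it satisfies every criterion in *both* samplesets: call rate strictly
#' above `call_rate_min`, MAF at least `maf_min`, HWE P strictly above
#' `hwe_p_min`, and concordance strictly above `concordance_min`. HWE is
#' computed on all subjects of a sampleset (it is a genotyping-quality
#' filter applied before any phenotype is defined). A variant with zero
#' non-missing genotypes simply fails call-rate.
#'
#' @param geno an [fa_geno] with two samplesets.
#' @param config an [analysis_config()].
#' @param pairs optional data.frame `id1, id2` of duplicate sample pairs for
#'   the concordance criterion.
#' @return data.frame, one row per variant x sampleset, with the measured
#'   quantities and per-criterion pass flags; the attribute `pass_ids` holds
#'   the ids of variants passing all criteria in all samplesets, and
#'   `pass_overall` a per-variant logical vector in variant order.
#' @export
variant_qc <- function(geno, config = analysis_config(), pairs = NULL) {
  stopifnot(inherits(geno, "fa_geno"))
  if (ncol(geno$dosage) < 1 || nrow(geno$dosage) < 2) {
    stop("variant_qc needs at least 1 variant and 2 subjects")
  }
  sets <- unique(geno$subjects$sampleset)
  conc <- if (!is.null(pairs) && nrow(pairs)) {
    duplicate_concordance(geno, pairs)
  } else NULL
  hwe_fun <- if (identical(config$hwe_test, "chisq")) hwe_chisq_p else hwe_exact_p

  rows <- lapply(sets, function(s) {
    d <- geno$dosage[geno$subjects$sampleset == s, , drop = FALSE]
    n <- nrow(d)
    nm <- colSums(!is.na(d))
    call_rate <- nm / n
    alt <- colSums(d, na.rm = TRUE)
    p_alt <- ifelse(nm > 0, alt / (2 * nm), NA_real_)
    maf <- pmin(p_alt, 1 - p_alt)
    hwe_p <- vapply(seq_len(ncol(d)), function(j) {
      x <- d[, j]
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      hwe_fun(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    }, numeric(1))
    data.frame(
      id = geno$variants$id, sampleset = s,
      call_rate = call_rate, maf = maf, hwe_p = hwe_p,
      duplicate_concordance = if (is.null(conc)) NA_real_ else conc,
      pass_call_rate = call_rate > config$call_rate_min,
      pass_maf = !is.na(maf) & maf >= config$maf_min,
      pass_hwe = !is.na(hwe_p) & hwe_p > config$hwe_p_min,
      pass_concordance = if (is.null(conc)) TRUE else
        is.na(conc) | conc > config$concordance_min,
      stringsAsFactors = FALSE
    )
  })
  rep <- do.call(rbind, rows)
  rep$pass <- rep$pass_call_rate & rep$pass_maf & rep$pass_hwe &
    rep$pass_concordance
  pass_overall <- tapply(rep$pass, rep$id, all)
  pass_overall <- unname(pass_overall[geno$variants$id])
  attr(rep, "pass_overall") <- pass_overall
  attr(rep, "pass_ids") <- geno$variants$id[pass_overall]
  rep
}

#' Duplicate-pair genotype concordance per variant
#'
#' For each variant, the fraction of duplicate pairs with both calls
#' non-missing whose calls agree. Pairs with a missing call at a variant are
#' excluded from that variant's denominator; a variant with no informative
#' pair gets `NA`.
#'
#' @param geno an [fa_geno].
#' @param pairs data.frame with columns `id1`, `id2` (subject ids).
#' @return Numeric vector, one concordance per variant (in variant order).
#' @export
duplicate_concordance <- function(geno, pairs) {
  stopifnot(inherits(geno, "fa_geno"), nrow(pairs) >= 1)
  i1 <- match(pairs$id1, geno$subjects$subject_id)
  i2 <- match(pairs$id2, geno$subjects$subject_id)
  if (anyNA(i1) || anyNA(i2)) stop("unknown subject id in duplicate pairs")
  d1 <- geno$dosage[i1, , drop = FALSE]
  d2 <- geno$dosage[i2, , drop = FALSE]
  both <- !is.na(d1) & !is.na(d2)
  agree <- both & (d1 == d2)
  denom <- colSums(both)
  out <- ifelse(denom > 0, colSums(agree, na.rm = TRUE) / denom, NA_real_)
  unname(out)
}

#' Greedy LD pruning
#'
#' Left-to-right scan in genomic order within a sliding window of
#' `window` variants: a variant is dropped when its dosage r-squared with
#' any already-retained variant inside the window is at or above
#' `r2_threshold`. With a threshold of 1 only perfect proxies are dropped.
#'
#' @param geno an [fa_geno].
#' @param r2_threshold pruning threshold in (0, 1].
#' @param window window size in variants.
#' @param step kept for interface compatibility with windowed pruners; the
#'   scan advances one variant at a time.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(geno, r2_threshold = 0.2, window = 50L, step = 5L) {
  stopifnot(inherits(geno, "fa_geno"),
            r2_threshold > 0, r2_threshold <= 1)
  ord <- order(geno$variants$chrom, geno$variants$pos)
  d <- geno$dosage[, ord, drop = FALSE]
  chrom <- geno$variants$chrom[ord]
  keep <- logical(ncol(d))
  kept_idx <- integer(0)
  for (j in seq_len(ncol(d))) {
    recent <- kept_idx[kept_idx > j - window & chrom[kept_idx] == chrom[j]]
    drop <- FALSE
    for (k in rev(recent)) {
      r2 <- pair_r2(d[, k], d[, j])
      if (!is.na(r2) && r2 >= r2_threshold - 1e-12) { drop <- TRUE; break }
    }
    if (!drop) { keep[j] <- TRUE; kept_idx <- c(kept_idx, j) }
  }
  geno$variants$id[ord][keep]
}

# Squared dosage correlation over pairwise-complete subjects; NA when either
# vector is constant.
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Iterated PCA with outlier removal
#'
#' Standardizes each variant's dosages by mean `2p` and SD `sqrt(2p(1-p))`
#' (missing entries imputed at the mean, constant variants skipped),
#' computes principal components by singular value decomposition, flags
#' subjects lying beyond `k_sd` standard deviations on any of the top
#' `n_pcs` components, removes them, and repeats for `rounds` rounds. The
#' final round's components are the GWAS covariates. Component signs are
#' canonicalized so the largest-|loading| entry of each component is
#' positive.
#'
#' @param geno an [fa_geno] restricted to LD-pruned variants.
#' @param config an [analysis_config()]; uses `pca_rounds`,
#'   `pca_outlier_sd` and `n_pcs`.
#' @param n_components number of components to return per round.
#' @return Object of class `fa_pca`: list of per-round results (`scores`,
#'   `eigenvalues`, `var_explained`, `outliers`) plus `final_scores` (the
#'   last round's score matrix, rownames = subject ids) and `removed` (all
#'   outlier ids).
#' @export
pca_rounds <- function(geno, config = analysis_config(), n_components = 10L) {
  stopifnot(inherits(geno, "fa_geno"), nrow(geno$dosage) >= 3)
  current <- seq_len(nrow(geno$dosage))
  ids <- geno$subjects$subject_id
  rounds <- list()
  removed <- character(0)
  for (r in seq_len(config$pca_rounds)) {
    d <- geno$dosage[current, , drop = FALSE]
    p <- colMeans(d, na.rm = TRUE) / 2
    usable <- !is.na(p) & p > 0 & p < 1
    x <- d[, usable, drop = FALSE]
    p <- p[usable]
    x <- sweep(x, 2, 2 * p)
    x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
    x[is.na(x)] <- 0
    k <- min(n_components, nrow(x) - 1L, ncol(x))
    sv <- svd(x, nu = k, nv = k)
    # Canonical sign: largest-|loading| entry positive.
    for (j in seq_len(k)) {
      piv <- which.max(abs(sv$v[, j]))
      if (sv$v[piv, j] < 0) {
        sv$v[, j] <- -sv$v[, j]
        sv$u[, j] <- -sv$u[, j]
      }
    }
    scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2,
                    sv$d[seq_len(k)], "*")
    rownames(scores) <- ids[current]
    colnames(scores) <- paste0("PC", seq_len(k))
    eig <- sv$d^2 / (nrow(x) - 1)
    check <- seq_len(min(config$n_pcs, k))
    out_flag <- rep(FALSE, nrow(scores))
    for (j in check) {
      s <- scores[, j]
      # Robust spread (scaled MAD, sd fallback) so that a compact cluster
      # of true outliers cannot inflate its own detection threshold.
      scale_j <- stats::mad(s)
      if (scale_j == 0) scale_j <- stats::sd(s)
      out_flag <- out_flag |
        abs(s - stats::median(s)) > config$pca_outlier_sd * scale_j
    }
    if (all(out_flag)) {
      stop("all subjects flagged as PCA outliers; raise pca_outlier_sd")
    }
    rounds[[r]] <- list(
      round = r,
      scores = scores,
      eigenvalues = eig[seq_len(k)],
      var_explained = eig[seq_len(k)] / sum(eig),
      outliers = rownames(scores)[out_flag]
    )
    removed <- c(removed, rownames(scores)[out_flag])
    current <- current[!out_flag]
  }
  structure(
    list(rounds = rounds,
         final_scores = rounds[[length(rounds)]]$scores,
         removed = removed),
    class = "fa_pca"
  )
}

#' @export
print.fa_pca <- function(x, ...) {
  cat(sprintf("<fa_pca> %d round(s); %d outlier(s) removed\n",
              length(x$rounds), length(x$removed)))
  invisible(x)
}

#' Method-of-moments IBD estimation (PI_HAT)
#'
#' Estimates the IBD-sharing probabilities Z0/Z1/Z2 for subject pairs from
#' identity-by-state counts and sample allele frequencies, using the
#' classical method of moments. Negative raw estimates are clamped to zero
#' and the triple renormalized onto the simplex; `pi_hat = z1/2 + z2` is
#' clamped to [0, 1]. Pairs with `pi_hat` above `config$pi_hat_dup` are
#' flagged as duplicates, with the first member (by subject-id sort order)
#' marked for removal.
#'
#' @param geno an [fa_geno], ideally restricted to LD-pruned common
#'   variants.
#' @param pairs optional data.frame `id1, id2`; defaults to all pairs.
#' @param config an [analysis_config()].
#' @return data.frame `id1, id2, n_snps, ibs0, ibs1, ibs2, z0, z1, z2,
#'   pi_hat, duplicate, remove`.
#' @export
ibd_pi_hat <- function(geno, pairs = NULL, config = analysis_config()) {
  stopifnot(inherits(geno, "fa_geno"))
  if (is.null(pairs)) {
    ids <- geno$subjects$subject_id
    idx <- utils::combn(ids, 2)
    pairs <- data.frame(id1 = idx[1, ], id2 = idx[2, ],
                        stringsAsFactors = FALSE)
  }
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  q <- 1 - p
  # Per-SNP IBS probabilities conditional on IBD state.
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- geno$dosage[match(pairs$id1[i], geno$subjects$subject_id), ]
    b <- geno$dosage[match(pairs$id2[i], geno$subjects$subject_id), ]
    ok <- !is.na(a) & !is.na(b) & p > 0 & p < 1
    ibs <- 2 - abs(a[ok] - b[ok])
    n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
    z0 <- n0 / sum(e0_ibs0[ok])
    z1 <- (n1 - z0 * sum(e0_ibs1[ok])) / sum(e1_ibs1[ok])
    z2 <- (n2 - z0 * sum(e0_ibs2[ok]) - z1 * sum(e1_ibs2[ok])) / sum(ok)
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
    pi_hat <- min(max(z[2] / 2 + z[3], 0), 1)
    data.frame(
      id1 = pairs$id1[i], id2 = pairs$id2[i], n_snps = sum(ok),
      ibs0 = n0, ibs1 = n1, ibs2 = n2,
      z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = pi_hat,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$duplicate <- out$pi_hat > config$pi_hat_dup
  out$remove <- ifelse(out$duplicate, pmin(out$id1, out$id2), NA_character_)
  out
}
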