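# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (enumeration, closed forms, hand formulas)
# and share no code with the implementation paths they check.

# Brute-force exact HWE: enumerate every heterozygote count consistent with
# the allele counts, with probabilities from log-factorials.
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab        # ref allele count
  log_prob <- function(h) {
    hom_a <- (na - h) / 2
    hom_b <- n - h - hom_a
    if (hom_a < 0 || hom_b < 0 || h < 0 || (na - h) %% 2 != 0) return(-Inf)
    lfactorial(n) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }
  hs <- 0:min(na, 2 * n - na)
  lp <- vapply(hs, log_prob, numeric(1))
  p <- exp(lp - max(lp[is.finite(lp)]))
  p <- p / sum(p)
  obs <- p[hs == n_ab]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Textbook Pearson chi-square statistic for a 2 x k count matrix.
pearson_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Hand-rolled BH step-up adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Build an fa_geno from a plain dosage matrix (subjects x variants).
make_geno <- function(dosage, sampleset = NULL, chrom = "6") {
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(sampleset)) sampleset <- rep("set1", n)
  fa_geno(
    dosage,
    data.frame(chrom = chrom, pos = 1000L + seq_len(m) * 100L,
               id = sprintf("v%03d", seq_len(m)), ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("P%04d", seq_len(n)),
               sampleset = sampleset, stringsAsFactors = FALSE)
  )
}

# Long questionnaire from a logical case matrix (subjects x foods);
# non-cases answer "none" everywhere.
make_questionnaire <- function(case, sampleset = NULL) {
  n <- nrow(case)
  foods <- colnames(case)
  ids <- rownames(case)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  if (is.null(sampleset)) sampleset <- rep("set1", n)
  data.frame(
    subject_id = rep(ids, times = length(foods)),
    sampleset = rep(sampleset, times = length(foods)),
    food = rep(foods, each = n),
    response = ifelse(as.vector(case), "mild", "none"),
    stringsAsFactors = FALSE
  )
}

# Small two-food panel for fast cohort simulations.
mini_panel <- function(foods = c("peach", "shrimp")) {
  p <- food_panel()
  p[p$food %in% foods, , drop = FALSE]
}

# Compact cohort configuration for tests.
quick_sim_config <- function(...) {
  defaults <- list(
    n_subjects_per_set = c(400L, 400L),
    n_snps = 20L, n_founder_haplotypes = 200L, ld_block_size = 5L,
    n_duplicate_pairs = 0L, n_admixed = 0L, missing_rate = 0,
    ct_low_frac = 0, seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
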