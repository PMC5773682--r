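test_that("exact HWE test matches full-enumeration oracle to 1e-12", {
  expect_equal(hwe_exact_p(100, 0, 0), 1)
  expect_gte(hwe_exact_p(25, 50, 25), 0.5)
  expect_lt(hwe_exact_p(0, 100, 0), 1e-6)

  set.seed(42)
  for (rep in 1:50) {
    n <- sample(10:200, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(
      hwe_exact_p(counts[1], counts[2], counts[3]),
      hwe_enum_oracle(counts[1], counts[2], counts[3]),
      tolerance = 1e-12
    )
  }
})

test_that("variant QC applies every criterion in both samplesets", {
  set.seed(7)
  n <- 200   # 100 per set
  sets <- rep(c("set1", "set2"), each = 100)
  good <- rbinom(n, 2, 0.3)
  mono <- rep(0L, n)
  all_het <- rep(1L, n)                      # extreme HWE violation
  low_cr <- good
  low_cr[sets == "set1"][1:3] <- NA          # 97% call rate in set1 only
  g <- make_geno(cbind(good, mono, all_het, low_cr), sampleset = sets)
  rep_qc <- variant_qc(g, analysis_config())
  pass <- attr(rep_qc, "pass_overall")
  expect_true(pass[1])
  expect_false(pass[2])    # MAF 0 fails
  expect_false(pass[3])    # HWE exact p < 1e-6
  expect_false(pass[4])    # call rate fails in one set -> overall fail
  hwe_row <- rep_qc[rep_qc$id == "v003" & rep_qc$sampleset == "set1", ]
  expect_lt(hwe_row$hwe_p, 1e-6)
})

test_that("QC pass set is invariant to subject and variant order", {
  co <- simulate_cohort(quick_sim_config(n_subjects_per_set = c(80L, 80L),
                                         missing_rate = 0.02, seed = 19L))
  g <- co$geno
  base <- sort(attr(variant_qc(g), "pass_ids"))
  perm_s <- sample(nrow(g$dosage))
  perm_v <- sample(ncol(g$dosage))
  g2 <- fa_geno(g$dosage[perm_s, perm_v], g$variants[perm_v, ],
                g$subjects[perm_s, ])
  expect_identical(sort(attr(variant_qc(g2), "pass_ids")), base)
})

test_that("duplicate concordance counts only informative pairs", {
  d <- rbind(
    a = c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 2L, 1L),
    b = c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 2L, 1L),
    c = c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 2L, 0L),   # differs at variant 10
    d = c(NA, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 2L, 0L)
  )
  rownames(d) <- NULL
  g <- make_geno(d)
  pairs_same <- data.frame(id1 = "P0001", id2 = "P0002")
  expect_equal(duplicate_concordance(g, pairs_same), rep(1, 10))

  pairs_diff <- data.frame(id1 = "P0003", id2 = "P0004")
  conc <- duplicate_concordance(g, pairs_diff)
  expect_true(is.na(conc[1]))               # missing call excluded
  expect_equal(conc[2:10], rep(1, 9))

  # Single pair disagreeing at one variant scores 0 there.
  pairs_13 <- data.frame(id1 = "P0001", id2 = "P0003")
  expect_equal(duplicate_concordance(g, pairs_13)[10], 0)
})

test_that("simulated duplicate pairs with genotype error match expectation", {
  set.seed(11)
  n_pairs <- 300
  err <- 0.005
  truth <- matrix(rbinom(n_pairs * 50, 2, 0.3), nrow = n_pairs)
  flip <- function(m) {
    e <- matrix(runif(length(m)) < err, nrow = nrow(m))
    m[e] <- (m[e] + sample(1:2, sum(e), replace = TRUE)) %% 3
    m
  }
  d <- rbind(flip(truth), flip(truth))
  g <- make_geno(d)
  pairs <- data.frame(id1 = sprintf("P%04d", 1:n_pairs),
                      id2 = sprintf("P%04d", n_pairs + 1:n_pairs))
  conc <- mean(duplicate_concordance(g, pairs))
  # Both copies agree if neither flipped, or both flipped to the same value.
  expected <- (1 - err)^2 + err^2 * 0.5
  se <- sqrt(expected * (1 - expected) / (n_pairs * 50))
  expect_lt(abs(conc - expected), 4 * se)
})

test_that("LD pruning drops correlated variants and keeps independent ones", {
  set.seed(3)
  base <- rbinom(400, 2, 0.4)
  g <- make_geno(cbind(base, base, rbinom(400, 2, 0.4)))
  kept <- ld_prune(g, 0.2)
  expect_identical(kept, c("v001", "v003"))

  # Threshold 1: only exact duplicates dropped.
  noisy <- base
  noisy[1:30] <- 2 - noisy[1:30]
  g2 <- make_geno(cbind(base, base, noisy))
  expect_identical(ld_prune(g2, 1.0), c("v001", "v003"))

  # Independent SNPs all retained.
  ind <- matrix(rbinom(400 * 20, 2, 0.4), ncol = 20)
  expect_equal(length(ld_prune(make_geno(ind), 0.2)), 20)
})

test_that("PCA flags planted admixed outliers and no one else", {
  cfg <- quick_sim_config(n_subjects_per_set = c(400L, 400L), n_snps = 100L,
                          ld_block_size = 1L, n_admixed = 19L, seed = 23L)
  co <- simulate_cohort(cfg)
  pruned <- geno_subset(co$geno, variants = ld_prune(co$geno, 0.2))
  pca <- pca_rounds(pruned, analysis_config())
  flagged_r1 <- pca$rounds[[1]]$outliers
  expect_gte(length(intersect(flagged_r1, co$truth$admixed)), 15)
  expect_lte(length(setdiff(flagged_r1, co$truth$admixed)), 2)

  # Homogeneous cohort: no outliers at 6 SD.
  cfg0 <- quick_sim_config(n_subjects_per_set = c(300L, 300L), n_snps = 80L,
                           ld_block_size = 1L, seed = 29L)
  co0 <- simulate_cohort(cfg0)
  pca0 <- pca_rounds(co0$geno, analysis_config())
  expect_length(pca0$removed, 0)

  # Constant variants are skipped, not divided by zero.
  d <- cbind(rep(1L, 50), matrix(rbinom(50 * 30, 2, 0.4), nrow = 50))
  expect_no_error(pca_rounds(make_geno(d), analysis_config()))
})

test_that("PCA scores are reproducible with canonical component signs", {
  co <- simulate_cohort(quick_sim_config(n_subjects_per_set = c(100L, 100L),
                                         n_snps = 50L, seed = 31L))
  p1 <- pca_rounds(co$geno, analysis_config())
  p2 <- pca_rounds(co$geno, analysis_config())
  expect_equal(p1$final_scores, p2$final_scores)
})

test_that("PI_HAT separates duplicates, relatives and unrelated pairs", {
  cfg <- quick_sim_config(n_subjects_per_set = c(100L, 100L), n_snps = 1000L,
                          ld_block_size = 1L, block_patterns = 1000L,
                          n_founder_haplotypes = 2000L, seed = 37L)
  f <- simulate_founders(cfg)
  co <- simulate_cohort(cfg, founders = f)
  g <- co$geno

  # Byte-identical duplicate.
  d <- rbind(g$dosage, g$dosage[1, , drop = FALSE])
  subj <- rbind(g$subjects, data.frame(subject_id = "DUP", sampleset = "set1"))
  # Parent-offspring by haplotype transmission.
  hap_child <- f$snp_hap[co$truth$founder_draws$hap1[1], ] +
    f$snp_hap[sample(nrow(f$snp_hap), 1), ]
  d <- rbind(d, hap_child)
  subj <- rbind(subj, data.frame(subject_id = "CHILD", sampleset = "set1"))
  g2 <- fa_geno(d, g$variants, subj)

  res <- ibd_pi_hat(g2, pairs = data.frame(
    id1 = c(g$subjects$subject_id[1], g$subjects$subject_id[1],
            g$subjects$subject_id[2]),
    id2 = c("DUP", "CHILD", g$subjects$subject_id[50])
  ))
  expect_gte(res$pi_hat[1], 0.95)                 # duplicate
  expect_lt(abs(res$pi_hat[2] - 0.5), 0.1)        # parent-offspring
  expect_lte(res$pi_hat[3], 0.1)                  # unrelated
  expect_true(res$duplicate[1])
  expect_equal(res$remove[1], min(g$subjects$subject_id[1], "DUP"))
  # Simplex projection holds.
  expect_equal(res$z0 + res$z1 + res$z2, rep(1, 3), tolerance = 1e-12)
})
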