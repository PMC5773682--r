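test_that("founder pool forces trivial cases and respects determinism", {
  cfg <- quick_sim_config(n_snps = 1L, ld_block_size = 1L,
                          n_founder_haplotypes = 2L, block_patterns = 2L,
                          maf_range = c(0.5, 0.5), seed = 11L)
  # With 1 SNP and 2 founders the pool is tiny but valid.
  f <- simulate_founders(cfg)
  expect_true(all(f$snp_hap %in% c(0L, 1L)))

  cfg2 <- quick_sim_config(seed = 5L)
  expect_identical(simulate_founders(cfg2)$snp_hap,
                   simulate_founders(cfg2)$snp_hap)
})

test_that("tag SNP hits its target r2 and r2 = 1 means identity on founders", {
  eff <- planted_effect("peach", 1.9, hla_locus = "DRB1",
                        hla_allele = "09:01", tag_r2 = 1.0)
  cfg <- quick_sim_config(planted_effects = list(eff), seed = 3L,
                          foods = mini_panel(),
                          baseline_prevalence = c(peach = 0.05, shrimp = 0.05))
  f <- simulate_founders(cfg)
  x <- as.integer(f$hla$DRB1 == "09:01")
  tag_col <- match(f$tag_map$snp[1], f$variants$id)
  expect_identical(f$snp_hap[, tag_col], x)

  # Pool of 200 founders, target 0.8: empirical dosage r2 over 2000 subjects
  # within +-0.1 (checked against the plain dosage-correlation oracle).
  eff8 <- planted_effect("peach", 1.9, hla_locus = "DRB1",
                         hla_allele = "09:01", tag_r2 = 0.8)
  cfg8 <- quick_sim_config(planted_effects = list(eff8), seed = 17L,
                           n_subjects_per_set = c(1000L, 1000L),
                           foods = mini_panel(),
                           baseline_prevalence = c(peach = 0.05, shrimp = 0.05))
  co <- simulate_cohort(cfg8)
  tag <- co$truth$tag_map$snp[1]
  d <- geno_subset(co$geno, variants = tag)$dosage[, 1]
  r2 <- stats::cor(d, co$truth$effects[[1]]$target_dosage)^2
  expect_gt(r2, 0.7)
  expect_lt(r2, 0.9)
})

test_that("unattainable tag r2 fails naming the founder-pool constraint", {
  eff <- planted_effect("peach", 2, hla_locus = "DRB1",
                        hla_allele = "99:99", tag_r2 = 0.8)
  cfg <- quick_sim_config(planted_effects = list(eff),
                          n_founder_haplotypes = 10L, seed = 2L,
                          foods = mini_panel(),
                          baseline_prevalence = c(peach = 0.05, shrimp = 0.05))
  expect_error(simulate_founders(cfg), "founder")
})

test_that("null model gives the configured prevalence and determinism holds", {
  cfg <- quick_sim_config(
    foods = mini_panel(), group_liability_sd = 0,
    baseline_prevalence = c(peach = 0.05, shrimp = 0.05),
    n_subjects_per_set = c(1000L, 1000L), seed = 9L
  )
  co <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$geno$dosage, co2$geno$dosage)
  expect_identical(co$pheno, co2$pheno)
  expect_identical(co$hla, co2$hla)

  frac <- mean(co$truth$case_flags[, "peach"])
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("a planted HLA odds ratio raises the case allele frequency", {
  hits <- vapply(1:40, function(s) {
    cfg <- quick_sim_config(
      foods = mini_panel(),
      baseline_prevalence = c(peach = 0.08, shrimp = 0.05),
      planted_effects = list(planted_effect(
        "peach", 1.9, hla_locus = "DRB1", hla_allele = "04:05"
      )),
      n_subjects_per_set = c(500L, 500L), n_snps = 4L, seed = s
    )
    co <- simulate_cohort(cfg)
    case <- co$truth$case_flags[, "peach"]
    drb1 <- co$hla[co$hla$locus == "DRB1", ]
    cnt <- function(rows) mean(c(rows$allele1, rows$allele2) == "04:05")
    cnt(drb1[case, ]) > cnt(drb1[!case, ])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("within-block LD exceeds between-block LD", {
  cfg <- quick_sim_config(n_snps = 30L, ld_block_size = 5L,
                          n_subjects_per_set = c(500L, 500L), seed = 21L)
  co <- simulate_cohort(cfg)
  blocks <- rep(seq_len(6), each = 5)
  r2 <- suppressWarnings(stats::cor(co$geno$dosage)^2)
  same <- outer(blocks, blocks, "==") & upper.tri(r2)
  diff <- !outer(blocks, blocks, "==") & upper.tri(r2)
  expect_gt(mean(r2[same], na.rm = TRUE), mean(r2[diff], na.rm = TRUE))
  expect_lt(mean(r2[diff], na.rm = TRUE), 0.05)
})

test_that("HLA allele frequencies converge to the configured spectra", {
  pool <- 5000L
  cfg <- quick_sim_config(n_subjects_per_set = c(2500L, 2500L),
                          n_snps = 2L, ld_block_size = 1L, seed = 31L,
                          n_founder_haplotypes = pool)
  co <- simulate_cohort(cfg)
  spectra <- hla_default_freqs()
  for (locus in names(spectra)) {
    calls <- co$hla[co$hla$locus == locus, ]
    obs <- c(calls$allele1, calls$allele2)
    for (allele in names(spectra[[locus]])) {
      f <- spectra[[locus]][[allele]]
      # Two sampling stages: spectrum -> founder pool -> cohort draws.
      se <- sqrt(f * (1 - f) * (1 / pool + 1 / length(obs)))
      expect_lt(abs(mean(obs == allele) - f), max(3.5 * se, 2e-3))
    }
  }
})

test_that("coupled loci form the expected common haplotypes", {
  cfg <- quick_sim_config(n_founder_haplotypes = 3000L, seed = 57L)
  f <- simulate_founders(cfg)
  partner <- hla_coupled_allele("DRB1", "04:05", "DQB1")
  hap_freq <- mean(f$hla$DRB1 == "04:05" & f$hla$DQB1 == partner)
  indep <- hla_default_freqs()$DRB1[["04:05"]] *
    hla_default_freqs()$DQB1[[partner]]
  expect_gt(hap_freq, 3 * indep)   # far above linkage equilibrium
  expect_gt(hap_freq, 0.04)
})

test_that("duplicate pairs are byte-identical before missingness", {
  cfg <- quick_sim_config(n_duplicate_pairs = 10L, missing_rate = 0,
                          seed = 12L)
  co <- simulate_cohort(cfg)
  dup <- co$truth$duplicates
  expect_equal(nrow(dup), 10)
  for (i in seq_len(nrow(dup))) {
    a <- co$geno$dosage[match(dup$original[i], co$geno$subjects$subject_id), ]
    b <- co$geno$dosage[match(dup$duplicate[i], co$geno$subjects$subject_id), ]
    expect_identical(unname(a), unname(b))
  }
})

test_that("a planted food with too few cases fails with guidance", {
  cfg <- quick_sim_config(
    foods = mini_panel(),
    baseline_prevalence = c(peach = 1e-6, shrimp = 0.05),
    planted_effects = list(planted_effect("peach", 1.5, snp = "snp00001")),
    n_subjects_per_set = c(50L, 50L), seed = 4L
  )
  expect_error(simulate_cohort(cfg), "increase n_subjects_per_set")
})

test_that("eQTL table generator honours designated RSS and null structure", {
  snps <- sprintf("v%03d", 1:10)

  # Designated pair with RSS 1 in both tables is recovered exactly.
  des <- data.frame(snp = "v001", gene = "TARGET")
  tabs <- simulate_eqtl_tables(snps, designated = des, seed = 5)
  ld <- data.frame(id = snps, r2 = 1, r2_equiv = 1)
  res <- candidate_genes(ld, tabs$gtex, tabs$hgvd)
  expect_identical(res$candidates, "TARGET")

  # Designated pair with HGVD r2_expl below the prefilter is excluded.
  des2 <- data.frame(snp = "v001", gene = "TARGET", r2_expl = 0.05)
  tabs2 <- simulate_eqtl_tables(snps, designated = des2, seed = 5)
  res2 <- candidate_genes(ld, tabs2$gtex, tabs2$hgvd)
  expect_false("TARGET" %in% res2$candidates)

  # Null-only tables produce an empty candidate set in >= 95% of seeds.
  empty <- vapply(1:50, function(s) {
    t0 <- simulate_eqtl_tables(snps, designated = NULL, seed = s)
    length(candidate_genes(ld, t0$gtex, t0$hgvd)$candidates) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)

  expect_error(simulate_eqtl_tables(character(0)), "non-empty")
})
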