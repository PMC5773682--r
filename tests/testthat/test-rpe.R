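test_that("allele counting contributes two copies per complete subject", {
  hla <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    locus = "DRB1",
    allele1 = c("09:01", "09:01", "09:01", "04:05"),
    allele2 = c("09:01", "09:01", "04:05", "04:05"),
    ct = 1
  )
  case <- matrix(c(TRUE, TRUE, FALSE, FALSE), ncol = 1,
                 dimnames = list(c("a", "b", "c", "d"), "peach"))
  ph <- build_phenotypes(make_questionnaire(case), analysis_config())
  tab <- count_alleles(hla, ph, "DRB1", "peach")
  expect_equal(tab$case[tab$category == "09:01"], 4)   # two homozygous cases
  expect_equal(tab$control[tab$category == "09:01"], 1)
  expect_equal(tab$control[tab$category == "04:05"], 3)
  expect_equal(sum(tab$case), 4)
  expect_equal(sum(tab$control), 4)
})

test_that("simulated allele frequencies match the configured spectra", {
  pool <- 4000L
  cfg <- quick_sim_config(n_subjects_per_set = c(1000L, 1000L), n_snps = 2L,
                          ld_block_size = 1L, seed = 53L,
                          n_founder_haplotypes = pool,
                          foods = mini_panel(),
                          baseline_prevalence = c(peach = 0.1, shrimp = 0.05))
  co <- simulate_cohort(cfg)
  ph <- build_phenotypes(co$pheno, analysis_config(min_cases_per_set = 5L))
  tab <- count_alleles(filter_hla_ct(co$hla), ph, "DQB1", "peach")
  spectra <- hla_default_freqs()$DQB1
  n <- sum(tab$control)
  for (i in seq_len(nrow(tab))) {
    f <- spectra[[tab$category[i]]]
    # Sampling variance has two stages: spectrum -> founder pool -> cohort.
    se <- sqrt(f * (1 - f) * (1 / pool + 1 / n))
    expect_lt(abs(tab$control[i] / n - f), max(3.5 * se, 5e-3))
  }
})

test_that("rare-category binning uses strict expected-count thresholds", {
  tab <- allele_count_table("DRB1", c("a", "b", "c"),
                            case = c(499, 1, 500), control = c(499, 1, 500))
  binned <- bin_rare(tab, 5)
  expect_true("binned" %in% binned$category)
  expect_false("b" %in% binned$category)

  common <- allele_count_table("DRB1", c("a", "b"), c(300, 300), c(300, 300))
  expect_identical(bin_rare(common, 5)$category, c("a", "b"))

  # Expected count exactly 5 in the worse arm is NOT binned (strict <).
  # Category b: total 20 copies, case margin 250/1000 -> expected 5.0.
  exact5 <- allele_count_table("DRB1", c("a", "b"),
                               case = c(245, 5), control = c(735, 15))
  e_case <- 250 * 20 / 1000
  expect_equal(e_case, 5)
  expect_identical(bin_rare(exact5, 5)$category, c("a", "b"))
})

test_that("locus chi-square equals the textbook Pearson oracle", {
  tab22 <- allele_count_table("X", c("a", "b"), c(10, 90), c(20, 80))
  lt <- locus_test(tab22)
  expect_equal(lt$statistic, 3.9216, tolerance = 1e-4)
  expect_equal(lt$df, 1)

  same <- allele_count_table("X", c("a", "b"), c(50, 50), c(100, 100))
  expect_equal(locus_test(same)$statistic, 0)
  expect_equal(locus_test(same)$p, 1)

  set.seed(61)
  for (rep in 1:40) {
    k <- sample(2:10, 1)
    m <- matrix(rpois(2 * k, 40) + 1, nrow = 2)
    tab <- allele_count_table("X", paste0("c", seq_len(k)), m[1, ], m[2, ])
    expect_equal(locus_test(tab)$statistic, pearson_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("single-allele test gives Pearson p, OR and the frequency form", {
  tab <- allele_count_table("DRB1", c("a", "b", "c"),
                            case = c(45, 30, 25), control = c(30, 40, 30))
  at <- allele_test(tab, "a")
  m <- matrix(c(45, 55, 30, 70), nrow = 2)
  expect_equal(at$p, stats::pchisq(pearson_oracle(m), 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(at$or, (45 * 70) / (55 * 30), tolerance = 1e-12)
  expect_equal(at$or, allele_or_from_freq(at$case_freq, at$control_freq),
               tolerance = 1e-12)

  eq <- allele_count_table("DRB1", c("a", "b"), c(50, 50), c(50, 50))
  ateq <- allele_test(eq, "a")
  expect_equal(ateq$or, 1)
  expect_equal(ateq$p, 1)

  # Haldane correction only when a zero cell appears.
  z <- allele_count_table("DRB1", c("a", "b"), c(0, 100), c(10, 90))
  expect_equal(allele_test(z, "a")$or,
               (0.5 * 90.5) / (100.5 * 10.5), tolerance = 1e-12)
})

test_that("RPE removal renormalizes frequencies exactly and stops correctly", {
  # Strong top allele, weaker secondary allele.
  tab <- allele_count_table(
    "DRB1", c("top", "mid", "rest"),
    case = c(450, 250, 1300), control = c(600, 620, 2780)
  )
  trace <- rpe_run(tab, analysis_config())
  s0 <- trace$steps[[1]]$table
  expect_equal(sum(s0$case_freq), 1, tolerance = 1e-12)
  expect_equal(sum(s0$control_freq), 1, tolerance = 1e-12)
  removed <- trace$steps[[2]]$excluded[1]
  expect_identical(removed, s0$category[which.min(s0$p)])
  s1 <- trace$steps[[2]]$table
  f_rm_case <- s0$case_freq[s0$category == removed]
  f_rm_ctrl <- s0$control_freq[s0$category == removed]
  for (cat in s1$category) {
    expect_equal(s1$case_freq[s1$category == cat],
                 renorm_freq(s0$case_freq[s0$category == cat], f_rm_case),
                 tolerance = 1e-12)
    expect_equal(s1$control_freq[s1$category == cat],
                 renorm_freq(s0$control_freq[s0$category == cat], f_rm_ctrl),
                 tolerance = 1e-12)
  }
  # All but the final step are locus-significant.
  n_steps <- length(trace$steps)
  for (s in trace$steps[-n_steps]) expect_lt(s$locus_p, 0.05)

  # A table that is null from the start records exactly one step.
  null_tab <- allele_count_table("DRB1", c("a", "b", "c"),
                                 case = c(100, 100, 100),
                                 control = c(200, 200, 200))
  tr0 <- rpe_run(null_tab, analysis_config())
  expect_length(tr0$steps, 1)
  expect_length(tr0$steps[[1]]$excluded, 0)
  expect_identical(tr0$termination, "locus_nonsignificant")

  expect_error(rpe_run(allele_count_table("X", "a", 10, 10)), "at least two")
})

test_that("RPE runs for exactly the constructed number of significant steps", {
  # Two strongly associated alleles then a null remainder: two removals.
  tab <- allele_count_table(
    "DRB1", c("a1", "a2", "null1", "null2"),
    case = c(400, 300, 500, 500), control = c(700, 640, 1665, 1665)
  )
  trace <- rpe_run(tab, analysis_config())
  expect_identical(trace$termination, "locus_nonsignificant")
  expect_length(trace$steps, 3)                       # steps 0, 1, 2
  expect_identical(trace$steps[[3]]$excluded, c("a1", "a2"))
})

test_that("the binned category is never removed by default", {
  tab <- allele_count_table(
    "DRB1", c("a", "binned", "c"),
    case = c(300, 200, 500), control = c(500, 150, 1500)
  )
  trace <- rpe_run(tab, analysis_config())
  for (s in trace$steps) expect_false("binned" %in% s$excluded)
})

test_that("EM haplotype estimation matches grid search and direct counts", {
  # All-homozygous subjects: phase is deterministic, frequencies = counts.
  hla <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    locus = rep(c("DRB1", "DQB1"), 3),
    allele1 = c("01:01", "02:01", "01:01", "02:01", "03:01", "04:01"),
    allele2 = c("01:01", "02:01", "01:01", "02:01", "03:01", "04:01"),
    ct = 1
  )
  em <- em_haplotypes(hla, c("DRB1", "DQB1"))
  expect_equal(unname(em$frequencies["01:01~02:01"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(em$frequencies["03:01~04:01"]), 1 / 3, tolerance = 1e-9)

  # Toy: AB/AB, AB/ab (double heterozygote), ab/ab. The MLE puts all mass
  # on AB and ab; a brute-force grid search over the 3-simplex agrees.
  toy <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    locus = rep(c("L1", "L2"), 3),
    allele1 = c("01:01", "11:01", "01:01", "11:01", "02:01", "12:01"),
    allele2 = c("01:01", "11:01", "02:01", "12:01", "02:01", "12:01"),
    ct = 1
  )
  em2 <- em_haplotypes(toy, c("L1", "L2"))
  haps <- c("01:01~11:01", "01:01~12:01", "02:01~11:01", "02:01~12:01")
  geno_lik <- function(f) {
    names(f) <- haps
    lik1 <- f["01:01~11:01"]^2
    lik3 <- f["02:01~12:01"]^2
    lik2 <- 2 * f["01:01~11:01"] * f["02:01~12:01"] +
      2 * f["01:01~12:01"] * f["02:01~11:01"]
    lik1 * lik2 * lik3
  }
  grid <- expand.grid(f1 = seq(0, 1, 0.02), f2 = seq(0, 1, 0.02),
                      f3 = seq(0, 1, 0.02))
  grid <- grid[grid$f1 + grid$f2 + grid$f3 <= 1, ]
  liks <- apply(grid, 1, function(r) geno_lik(c(r[1], r[2], r[3],
                                                1 - sum(r))))
  best <- grid[which.max(liks), ]
  expect_equal(unname(em2$frequencies[haps[1]]), best$f1, tolerance = 0.02)
  # Against the analytic MLE (0.5, 0, 0, 0.5) to tight tolerance.
  expect_equal(unname(em2$frequencies[haps[1]]), 0.5, tolerance = 1e-4)
  expect_equal(unname(em2$frequencies[haps[4]]), 0.5, tolerance = 1e-4)
  expect_lt(em2$frequencies[haps[2]] + em2$frequencies[haps[3]], 1e-4)
})

test_that("EM recovers simulated two-locus haplotype frequencies", {
  set.seed(71)
  haps <- c("01:01~10:01", "02:01~11:01", "03:01~12:01", "01:01~11:01")
  freq <- c(0.4, 0.3, 0.2, 0.1)
  n <- 2000
  draw <- function() sample(haps, 2 * n, replace = TRUE, prob = freq)
  h1 <- draw()[1:n]; h2 <- draw()[1:n]
  split_h <- function(h, i) vapply(strsplit(h, "~"), `[`, character(1), i)
  hla <- rbind(
    data.frame(subject_id = sprintf("s%04d", 1:n), locus = "L1",
               allele1 = split_h(h1, 1), allele2 = split_h(h2, 1), ct = 1),
    data.frame(subject_id = sprintf("s%04d", 1:n), locus = "L2",
               allele1 = split_h(h1, 2), allele2 = split_h(h2, 2), ct = 1)
  )
  em <- em_haplotypes(hla, c("L1", "L2"))
  for (i in seq_along(haps)) {
    se <- sqrt(freq[i] * (1 - freq[i]) / (2 * n))
    expect_lt(abs(em$frequencies[haps[i]] - freq[i]), 4 * se)
  }
})

test_that("haplotype RPE bins rare haplotypes and recovers a planted one", {
  risk_hap <- c(DRB1 = "04:05",
                DQB1 = hla_coupled_allele("DRB1", "04:05", "DQB1"))
  cfg <- quick_sim_config(
    foods = mini_panel(),
    baseline_prevalence = c(peach = 0.02, shrimp = 0.2),
    planted_effects = list(planted_effect("shrimp", 2.0,
                                          haplotype = risk_hap)),
    n_subjects_per_set = c(2500L, 2500L), n_snps = 4L, seed = 73L
  )
  co <- simulate_cohort(cfg)
  ph <- build_phenotypes(co$pheno, analysis_config(min_cases_per_set = 10L))
  res <- haplotype_rpe(filter_hla_ct(co$hla), c("DRB1", "DQB1"), ph,
                       "shrimp", analysis_config())
  # Binning: every non-binned category has frequency >= 1% in both arms.
  tab <- res$table
  keep <- tab$category != "binned"
  expect_true(all(tab$case[keep] / sum(tab$case) >= 0.01 |
                    tab$control[keep] / sum(tab$control) >= 0.01))
  # The planted haplotype is the first removal.
  expect_identical(res$trace$steps[[2]]$excluded[1],
                   paste(risk_hap, collapse = "~"))

  # Degenerate world: a single haplotype cannot be analysed.
  mono <- data.frame(
    subject_id = rep(sprintf("m%02d", 1:20), each = 2),
    locus = rep(c("DRB1", "DQB1"), 20),
    allele1 = rep(c("01:01", "05:01"), 20),
    allele2 = rep(c("01:01", "05:01"), 20), ct = 1
  )
  case <- matrix(rep(c(TRUE, FALSE), 10), ncol = 1,
                 dimnames = list(sprintf("m%02d", 1:20), "peach"))
  ph2 <- build_phenotypes(make_questionnaire(case), analysis_config())
  expect_error(haplotype_rpe(mono, c("DRB1", "DQB1"), ph2, "peach"),
               "fewer than two")
})
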