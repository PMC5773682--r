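#' Synthetic cohort configuration
#'
#' Configuration for the truth-annotated synthetic cohort generator. The
#' generator emulates the study design the downstream pipeline expects: two
#' samplesets genotyped on biallelic SNPs arranged in LD blocks, multi-allelic
#' HLA loci drawn from realistic control spectra, per-food case/control status
#' from an additive logistic liability model with group-correlated liabilities
#' (so that, e.g., shellfish foods cross-react), a mild/severe response split,
#' duplicate sample pairs, a small admixed-outlier fraction, and uniform
#' genotype missingness.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults (all overridable):
#' * `n_subjects_per_set = c(5751, 5628)`: the two samplesets' sizes.
#' * `n_snps = 200`, `ld_block_size = 10`, `block_patterns = 4`,
#'   `n_founder_haplotypes = 200`, `maf_range = c(0.05, 0.5)`: SNP haplotypes
#'   are sampled from a founder pool; within a block founders carry one of a
#'   few block-wide allele patterns, which creates within-block LD while
#'   between-block LD is ~0.
#' * `hla_allele_freqs = hla_default_freqs()`: per-locus allele spectra.
#' * `planted_effects = list()`: see [planted_effect()].
#' * `baseline_prevalence`: named per-food case probabilities; seven foods
#'   (kiwi, peach, chinese_yam, egg, mackerel, crab, shrimp) default to
#'   2.5--5.1% so they clear the >100-cases-per-set eligibility rule at the
#'   default sampleset sizes, the remaining twenty foods to 0.8%.
#' * `group_liability_sd = 1`: SD of the per-subject, per-food-group Gaussian
#'   liability added to the logit, which induces within-group
#'   cross-reactivity.
#' * `severe_fraction = 0.15`: probability a case reports the severe rather
#'   than the mild response.
#' * `n_duplicate_pairs = 329`, `n_admixed = 19`, `admix_shift = 0.6`,
#'   `missing_rate = 0.002`, `ct_low_frac = 0.05`: data-quality artefacts the
#'   QC stages must detect. Admixed subjects have their SNP allele
#'   frequencies shifted by `admix_shift` toward an alternative ancestry
#'   profile; `ct_low_frac` of HLA calls get a call-threshold score drawn
#'   Uniform(0.3, 1) instead of 1.0, exercising the CT > 0.5 filter.
#' * `seed = 1`: single integer seed from which all generator randomness
#'   flows.
#'
#' @return An object of class `fa_simconfig`.
#' @seealso [simulate_cohort()], [planted_effect()]
#' @export
sim_config <- function(...) {
  panel <- food_panel()
  prev <- stats::setNames(rep(0.008, nrow(panel)), panel$food)
  prev[c("kiwi", "peach", "egg", "shrimp")] <- 0.030
  prev[c("mackerel", "crab")] <- 0.025
  prev["chinese_yam"] <- 0.051
  cfg <- list(
    n_subjects_per_set = c(5751L, 5628L),
    n_snps = 200L,
    n_founder_haplotypes = 200L,
    ld_block_size = 10L,
    block_patterns = 4L,
    maf_range = c(0.05, 0.5),
    hla_allele_freqs = hla_default_freqs(),
    hla_coupling = c(DQB1 = 0.85, DPB1 = 0.5),
    planted_effects = list(),
    baseline_prevalence = prev,
    group_liability_sd = 1,
    severe_fraction = 0.15,
    n_duplicate_pairs = 329L,
    n_admixed = 19L,
    admix_shift = 0.6,
    missing_rate = 0.002,
    ct_low_frac = 0.05,
    foods = panel,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all sim_config overrides must be named")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  if (length(cfg$n_subjects_per_set) == 1) {
    cfg$n_subjects_per_set <- rep(cfg$n_subjects_per_set, 2)
  }
  if (length(cfg$baseline_prevalence) == 1) {
    cfg$baseline_prevalence <- stats::setNames(
      rep(cfg$baseline_prevalence, nrow(cfg$foods)), cfg$foods$food
    )
  }
  .validate_sim_config(cfg)
  structure(cfg, class = "fa_simconfig")
}

.validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$n_subjects_per_set) == 2, all(cfg$n_subjects_per_set >= 1),
    cfg$n_snps >= 1, cfg$n_founder_haplotypes >= 2, cfg$ld_block_size >= 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$severe_fraction >= 0, cfg$severe_fraction <= 1,
    cfg$group_liability_sd >= 0,
    all(c("food", "group") %in% names(cfg$foods))
  )
  for (locus in names(cfg$hla_allele_freqs)) {
    f <- cfg$hla_allele_freqs[[locus]]
    if (any(f <= 0) || any(f >= 1)) {
      stop("HLA allele frequencies at ", locus, " must lie in (0, 1)")
    }
    if (abs(sum(f) - 1) > 1e-8) {
      stop("HLA allele frequencies at ", locus, " must sum to 1")
    }
  }
  if (any(cfg$hla_coupling < 0) || any(cfg$hla_coupling > 1)) {
    stop("hla_coupling values must lie in [0, 1]")
  }
  if (!setequal(names(cfg$baseline_prevalence), cfg$foods$food)) {
    stop("baseline_prevalence must be named by the foods of the panel")
  }
  for (e in cfg$planted_effects) {
    if (!inherits(e, "fa_planted_effect")) {
      stop("planted_effects must be built with planted_effect()")
    }
    if (!e$food %in% cfg$foods$food) {
      stop("planted effect targets unknown food: ", e$food)
    }
  }
  invisible(cfg)
}

#' Declare a planted risk effect
#'
#' Describes one causal effect the generator plants: a food, an odds ratio
#' per copy of the risk target, and the target itself — a SNP, an HLA allele,
#' or a multi-locus HLA haplotype. For HLA-allele and haplotype targets an
#' optional tag SNP can be requested: a SNP whose founder alleles are coupled
#' to the risk target at a chosen dosage r-squared, so the SNP-level GWAS can
#' see the HLA signal the way array data sees an untyped causal allele.
#'
#' @param food food name from the panel.
#' @param odds_ratio per-copy odds ratio (> 0).
#' @param snp variant id, for a SNP target.
#' @param hla_locus,hla_allele locus (e.g. `"DRB1"`) and two-field allele
#'   code (e.g. `"09:01"`), for an HLA-allele target.
#' @param haplotype named character vector, e.g.
#'   `c(DRB1 = "04:05", DQB1 = "04:01")`, for a haplotype target.
#' @param tag_r2 optional target dosage r-squared between a dedicated tag SNP
#'   and the HLA target (HLA/haplotype targets only).
#' @return An object of class `fa_planted_effect`.
#' @examples
#' planted_effect("peach", 1.9, hla_locus = "DRB1", hla_allele = "09:01",
#'                tag_r2 = 0.8)
#' @export
planted_effect <- function(food, odds_ratio, snp = NULL, hla_locus = NULL,
                           hla_allele = NULL, haplotype = NULL, tag_r2 = NULL) {
  stopifnot(is.numeric(odds_ratio), length(odds_ratio) == 1, odds_ratio > 0)
  kinds <- c(!is.null(snp), !is.null(hla_locus) || !is.null(hla_allele),
             !is.null(haplotype))
  if (sum(kinds) != 1) {
    stop("specify exactly one target: snp, hla_locus/hla_allele, or haplotype")
  }
  type <- c("snp", "hla", "haplotype")[kinds]
  if (type == "hla" && (is.null(hla_locus) || is.null(hla_allele))) {
    stop("an HLA target needs both hla_locus and hla_allele")
  }
  if (type == "haplotype" && is.null(names(haplotype))) {
    stop("haplotype must be a named vector: locus -> allele")
  }
  if (!is.null(tag_r2)) {
    stopifnot(tag_r2 > 0, tag_r2 <= 1)
    if (type == "snp") stop("tag_r2 applies only to HLA or haplotype targets")
  }
  structure(
    list(food = food, odds_ratio = odds_ratio, type = type, snp = snp,
         hla_locus = hla_locus, hla_allele = hla_allele,
         haplotype = haplotype, tag_r2 = tag_r2),
    class = "fa_planted_effect"
  )
}

#' Simulate the founder haplotype pool
#'
#' Builds `n_founder_haplotypes` founder haplotypes, each carrying one allele
#' per SNP and one allele per HLA locus. SNPs are organised in LD blocks:
#' within a block every founder carries one of a small number of block-wide
#' allele patterns, so SNPs in the same block are correlated across founders
#' while SNPs in different blocks are independent. For every planted HLA or
#' haplotype effect that requests a tag SNP, the first SNP of a dedicated
#' block is overwritten so its founder allele matches the risk-target
#' indicator with probability `sqrt(tag_r2)` (and is otherwise redrawn at the
#' target's founder frequency), which yields a founder-level — and hence
#' subject-dosage-level — correlation of about `sqrt(tag_r2)`.
#'
#' @param config an [sim_config()] object.
#' @return An object of class `fa_founders`: founder SNP haplotypes
#'   (`snp_hap`, founders x SNPs, 0/1), founder HLA alleles (`hla`), the
#'   variant table (`variants`), and the tag-SNP map (`tag_map`).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "fa_simconfig"))
  with_seed(sub_seed(config$seed, 1L), {
    n_f <- config$n_founder_haplotypes
    n_snps <- config$n_snps
    bs <- config$ld_block_size
    block <- ceiling(seq_len(n_snps) / bs)
    n_blocks <- max(block)

    snp_hap <- matrix(0L, nrow = n_f, ncol = n_snps)
    for (b in seq_len(n_blocks)) {
      cols <- which(block == b)
      npat <- min(config$block_patterns, n_f)
      maf <- stats::runif(length(cols), config$maf_range[1], config$maf_range[2])
      patterns <- matrix(
        stats::rbinom(npat * length(cols), 1L, rep(maf, each = npat)),
        nrow = npat
      )
      w <- stats::rexp(npat)
      assign_pat <- sample.int(npat, n_f, replace = TRUE, prob = w / sum(w))
      snp_hap[, cols] <- patterns[assign_pat, , drop = FALSE]
    }

    # HLA alleles: the first locus anchors a latent uniform variable per
    # founder; coupled loci reuse that variable with probability
    # hla_coupling[locus] (a comonotone-copula mixture). Marginal spectra
    # are preserved exactly while common multi-locus haplotypes emerge, as
    # in real MHC haplotype structure.
    loci <- names(config$hla_allele_freqs)
    u_anchor <- stats::runif(n_f)
    hla <- as.data.frame(
      lapply(seq_along(loci), function(li) {
        f <- config$hla_allele_freqs[[li]]
        cpl <- if (li == 1) 1 else
          unname(config$hla_coupling[loci[li]] %|NA|% 0)
        u <- ifelse(stats::runif(n_f) < cpl, u_anchor, stats::runif(n_f))
        hla_quantile_allele(f, u)
      }),
      stringsAsFactors = FALSE
    )
    names(hla) <- loci

    variants <- data.frame(
      chrom = "6",
      pos = 1000000L + seq_len(n_snps) * 1000L,
      id = sprintf("snp%05d", seq_len(n_snps)),
      ref = "A", alt = "G",
      block = block,
      stringsAsFactors = FALSE
    )

    tag_map <- data.frame(
      effect = integer(0), snp = character(0), target_r2 = numeric(0),
      stringsAsFactors = FALSE
    )
    tagged <- which(vapply(
      config$planted_effects,
      function(e) e$type != "snp" && !is.null(e$tag_r2), logical(1)
    ))
    if (length(tagged) > n_blocks) {
      stop("not enough LD blocks to host ", length(tagged), " tag SNPs; ",
           "increase n_snps or ld_block_size")
    }
    for (k in seq_along(tagged)) {
      e <- config$planted_effects[[tagged[k]]]
      x <- founder_target_indicator(hla, e)
      n1 <- sum(x)
      n0 <- n_f - n1
      if (n1 == 0 || n0 == 0) {
        stop("tag r2 of ", e$tag_r2, " is unattainable: the planted target is ",
             if (n1 == 0) "absent from" else "fixed in",
             " the founder pool; increase n_founder_haplotypes")
      }
      # Deterministic given the carrier pattern: the tag allele matches every
      # carrier, plus b non-carriers chosen to bring the founder-level
      # correlation as close as the pool's granularity allows to
      # sqrt(tag_r2). phi(b) = sqrt(n1 (n0 - b) / ((n1 + b) n0)).
      b_grid <- 0:n0
      phi <- sqrt(n1 * (n0 - b_grid) / ((n1 + b_grid) * n0))
      b <- b_grid[which.min(abs(phi - sqrt(e$tag_r2)))]
      achieved <- phi[b + 1]^2
      if (abs(achieved - e$tag_r2) > 0.05) {
        stop("tag r2 of ", e$tag_r2, " is unattainable with a pool of ", n_f,
             " founders (closest achievable: ", signif(achieved, 3),
             "); increase n_founder_haplotypes")
      }
      tag <- x
      tag[sample(which(x == 0L), b)] <- 1L
      col <- which(block == k)[1]
      snp_hap[, col] <- as.integer(tag)
      tag_map <- rbind(tag_map, data.frame(
        effect = tagged[k], snp = variants$id[col], target_r2 = e$tag_r2,
        stringsAsFactors = FALSE
      ))
    }

    structure(
      list(snp_hap = snp_hap, hla = hla, variants = variants,
           tag_map = tag_map),
      class = "fa_founders"
    )
  })
}

# Quantile map of a latent uniform onto an allele spectrum, with alleles
# ordered by decreasing frequency (name-sorted ties) so coupled loci align
# their common alleles.
hla_quantile_allele <- function(f, u) {
  o <- order(-f, names(f))
  cum <- cumsum(f[o])
  names(f)[o][findInterval(u, cum, left.open = TRUE) + 1L]
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Most strongly coupled partner allele at another HLA locus
#'
#' Under the generator's comonotone coupling, each allele occupies an
#' interval of the latent uniform scale (alleles sorted by decreasing
#' frequency per locus). The partner allele of `allele` at `locus` is the
#' one whose interval overlaps it most — the allele with which it
#' preferentially forms haplotypes. Useful for constructing a plantable
#' high-frequency risk haplotype.
#'
#' @param anchor_locus,allele the anchor locus and allele code.
#' @param locus target locus.
#' @param freqs per-locus spectra (default [hla_default_freqs()]).
#' @return The partner allele code at `locus`.
#' @examples
#' hla_coupled_allele("DRB1", "04:05", "DQB1")
#' @export
hla_coupled_allele <- function(anchor_locus, allele, locus,
                               freqs = hla_default_freqs()) {
  iv <- function(f) {
    o <- order(-f, names(f))
    cum <- cumsum(f[o])
    data.frame(allele = names(f)[o], lo = c(0, utils::head(cum, -1)),
               hi = cum, stringsAsFactors = FALSE)
  }
  a <- iv(freqs[[anchor_locus]])
  a <- a[a$allele == allele, ]
  if (!nrow(a)) stop("unknown allele ", allele, " at ", anchor_locus)
  b <- iv(freqs[[locus]])
  overlap <- pmax(0, pmin(a$hi, b$hi) - pmax(a$lo, b$lo))
  b$allele[which.max(overlap)]
}

# 0/1 indicator, per founder haplotype, of carrying the risk target of a
# planted HLA-allele or haplotype effect.
founder_target_indicator <- function(founder_hla, effect) {
  if (effect$type == "hla") {
    as.integer(founder_hla[[effect$hla_locus]] == effect$hla_allele)
  } else if (effect$type == "haplotype") {
    hit <- rep(TRUE, nrow(founder_hla))
    for (locus in names(effect$haplotype)) {
      hit <- hit & founder_hla[[locus]] == effect$haplotype[[locus]]
    }
    as.integer(hit)
  } else {
    stop("SNP effects have no founder HLA indicator")
  }
}

#' Simulate a complete two-sampleset cohort
#'
#' Draws each subject as two founder haplotypes (SNP dosage = haplotype sum,
#' HLA genotype = the two founder alleles), assigns per-food case status from
#' the logistic model `logit p = qlogis(prevalence) + group liability +
#' sum(log OR x target dosage)`, splits cases into mild/severe reporters,
#' appends byte-identical duplicate pairs under new ids, shifts the SNP
#' allele frequencies of a small admixed fraction, and finally injects
#' uniform missingness into the SNP dosages.
#'
#' @param config an [sim_config()] object.
#' @param founders optionally a pre-built [simulate_founders()] pool (must
#'   come from the same config).
#' @return An object of class `fa_cohort` with elements
#'   \describe{
#'     \item{geno}{[fa_geno] dosage matrix (duplicates included).}
#'     \item{hla}{data.frame `subject_id, locus, allele1, allele2, ct`.}
#'     \item{pheno}{long data.frame `subject_id, sampleset, food, response`
#'       with `response` in `none/mild/severe`.}
#'     \item{truth}{generator truth: per-subject founder assignments,
#'       per-group liabilities, planted targets with true log odds and the
#'       per-subject target dosages, duplicate map, admixed ids.}
#'   }
#' @export
simulate_cohort <- function(config, founders = NULL) {
  stopifnot(inherits(config, "fa_simconfig"))
  founders <- founders %||% simulate_founders(config)
  with_seed(sub_seed(config$seed, 2L), {
    n1 <- config$n_subjects_per_set[1]
    n2 <- config$n_subjects_per_set[2]
    n <- n1 + n2
    n_f <- nrow(founders$snp_hap)
    loci <- names(founders$hla)
    foods <- config$foods

    subject_id <- sprintf("S%06d", seq_len(n))
    sampleset <- rep(c("set1", "set2"), c(n1, n2))
    f1 <- sample.int(n_f, n, replace = TRUE)
    f2 <- sample.int(n_f, n, replace = TRUE)

    dosage <- founders$snp_hap[f1, , drop = FALSE] +
      founders$snp_hap[f2, , drop = FALSE]

    hla_a1 <- lapply(loci, function(l) founders$hla[[l]][f1])
    hla_a2 <- lapply(loci, function(l) founders$hla[[l]][f2])
    names(hla_a1) <- names(hla_a2) <- loci

    # Admixed subjects: redraw SNP genotypes from frequencies shifted toward
    # an alternative ancestry profile. HLA calls are left untouched; PCA is
    # expected to flag these subjects on SNP data alone.
    admixed_ids <- character(0)
    if (config$n_admixed > 0) {
      adm <- sample.int(n, min(config$n_admixed, n))
      admixed_ids <- subject_id[adm]
      p_pop <- colMeans(founders$snp_hap)
      q_alt <- stats::runif(ncol(dosage), 0.05, 0.95)
      p_adm <- (1 - config$admix_shift) * p_pop + config$admix_shift * q_alt
      dosage[adm, ] <- matrix(
        stats::rbinom(length(adm) * ncol(dosage), 2L, rep(p_adm, each = length(adm))),
        nrow = length(adm)
      )
    }

    # Per-effect dosage of the planted risk target.
    effect_dose <- lapply(config$planted_effects, function(e) {
      if (e$type == "snp") {
        j <- match(e$snp, founders$variants$id)
        if (is.na(j)) stop("planted SNP not in variant table: ", e$snp)
        dosage[, j]
      } else {
        x <- founder_target_indicator(founders$hla, e)
        x[f1] + x[f2]
      }
    })

    groups <- unique(foods$group)
    liab <- matrix(
      stats::rnorm(n * length(groups), 0, config$group_liability_sd),
      nrow = n, dimnames = list(NULL, groups)
    )

    response <- matrix("none", nrow = n, ncol = nrow(foods),
                       dimnames = list(NULL, foods$food))
    case_flags <- matrix(FALSE, nrow = n, ncol = nrow(foods),
                         dimnames = list(NULL, foods$food))
    for (i in seq_len(nrow(foods))) {
      food <- foods$food[i]
      eta <- stats::qlogis(config$baseline_prevalence[[food]]) +
        liab[, foods$group[i]]
      for (k in seq_along(config$planted_effects)) {
        e <- config$planted_effects[[k]]
        if (e$food == food) eta <- eta + log(e$odds_ratio) * effect_dose[[k]]
      }
      case <- stats::rbinom(n, 1L, stats::plogis(eta)) == 1L
      case_flags[, i] <- case
      severe <- case & stats::runif(n) < config$severe_fraction
      response[case, i] <- "mild"
      response[severe, i] <- "severe"
    }

    for (e in config$planted_effects) {
      n_cases <- sum(case_flags[, e$food])
      if (n_cases < 2) {
        stop("planted food '", e$food, "' produced only ", n_cases,
             " case(s); increase n_subjects_per_set or baseline_prevalence")
      }
    }

    # Duplicate pairs: byte-identical genotype copies under distinct ids.
    dup_map <- data.frame(original = character(0), duplicate = character(0),
                          stringsAsFactors = FALSE)
    if (config$n_duplicate_pairs > 0) {
      dsrc <- sort(sample.int(n, min(config$n_duplicate_pairs, n)))
      dup_id <- paste0(subject_id[dsrc], "d")
      dup_map <- data.frame(original = subject_id[dsrc], duplicate = dup_id,
                            stringsAsFactors = FALSE)
      subject_id <- c(subject_id, dup_id)
      sampleset <- c(sampleset, sampleset[dsrc])
      dosage <- rbind(dosage, dosage[dsrc, , drop = FALSE])
      for (l in loci) {
        hla_a1[[l]] <- c(hla_a1[[l]], hla_a1[[l]][dsrc])
        hla_a2[[l]] <- c(hla_a2[[l]], hla_a2[[l]][dsrc])
      }
      response <- rbind(response, response[dsrc, , drop = FALSE])
      n <- length(subject_id)
    }

    if (config$missing_rate > 0) {
      miss <- stats::runif(length(dosage)) < config$missing_rate
      dosage[miss] <- NA_integer_
    }

    geno <- fa_geno(
      dosage,
      founders$variants[, c("chrom", "pos", "id", "ref", "alt")],
      data.frame(subject_id = subject_id, sampleset = sampleset,
                 stringsAsFactors = FALSE)
    )

    ct <- matrix(1, nrow = n, ncol = length(loci))
    low <- matrix(stats::runif(n * length(loci)) < config$ct_low_frac,
                  nrow = n)
    ct[low] <- stats::runif(sum(low), 0.3, 1)
    hla <- do.call(rbind, lapply(seq_along(loci), function(li) {
      data.frame(
        subject_id = subject_id, locus = loci[li],
        allele1 = hla_a1[[loci[li]]], allele2 = hla_a2[[loci[li]]],
        ct = ct[, li], stringsAsFactors = FALSE
      )
    }))
    rownames(hla) <- NULL

    pheno <- data.frame(
      subject_id = rep(subject_id, times = nrow(foods)),
      sampleset = rep(sampleset, times = nrow(foods)),
      food = rep(foods$food, each = n),
      response = as.vector(response),
      stringsAsFactors = FALSE
    )

    truth <- list(
      seed = config$seed,
      founder_draws = data.frame(subject_id = subject_id[seq_len(n1 + n2)],
                                 hap1 = f1, hap2 = f2),
      liabilities = liab,
      effects = lapply(seq_along(config$planted_effects), function(k) {
        e <- config$planted_effects[[k]]
        list(food = e$food, type = e$type, snp = e$snp,
             hla_locus = e$hla_locus, hla_allele = e$hla_allele,
             haplotype = e$haplotype, log_or = log(e$odds_ratio),
             target_dosage = effect_dose[[k]])
      }),
      tag_map = founders$tag_map,
      duplicates = dup_map,
      admixed = admixed_ids,
      case_flags = case_flags
    )

    structure(list(geno = geno, hla = hla, pheno = pheno, truth = truth,
                   founders = founders),
              class = "fa_cohort")
  })
}

#' @export
print.fa_cohort <- function(x, ...) {
  cat(sprintf(
    "<fa_cohort> %d subjects x %d SNPs, %d HLA loci, %d foods, %d planted effect(s)\n",
    nrow(x$geno$dosage), ncol(x$geno$dosage), length(unique(x$hla$locus)),
    length(unique(x$pheno$food)), length(x$truth$effects)
  ))
  invisible(x)
}

#' Simulate GTEx-like and HGVD-like eQTL summary tables
#'
#' Builds the two eQTL summary dialects the overlap analysis consumes: a
#' GTEx-like table of significant SNP-gene-tissue P-values and an HGVD-like
#' table of SNP-gene P-values with the fraction of expression variance
#' explained (`r2_expl`). Designated SNP-gene pairs are written with
#' controlled relative signal strength (RSS) in each table, anchored by a
#' per-gene top association at P = 1e-12; all other content is null.
#' Null HGVD rows draw `r2_expl` below 0.1 (a null SNP explains almost none
#' of a gene's expression variance), and HGVD covers only a `hgvd_coverage`
#' fraction of SNPs, emulating its sparse array-based positions.
#'
#' @param snps character vector of SNP ids available to the tables.
#' @param designated optional data.frame with columns `snp`, `gene` and
#'   optionally `rss_gtex`, `rss_hgvd` (target RSS values, default 1) and
#'   `r2_expl` (HGVD variance explained, default 0.5).
#' @param seed integer seed.
#' @param n_tissues number of tissues carrying each designated GTEx pair
#'   (>= 10 by default so designated genes survive the tissue-count filter).
#' @param null_genes character vector of genes receiving only null content.
#' @param hgvd_coverage fraction of SNP-gene combinations covered by the
#'   HGVD-like table.
#' @param null_p_min lower bound of the null P-value distribution.
#' @return list with data.frames `gtex` (`snp, gene, tissue, p`) and `hgvd`
#'   (`snp, gene, p, r2_expl`).
#' @export
simulate_eqtl_tables <- function(snps, designated = NULL, seed = 1,
                                 n_tissues = 12,
                                 null_genes = paste0("GENE", 1:4),
                                 hgvd_coverage = 0.25,
                                 null_p_min = 0.01) {
  if (length(snps) == 0) stop("simulate_eqtl_tables needs a non-empty SNP list")
  with_seed(sub_seed(seed, 3L), {
    anchor_p <- 1e-12
    tissues <- sprintf("tissue%02d", seq_len(44))
    gtex <- list()
    hgvd <- list()

    if (!is.null(designated) && nrow(designated)) {
      if (!all(c("snp", "gene") %in% names(designated))) {
        stop("designated needs columns snp and gene")
      }
      if (is.null(designated$rss_gtex)) designated$rss_gtex <- 1
      if (is.null(designated$rss_hgvd)) designated$rss_hgvd <- 1
      if (is.null(designated$r2_expl)) designated$r2_expl <- 0.5
      for (i in seq_len(nrow(designated))) {
        d <- designated[i, ]
        top_snp <- paste0(d$gene, "_top")
        use_tissues <- tissues[seq_len(min(n_tissues, length(tissues)))]
        p_pair <- 10^(-(-log10(anchor_p)) * d$rss_gtex)
        gtex[[length(gtex) + 1]] <- data.frame(
          snp = c(rep(top_snp, length(use_tissues)),
                  rep(d$snp, length(use_tissues))),
          gene = d$gene,
          tissue = rep(use_tissues, 2),
          p = c(rep(anchor_p, length(use_tissues)),
                rep(p_pair, length(use_tissues))),
          stringsAsFactors = FALSE
        )
        hgvd[[length(hgvd) + 1]] <- data.frame(
          snp = c(top_snp, d$snp), gene = d$gene,
          p = c(anchor_p, 10^(-(-log10(anchor_p)) * d$rss_hgvd)),
          r2_expl = c(0.5, d$r2_expl),
          stringsAsFactors = FALSE
        )
      }
    }

    for (g in null_genes) {
      in_gtex <- stats::runif(length(snps)) < 0.4
      if (any(in_gtex)) {
        nt <- sample.int(3, sum(in_gtex), replace = TRUE)
        gtex[[length(gtex) + 1]] <- do.call(rbind, lapply(
          which(in_gtex), function(j) {
            k <- sample.int(3, 1)
            data.frame(
              snp = snps[j], gene = g, tissue = sample(tissues, k),
              p = stats::runif(k, null_p_min, 1),
              stringsAsFactors = FALSE
            )
          }
        ))
      }
      in_hgvd <- stats::runif(length(snps)) < hgvd_coverage
      if (any(in_hgvd)) {
        hgvd[[length(hgvd) + 1]] <- data.frame(
          snp = snps[in_hgvd], gene = g,
          p = stats::runif(sum(in_hgvd), null_p_min, 1),
          r2_expl = stats::runif(sum(in_hgvd), 0, 0.08),
          stringsAsFactors = FALSE
        )
      }
    }

    gtex <- if (length(gtex)) do.call(rbind, gtex) else {
      data.frame(snp = character(0), gene = character(0),
                 tissue = character(0), p = numeric(0))
    }
    hgvd <- if (length(hgvd)) do.call(rbind, hgvd) else {
      data.frame(snp = character(0), gene = character(0), p = numeric(0),
                 r2_expl = numeric(0))
    }
    rownames(gtex) <- rownames(hgvd) <- NULL
    list(gtex = gtex, hgvd = hgvd)
  })
}
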