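#' Case/control allele count table at one multi-allelic locus
#'
#' @param locus locus label (or a `~`-joined locus tuple for haplotypes).
#' @param category allele or haplotype codes (may include `"binned"`).
#' @param case,control non-negative allele-copy counts per category.
#' @return Object of class `fa_counts` (a data.frame `category, case,
#'   control` with a `locus` attribute).
#' @export
allele_count_table <- function(locus, category, case, control) {
  stopifnot(length(category) == length(case),
            length(category) == length(control),
            all(case >= 0), all(control >= 0))
  if (anyDuplicated(category)) stop("duplicate categories in count table")
  out <- data.frame(category = as.character(category),
                    case = as.numeric(case), control = as.numeric(control),
                    stringsAsFactors = FALSE)
  attr(out, "locus") <- locus
  class(out) <- c("fa_counts", "data.frame")
  out
}

#' Tabulate HLA allele copies by case/control status
#'
#' Each subject with a complete genotype at the locus contributes two allele
#' copies to their arm; subjects missing either allele at the locus (e.g.
#' dropped by the CT filter) are excluded from that locus. Subjects that are
#' neither a case for the food nor a panel-wide control are excluded.
#'
#' @param hla CT-filtered HLA call data.frame (`subject_id, locus, allele1,
#'   allele2, ct`).
#' @param pheno an [build_phenotypes()] result.
#' @param locus locus to tabulate.
#' @param food food defining the case arm.
#' @return An [allele_count_table()].
#' @export
count_alleles <- function(hla, pheno, locus, food) {
  calls <- hla[hla$locus == locus & !is.na(hla$allele1) & !is.na(hla$allele2), ]
  y <- case_status(pheno, food, calls$subject_id)
  calls <- calls[!is.na(y), , drop = FALSE]
  y <- y[!is.na(y)]
  alleles <- sort(unique(c(calls$allele1, calls$allele2)))
  case <- table(factor(c(calls$allele1[y == 1], calls$allele2[y == 1]),
                       levels = alleles))
  ctrl <- table(factor(c(calls$allele1[y == 0], calls$allele2[y == 0]),
                       levels = alleles))
  allele_count_table(locus, alleles, as.numeric(case), as.numeric(ctrl))
}

#' Collapse rare categories into a "binned" category
#'
#' Computes the expected count of each category in each arm from the table
#' margins (`row total x column total / grand total`) and merges categories
#' whose expected count is strictly below `min_expected` in either arm into
#' a single `"binned"` category. After merging, expectations are
#' re-evaluated once on the merged table and any newly sub-threshold
#' categories are also merged; the procedure does not iterate further.
#' A category with expected count exactly `min_expected` is kept.
#'
#' @param table an [allele_count_table()].
#' @param min_expected binning threshold (default 5).
#' @return A new [allele_count_table()], possibly containing `"binned"`.
#' @export
bin_rare <- function(table, min_expected = 5) {
  stopifnot(inherits(table, "fa_counts"))
  merge_pass <- function(tab) {
    n_case <- sum(tab$case)
    n_ctrl <- sum(tab$control)
    grand <- n_case + n_ctrl
    if (grand <= 0) stop("count table has zero total")
    cat_tot <- tab$case + tab$control
    e_case <- n_case * cat_tot / grand
    e_ctrl <- n_ctrl * cat_tot / grand
    below <- (e_case < min_expected | e_ctrl < min_expected) &
      tab$category != "binned"
    if (!any(below)) return(list(tab = tab, merged = FALSE))
    binned_case <- sum(tab$case[below])
    binned_ctrl <- sum(tab$control[below])
    keep <- tab[!below, , drop = FALSE]
    if ("binned" %in% keep$category) {
      i <- which(keep$category == "binned")
      keep$case[i] <- keep$case[i] + binned_case
      keep$control[i] <- keep$control[i] + binned_ctrl
    } else {
      keep <- rbind(keep, data.frame(category = "binned",
                                     case = binned_case,
                                     control = binned_ctrl))
    }
    list(tab = keep, merged = TRUE)
  }
  p1 <- merge_pass(table)
  out <- if (p1$merged) merge_pass(p1$tab)$tab else p1$tab
  allele_count_table(attr(table, "locus"), out$category, out$case, out$control)
}

#' Locus-level 2xk chi-square test
#'
#' Pearson chi-square statistic of the 2-by-k contingency table of
#' case/control status versus categories, with k - 1 degrees of freedom.
#' Categories with zero total count are dropped before testing.
#'
#' @param table an [allele_count_table()].
#' @return list `statistic, df, p`.
#' @export
locus_test <- function(table) {
  stopifnot(inherits(table, "fa_counts"))
  tab <- table[table$case + table$control > 0, , drop = FALSE]
  if (nrow(tab) < 2) stop("locus test needs k >= 2 non-empty categories")
  m <- rbind(case = tab$case, control = tab$control)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Single-allele 2x2 chi-square test with odds ratio
#'
#' Tests one category against all others combined, by a Pearson chi-square
#' (no continuity correction) on the 2x2 table of (this category vs rest) x
#' (case vs control). The odds ratio is `(a d)/(b c)`; when any cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied to
#' the OR only.
#'
#' @param table an [allele_count_table()].
#' @param category category to test.
#' @return list `p, or, case_freq, control_freq`.
#' @export
allele_test <- function(table, category) {
  stopifnot(inherits(table, "fa_counts"))
  i <- match(category, table$category)
  if (is.na(i)) stop("category not present: ", category)
  a <- table$case[i];    b <- sum(table$case) - a
  c_ <- table$control[i]; d <- sum(table$control) - c_
  m <- matrix(c(a, b, c_, d), nrow = 2)
  p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p = unname(p), or = or,
       case_freq = a / (a + b), control_freq = c_ / (c_ + d))
}

#' Odds ratio from case/control category frequencies
#'
#' The frequency form of the single-category odds ratio:
#' `(f_case/(1-f_case)) / (f_ctrl/(1-f_ctrl))`. Exactly equal to the
#' count-based `(a d)/(b c)` odds ratio of [allele_test()].
#'
#' @param f_case,f_ctrl category frequencies in cases and controls.
#' @return Odds ratio (vectorized).
#' @examples
#' allele_or_from_freq(0.225, 0.148)  # ~1.67
#' @export
allele_or_from_freq <- function(f_case, f_ctrl) {
  (f_case / (1 - f_case)) / (f_ctrl / (1 - f_ctrl))
}

#' Renormalized frequency after removing a category
#'
#' After a category with frequency `f_removed` is removed entirely from an
#' arm, the remaining categories' frequencies are divided by
#' `1 - f_removed`.
#'
#' @param f frequency (or vector of frequencies) before removal.
#' @param f_removed frequency of the removed category in the same arm.
#' @return Renormalized frequency.
#' @examples
#' renorm_freq(0.020, 0.148)  # 0.020 / 0.852
#' @export
renorm_freq <- function(f, f_removed) {
  f / (1 - f_removed)
}

#' Stepwise Relative Predispositional Effects (RPE) analysis
#'
#' Runs the RPE loop on a binned count table: test the locus (2xk
#' chi-square); while the locus P is below `rpe_locus_stop_p`, test every
#' remaining category (2x2 chi-square with OR), record the step, remove the
#' lowest-P category's copies entirely from both cases and controls, and
#' repeat with the removed category added to the exclusion list. The final
#' recorded step is the first whose locus P reaches the stopping threshold
#' (or the state in which fewer than two categories remain). The artificial
#' `"binned"` category is never selected for removal unless
#' `config$rpe_allow_bin_removal` is set.
#'
#' @param table an [allele_count_table()], normally after [bin_rare()].
#' @param config an [analysis_config()].
#' @return Object of class `fa_rpe`: list with `steps` (each holding the
#'   step index, the categories excluded so far, the locus test, and a
#'   per-category data.frame `category, case, control, case_freq,
#'   control_freq, p, or`) and `termination` (`"locus_nonsignificant"` or
#'   `"exhausted"`).
#' @export
rpe_run <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "fa_counts"))
  if (nrow(table) < 2) stop("RPE needs at least two categories to start")
  tab <- table
  excluded <- character(0)
  steps <- list()
  termination <- NULL
  repeat {
    lt <- locus_test(tab)
    per_cat <- do.call(rbind, lapply(tab$category, function(cc) {
      at <- allele_test(tab, cc)
      data.frame(category = cc, case = tab$case[match(cc, tab$category)],
                 control = tab$control[match(cc, tab$category)],
                 case_freq = at$case_freq, control_freq = at$control_freq,
                 p = at$p, or = at$or, stringsAsFactors = FALSE)
    }))
    steps[[length(steps) + 1]] <- list(
      step = length(steps),
      excluded = excluded,
      locus_statistic = lt$statistic, locus_df = lt$df, locus_p = lt$p,
      table = per_cat
    )
    if (lt$p >= config$rpe_locus_stop_p) {
      termination <- "locus_nonsignificant"
      break
    }
    removable <- per_cat
    if (!config$rpe_allow_bin_removal) {
      removable <- removable[removable$category != "binned", , drop = FALSE]
    }
    if (!nrow(removable)) { termination <- "exhausted"; break }
    top <- removable$category[order(removable$p, removable$category)][1]
    excluded <- c(excluded, top)
    tab <- allele_count_table(
      attr(tab, "locus"),
      tab$category[tab$category != top],
      tab$case[tab$category != top],
      tab$control[tab$category != top]
    )
    if (nrow(tab) < 2) { termination <- "exhausted"; break }
  }
  structure(list(locus = attr(table, "locus"), steps = steps,
                 termination = termination),
            class = "fa_rpe")
}

#' @export
print.fa_rpe <- function(x, ...) {
  cat(sprintf("<fa_rpe> locus %s: %d step(s), termination: %s\n",
              x$locus, length(x$steps), x$termination))
  for (s in x$steps) {
    cat(sprintf("  step %d: excluded [%s], locus P = %.4g\n",
                s$step, paste(s$excluded, collapse = ", "), s$locus_p))
  }
  invisible(x)
}

#' Flatten an RPE trace to a table
#'
#' One row per step x category, mirroring the usual published RPE layout.
#'
#' @param trace an `fa_rpe` object.
#' @return data.frame `step, excluded, locus_p, category, case_freq,
#'   control_freq, p, or`.
#' @export
rpe_trace_table <- function(trace) {
  stopifnot(inherits(trace, "fa_rpe"))
  do.call(rbind, lapply(trace$steps, function(s) {
    data.frame(
      step = s$step,
      excluded = paste(s$excluded, collapse = ","),
      locus_p = s$locus_p,
      s$table,
      stringsAsFactors = FALSE
    )
  }))
}

# Enumerate the haplotype-pair phase configurations consistent with one
# subject's unphased multi-locus genotype. g is a list of length-2 allele
# vectors, one per locus.
phase_configs <- function(g) {
  het <- vapply(g, function(x) x[1] != x[2], logical(1))
  n_het <- sum(het)
  if (n_het <= 1) {
    h1 <- vapply(g, `[`, character(1), 1)
    h2 <- vapply(g, `[`, character(1), 2)
    return(list(list(h1 = h1, h2 = h2)))
  }
  # Fix the orientation of the first heterozygous locus; enumerate the rest.
  free <- which(het)[-1]
  grid <- expand.grid(rep(list(c(1L, 2L)), length(free)))
  lapply(seq_len(nrow(grid)), function(r) {
    pick <- rep(1L, length(g))
    pick[free] <- as.integer(grid[r, ])
    h1 <- mapply(function(x, k) x[k], g, pick)
    h2 <- mapply(function(x, k) x[3L - k], g, pick)
    list(h1 = unname(h1), h2 = unname(h2))
  })
}

#' EM estimation of multi-locus haplotype frequencies
#'
#' Standard expectation-maximisation over the phase configurations
#' consistent with each subject's unphased genotype at 2-3 HLA loci.
#' The log-likelihood is non-decreasing across iterations; convergence is
#' declared when the largest absolute frequency change drops below `tol`.
#' Each subject is also assigned their most probable phase (haplotype
#' pair) under the converged frequencies.
#'
#' @param hla CT-filtered HLA call data.frame.
#' @param loci character vector of 2-3 loci, e.g. `c("DRB1", "DQB1")`.
#' @param subjects optional subject ids to restrict to; only subjects with
#'   complete genotypes at all requested loci are used.
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list with `frequencies` (named, sums to 1; names are
#'   `~`-joined allele codes), `phase` (data.frame `subject_id, hap1,
#'   hap2, prob`), `log_lik`, `n_iter`, `converged`, and `posteriors`
#'   (per-subject config weights, for fractional counting).
#' @export
em_haplotypes <- function(hla, loci, subjects = NULL, tol = 1e-8,
                          max_iter = 1000L) {
  stopifnot(length(loci) >= 2, length(loci) <= 3)
  calls <- hla[hla$locus %in% loci, , drop = FALSE]
  if (!is.null(subjects)) calls <- calls[calls$subject_id %in% subjects, ]
  wide <- split(calls, calls$subject_id)
  complete <- vapply(wide, function(x) all(loci %in% x$locus), logical(1))
  wide <- wide[complete]
  if (!length(wide)) stop("no subjects complete at all requested loci")

  genos <- lapply(wide, function(x) {
    lapply(loci, function(l) {
      row <- x[x$locus == l, ][1, ]
      sort(c(row$allele1, row$allele2))
    })
  })
  configs <- lapply(genos, phase_configs)
  hap_label <- function(h) paste(h, collapse = "~")
  config_haps <- lapply(configs, function(cfgs) {
    lapply(cfgs, function(cf) c(hap_label(cf$h1), hap_label(cf$h2)))
  })
  all_haps <- sort(unique(unlist(config_haps)))
  f <- stats::setNames(rep(1 / length(all_haps), length(all_haps)), all_haps)

  n <- length(genos)
  loglik <- -Inf
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(max_iter)) {
    counts <- stats::setNames(numeric(length(all_haps)), all_haps)
    ll <- 0
    post <- vector("list", n)
    for (i in seq_len(n)) {
      hp <- config_haps[[i]]
      w <- vapply(hp, function(pair) {
        pr <- f[pair[1]] * f[pair[2]]
        if (pair[1] != pair[2]) 2 * pr else pr
      }, numeric(1))
      tot <- sum(w)
      ll <- ll + log(tot)
      w <- w / tot
      post[[i]] <- w
      for (k in seq_along(hp)) {
        counts[hp[[k]][1]] <- counts[hp[[k]][1]] + w[k]
        counts[hp[[k]][2]] <- counts[hp[[k]][2]] + w[k]
      }
    }
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    loglik <- ll
    if (delta < tol) { converged <- TRUE; break }
  }

  phase <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- which.max(post[[i]])
    data.frame(
      subject_id = names(genos)[i],
      hap1 = config_haps[[i]][[k]][1],
      hap2 = config_haps[[i]][[k]][2],
      prob = post[[i]][k],
      stringsAsFactors = FALSE
    )
  }))
  list(frequencies = f, phase = phase, log_lik = loglik, n_iter = iter,
       converged = converged, posteriors = post,
       config_haps = config_haps, subject_ids = names(genos))
}

#' RPE analysis of multi-locus HLA haplotypes
#'
#' Estimates haplotype phase by [em_haplotypes()] (pooled over cases and
#' controls of the food's analysis set), counts haplotype copies per arm —
#' by each subject's most probable phase by default
#' (`config$hap_count_mode = "hard"`), or by posterior-weighted fractional
#' counts (`"fractional"`) — bins haplotypes with frequency strictly below
#' `config$hap_bin_min_freq` in either arm, and runs [rpe_run()] on the
#' resulting table.
#'
#' @param hla CT-filtered HLA calls.
#' @param loci 2-3 loci defining the haplotype.
#' @param pheno an [build_phenotypes()] result.
#' @param food case-defining food.
#' @param config an [analysis_config()].
#' @return list with `trace` (the `fa_rpe`), `table` (binned
#'   [allele_count_table()]) and `em` (the [em_haplotypes()] fit).
#' @export
haplotype_rpe <- function(hla, loci, pheno, food,
                          config = analysis_config()) {
  ids <- pheno$subjects$subject_id
  y <- case_status(pheno, food, ids)
  analysis_ids <- ids[!is.na(y)]
  em <- em_haplotypes(hla, loci, subjects = analysis_ids)
  y_sub <- y[match(em$subject_ids, ids)]

  if (identical(config$hap_count_mode, "fractional")) {
    haps <- sort(unique(unlist(em$config_haps)))
    case <- stats::setNames(numeric(length(haps)), haps)
    ctrl <- case
    for (i in seq_along(em$subject_ids)) {
      w <- em$posteriors[[i]]
      for (k in seq_along(w)) {
        pair <- em$config_haps[[i]][[k]]
        if (y_sub[i] == 1L) {
          case[pair[1]] <- case[pair[1]] + w[k]
          case[pair[2]] <- case[pair[2]] + w[k]
        } else {
          ctrl[pair[1]] <- ctrl[pair[1]] + w[k]
          ctrl[pair[2]] <- ctrl[pair[2]] + w[k]
        }
      }
    }
    tab <- allele_count_table(paste(loci, collapse = "~"), names(case),
                              as.numeric(case), as.numeric(ctrl))
  } else {
    copies <- c(em$phase$hap1, em$phase$hap2)
    arm <- rep(y_sub, 2)
    haps <- sort(unique(copies))
    case <- table(factor(copies[arm == 1L], levels = haps))
    ctrl <- table(factor(copies[arm == 0L], levels = haps))
    tab <- allele_count_table(paste(loci, collapse = "~"), haps,
                              as.numeric(case), as.numeric(ctrl))
  }

  n_case <- sum(tab$case)
  n_ctrl <- sum(tab$control)
  if (n_case == 0 || n_ctrl == 0) stop("haplotype RPE needs both arms populated")
  f_case <- tab$case / n_case
  f_ctrl <- tab$control / n_ctrl
  rare <- (f_case < config$hap_bin_min_freq | f_ctrl < config$hap_bin_min_freq)
  if (any(rare)) {
    keep <- tab[!rare, , drop = FALSE]
    keep <- rbind(keep, data.frame(category = "binned",
                                   case = sum(tab$case[rare]),
                                   control = sum(tab$control[rare])))
    tab <- allele_count_table(paste(loci, collapse = "~"), keep$category,
                              keep$case, keep$control)
  }
  if (nrow(tab) < 2) {
    stop("fewer than two haplotype categories remain after binning; ",
         "the haplotype distribution is too concentrated for RPE")
  }
  trace <- rpe_run(tab, config)
  list(trace = trace, table = tab, em = em)
}
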