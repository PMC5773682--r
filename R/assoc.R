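#' Build per-food case/control phenotypes and the eligible-food list
#'
#' Codes a subject as a case for a food when their response to it is mild or
#' severe, and as a (shared) control when every response across the whole
#' panel is "none". Subjects who are neither (reactive to some other food
#' only) are excluded from that food's analysis. A food is eligible for GWAS
#' when its case count is strictly greater than `config$min_cases_per_set`
#' in both samplesets.
#'
#' @param questionnaire long data.frame `subject_id, sampleset, food,
#'   response` with responses `none/mild/severe` for every food.
#' @param config an [analysis_config()].
#' @return Object of class `fa_pheno`: list with `subjects` (data.frame
#'   `subject_id, sampleset, control`), `case` (logical subjects x foods
#'   matrix), `eligible` (character vector of eligible foods) and `foods`.
#' @export
build_phenotypes <- function(questionnaire, config = analysis_config()) {
  need <- c("subject_id", "sampleset", "food", "response")
  if (!all(need %in% names(questionnaire))) {
    stop("questionnaire missing required column(s): ",
         paste(setdiff(need, names(questionnaire)), collapse = ", "))
  }
  foods <- sort(unique(questionnaire$food))
  ids <- unique(questionnaire$subject_id)
  n_resp <- table(questionnaire$subject_id)
  if (any(n_resp != length(foods))) {
    stop("every subject must have a response for every food")
  }
  case <- matrix(FALSE, nrow = length(ids), ncol = length(foods),
                 dimnames = list(ids, foods))
  idx <- cbind(match(questionnaire$subject_id, ids),
               match(questionnaire$food, foods))
  case[idx] <- questionnaire$response %in% c("mild", "severe")
  sets <- questionnaire$sampleset[match(ids, questionnaire$subject_id)]
  subjects <- data.frame(
    subject_id = ids, sampleset = sets,
    control = rowSums(case) == 0,
    stringsAsFactors = FALSE
  )
  counts <- rowsum(case + 0, sets)
  eligible <- foods[apply(counts > config$min_cases_per_set, 2, all)]
  structure(
    list(subjects = subjects, case = case, eligible = eligible,
         foods = foods),
    class = "fa_pheno"
  )
}

#' @export
print.fa_pheno <- function(x, ...) {
  cat(sprintf(
    "<fa_pheno> %d subjects (%d controls), %d foods, eligible: %s\n",
    nrow(x$subjects), sum(x$subjects$control), length(x$foods),
    paste(x$eligible, collapse = ", ")
  ))
  invisible(x)
}

# Case(1)/control(0)/NA status vector for one food, aligned to `ids`.
case_status <- function(pheno, food, ids) {
  stopifnot(inherits(pheno, "fa_pheno"))
  if (!food %in% pheno$foods) stop("unknown food: ", food)
  i <- match(ids, pheno$subjects$subject_id)
  y <- rep(NA_integer_, length(ids))
  is_case <- pheno$case[, food][i]
  is_ctrl <- pheno$subjects$control[i]
  y[!is.na(is_case) & is_case] <- 1L
  y[!is.na(is_ctrl) & is_ctrl] <- 0L
  y
}

# One logistic fit by IRLS (glm.fit); returns beta/se/p for the column of
# interest, with separation/non-convergence reported instead of statistics.
logistic_fit_term <- function(x, y, term_col, max_iter = 25L,
                              max_abs_beta = 20) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      x, y, family = stats::binomial(),
      control = list(maxit = max_iter)
    )),
    error = function(e) NULL
  )
  bad <- is.null(fit) || !fit$converged ||
    any(!is.finite(fit$coefficients)) ||
    max(abs(fit$coefficients)) > max_abs_beta
  if (!bad) {
    # Wald SEs from the final IRLS weighted least squares.
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(cov) || fit$rank < ncol(x)) bad <- TRUE else {
      se <- sqrt(diag(cov))[term_col]
      beta <- fit$coefficients[term_col]
      if (!is.finite(se) || se <= 0) bad <- TRUE
    }
  }
  if (bad) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE))
  }
  z <- beta / se
  list(beta = unname(beta), se = unname(se), p = p_from_z(z),
       converged = TRUE)
}

#' Per-sampleset additive logistic GWAS
#'
#' Fits, per variant, the logistic regression `case ~ intercept + dosage
#' (+ covariates)` by iteratively reweighted least squares on the subjects
#' with a non-missing dosage (per-variant complete cases), and reports the
#' Wald beta, SE and two-sided P for the dosage term. Fits that do not
#' converge within `config$gwas_max_iter` iterations, diverge beyond
#' `config$gwas_max_abs_beta` in |beta| (separation), or have a constant
#' dosage are returned with `converged = FALSE` and statistics withheld.
#'
#' @param geno an [fa_geno].
#' @param pheno an [build_phenotypes()] result.
#' @param food food to analyse.
#' @param covariates optional numeric matrix of covariates (e.g. the final
#'   PCA scores), rownames = subject ids.
#' @param sampleset optional sampleset label to restrict to; default uses
#'   all subjects in `geno`.
#' @param variants optional variant ids to restrict to.
#' @param condition_on optional variant id whose dosage is added as a
#'   covariate (conditional analysis). When a tested variant is identical
#'   or perfectly collinear with the conditioning variant its record is
#'   returned converged with `wald_p = 1` and `beta = 0` by convention, so
#'   that `r2_equiv` of a variant with itself is exactly 1.
#' @return Object of class `fa_gwas`: list with `food`, `sampleset`,
#'   `records` (data.frame `id, effect_allele, other_allele, n_cases,
#'   n_controls, beta, se, p, converged`) and `lambda_gc` (NA with fewer
#'   than 100 informative P-values).
#' @export
logistic_gwas <- function(geno, pheno, food, covariates = NULL,
                          sampleset = NULL, variants = NULL,
                          condition_on = NULL,
                          config = analysis_config()) {
  stopifnot(inherits(geno, "fa_geno"))
  if (!is.null(sampleset)) {
    geno <- geno_subset(geno, subjects = geno$subjects$sampleset %in% sampleset)
  }
  if (!is.null(variants)) geno <- geno_subset(geno, variants = variants)
  ids <- geno$subjects$subject_id
  y_all <- case_status(pheno, food, ids)
  use <- !is.na(y_all)
  if (sum(y_all[use] == 1L) == 0) stop("no cases for food '", food, "'")
  if (sum(y_all[use] == 0L) == 0) stop("no controls for food '", food, "'")

  cov <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) {
      stop("covariates must have subject ids as rownames")
    }
    cov <- covariates[match(ids, rownames(covariates)), , drop = FALSE]
    use <- use & stats::complete.cases(cov)
  }
  cond_dose <- NULL
  if (!is.null(condition_on)) {
    cond_dose <- geno_dosage(geno, condition_on)
    use <- use & !is.na(cond_dose)
  }

  d <- geno$dosage[use, , drop = FALSE]
  y <- y_all[use]
  covu <- if (!is.null(cov)) cov[use, , drop = FALSE] else NULL
  condu <- if (!is.null(cond_dose)) cond_dose[use] else NULL

  fit_one <- function(j) {
    dose <- d[, j]
    ok <- !is.na(dose)
    yy <- y[ok]; dd <- dose[ok]
    n_ca <- sum(yy == 1L); n_co <- sum(yy == 0L)
    if (!is.null(condu)) {
      cc <- condu[ok]
      r <- suppressWarnings(stats::cor(dd, cc))
      if (stats::sd(dd) == 0 || (!is.na(r) && abs(r) > 1 - 1e-12)) {
        # Tested variant is (a perfect proxy of) the conditioning variant.
        return(list(beta = 0, se = NA_real_, p = 1, converged = TRUE,
                    n_cases = n_ca, n_controls = n_co))
      }
    }
    if (n_ca == 0 || n_co == 0 || stats::sd(dd) == 0) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  converged = FALSE, n_cases = n_ca, n_controls = n_co))
    }
    x <- cbind(1, dd)
    if (!is.null(condu)) x <- cbind(x, condu[ok])
    if (!is.null(covu)) x <- cbind(x, covu[ok, , drop = FALSE])
    res <- logistic_fit_term(x, yy, term_col = 2L,
                             max_iter = config$gwas_max_iter,
                             max_abs_beta = config$gwas_max_abs_beta)
    c(res, list(n_cases = n_ca, n_controls = n_co))
  }

  fits <- lapply(seq_len(ncol(d)), fit_one)
  records <- data.frame(
    chrom = geno$variants$chrom,
    pos = geno$variants$pos,
    id = geno$variants$id,
    effect_allele = geno$variants$alt,
    other_allele = geno$variants$ref,
    n_cases = vapply(fits, `[[`, integer(1), "n_cases"),
    n_controls = vapply(fits, `[[`, integer(1), "n_controls"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  lam <- if (sum(!is.na(records$p)) >= 100) {
    lambda_gc(records$p[!is.na(records$p)])
  } else NA_real_
  structure(
    list(food = food,
         sampleset = if (is.null(sampleset)) "all" else sampleset,
         condition_on = condition_on,
         records = records, lambda_gc = lam),
    class = "fa_gwas"
  )
}

#' @export
print.fa_gwas <- function(x, ...) {
  cat(sprintf(
    "<fa_gwas> %s / %s: %d variants, lambda_GC = %s%s\n",
    x$food, x$sampleset, nrow(x$records),
    ifelse(is.na(x$lambda_gc), "NA", format(round(x$lambda_gc, 4))),
    if (!is.null(x$condition_on)) paste0(" (conditioned on ", x$condition_on, ")")
    else ""
  ))
  invisible(x)
}

#' Conditional logistic GWAS
#'
#' Convenience wrapper around [logistic_gwas()] that re-fits the identical
#' model with the conditioning variant's dosage added as a covariate.
#'
#' @inheritParams logistic_gwas
#' @param condition_on variant id to condition on.
#' @return An `fa_gwas` object.
#' @export
conditional_gwas <- function(geno, pheno, food, condition_on,
                             covariates = NULL, sampleset = NULL,
                             variants = NULL, config = analysis_config()) {
  if (!condition_on %in% geno$variants$id) {
    stop("conditioning variant not present: ", condition_on)
  }
  logistic_gwas(geno, pheno, food, covariates = covariates,
                sampleset = sampleset, variants = variants,
                condition_on = condition_on, config = config)
}

#' Genomic-control inflation factor
#'
#' The median of the 1-df chi-square quantiles corresponding to the observed
#' P-values, divided by the null median 0.4549364.
#'
#' @param p numeric vector of at least 100 P-values.
#' @return Scalar lambda_GC.
#' @examples
#' lambda_gc(rep(0.5, 100))  # exactly 1
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) stop("lambda_gc needs at least 100 p-values")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
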