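#' Genotype matrix container
#'
#' Bundles a subjects-by-variants additive dosage matrix with its variant
#' metadata and per-subject sampleset labels. Dosages count copies of the
#' alternate allele: 0, 1 or 2, with `NA` for missing calls.
#'
#' @param dosage integer matrix, subjects in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`. Row names are subject ids, column names
#'   variant ids (supplied from `subjects`/`variants` if absent).
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`; one row per dosage column.
#' @param subjects data.frame with columns `subject_id` and `sampleset`;
#'   one row per dosage row.
#'
#' @return An object of class `fa_geno`.
#' @export
fa_geno <- function(dosage, variants, subjects) {
  dosage <- as.matrix(dosage)
  stopifnot(
    is.data.frame(variants), is.data.frame(subjects),
    all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
    all(c("subject_id", "sampleset") %in% names(subjects)),
    nrow(dosage) == nrow(subjects),
    ncol(dosage) == nrow(variants)
  )
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject ids in genotype matrix")
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant ids in genotype matrix")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    stop("non-missing dosages must be 0, 1 or 2")
  }
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- subjects$subject_id
  colnames(dosage) <- variants$id
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  rownames(subjects) <- NULL
  structure(
    list(dosage = dosage, variants = variants, subjects = subjects),
    class = "fa_geno"
  )
}

#' @export
print.fa_geno <- function(x, ...) {
  cat(sprintf(
    "<fa_geno> %d subjects x %d variants (%s)\n",
    nrow(x$dosage), ncol(x$dosage),
    paste(sprintf(
      "%s: %d", names(table(x$subjects$sampleset)),
      as.integer(table(x$subjects$sampleset))
    ), collapse = ", ")
  ))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param geno an [fa_geno] object.
#' @param subjects optional character vector of subject ids (or logical/
#'   integer index) to keep.
#' @param variants optional character vector of variant ids (or logical/
#'   integer index) to keep.
#' @return A new [fa_geno] restricted to the requested rows/columns.
#' @export
geno_subset <- function(geno, subjects = NULL, variants = NULL) {
  stopifnot(inherits(geno, "fa_geno"))
  si <- seq_len(nrow(geno$dosage))
  vi <- seq_len(ncol(geno$dosage))
  if (!is.null(subjects)) {
    si <- if (is.character(subjects)) {
      match(subjects, geno$subjects$subject_id)
    } else which(rep_len(TRUE, nrow(geno$dosage)))[subjects]
    if (anyNA(si)) stop("unknown subject id(s) in geno_subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) {
      match(variants, geno$variants$id)
    } else which(rep_len(TRUE, ncol(geno$dosage)))[variants]
    if (anyNA(vi)) stop("unknown variant id(s) in geno_subset")
  }
  fa_geno(
    geno$dosage[si, vi, drop = FALSE],
    geno$variants[vi, , drop = FALSE],
    geno$subjects[si, , drop = FALSE]
  )
}

# Dosage vector for one variant id.
geno_dosage <- function(geno, variant_id) {
  j <- match(variant_id, geno$variants$id)
  if (is.na(j)) stop("unknown variant id: ", variant_id)
  geno$dosage[, j]
}
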