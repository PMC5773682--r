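#' Read a VCF file into a genotype matrix
#'
#' Loads biallelic GT records from a VCF 4.x file. Multi-allelic records are
#' rejected with a message listing their ids; half-calls (e.g. `./1`) and
#' `./.` are treated as missing. Only the GT field is interpreted; phase
#' separators (`/` or `|`) are accepted and phase is not preserved.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param sampleset optional named assignment of subjects to samplesets:
#'   either a single label for all subjects or a named character vector
#'   `subject_id -> sampleset`. Defaults to `"set1"`.
#' @return An [fa_geno] object.
#' @export
read_vcf <- function(path, sampleset = "set1") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  # Cheap structural pre-check so malformed input fails with a line number.
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("malformed VCF: empty file at line 1")
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("malformed VCF header: no #CHROM line found")
  hdr <- hdr[1]
  ncol_expected <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (ncol_expected < 10) {
    stop("malformed VCF header at line ", hdr, ": no sample columns")
  }
  body <- which(!startsWith(lines, "#"))
  body <- body[body > hdr]
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != ncol_expected)) {
    stop("malformed VCF record at line ", body[which(nf != ncol_expected)[1]])
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) {
    fix_m <- matrix(fix_m, nrow = 1, dimnames = list(NULL, names(fix_m)))
  }
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic records are not supported: ",
         paste(fix$ID[multi], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dose[gt == "0/0"] <- 0L
  dose[gt == "0/1" | gt == "1/0"] <- 1L
  dose[gt == "1/1"] <- 2L
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1") |
    grepl("\\.", gt)
  if (!all(known)) {
    stop("unsupported GT value(s): ",
         paste(unique(gt[!known]), collapse = ", "))
  }

  subjects <- colnames(gt)
  sets <- if (length(sampleset) == 1 && is.null(names(sampleset))) {
    rep(sampleset, length(subjects))
  } else {
    out <- unname(sampleset[subjects])
    if (anyNA(out)) stop("sampleset mapping missing for some subjects")
    out
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  fa_geno(
    t(dose),
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    data.frame(subject_id = subjects, sampleset = sets,
               stringsAsFactors = FALSE)
  )
}

#' Write a genotype matrix as VCF
#'
#' Writes unphased GT records (1-based positions, `./.` for missing).
#' Deterministic: the same matrix always produces a byte-identical file.
#'
#' @param geno an [fa_geno] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "fa_geno"))
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(geno$dosage), ncol = nrow(geno$dosage))
  ok <- !is.na(t(geno$dosage))
  gt[ok] <- gtcode[t(geno$dosage)[ok] + 1L]
  rec <- paste(
    geno$variants$chrom, geno$variants$pos, geno$variants$id,
    geno$variants$ref, geno$variants$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$subjects$subject_id), collapse = "\t")
  ), con = path)
  cat(rec, sep = "\n", file = path, append = TRUE)
  invisible(path)
}

#' Write / read a TSV dosage matrix
#'
#' Variants in rows (columns `chrom, pos, id, ref, alt` then one column per
#' subject), tab-separated, `.` for missing, no quoting.
#'
#' @param geno an [fa_geno] object.
#' @param path file path.
#' @param sampleset as in [read_vcf()].
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns an [fa_geno].
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "fa_geno"))
  d <- t(geno$dosage)
  dd <- matrix(as.character(d), nrow = nrow(d))
  dd[is.na(dd)] <- "."
  out <- cbind(
    geno$variants$chrom, geno$variants$pos, geno$variants$id,
    geno$variants$ref, geno$variants$alt, dd
  )
  colnames(out) <- c("chrom", "pos", "id", "ref", "alt",
                     geno$subjects$subject_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, sampleset = "set1") {
  if (!file.exists(path)) stop("dosage TSV not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("dosage TSV missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  subjects <- setdiff(names(tab), need)
  d <- as.matrix(tab[, subjects, drop = FALSE])
  d[d == "."] <- NA
  suppressWarnings(storage.mode(d) <- "integer")
  bad <- !is.na(d) & !(d %in% c(0L, 1L, 2L))
  if (any(bad)) stop("dosage TSV contains out-of-domain dosage values")
  sets <- if (length(sampleset) == 1 && is.null(names(sampleset))) {
    rep(sampleset, length(subjects))
  } else {
    out <- unname(sampleset[subjects])
    if (anyNA(out)) stop("sampleset mapping missing for some subjects")
    out
  }
  fa_geno(
    t(d),
    data.frame(chrom = tab$chrom, pos = as.integer(tab$pos), id = tab$id,
               ref = tab$ref, alt = tab$alt, stringsAsFactors = FALSE),
    data.frame(subject_id = subjects, sampleset = sets,
               stringsAsFactors = FALSE)
  )
}

#' Read an HLA genotype call table, applying the call-threshold filter
#'
#' Reads the five-column TSV dialect `subject_id, locus, allele1, allele2,
#' ct` and drops rows whose call-threshold score does not exceed `ct_min`
#' (strictly greater than, i.e. `ct = 0.5` is excluded at the default 0.5
#' cut-off). Allele codes must be two-field numeric codes such as `09:01`.
#'
#' @param path TSV path.
#' @param config an [analysis_config()]; `ct_min` is the filter threshold.
#' @return data.frame of retained calls, with attributes `n_excluded_ct`
#'   (count of dropped rows) and `completeness` (per-locus fraction of
#'   subjects retained).
#' @export
read_hla_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("HLA table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("subject_id", "locus", "allele1", "allele2", "ct")
  if (!all(need %in% names(tab))) {
    stop("HLA table missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab$ct <- as.numeric(tab$ct)
  if (anyNA(tab$ct) || any(tab$ct < 0 | tab$ct > 1)) {
    stop("ct scores must be numeric in [0, 1]")
  }
  ok_code <- grepl("^\\d{2,3}:\\d{2,3}$", tab$allele1) &
    grepl("^\\d{2,3}:\\d{2,3}$", tab$allele2)
  if (!all(ok_code)) {
    stop("malformed HLA allele code at row ", which(!ok_code)[1])
  }
  keep <- tab$ct > config$ct_min
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_subj <- length(unique(tab$subject_id))
  completeness <- vapply(
    split(out, out$locus),
    function(x) length(unique(x$subject_id)) / n_subj, numeric(1)
  )
  attr(out, "n_excluded_ct") <- sum(!keep)
  attr(out, "completeness") <- completeness
  out
}

#' Filter HLA calls by call threshold (in-memory variant)
#'
#' Same CT filter as [read_hla_table()] but applied to an already loaded
#' data.frame (e.g. the `hla` element of a simulated cohort).
#'
#' @param hla data.frame with at least columns `subject_id, locus, allele1,
#'   allele2, ct`.
#' @param config an [analysis_config()].
#' @return The filtered data.frame with attribute `n_excluded_ct`.
#' @export
filter_hla_ct <- function(hla, config = analysis_config()) {
  keep <- hla$ct > config$ct_min
  out <- hla[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_ct") <- sum(!keep)
  out
}

.sumstat_cols <- c("chrom", "pos", "id", "effect_allele", "other_allele",
                   "n_cases", "n_controls", "beta", "se", "p", "sampleset")

#' Write / read association summary statistics
#'
#' Tab-separated summary statistics with columns `chrom, pos, id,
#' effect_allele, other_allele, n_cases, n_controls, beta, se, p, sampleset`
#' (the `sampleset` column carries `"meta"` for pooled records). Numeric
#' columns round-trip to at least 12 significant digits; `p` is checked to
#' lie in [0, 1] on read.
#'
#' @param records data.frame with the columns above.
#' @param path file path.
#' @return `write_summary_stats` returns `path` invisibly;
#'   `read_summary_stats` returns the records data.frame.
#' @export
write_summary_stats <- function(records, path) {
  miss <- setdiff(.sumstat_cols, names(records))
  if (length(miss)) {
    stop("summary statistics missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- records[, .sumstat_cols, drop = FALSE]
  for (col in c("beta", "se", "p")) {
    out[[col]] <- sprintf("%.15g", out[[col]])
    out[[col]][out[[col]] == "NA"] <- "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("summary statistics not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = ".")
  miss <- setdiff(.sumstat_cols, names(tab))
  if (length(miss)) {
    stop("summary statistics missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab$pos <- as.integer(tab$pos)
  tab$n_cases <- as.integer(tab$n_cases)
  tab$n_controls <- as.integer(tab$n_controls)
  for (col in c("beta", "se", "p")) tab[[col]] <- as.numeric(tab[[col]])
  bad_p <- !is.na(tab$p) & (tab$p < 0 | tab$p > 1)
  if (any(bad_p)) {
    stop("p outside [0, 1] at row ", which(bad_p)[1])
  }
  tab
}

#' Write / read a long phenotype table
#'
#' TSV dialect `subject_id, sampleset, food, response` with `response` in
#' `none/mild/severe`.
#'
#' @param pheno long data.frame as produced by [simulate_cohort()].
#' @param path file path.
#' @return `write_pheno_tsv` returns `path` invisibly; `read_pheno_tsv`
#'   returns the data.frame.
#' @export
write_pheno_tsv <- function(pheno, path) {
  need <- c("subject_id", "sampleset", "food", "response")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table missing required column(s): ",
         paste(setdiff(need, names(pheno)), collapse = ", "))
  }
  utils::write.table(pheno[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  if (!file.exists(path)) stop("phenotype table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("subject_id", "sampleset", "food", "response")
  if (!all(need %in% names(tab))) {
    stop("phenotype table missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  bad <- !tab$response %in% c("none", "mild", "severe")
  if (any(bad)) {
    stop("invalid response value at row ", which(bad)[1],
         " (must be none/mild/severe)")
  }
  tab
}

#' Write a simulated cohort to disk
#'
#' Writes every synthetic input in its external dialect: genotypes as VCF
#' and as a TSV dosage matrix, the questionnaire as a phenotype TSV, HLA
#' calls as a five-column TSV, and the generator truth as structured JSON.
#'
#' @param cohort an `fa_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fa_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "dosage.tsv"),
    pheno = file.path(dir, "phenotypes.tsv"),
    hla = file.path(dir, "hla_calls.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(cohort$geno, paths[["vcf"]])
  write_dosage_tsv(cohort$geno, paths[["dosage"]])
  write_pheno_tsv(cohort$pheno, paths[["pheno"]])
  utils::write.table(cohort$hla, paths[["hla"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  truth$liabilities <- as.data.frame(truth$liabilities)
  truth$case_flags <- as.data.frame(truth$case_flags)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
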