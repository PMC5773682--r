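#' Relative signal strength (RSS)
#'
#' How close an eQTL SNP's signal is to the strongest signal for its gene:
#' `RSS = -log10(P_snp) / -log10(P_gene_min)`. The gene's top SNP scores
#' exactly 1 and `P_snp = 1` scores 0. P-values of zero are floored at
#' 1e-320 before logs.
#'
#' @param p_snp SNP-gene P-value(s).
#' @param p_gene_min minimum P-value over all SNPs for the gene (in the
#'   same database, and tissue where applicable).
#' @return RSS value(s), >= 0.
#' @examples
#' rss(1e-4, 1e-20)  # 0.2
#' @export
rss <- function(p_snp, p_gene_min) {
  if (any(p_snp <= 0) || any(p_gene_min <= 0)) stop("p-values must be > 0")
  denom <- -log10(floor_p(p_gene_min))
  if (any(denom == 0)) stop("p_gene_min of 1 gives an undefined RSS")
  (-log10(floor_p(p_snp))) / denom
}

#' HGVD variance-explained prefilter
#'
#' Keeps only records whose expression variance explained exceeds
#' `config$hgvd_r2_min` (strictly; `r2_expl = 0.1` is dropped at the
#' default threshold).
#'
#' @param records HGVD-dialect data.frame (`snp, gene, p, r2_expl`).
#' @param config an [analysis_config()].
#' @return Filtered data.frame.
#' @export
hgvd_prefilter <- function(records, config = analysis_config()) {
  stopifnot(all(c("snp", "gene", "p", "r2_expl") %in% names(records)))
  out <- records[!is.na(records$r2_expl) &
                   records$r2_expl > config$hgvd_r2_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GTEx tissue-count confidence filter
#'
#' Drops genes whose best SNP is associated in fewer than `min_tissues`
#' tissues. Applied to listing output only, not to the candidate-gene
#' logic.
#'
#' @param records GTEx-dialect data.frame (`snp, gene, tissue, p`).
#' @param min_tissues minimum tissue count (default 10, `>=`).
#' @return Filtered data.frame.
#' @export
gtex_tissue_count_filter <- function(records, min_tissues = 10L) {
  stopifnot(all(c("snp", "gene", "tissue", "p") %in% names(records)))
  if (!nrow(records)) return(records)
  pair_tissues <- stats::aggregate(
    tissue ~ snp + gene, data = records,
    FUN = function(x) length(unique(x))
  )
  best <- tapply(pair_tissues$tissue, pair_tissues$gene, max)
  keep_genes <- names(best)[best >= min_tissues]
  out <- records[records$gene %in% keep_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per (snp, gene) RSS within the HGVD dialect (gene minimum over the
# supplied, already prefiltered records).
rss_hgvd_table <- function(hgvd) {
  if (!nrow(hgvd)) {
    return(data.frame(snp = character(0), gene = character(0),
                      rss_hgvd = numeric(0)))
  }
  gene_min <- tapply(hgvd$p, hgvd$gene, min)
  data.frame(
    snp = hgvd$snp, gene = hgvd$gene,
    rss_hgvd = rss(hgvd$p, unname(gene_min[hgvd$gene])),
    stringsAsFactors = FALSE
  )
}

# Per (snp, gene) max-over-tissues RSS and tissue count within the GTEx
# dialect (gene minimum taken per tissue before the max).
rss_gtex_table <- function(gtex) {
  if (!nrow(gtex)) {
    return(data.frame(snp = character(0), gene = character(0),
                      max_rss_gtex = numeric(0), n_tissues = integer(0)))
  }
  key <- paste(gtex$gene, gtex$tissue, sep = "\r")
  gt_min <- tapply(gtex$p, key, min)
  r <- rss(gtex$p, unname(gt_min[key]))
  pair <- paste(gtex$snp, gtex$gene, sep = "\r")
  max_r <- tapply(r, pair, max)
  n_tis <- tapply(gtex$tissue, pair, function(x) length(unique(x)))
  parts <- do.call(rbind, strsplit(names(max_r), "\r", fixed = TRUE))
  data.frame(
    snp = parts[, 1], gene = parts[, 2],
    max_rss_gtex = unname(max_r),
    n_tissues = as.integer(unname(n_tis[names(max_r)])),
    stringsAsFactors = FALSE
  )
}

#' Dual-database eQTL candidate-gene filter
#'
#' Implements the two-stage overlap rule around a GWAS top SNP. The HGVD
#' table is first prefiltered for variance explained
#' ([hgvd_prefilter()]); RSS is computed within each database (per tissue
#' for GTEx, then maximized over tissues). SNPs must lie in the moderate-LD
#' set of the GWAS top SNP (`r2 > 0.5` or `r2_equiv > 0.5`). The candidate
#' set contains genes with at least one moderate-LD SNP satisfying the AND
#' rule `rss_hgvd > rss_min & max_rss_gtex > rss_min`; the listing table
#' contains all pairs satisfying the OR rule
#' `rss_hgvd > rss_min | max_rss_gtex > rss_min` (with the GTEx
#' tissue-count confidence filter applied to the listing only).
#'
#' @param ld_set data.frame from [ld_class()] (columns `id, r2, r2_equiv`,
#'   optionally precomputed `moderate`).
#' @param gtex GTEx-dialect records.
#' @param hgvd HGVD-dialect records (unfiltered; the prefilter is applied
#'   here).
#' @param config an [analysis_config()].
#' @return list with `candidates` (character gene set), `overlap`
#'   (per-pair table with both RSS values and the candidate flag) and
#'   `listing` (OR-rule pair table after the tissue-count filter).
#' @export
candidate_genes <- function(ld_set, gtex, hgvd, config = analysis_config()) {
  if (!"moderate" %in% names(ld_set)) {
    ld_set <- ld_class(ld_set, config)
  }
  mod_snps <- ld_set$id[ld_set$moderate]
  hgvd_f <- hgvd_prefilter(hgvd, config)
  rh <- rss_hgvd_table(hgvd_f)
  rg <- rss_gtex_table(gtex)
  overlap <- merge(rg, rh, by = c("snp", "gene"), all = TRUE)
  overlap$moderate_ld <- overlap$snp %in% mod_snps
  pass_g <- !is.na(overlap$max_rss_gtex) & overlap$max_rss_gtex > config$rss_min
  pass_h <- !is.na(overlap$rss_hgvd) & overlap$rss_hgvd > config$rss_min
  overlap$candidate <- overlap$moderate_ld & pass_g & pass_h
  candidates <- sort(unique(overlap$gene[overlap$candidate]))

  listing <- overlap[overlap$moderate_ld & (pass_g | pass_h), , drop = FALSE]
  gtex_ok <- gtex_tissue_count_filter(gtex, config$gtex_min_tissues)
  kept_genes <- unique(gtex_ok$gene)
  # The tissue-count filter trims only the GTEx-supported side of the
  # listing; HGVD-only evidence is unaffected by GTEx tissue counts.
  drop_row <- !is.na(listing$max_rss_gtex) & !listing$gene %in% kept_genes &
    !(!is.na(listing$rss_hgvd) & listing$rss_hgvd > config$rss_min)
  listing <- listing[!drop_row, , drop = FALSE]
  rownames(overlap) <- rownames(listing) <- NULL
  list(candidates = candidates, overlap = overlap, listing = listing)
}
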