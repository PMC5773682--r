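# fagwas

Case-control GWAS and HLA fine-mapping for self-reported food allergy, as
a reusable, fully testable R pipeline.

Questionnaire-based food-allergy cohorts pose a specific analysis problem:
two samplesets genotyped in stages, per-food case definitions against one
shared control pool, association signals concentrated in the MHC, and
fine-mapping that must work at the level of multi-allelic HLA alleles and
haplotypes rather than single SNPs. `fagwas` implements that chain end to
end for analysts who want every stage scriptable and verifiable:

* **QC** — per-variant call rate, MAF, exact Hardy-Weinberg and
  duplicate-concordance filters applied in *both* samplesets; LD pruning;
  iterated PCA with automated outlier removal; method-of-moments IBD
  (`PI_HAT`) duplicate detection.
* **Association** — per-food additive logistic GWAS with PC covariates
  (`case ~ dosage + PC1 + PC2`), conditional analysis, genomic-control
  λ.
* **Selection and pooling** — bi-directional discovery-evaluation
  (`P ≤ 1e-4` in one set; `P < 0.05` and BH FDR `< 0.2` in the other),
  fixed-effects inverse-variance meta-analysis
  (`β = Σw·b/Σw`, `w = 1/se²`), significance tiers at
  `P < 1.21e-7` (0.05/411,521) and `P < 4.4e-9`.
* **LD metrics** — dosage r² and the conditional-signal statistic
  `r²_equiv = (Z_B − Z_B|A)/Z_A` with `Z = −log10 P`.
* **HLA RPE** — Relative Predispositional Effects analysis: 2×k locus
  chi-square, per-allele 2×2 tests with odds ratios, expected-count
  binning, stepwise removal of the top allele until the locus is
  non-significant; EM haplotype estimation and haplotype-level RPE.
* **eQTL overlap** — relative signal strength
  `RSS = −log10(P_SNP)/−log10(P_gene.min)` against GTEx-like and
  HGVD-like summary tables with the dual-database candidate-gene filter.
* **Cross-reactivity** — the asymmetric food-pair reactivity proportion
  matrix with clustering order for heatmaps.
* **Synthetic cohorts** — a truth-annotated generator (founder-pool LD
  blocks, coupled multi-allelic HLA loci, planted SNP/allele/haplotype
  effects with tag SNPs, group-correlated food liabilities, duplicates,
  admixed outliers, missingness) so every stage can be checked against
  planted ground truth.

## Worked example

Simulate a two-sampleset cohort with an HLA-DRB1*04:05 shrimp-allergy
effect (OR 1.9) tagged by a SNP at r² ≈ 0.8, run the QC funnel, the
per-set GWAS, the meta-analysis, and the RPE analysis:

```r
library(fagwas)

cfg <- sim_config(
  n_subjects_per_set = c(2000, 2000), n_snps = 300,
  n_founder_haplotypes = 1000, seed = 11,
  planted_effects = list(
    planted_effect("shrimp", 1.9, hla_locus = "DRB1", hla_allele = "04:05",
                   tag_r2 = 0.8)
  ),
  baseline_prevalence = stats::setNames(
    ifelse(food_panel()$food %in% c("shrimp", "peach"), 0.08, 0.01),
    food_panel()$food
  ),
  n_duplicate_pairs = 10, n_admixed = 5
)
cohort <- simulate_cohort(cfg)
config <- analysis_config(min_cases_per_set = 50)

qc <- variant_qc(cohort$geno, config,
                 pairs = setNames(cohort$truth$duplicates, c("id1", "id2")))
length(attr(qc, "pass_ids"))
#> [1] 197

pruned <- geno_subset(cohort$geno, variants = ld_prune(cohort$geno, 0.2))
pca <- pca_rounds(pruned, config)
all(cohort$truth$admixed %in% pca$removed)
#> [1] TRUE

pheno <- build_phenotypes(cohort$pheno, config)
pheno$eligible
#> [1] "peach"  "shrimp"

tag <- cohort$truth$tag_map$snp
runs <- lapply(c("set1", "set2"), function(s)
  logistic_gwas(cohort$geno, pheno, "shrimp", sampleset = s,
                covariates = pca$final_scores[, 1:2]))
meta <- meta_analyse(runs[[1]]$records, runs[[2]]$records)
subset(meta, id == tag,
       select = c(id, p_a, p_b, or_meta, or_lo, or_hi, p_meta))
#>         id          p_a          p_b  or_meta    or_lo    or_hi       p_meta
#> 1 snp00001 1.527798e-06 0.0001678632 1.699723 1.431364 2.018395 1.444448e-09
```

The tag SNP reaches `P = 1.5e-6` and `1.7e-4` in the two sets and pools to
OR 1.70 [1.43–2.02] at `P_meta = 1.4e-9` — the expected attenuation of the
planted OR 1.9 seen through a tag at r² ≈ 0.8. The RPE analysis then
pinpoints the allele behind the SNP signal:

```r
tab <- bin_rare(count_alleles(filter_hla_ct(cohort$hla, config),
                              pheno, "DRB1", "shrimp"))
rpe_run(tab, config)
#> <fa_rpe> locus DRB1: 2 step(s), termination: locus_nonsignificant
#>   step 0: excluded [], locus P = 2.93e-05
#>   step 1: excluded [04:05], locus P = 0.4593
```

The locus is significant, the planted 04:05 allele is the first stepwise
removal, and after removing it the locus signal is gone — the single-allele
structure is recovered exactly.

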