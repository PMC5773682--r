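---
title: "Methods: a two-sampleset food-allergy GWAS and HLA fine-mapping pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-sampleset food-allergy GWAS and HLA fine-mapping pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fagwas` re-implements, at desk scale, the analysis chain used in
questionnaire-based food-allergy genetics: quality control of array
genotypes, per-food case-control GWAS in two samplesets, bi-directional
discovery-evaluation candidate selection, inverse-variance meta-analysis,
conditional analysis with an LD-equivalent statistic, stepwise Relative
Predispositional Effects (RPE) analysis of HLA alleles and haplotypes,
eQTL-overlap gene prioritisation, and a food cross-reactivity matrix. Every
stage can be driven by a truth-annotated synthetic cohort generator, so the
whole pipeline is verifiable against planted ground truth.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions that were genuinely open.

## The statistical model

**Phenotypes.** A questionnaire asks each subject, for each of 27 foods,
whether they experienced mild or severe allergic reactions. A subject is a
*case* for a food if they answered mild or severe for it; mild and severe
reporters are pooled into a single case arm because severe reports alone
are too sparse to power an analysis (the severe flag is retained in the
data model). A subject is a *control* — shared across all foods — only if
they answered "none" for every food. Subjects reactive only to other foods
are excluded from a given food's analysis. A food is analysed only when its
case count is strictly greater than `min_cases_per_set` (default 100) in
both samplesets.

**Association.** Per variant, an additive logistic regression
`case ~ intercept + dosage + PC1 + PC2` is fitted by iteratively
reweighted least squares on per-variant complete cases, and the Wald test
of the dosage coefficient is reported. Separation or non-convergence
(|beta| > 20 or more than 25 IRLS iterations) yields `converged = FALSE`
with statistics withheld, mirroring how standard GWAS tools emit NA.
Conditional analysis adds the conditioning variant's dosage as a covariate;
a tested variant identical or perfectly collinear with the conditioning
variant is returned with `P = 1` by convention, so the LD-equivalent
statistic of a variant with itself is exactly 1.

**Two-sampleset selection and pooling.** Neither sampleset is a designated
discovery panel, so selection is bi-directional: a candidate must reach
`P <= 1e-4` in one set and `P < 0.05` with Benjamini-Hochberg FDR `< 0.2`
in the other, in either direction, with no constraint on effect-direction
concordance. The evaluation FDR universe is not uniquely determined by the
selection rule itself; the default computes it per direction over the
evaluation-arm P-values of the variants that passed discovery in the other
arm, and a `genome_wide` option is provided. Candidates are pooled by
fixed-effects inverse-variance weighting and tiered at
`p_nominal = 1.21e-7` (0.05 over an effective count of 411,521 independent
tests) and `p_strong = 4.4e-9` (the nominal cut-off further divided by the
27 foods). Both cut-offs are stored verbatim rather than recomputed because
the printed values are themselves rounded; recomputing would shift the
boundary within its own rounding error. Extremely small pooled P-values
are computed on the log scale to avoid underflow.

**LD metrics.** Two measures rank variants around a top SNP: the ordinary
squared dosage correlation r², and `r2_equiv = (Z_B - Z_B|A) / Z_A` with
`Z = -log10(P)`, which measures how much of variant B's signal disappears
after conditioning on top variant A. `r2_equiv` is deliberately not
clamped: conditioning can increase a P-value's significance, giving
negative values. P-values of zero are floored at 1e-320 before logs.
Moderate and high LD sets use the OR rule (`r² > 0.5` or `r2_equiv > 0.5`;
`> 0.8` for high), with an `equiv_only` variant for ranking work.

**RPE.** At a multi-allelic HLA locus, a 2×k chi-square of case/control
status versus allele tests the locus; if `P_locus < 0.05`, each allele is
tested by a 2×2 Pearson chi-square (no continuity correction) with an odds
ratio, the lowest-P allele is removed entirely from both arms, and the
procedure repeats until the locus is no longer significant. Removing a
category with frequency f rescales every remaining frequency by
`1/(1 - f)` exactly — the arithmetic is carried on counts, so this
identity holds to machine precision and is asserted in the tests. Alleles
with expected counts below five in either arm are collapsed into a
`"binned"` category (one merge pass plus one re-evaluation). The binned
composite is never itself selected for removal by default, because it is an
artefact of the binning rule rather than an allele; a configuration flag
can lift this. Odds ratios use the Haldane-Anscombe +0.5 correction only
when a zero cell appears.

**Haplotypes.** Haplotype phase over 2-3 HLA loci is estimated by a
standard EM over the phase configurations consistent with each unphased
genotype, pooled over cases and controls; counting is by each subject's
most probable phase (hard assignment) so the count tables stay integer and
the RPE renormalisation identity stays exact, with a fractional
(posterior-weighted) counting mode available. Haplotypes below 1%
frequency in either arm are binned. EM converges when the largest
frequency change falls below 1e-8 (cap 1000 iterations); the log-likelihood
is non-decreasing by construction.

**eQTL overlap.** For each SNP-gene pair, the relative signal strength
`RSS = -log10(P_SNP) / -log10(P_gene.min)` is computed within each eQTL
resource, with the gene minimum taken per tissue for the GTEx-like dialect
before maximising over tissues. HGVD-like records must first explain more
than 10% of expression variance (`R² > 0.1`, strictly). Candidate genes
need at least one moderate-LD SNP with RSS > 0.2 in *both* resources; the
listing table uses the OR rule, with a ≥10-tissue confidence filter applied
to the GTEx-supported side of the listing only. Whether the tissue filter
should also gate candidate status is not determinable from the selection
rules alone; here it does not, and the filter affects reporting only.

**Cross-reactivity.** `M[x, y]` is the proportion of reporters of food x
who also report food y — deliberately asymmetric, with no exclusivity
adjustment of the denominator. Heatmap ordering uses average-linkage
clustering on the symmetrised matrix `max(M, t(M))`.

## Quality control

Variants must satisfy, in *both* samplesets: call rate strictly above 99%,
MAF at least 0.01, exact Hardy-Weinberg P strictly above 1e-6, and (when
duplicate pairs exist) duplicate-pair concordance strictly above 90%. The
HWE test form is the classical two-sided exact test (sum of all
heterozygote configurations no more probable than the observed one,
conditional on allele counts), computed by a stable ratio recurrence and
verified against a full-enumeration oracle; a chi-square variant is
selectable. HWE is evaluated on all subjects of a sampleset because it is a
genotyping-quality filter applied before phenotypes exist.

PCA standardises each variant by mean 2p and SD sqrt(2p(1-p)), imputes
missing entries at the mean, and takes a singular value decomposition;
component signs are canonicalised (largest-|loading| entry positive).
Outlier removal is automated as `k` robust SDs (scaled MAD, with an SD
fallback for degenerate spread) on the top components, default `k = 6`,
iterated for three rounds; the final round's components are the GWAS
covariates. The MAD is used instead of the plain SD because a compact
cluster of genuine outliers inflates the SD enough to hide itself at any
fixed `k`. Duplicate detection uses method-of-moments IBD estimation from
IBS counts and sample allele frequencies, projected onto the simplex, with
`PI_HAT = Z1/2 + Z2 > 0.8` flagging duplicates; exact numerical parity
with any particular external implementation is not promised — the
property-level behaviour (duplicates near 1, parent-offspring near 0.5,
unrelated near 0) is what the tests pin down. LD pruning is a greedy
left-to-right scan (window 50 variants — the window and step are exposed in
configuration since no canonical value exists for them).

## The synthetic cohort generator

The generator is a first-class module: it emulates exactly the data
structure the pipeline assumes, and its truth object records everything
that was planted.

* **Founder pool.** Subjects draw two haplotypes from a founder pool.
  Within an LD block all founders carry one of a few block-wide allele
  patterns, creating within-block LD with near-zero between-block LD.
  Because allele frequencies are realised once in the pool, cohort
  frequencies inherit a founder-pool sampling variance of roughly
  `f(1-f)/n_founders` on top of subject-level noise — and a small pool
  induces cryptic relatedness (shared founders) that visibly inflates null
  test statistics. Calibration experiments therefore use pools of 2000+
  founders; the default pool of 200 is intentionally "population-like" for
  LD and IBD work.
* **HLA.** Each founder carries one allele per locus, drawn from control
  spectra of a Japanese female cohort (defaults in `hla_default_freqs()`,
  with residual mass pooled into a `99:99` code). Loci are coupled by a
  comonotone-copula mixture: the first locus anchors a latent uniform
  variable that coupled loci reuse with probability `hla_coupling`
  (defaults DQB1 0.85, DPB1 0.5). This preserves every marginal spectrum
  exactly while creating the common multi-locus haplotypes real MHC data
  has; `hla_coupled_allele()` reports which partner allele a given allele
  preferentially pairs with, which is how tests construct plantable risk
  haplotypes.
* **Tag SNPs.** A planted HLA effect can request a tag SNP at a target
  dosage r². The tag is constructed deterministically from the founder
  carrier pattern: it matches every carrier and the number of
  non-carrier matches is chosen to hit the target correlation as closely
  as the pool's granularity allows (unattainable targets fail loudly,
  naming the pool-size constraint).
* **Phenotypes.** Per food, `logit P(case) = qlogis(prevalence) +
  group liability + sum(log OR × target dosage)`. The per-subject,
  per-food-group Gaussian liability (SD default 1) induces within-group
  cross-reactivity without modelling shared epitopes; setting it to zero
  gives independent foods. Seven foods default to prevalences of 2.5-5.1%
  so they clear the eligibility rule at the default sampleset sizes
  (5751/5628); the remaining twenty default to 0.8%. Case counts per food
  are free parameters of the generator, not calibrated values. Severe
  reports are a post-hoc label on cases (default 15%) because the analysis
  pools mild and severe.
* **Artefacts.** Duplicate pairs are byte-identical copies under new ids
  (default 329 pairs); 19 admixed subjects have SNP genotypes redrawn from
  frequencies shifted 60% toward an alternative ancestry profile;
  missingness is uniform; a configurable fraction of HLA calls gets a
  call-threshold score drawn Uniform(0.3, 1) to exercise the strict
  CT > 0.5 filter.
* **eQTL tables.** Designated SNP-gene pairs get controlled RSS against a
  per-gene anchor association at P = 1e-12; null HGVD rows draw variance
  explained below 0.1 (a null SNP explains essentially none of a gene's
  expression), and HGVD covers only a quarter of SNP-gene combinations,
  emulating its sparse array positions.

What the generator does *not* emulate: realistic human LD maps and
recombination, chromosome-scale structure, imputation uncertainty, age/sex
structure (the emulated cohort is all-female), genotyping batch effects,
or true shared-epitope biology behind cross-reactivity. Passing tests
demonstrate that the statistical machinery is correct and calibrated under
the generator's assumptions, not that it would be robust to artefacts the
generator does not produce.

## Numerical choices

* All randomness flows from one integer seed through an internal
  seed-scoping helper; the caller's RNG state is never disturbed, and the
  same configuration regenerates bit-identical cohorts.
* Boundary conventions are read literally from the rules they implement:
  call rate and HWE strictly greater; MAF inclusive; CT strictly greater
  than 0.5 (a CT of exactly 0.5 is excluded); eligibility strictly more
  than 100 cases; binning strictly below an expected count of five;
  HGVD prefilter strictly above 0.1.
* LD pruning compares r² with a 1e-12 tolerance so that a threshold of
  1.0 drops exact duplicates despite floating-point correlation.
* Two-sided normal tails are computed via `pnorm(log.p = TRUE)`;
  `lambda_GC` uses the exact 1-df null median `qchisq(0.5, 1)`.
* Degenerate inputs are answered, not crashed on: monomorphic variants
  fail MAF; zero-call variants fail call rate; constant dosages return
  unconverged records; constant vectors give `NA` r²; foods with no
  reporters give `NA` cross-reactivity rows.

## Problem sizes used in the checks

The shipped test-and-acceptance runs use desk-scale designs chosen to make
each property measurable with comfortable Monte-Carlo margins: coverage of
a planted OR 1.9 (MAF 0.13) on 1000 cases / 4000 controls over 200
replicates; RPE first-removal recovery of a planted OR 2.0 allele over 100
seeds at ~1100 cases per replicate; null calibration on 5000 independent
SNPs at n = 2000 from a 2000-founder pool; eQTL designated-gene recovery
over 100 table pairs. The two worked examples (meta-analysis pooling and
RPE allele arithmetic) are recomputed from previously reported summary
tables shipped under `inst/extdata/`, and agreement is limited by the
rounding of those printed inputs — pooled odds ratios reproduce at two
decimals and pooled P-values to within 0.1 on the -log10 scale.

## Known limitations

* The IBD estimator is moment-based without finite-sample allele-frequency
  bias correction; it is accurate at the property level, not a re-creation
  of any specific tool's output.
* Hard-assignment haplotype counting understates phase uncertainty; the
  fractional mode propagates it into counts but then the count-level
  exactness assertions no longer apply.
* The discovery-evaluation FDR universe and the placement of the GTEx
  tissue filter are both under-determined by the rules they come from;
  the defaults chosen here are documented above and switchable.
* `r2_equiv` couples to dosage r² only loosely (the tests assert agreement
  within ±0.15 on average for a proxy of known r²); it is a ranking
  statistic, not an estimator of r².
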