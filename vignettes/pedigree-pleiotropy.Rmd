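---
title: "Methods: pedigree-aware polygenic risk and pleiotropy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware polygenic risk and pleiotropy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pedprs` analyses the genetic architecture of a binary, highly heritable
phenotype segregating in one extended multigenerational pedigree. This
vignette documents the statistical models, the parameter choices and their
rationale, what the synthetic-data generator does and does not emulate, and
the numerical decisions a maintainer should know about.

## Relatedness model

All association and heritability machinery conditions on the numerator
relationship matrix $A = 2\Phi$, computed from pedigree structure alone by
the recursive tabular method in generation order:

$$A_{ij} = \tfrac12\,(A_{j,\mathrm{father}(i)} + A_{j,\mathrm{mother}(i)}),
\qquad A_{ii} = 1 + \tfrac12 A_{\mathrm{father}(i),\mathrm{mother}(i)},$$

with founders unrelated and non-inbred. The diagonal is $1+f_i$, $f_i$ the
pedigree inbreeding coefficient, so consanguineous loops raise both the
diagonal and the off-diagonal entries. $A$ is used as the covariance kernel
rather than a genotype-based GRM because the pedigree is known exactly and
genotype-based kinship would absorb part of the very signal (founder-allele
sharing) under study. The test suite checks $A$ against an independent
single-locus gene-dropping IBD estimator (unique founder allele labels,
10,000 unlinked loci) and verifies positive semi-definiteness on random
pedigrees.

Two inbreeding measures are emitted side by side — pedigree $f$ and the
method-of-moments excess-homozygosity
$F = (O_\mathrm{hom} - E_\mathrm{hom})/(L - E_\mathrm{hom})$ with
$E_\mathrm{hom} = \sum_j \bigl(1 - 2p_j(1-p_j)\bigr)$ — because analyses of
homozygosity against risk scores may reasonably use either. $E_\mathrm{hom}$
uses founder-only allele frequencies: frequencies estimated over the whole
pedigree are not independent draws and would bias $F$ toward zero in large
sibships.

## Mixed-model association and heritability

The association model is

$$y = W\alpha + x\beta + g + \varepsilon, \qquad
g \sim N(0, \sigma_g^2 A), \quad \varepsilon \sim N(0, \sigma_e^2 I),$$

fitted by REML. $A = U D U^\top$ is decomposed once; in the rotated basis
the covariance is diagonal, the fixed effects and $\sigma_e^2$ are profiled
out, and the restricted likelihood is a one-dimensional function of
$\lambda = \sigma_g^2/\sigma_e^2$, maximised by bounded search on
$\log\lambda \in [\log 10^{-5}, \log 10^{5}]$ with tolerance $10^{-8}$ and
compared against the $\lambda = 0$ boundary. $\beta/\mathrm{SE}$ is referred
to the standard normal (large-sample Wald). Heritability uses the same
machinery without $x$: $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ with a
likelihood-ratio test against the boundary null using the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture.

Binary affection status is modelled on the observed 0/1 scale with this
linear mixed model; no liability-scale transformation is applied to the
estimates. Two consequences are documented rather than corrected:

* A liability simulated at $h^2 = 0.8$ yields an attenuated estimate on the
  binary scale (the worked example in the README shows ~0.6); parameter
  recovery is therefore validated on the matched (liability) scale.
* The same convention is used for the block-scan power check: ranking power
  for a single causal block is asserted on the matched scale, while the
  binary-scale scan is exercised by the pipeline and by the family-wise
  error tests.

One calibration fact shapes what the validation suite can meaningfully
assert: for an unbiased estimator with a correctly calibrated standard
error, $|\hat\beta - \beta|\le \mathrm{SE}$ holds with probability
$\approx 0.683$, not more. Recovery of the configured score effect is
therefore best judged by the mean of $\hat\beta$ across replicates (which
the acceptance script reports) rather than by per-replicate 1-SE agreement.

Covariates default to an intercept only; sex, age or ancestry columns can be
passed as a matrix but no default set is imposed, since the appropriate set
is study-specific.

## Polygenic scores

Harmonisation maps external summary statistics onto cohort ALT dosages:
effect allele = ALT keeps the sign, effect allele = REF flips it,
strand-ambiguous A/T and C/G variants and allele mismatches are dropped and
counted. Clumping is greedy: the smallest-p unclumped variant indexes a
clump and removes neighbours within 250 kb at $r^2 > 0.1$ (common PRS
defaults), with p-value ties broken by genomic position so results do not
depend on input order; $r^2$ comes from cohort dosage correlations, which is
appropriate here because the cohort is the only sample from its founder
population. The raw score is the weighted sum (not the per-variant mean);
cohort standardisation makes the distinction immaterial downstream. Missing
dosages are mean-imputed at twice the founder ALT frequency — founder-based
imputation avoids leaking case status through the imputed values.

Local scores restrict the sum to one LD block at a time. Blocks are 0-based
half-open intervals (BED convention); a 1-based variant position $p$ belongs
to a block when $\mathrm{start} \le p-1 < \mathrm{end}$. Because blocks
partition each chromosome, raw block scores decompose the raw genome-wide
score exactly (asserted to $10^{-10}$ relative error). Local scores are
standardised per block before association — the natural analogue of the
genome-wide convention; raw local scores are also kept in the result object
for users who prefer unscaled effects.

The block-wise scan fits one mixed model per non-empty block. The
Bonferroni denominator is the number of blocks actually tested, not the
nominal block count: an empty block carries no test. Variance components
are refit per block by default; a `shared_components` mode reuses the
no-score fit for speed. Married-in individuals are retained in scans (the
contrast of interest is affected versus unaffected relatives, and excluding
married-in spouses would discard informative controls); in-family-only
analyses can be run by subsetting.

## Sibling transmission disequilibrium

Within each nuclear family containing at least one affected and one
unaffected sibling, the deviation is the mean cohort-standardised score of
affected minus unaffected siblings; the test is a two-sided one-sample
t-test of the per-family deviations against zero. This sibling contrast
(rather than the proband-versus-mid-parent original) is the package's main
design choice in this module: it requires no parental genotypes and is the
natural within-family complement to the cohort-level mixed model. Fewer
than two qualifying families yields a deviation without a p-value, flagged.

## Mendelian calling and comorbidity rules

Dosages are hard-called by rounding (threshold 0.5) before calling; a
heterozygous or homozygous state predicts dominant disease, only the
homozygous state predicts recessive disease, and recessive heterozygotes
are carriers. Compound heterozygosity is out of model — phase is not
tracked at calling time — so "completely inactivated" in the
loss-of-function burden means a single homozygous LoF variant in the gene.
Founder-enrichment filtering keeps variants common internally (> 5%) and
rare in every external reference (< 2%), both thresholds configurable.

Association rules treat each individual as a transaction: one phenotype
item (one of the nested diagnostic models — narrow ⊂ broad ⊂
broad-extended — versus unaffected) plus one item per predicted Mendelian
disease. By default only predicted-affected states contribute items; a
carrier-level mode adds `carrier_*` items, since either convention is
defensible for recessive alleles. Rules are enumerated exhaustively over
single-antecedent/single-consequent pairs with exact counting; default
thresholds (support and confidence both 0.01) are deliberately low so that
weak-support comorbidity rules are not silently excluded. The Fisher
enrichment test is exact: the two-sided p is the total hypergeometric
probability of tables with point probability at most that observed, and the
reported odds ratio is the sample $ad/bc$.

## The synthetic study

The generator exists so that every stage can be validated without access to
restricted family data. From one seed it grows a pedigree from a pioneer
couple (children marry mostly married-in founders, occasionally a
same-generation relative), drops founder haplotypes through it, injects
Mendelian founder variants, simulates an external GWAS, and draws
liability-threshold phenotypes. Defaults describe the validated desk scale:

* **400 individuals, 2,000 variants on 5 chromosomes, 50 LD blocks** — all
  validation runs complete in minutes on one core; the structure (many
  blocks, several variants per block, multigenerational relatedness) is
  what matters, not the count.
* **Liability** $= c\,\mathrm{PRS}_z + a + e$ with $c = 0.4$ (standardized
  true-score effect), $\sigma_a^2 = h^2 - c^2$ (kinship-structured
  polygenic background), $\sigma_e^2 = 1 - h^2$, $h^2 = 0.8$ — a highly
  heritable phenotype with a realistic single-trait score effect. The three
  components sum to unit variance by construction (no empirical rescaling),
  so founder prevalence equals the configured $K$ exactly in expectation.
* **Prevalence** $K = 0.25$ for the broadest phenotype — a broad
  any-psychiatric-phenotype definition in a densely affected pedigree, not
  a population point prevalence of bipolar I.
* **Diagnostic categories** (BPI, BPII, MDDR, minor; proportions
  0.25/0.20/0.25/0.30 of affected) are carved from descending liability
  quantiles so the nested phenotype models hold by construction. The exact
  proportions are configuration, not estimates.
* **Pioneer risk boost** 0.3: pioneer haplotypes are enriched for risk
  alleles at causal loci, emulating ascertainment of a pedigree founded by
  high-risk individuals; this is what makes pioneer descendants
  score-enriched relative to married-in spouses and lets a pioneer-carried
  dominant variant co-segregate with affection.
* **Recombination** follows the Haldane (no-interference) map at 1 cM/Mb;
  interference is irrelevant at block scale.
* **GWAS noise**: $\hat\beta_j = \beta_j + N(0, \mathrm{SE}_j^2)$ with
  $\mathrm{SE}_j = (2p_j(1-p_j)N)^{-1/2}$, $N = 50{,}000$; half the rows
  report the REF allele as effect allele to exercise harmonisation.
* **Pleiotropy**: a second trait shares a subset of the causal blocks (with
  correlated effects) and has private causal blocks, giving the cross-trait
  overlap machinery genuine structure to find.

What the generator does **not** emulate: realistic within-block LD (variant
spacing makes most variants nearly independent, so clumping removes little),
genotyping or imputation error, ascertainment of the GWAS base cohort,
assortative mating, sex-specific maps, and phenotype misclassification.
Passing tests therefore demonstrate correctness of the machinery under the
stated model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Eigenvalues of $A$ are clipped at zero below $10^{-8}\times$ the spectral
  radius; genuinely indefinite kernels are errors.
* A kinship matrix proportional to the identity makes $\sigma_g^2$
  unidentifiable; `estimate_heritability()` refuses it explicitly, while
  association fits degrade gracefully to OLS.
* Constant predictors, empty leave-one-out remainders, thresholds passing
  zero variants, and zero-variance score standardisation are explicit
  errors or flagged degeneracies, never silent zeros.
* pTDT with identical deviations in every family reports $t = 0, p = 1$ (no
  spread) rather than NaN.
* All scan/overlap results are invariant to block and individual ordering;
  ties in the decile split are broken by stable input order.

## Known limitations

Single-kernel variance decomposition (no dominance, no shared-environment
component); no generalized (logistic) mixed model; no external-panel LD;
no X-chromosome-specific kinship; rule mining reports descriptive measures
without per-rule significance. These mirror the intended scope: a
transparent, fully testable reimplementation of the pedigree
PRS-and-pleiotropy analysis pattern at desk scale.
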