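---
title: "Trait-correlated expression with eQTL, ASE and GWAS integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-correlated expression with eQTL, ASE and GWAS integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcexpr)
```

# The analysis problem

In outbred livestock cohorts, a quantitative trait such as intramuscular
fat percentage is measured on a few hundred animals together with chip
genotypes, a bulk RNA-seq TPM matrix and allele-level read counts at
heterozygous sites. GWAS at this sample size has limited power and poor
resolution, so candidate genes are prioritized by combining three
independent lines of evidence: genes whose expression tracks the trait,
markers that regulate those genes (eQTL, allele-specific expression), and
markers associated with the trait itself. `tcexpr` implements that
workflow as a single pipeline over five standard inputs: a gene x sample
TPM matrix, a SNP x sample dosage matrix (VCF or TSV), a sample table
(sex, slaughter batch, boar, age, phenotype), a per-site allele read-count
table, and gene/SNP position annotations.

# Models and procedures

## Covariate adjustment

Both the phenotype and each gene's log2-transformed expression are
corrected with the fixed linear model

$$Y = G + Ba + Bo + A + e$$

where $G$ is sex, $Ba$ slaughter batch, $Bo$ boar (sire), $A$ age in days,
and $e$ the residual carried forward. Categorical factors are one-hot
encoded with the first level dropped; the design must be full rank after
encoding, and an aliased column aborts the fit with its name. Mixed models
with a relationship-matrix random effect are deliberately out of scope: in
an F1 cross the genomic relationship structure is close to the fixed sire
term, and fitting both over-corrects. Samples missing the phenotype or any
covariate are dropped listwise with a logged count; a factor level
observed in fewer than 3 samples triggers a warning because its effect is
essentially unidentifiable.

Expression enters after two steps with strict inequalities: a gene is kept
when its TPM exceeds 0.01 in strictly more than 90% of samples (a gene at
exactly 90% is dropped), then transformed as $\log_2(\mathrm{TPM} + 1)$.
The offset is a choice: the filter already removes near-zero genes, the
+1 pseudocount keeps the transform bounded below by 0 and is the common
default; it is configurable (`log_offset`).

## Trait-gene correlation and permutation FDR

Pearson's $r$ is computed between residual vectors, with the two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.
Significance is judged by an empirical FDR rather than BH because the
trait-correlation screen is the pipeline's primary discovery step and the
expression residuals are strongly inter-correlated.

The permutation scheme permutes the *phenotype* residual vector once per
permutation, jointly for all genes. This preserves the gene-gene
correlation structure of the expression matrix under the null and costs
one matrix product per permutation; per-gene independent permutation would
give the same marginal null at thousands of times the cost. With $B$
permutations (default 10,000) the FDR at a gene with observed p-value $t$
is the pooled-null estimate

$$\widehat{FDR}(t) = \frac{\frac{1}{B}\sum_b \#\{p^{(b)} \le t\}}{\#\{p^{obs} \le t\}},$$

made monotone non-decreasing in $t$ (step-up from the largest p-value) and
clipped to $[10^{-5}, 1]$. The pooled estimator is used instead of
per-gene permutation p-values because $B$ permutations cannot resolve a
per-gene p-value below $1/B$, while the pooled null contains
$B \times n_{genes}$ draws; the $10^{-5}$ floor caps how extreme an
empirical FDR is ever reported. Internally the permuted p-value counting
happens in $|r|$-space using the exact null relation
$r^2 \sim \mathrm{Beta}(\tfrac12, \tfrac{n-2}{2})$, which avoids
recomputing t-distribution tails $B \times n_{genes}$ times; the
equivalence is exact, not an approximation. The default significance
threshold is permutation FDR $\le 0.01$. Genes with zero residual variance
are flagged and excluded from FDR estimation rather than silently given
$r = 0$.

## GWAS and eQTL association

Both association analyses share one OLS kernel: the response (normalized
phenotype, or a gene's log2 expression) is regressed on allele dosage
(0/1/2, additive coding, no dominance term) plus the covariates, and the
dosage slope is t-tested. The kernel is computed by the
Frisch–Waugh–Lovell route — response and dosages are residualized on the
design, and the slope of the residual regression equals the full-model
slope — with degrees of freedom $n - p - 1$ for a $p$-column design, so
the result is numerically identical to refitting the full model per SNP
(the tests verify this against explicit normal-equation fits at 1e-10).
Alongside the slope the correlation-scale statistic
$r = \mathrm{sign}(t)\sqrt{t^2/(t^2+df)}$ is reported, which is what
MatrixEQTL-style tools print. Missing dosages are mean-imputed per SNP
*inside* the association only — the stored genotype matrix keeps its NAs —
and monomorphic SNPs are skipped with a flag.

The association design adds the top five principal components of the
column-standardized dosage matrix (SVD on mean-imputed, polymorphic SNPs)
and age to the categorical covariates. "Normalized" phenotype defaults to
the covariate-residualized, variance-standardized trait; a rank-based
inverse-normal transform is available (`gwas_normalize =
"inverse_normal"`) since normalization conventions differ between tools.

A SNP-gene pair is *cis* when the SNP lies on the gene's chromosome and
its distance to the gene body interval $[start, end]$ is at most 1 Mb
(inclusive boundary; distance 0 inside the gene; strand ignored, the
window is symmetric). Everything else is *trans*. The 1 Mb default is the
common chip-density choice and is configurable (`cis_window`). eQTL FDR is
Benjamini–Hochberg *within scope* — cis and trans p-values adjusted
separately — because the two hypothesis families have very different sizes
and prior probabilities. GWAS uses two thresholds: suggestive
$p \le 10^{-3}$ and genome-wide Bonferroni $0.05/n_{SNPs}$ (for a
36,045-SNP chip: 1.39e-6).

## Allele-specific expression

At each heterozygous site (dosage exactly 1) with at least `min_depth`
(default 10) reads, the reference read fraction is tested with an exact
two-sided binomial test against $p_0 = 0.5$; BH adjustment runs across the
samples of each site, and a sample is called imbalanced at site FDR 0.05.
Genes summarize as: `het_n` heterozygotes tested at the reporting site,
`ase_n` of them imbalanced, `ratio = ase_n/het_n`. The reporting site is
the site in the gene body with the most tested heterozygotes, ties broken
by smaller median site p-value, then site id. Reference-mapping bias
correction is upstream of this package (N-masked alignment); as a partial
substitute the null reference fraction `ase_p0` is exposed, so a global
bias estimate can replace 0.5. For gene-set overlaps, an "ASE gene" is one
with at least one imbalanced heterozygote at its reporting site; under the
null this mislabels a gene with probability roughly the site FDR, which
the calibration suite bounds.

## Preranked GSEA

Genes are ranked by their trait correlation coefficient and each set is
scored with the weighted Kolmogorov–Smirnov running sum: hits increment by
$|r|^{w}$ (default $w = 1$) normalized by the hit total, misses decrement
by $1/(N - N_h)$; the enrichment score is the extremum. The null permutes
*gene labels* (set membership redrawn uniformly, size preserved) rather
than phenotypes, the standard choice for preranked input where no
sample-level data is available to the enrichment step.
$NES = ES/\mathrm{mean}(|ES_{null}|)$ over same-sign null scores; FDR
follows the usual pooled positive/negative procedure with significance at
FDR < 0.25, the conventional GSEA default. Degenerate sets (no overlap
with the ranking, or covering it entirely) are errors, not silent zeros.

## Integration

Overlap sets are exact intersections with deterministically sorted
membership lists: correlated ∩ cis-eQTL targets, correlated ∩ ASE genes,
the three-way intersection, and correlated ∩ *specific-trans* genes
(significant trans signal and no significant cis signal). A
SNP-gene-trait *triple* requires one and the same marker to pass all
three filters — correlation FDR $\le 0.01$ for the gene, eQTL FDR < 0.05
for the (SNP, gene) pair, GWAS $p \le 10^{-3}$ for the SNP. The eQTL
cutoff of 0.05 (strict `<`) is the package's choice for a secondary,
already-targeted test family; all three thresholds are configurable. The
identical-marker rule (rather than LD-linked markers) keeps the join exact
and auditable; with chip densities this is conservative. Component
statistics in a triple row are copied unchanged from the upstream tables,
so every number is traceable. Near a lead GWAS SNP the nearest
trait-correlated gene is reported when its interval distance is at most
2 Mb, ties broken by smaller correlation FDR then gene id.

# The synthetic-data generator

`simulate_population()` emulates the target study design: 189 animals by
default, sex (2 levels), slaughter batch (4), boar (8 sires), slaughter
age uniform on 210 ± 6 days, a percent-scale phenotype centred at 3.35,
and Hardy–Weinberg genotypes at per-SNP MAF drawn from (0.05, 0.5).
Planted effects are all recorded in a truth table:

* *Trait-correlated genes* (default 1.5% of genes, matching the observed
  ~212/13,450 proportion) are built so their covariate-adjusted partial
  correlation with the trait equals a drawn $\rho$ with magnitude in
  (0.20, 0.37) — the band reported in such cohorts — and random sign: the
  gene residual is $\rho z + \sqrt{1-\rho^2}\,w$ scaled by the residual
  SD, where $z$ is the standardized non-covariate phenotype component.
* *cis-eQTLs* shift log2 expression by `cis_beta` (default 1) per dosage
  unit of a SNP relocated within 50 kb of the gene; *trans-eQTLs* do the
  same from a SNP on another chromosome.
* *QTLs* either act directly on the phenotype or — for the first
  `n_mediated` of them — through a cis gene's expression, creating a true
  SNP-gene-trait mediation chain. The genetic component is rescaled so it
  explains `qtl_h2` of the phenotype's non-covariate variance.
* *ASE genes* receive an exonic heterozygous site whose reads are binomial
  with reference fraction `ase_imbalance` (default 0.8) at Poisson depth
  `ase_depth` (default 30); additional null exonic genes get balanced
  sites so false-positive behaviour is measurable. Allele counts exist
  only where dosage is 1.
* Covariate coefficients for the phenotype and for every gene are drawn
  once and recorded, so residualization has a known answer.

SNPs are independent by default — linkage disequilibrium is irrelevant to
the per-marker statistics — with an optional block-LD mode (adjacent-SNP
copying within blocks) for cis-window integration tests. What the
generator does **not** emulate: read-level sequencing noise and mapping
bias, population/kinship structure, LD with ungenotyped causal variants,
batch-by-expression interactions, and heavy-tailed TPM distributions.
Passing tests on this generator therefore demonstrate the statistical
machinery (calibration, recovery, thresholds, determinism), not robustness
to those real-data artifacts.

# Numerical choices and degenerate inputs

* Residual orthogonality to the design is maintained to $10^{-8}$
  (scaled); QR decomposition, not explicit normal equations, does the
  fitting.
* Correlations are clamped to $[-1, 1]$ before p-value computation;
  $|r| = 1$ returns $p = 0$ exactly.
* Zero-variance genes/SNPs: flagged and excluded (correlation, FDR,
  association), never silently imputed.
* Permutation streams are fully determined by the mandatory seed; the same
  config and seed reproduce every output byte-identically.
* Serialized p-values/FDRs are printed in scientific notation with 3
  significant digits; this formatting round-trips exactly.
* Empty stages (no significant genes, no coverage) produce header-only
  tables and `NULL`/empty returns, not errors.

# Problem sizes used by the test and acceptance suites

The calibration suite runs 20 null simulations at n = 200 with 2,000
genes and 2,000 SNPs; recovery suites use 20–25 seeds at n = 189–200 with
300–500 genes/SNPs and 300–1,000 permutations per stage. These sizes give
stable Monte-Carlo estimates (binomial SE below ~0.01 on the pooled
fractions) while keeping a full run in minutes on one core. The
mediated-triple scenario plants a single major QTL at `qtl_h2 = 0.4` —
the upper end of heritability reported for fat-deposition traits — which
a power calculation puts at ~95% joint recovery through all three
filters at n = 200; weaker plantings are exercised by the per-stage
suites instead.

# Known limitations

* The permutation FDR is a pooled-null estimator: it assumes
  exchangeability of genes under the null and reports a set-level rate,
  so per-gene values below 1e-5 are never claimed.
* The ASE module starts from allele counts; it cannot correct
  reference-mapping bias beyond a global `ase_p0`.
* The eQTL scan is exhaustive (all pairs); at chip x transcriptome scale
  this is memory-bound — restrict with the `pairs` argument for larger
  inputs.
* Integration is set intersection, not colocalization or Mendelian
  randomization; a triple is evidence of co-occurrence at one marker, not
  a causal estimate.
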