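# tcexpr

Integrative candidate-gene analysis for quantitative traits measured
alongside bulk RNA-seq and SNP genotypes — the setting of livestock
meat-quality studies such as intramuscular fat (IMF) mapping in pig
populations, where a few hundred animals have a phenotype, chip genotypes,
a TPM expression matrix and per-site allele read counts.

GWAS alone rarely pins down causal genes in such cohorts. `tcexpr`
implements the complementary strategy of *trait-correlated expression*
combined with regulatory-variant evidence, as one reusable, tested
pipeline:

1. **Trait–gene correlation.** Phenotype and log2 expression are
   pre-adjusted with the fixed linear model `Y = G + Ba + Bo + A + e`
   (sex, slaughter batch, boar, age); Pearson correlations between the
   residuals are tested with `t = r·√((n−2)/(1−r²))`, and significance is
   assessed by an empirical FDR from joint permutations of the phenotype
   (default 10,000), floored at 1e-5.
2. **Association.** GWAS (dosage → normalized phenotype) and cis/trans
   eQTL mapping (dosage → log2 expression) share one OLS kernel with
   sex/batch/boar/age plus the top five genotype principal components as
   covariates; the dosage slope is t-tested and reported with
   `r = sign(t)·√(t²/(t²+df))`. Bonferroni (`0.05/n_SNPs`) and per-scope
   Benjamini–Hochberg FDR set the thresholds.
3. **Allele-specific expression.** Heterozygous sites with ≥ 10 reads get
   exact binomial tests of the reference fraction against 0.5, BH-adjusted
   across samples per site; genes are summarized as Het (tested
   heterozygotes), ASE (imbalanced ones) and ratio = ASE/Het.
4. **Preranked GSEA.** Genes ranked by correlation coefficient; weighted
   Kolmogorov–Smirnov enrichment scores with gene-label permutation NES
   and the standard pooled positive/negative FDR (significance at
   FDR < 0.25).
5. **Integration.** Set overlaps (correlated ∩ cis-eQTL ∩ ASE, correlated
   ∩ specific-trans), SNP–gene–trait triple candidates (one marker passing
   correlation FDR ≤ 0.01, eQTL FDR < 0.05 and GWAS p ≤ 1e-3
   simultaneously), and the nearest trait-correlated gene to the lead
   GWAS SNP.

A first-class synthetic-data generator (`sim_config()`,
`simulate_population()`) emulates the study design — 189 animals,
sex/batch/boar covariates, 210 ± 6 day slaughter age, a percent-scale
phenotype — with planted, recorded effects, so the whole pipeline is
testable end to end without any external data.

## Worked example

The numbered drivers under `analysis/` run the whole study on simulated
data (`Rscript analysis/01_simulate.R` … `06_integrate.R`). The simulated
cohort plants 30 trait-correlated genes (|r| 0.20–0.37), 10 cis-eQTLs,
5 trans-eQTLs, 5 ASE genes (reference fraction 0.8) and one major QTL that
acts on the trait through a cis gene's expression. Output from a full run:

```
15 genes significantly correlated with the trait (permutation FDR <= 0.01)
  2 negative, 13 positive; |r| range 0.28-0.62
  13 of 30 planted trait-correlated genes recovered
...
eQTL: 9 cis-target genes, 6 specific-trans genes (BH FDR < 0.05)
  9 of 10 planted cis pairs recovered
...
1 SNP-gene-trait triple(s) (cor FDR <= 0.01, eQTL FDR < 0.05, GWAS p <= 1e-3):
  snp_id gene_id   cor    cor_p cor_fdr eqtl_r   eqtl_p eqtl_fdr type gwas_r   gwas_p
 rs00840   G1880 0.617 3.18e-21   1e-05  0.524 1.54e-13 1.73e-10  cis   0.25 0.000952
planted mediated pair rs00840-G1880 recovered: TRUE
```

Reading the triple row: gene G1880's residual expression correlates with
the trait (r = 0.62, permutation FDR at the 1e-5 floor), marker rs00840 is
a cis-eQTL for G1880 (r = 0.52, FDR 1.7e-10) and the same marker
associates with the trait itself (p = 9.5e-4) — exactly the planted
mediation chain. Genes with |r| ≈ 0.20 planted at the edge of detectability
are only partly recovered at n = 189, which mirrors how such cohorts behave.

The same pipeline runs from files (VCF/TSV) via `run_pipeline()`:

```r
library(tcexpr)
res <- run_pipeline(list(
  seed = 1, out_dir = "out",
  paths = list(genotypes = "genotypes.vcf", expression = "expression.tsv",
               samples = "samples.tsv", annotation = "annotation.tsv",
               allele_counts = "allele_counts.tsv"),
  thresholds = list(cor_n_perm = 10000)))
```

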