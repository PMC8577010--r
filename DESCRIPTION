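Package: tcexpr
Title: Trait-Correlated Expression, eQTL, ASE and GWAS Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative candidate-gene analysis pipeline for quantitative
    traits measured alongside bulk RNA-seq and SNP genotypes. Implements
    covariate-adjusted trait-expression Pearson correlation with a
    permutation-based false discovery rate, linear-model association for GWAS
    and cis/trans eQTL mapping with genotype principal components,
    allele-specific expression summarization from heterozygous read counts,
    preranked gene-set enrichment, and SNP-gene-trait triple integration for
    candidate-gene prioritization. Includes a synthetic-data generator with
    planted, recorded effects so the whole pipeline is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
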