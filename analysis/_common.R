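# shared paths and loaders for the numbered analysis drivers
suppressPackageStartupMessages(library(tcexpr))

DATA_DIR <- "results/analysis/data"
OUT_DIR <- "results/analysis"
SEED <- 20260923L

dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

# the simulated study: 189 animals, 2000 genes, 2000 chip SNPs, planted
# trait-correlated genes, cis/trans eQTLs, ASE genes, and one major QTL
# acting on the trait through a cis gene's expression (a full
# SNP-gene-trait triple)
study_config <- function() {
  sim_config(n_samples = 189, n_genes = 2000, n_snps = 2000,
             n_qtl = 1, n_mediated = 1, qtl_h2 = 0.4,
             maf_range = c(0.1, 0.5), seed = SEED)
}

load_study <- function() {
  stopifnot(dir.exists(DATA_DIR))
  gt <- read_genotypes(file.path(DATA_DIR, "genotypes.vcf"), dialect = "vcf")
  list(genotypes = gt,
       expression = read_expression(file.path(DATA_DIR, "expression.tsv")),
       samples = read_sample_table(file.path(DATA_DIR, "samples.tsv")),
       annotation = read_gene_annotation(file.path(DATA_DIR, "annotation.tsv")),
       allele_counts = read_allele_counts(file.path(DATA_DIR, "allele_counts.tsv")),
       truth = utils::read.delim(file.path(DATA_DIR, "truth_effects.tsv")))
}

# filter + log2 + covariate residualization, shared by several drivers
prepare_residuals <- function(dat) {
  lg <- log2_transform(filter_expressed(dat$expression))
  des <- suppressWarnings(build_design(dat$samples))
  er <- residualize_matrix(lg[, des$sample_ids, drop = FALSE], des)
  ph <- residualize(dat$samples$phenotype[match(des$sample_ids,
                                                dat$samples$sample_id)],
                    des)$residuals
  list(lg = lg, design = des, expr_resid = er, pheno_resid = ph)
}

save_table <- function(df, name) {
  utils::write.table(df, file.path(OUT_DIR, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
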