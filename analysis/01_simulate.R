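#!/usr/bin/env Rscript
# Generate the synthetic study population used by every later step:
# genotypes, covariates, phenotype, expression and allele counts, with every
# planted effect recorded in a truth table.
source("analysis/_common.R")

cfg <- study_config()
sim <- simulate_population(cfg)
write_simulation(sim, DATA_DIR)

eff <- sim$truth$effects
cat(sprintf("simulated %d samples, %d genes, %d SNPs (seed %d)\n",
            cfg$n_samples, cfg$n_genes, cfg$n_snps, cfg$seed))
cat("planted effects by kind:\n")
print(table(eff$kind))
cat(sprintf("phenotype: mean %.2f, sd %.2f (IMF-like percent scale)\n",
            mean(sim$samples$phenotype), sd(sim$samples$phenotype)))
cat(sprintf("allele-count rows at heterozygous exonic sites: %d\n",
            nrow(sim$allele_counts)))
cat(sprintf("data written under %s\n", DATA_DIR))
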