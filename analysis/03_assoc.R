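#!/usr/bin/env Rscript
# Linear-model association: GWAS of the normalized phenotype and cis/trans
# eQTL mapping, both with sex/batch/boar/age plus the top five genotype PCs.
source("analysis/_common.R")

dat <- load_study()
pr <- prepare_residuals(dat)
pcs <- genotype_pcs(dat$genotypes, k = 5)
des <- suppressWarnings(build_design(dat$samples, extra = pcs))
gt <- dat$genotypes
gt$dosage <- gt$dosage[, des$sample_ids]

## GWAS
ph <- residualize(dat$samples$phenotype[match(des$sample_ids,
                                              dat$samples$sample_id)],
                  des)$residuals
gwas <- linear_assoc(as.numeric(scale(ph)), gt, des)
gwas$chrom <- gt$map$chrom[match(gwas$snp_id, gt$map$snp_id)]
gwas$pos <- gt$map$pos[match(gwas$snp_id, gt$map$snp_id)]
save_table(gwas, "gwas")
thr <- bonferroni_threshold(0.05, sum(!gwas$skipped))
cat(sprintf("GWAS: %d SNPs tested; genome-wide threshold %s\n",
            sum(!gwas$skipped), format_sci3(thr)))
cat(sprintf("  %d SNPs at p <= 1e-3; %d genome-wide significant\n",
            sum(gwas$p <= 1e-3, na.rm = TRUE),
            sum(gwas$p <= thr, na.rm = TRUE)))
lead <- gwas[which.min(gwas$p), ]
cat(sprintf("  lead SNP %s (chr%s:%d, p = %s)\n",
            lead$snp_id, lead$chrom, lead$pos, format_sci3(lead$p)))

## eQTL: all pairs, BH within cis and trans scopes
lg <- pr$lg
eq <- eqtl_assoc(lg[, des$sample_ids, drop = FALSE], gt, des)
si <- match(eq$snp_id, gt$map$snp_id)
gi <- match(eq$gene_id, dat$annotation$gene_id)
eq$type <- classify_cis_trans(gt$map$chrom[si], gt$map$pos[si],
                              dat$annotation[gi, ], window = 1e6)
eq$fdr <- NA_real_
for (tp in c("cis", "trans")) {
  rows <- which(eq$type == tp & !is.na(eq$p))
  eq$fdr[rows] <- bh_fdr(eq$p[rows])
}
sig <- eq[!is.na(eq$fdr) & eq$fdr < 0.05, ]
save_table(sig, "eqtl_significant")
cis_genes <- unique(sig$gene_id[sig$type == "cis"])
trans_genes <- setdiff(unique(sig$gene_id[sig$type == "trans"]), cis_genes)
cat(sprintf("eQTL: %d cis-target genes, %d specific-trans genes (BH FDR < 0.05)\n",
            length(cis_genes), length(trans_genes)))
truth_cis <- dat$truth[dat$truth$kind == "cis-eQTL", ]
hit <- sum(paste(truth_cis$snp_id, truth_cis$gene_id) %in%
             paste(sig$snp_id, sig$gene_id))
cat(sprintf("  %d of %d planted cis pairs recovered\n", hit, nrow(truth_cis)))
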