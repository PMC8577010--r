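#!/usr/bin/env Rscript
# Integration: overlap of trait-correlated genes with eQTL/ASE gene sets,
# SNP-gene-trait triple candidates, and the nearest correlated gene to the
# lead GWAS SNP.
source("analysis/_common.R")

dat <- load_study()
cor_tab <- utils::read.delim(file.path(OUT_DIR, "correlation.tsv"))
eq <- utils::read.delim(file.path(OUT_DIR, "eqtl_significant.tsv"))
gwas <- utils::read.delim(file.path(OUT_DIR, "gwas.tsv"))
ase <- utils::read.delim(file.path(OUT_DIR, "ase_genes.tsv"))

correlated <- cor_tab$gene_id[cor_tab$significant]
cis_genes <- unique(eq$gene_id[eq$type == "cis"])
trans_specific <- setdiff(unique(eq$gene_id[eq$type == "trans"]), cis_genes)
ase_genes <- ase$gene_id[ase$ase_n >= 1]

ov <- overlap_sets(correlated, cis_genes, ase_genes, trans_specific)
save_table(data.frame(set = names(ov$counts), n = as.integer(ov$counts),
                      members = vapply(ov$members, paste, character(1),
                                       collapse = "/")),
           "overlaps")
cat("overlap counts (trait-correlated genes vs eQTL/ASE sets):\n")
print(ov$counts)

triples <- triple_candidates(cor_tab, eq, gwas)
save_table(triples, "triples")
cat(sprintf("\n%d SNP-gene-trait triple(s) (cor FDR <= 0.01, eQTL FDR < 0.05, GWAS p <= 1e-3):\n",
            nrow(triples)))
if (nrow(triples)) print(triples, row.names = FALSE, digits = 3)
med <- dat$truth[dat$truth$kind == "QTL" & !is.na(dat$truth$gene_id), ]
cat(sprintf("planted mediated pair %s-%s recovered: %s\n", med$snp_id, med$gene_id,
            any(triples$snp_id == med$snp_id & triples$gene_id == med$gene_id)))

lead <- gwas[which.min(gwas$p), ]
nearest <- nearest_correlated_gene(lead$chrom, lead$pos, dat$annotation,
                                   cor_tab[cor_tab$significant, ])
if (!is.null(nearest)) {
  save_table(nearest, "nearest_gene")
  cat(sprintf("\nnearest trait-correlated gene to lead SNP %s: %s (%.2f Mb away)\n",
              lead$snp_id, nearest$gene_id, nearest$distance / 1e6))
} else {
  cat("\nno trait-correlated gene within 2 Mb of the lead SNP\n")
}
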