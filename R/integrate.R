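#' Overlaps between trait-correlated genes and eQTL/ASE gene sets
#'
#' Exact set intersections of the trait-correlated genes with cis-eQTL
#' target genes, ASE genes and specific-trans-eQTL genes (trans signal and
#' no cis signal), with deterministic sorted membership lists.
#'
#' @param correlated,cis_genes,ase_genes,trans_genes character vectors of
#'   gene ids in a shared namespace
#' @return list with `counts` (named integer vector) and `members` (named
#'   list of sorted gene id vectors) for: correlated_cis, correlated_ase,
#'   correlated_cis_ase (three-way), correlated_trans
#' @export
overlap_sets <- function(correlated, cis_genes, ase_genes, trans_genes) {
  members <- list(
    correlated_cis = sort(intersect(correlated, cis_genes)),
    correlated_ase = sort(intersect(correlated, ase_genes)),
    correlated_cis_ase = sort(Reduce(intersect, list(correlated, cis_genes, ase_genes))),
    correlated_trans = sort(intersect(correlated, trans_genes))
  )
  list(counts = vapply(members, length, integer(1)), members = members)
}

#' SNP-gene-trait triple candidates
#'
#' Joins the three upstream result tables on the *same* marker: a
#' (SNP, gene) pair qualifies when the gene passes the correlation FDR
#' threshold, the pair passes the eQTL FDR threshold, and the SNP passes the
#' GWAS p threshold. Component statistics are copied byte-identically from
#' the upstream tables.
#'
#' @param cor_res correlation table (gene_id, r, p, fdr_perm)
#' @param eqtl_res eQTL table (snp_id, gene_id, r_assoc, p, fdr, type)
#' @param gwas_res GWAS table (snp_id, r_assoc, p)
#' @param cor_fdr correlation significance threshold, default 0.01
#' @param eqtl_fdr eQTL FDR threshold, default 0.05 (strict `<`)
#' @param gwas_p GWAS p threshold, default 1e-3 (`<=`)
#' @return data.frame ordered by gene then GWAS p: snp_id, gene_id,
#'   cor (r), cor_p, cor_fdr, eqtl_r, eqtl_p, eqtl_fdr, type, gwas_r, gwas_p
#' @export
triple_candidates <- function(cor_res, eqtl_res, gwas_res,
                              cor_fdr = 0.01, eqtl_fdr = 0.05, gwas_p = 1e-3) {
  if (is.null(cor_res)) stopf("missing upstream table: correlation")
  if (is.null(eqtl_res)) stopf("missing upstream table: eQTL")
  if (is.null(gwas_res)) stopf("missing upstream table: GWAS")
  need_cor <- c("gene_id", "r", "p", "fdr_perm")
  need_eqtl <- c("snp_id", "gene_id", "r_assoc", "p", "fdr", "type")
  need_gwas <- c("snp_id", "r_assoc", "p")
  if (!all(need_cor %in% names(cor_res))) stopf("correlation table lacks required columns")
  if (!all(need_eqtl %in% names(eqtl_res))) stopf("eQTL table lacks required columns")
  if (!all(need_gwas %in% names(gwas_res))) stopf("GWAS table lacks required columns")
  cor_ok <- cor_res[!is.na(cor_res$fdr_perm) & cor_res$fdr_perm <= cor_fdr, ]
  eqtl_ok <- eqtl_res[!is.na(eqtl_res$fdr) & eqtl_res$fdr < eqtl_fdr, ]
  gwas_ok <- gwas_res[!is.na(gwas_res$p) & gwas_res$p <= gwas_p, ]
  cor_ok <- data.frame(gene_id = cor_ok$gene_id, cor = cor_ok$r,
                       cor_p = cor_ok$p, cor_fdr = cor_ok$fdr_perm,
                       stringsAsFactors = FALSE)
  eqtl_ok <- data.frame(snp_id = eqtl_ok$snp_id, gene_id = eqtl_ok$gene_id,
                        eqtl_r = eqtl_ok$r_assoc, eqtl_p = eqtl_ok$p,
                        eqtl_fdr = eqtl_ok$fdr, type = eqtl_ok$type,
                        stringsAsFactors = FALSE)
  gwas_ok <- data.frame(snp_id = gwas_ok$snp_id, gwas_r = gwas_ok$r_assoc,
                        gwas_p = gwas_ok$p, stringsAsFactors = FALSE)
  j <- merge(eqtl_ok, cor_ok, by = "gene_id")
  j <- merge(j, gwas_ok, by = "snp_id")
  out <- j[, c("snp_id", "gene_id", "cor", "cor_p", "cor_fdr",
               "eqtl_r", "eqtl_p", "eqtl_fdr", "type", "gwas_r", "gwas_p"),
           drop = FALSE]
  out <- out[order(out$gene_id, out$gwas_p, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nearest trait-correlated gene to a lead GWAS SNP
#'
#' Among trait-correlated genes on the lead SNP's chromosome, returns the
#' one minimizing distance from the SNP to the gene body interval, if that
#' distance is at most `max_dist`. Ties are broken by smaller correlation
#' FDR, then lexicographic gene id.
#'
#' @param lead_chrom,lead_pos lead SNP coordinates
#' @param anno a [gene_annotation()] table
#' @param correlated data.frame (gene_id, fdr_perm) of trait-correlated genes
#' @param max_dist maximum distance in bp, default 2e6
#' @return one-row data.frame (gene_id, distance, fdr_perm) or NULL when no
#'   gene qualifies
#' @export
nearest_correlated_gene <- function(lead_chrom, lead_pos, anno, correlated,
                                    max_dist = 2e6) {
  anno <- gene_annotation(anno)
  cand <- anno[anno$chrom == as.character(lead_chrom) &
                 anno$gene_id %in% correlated$gene_id, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  d <- interval_distance(lead_pos, cand$start, cand$end)
  keep <- d <= max_dist
  if (!any(keep)) return(NULL)
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  fdr <- correlated$fdr_perm[match(cand$gene_id, correlated$gene_id)]
  ord <- order(d, fdr, cand$gene_id)
  data.frame(gene_id = cand$gene_id[ord[1]], distance = d[ord[1]],
             fdr_perm = fdr[ord[1]], stringsAsFactors = FALSE)
}
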