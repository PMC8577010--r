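#' Exact binomial test for allelic imbalance at one site
#'
#' Two-sided exact binomial test of the reference read count against a null
#' reference fraction `p0` (0.5 unless a global reference-mapping bias
#' estimate is supplied).
#'
#' @param ref_count,alt_count reference/alternate allele read counts
#' @param p0 null reference-allele fraction, default 0.5
#' @return list with `ref_fraction` and `p`; NULL if total coverage is 0
#' @export
ase_site_test <- function(ref_count, alt_count, p0 = 0.5) {
  tot <- ref_count + alt_count
  if (tot == 0) return(NULL)
  list(ref_fraction = ref_count / tot,
       p = stats::binom.test(ref_count, tot, p = p0)$p.value)
}

#' Per-site ASE calls across samples
#'
#' Tests every (SNP, sample) pair with coverage at least `min_depth` for
#' allelic imbalance and flags significant sites after Benjamini-Hochberg
#' adjustment across the samples of each SNP.
#'
#' @param counts allele count table (see [allele_count_table()])
#' @param gt optional [genotype_matrix()]; when given, only pairs with
#'   dosage 1 (heterozygotes) are tested and others are dropped with a message
#' @param min_depth minimum total reads to test a site, default 10
#' @param p0 null reference fraction, default 0.5
#' @param site_fdr BH threshold within each SNP's samples, default 0.05
#' @return data.frame: snp_id, sample_id, ref_count, alt_count, ref_fraction,
#'   p, fdr, is_ase, tested (FALSE when below min_depth)
#' @export
ase_calls <- function(counts, gt = NULL, min_depth = 10, p0 = 0.5,
                      site_fdr = 0.05) {
  counts <- allele_count_table(counts)
  if (!is.null(gt)) {
    i <- match(counts$snp_id, rownames(gt$dosage))
    j <- match(counts$sample_id, colnames(gt$dosage))
    known <- !is.na(i) & !is.na(j)
    het <- known & gt$dosage[cbind(i, j)] %in% 1
    if (any(!het))
      message(sprintf("dropped %d allele-count row(s) not at heterozygous sites",
                      sum(!het)))
    counts <- counts[het, , drop = FALSE]
  }
  tot <- counts$ref_count + counts$alt_count
  tested <- tot >= min_depth
  p <- rep(NA_real_, nrow(counts))
  idx <- which(tested)
  p[idx] <- vapply(idx, function(k) {
    stats::binom.test(counts$ref_count[k], tot[k], p = p0)$p.value
  }, numeric(1))
  out <- counts
  out$ref_fraction <- ifelse(tot > 0, counts$ref_count / tot, NA_real_)
  out$p <- p
  out$tested <- tested
  out$fdr <- rep(NA_real_, nrow(out))
  for (s in unique(out$snp_id[tested])) {
    rows <- which(out$snp_id == s & tested)
    out$fdr[rows] <- bh_fdr(out$p[rows])
  }
  out$is_ase <- !is.na(out$fdr) & out$fdr <= site_fdr
  out
}

#' Summarize ASE per gene (Het / ASE / ratio)
#'
#' Assigns tested sites to genes by position (SNP inside the gene body),
#' picks one reporting site per gene — the site with the most heterozygotes
#' with sufficient coverage, ties broken by the smaller median site p-value —
#' and reports: `het_n` (heterozygotes tested), `ase_n` (those with a
#' significant imbalance after per-site BH adjustment) and
#' `ratio = ase_n / het_n`.
#'
#' @param calls output of [ase_calls()]
#' @param gt a [genotype_matrix()] providing SNP positions
#' @param anno a [gene_annotation()] table
#' @return data.frame: gene_id, snp_id, het_n, ase_n, ratio; genes with no
#'   tested heterozygote are excluded
#' @export
summarize_gene_ase <- function(calls, gt, anno) {
  anno <- gene_annotation(anno)
  map <- gt$map
  tested <- calls[calls$tested, , drop = FALSE]
  if (nrow(tested) == 0)
    return(data.frame(gene_id = character(0), snp_id = character(0),
                      het_n = integer(0), ase_n = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  pos <- map$pos[match(tested$snp_id, map$snp_id)]
  chrom <- map$chrom[match(tested$snp_id, map$snp_id)]
  if (any(is.na(pos))) stopf("allele counts reference SNPs absent from the genotype map")
  res <- lapply(seq_len(nrow(anno)), function(g) {
    inside <- chrom == anno$chrom[g] & pos >= anno$start[g] & pos <= anno$end[g]
    if (!any(inside)) return(NULL)
    sub <- tested[inside, , drop = FALSE]
    per_site <- split(sub, sub$snp_id)
    het_n <- vapply(per_site, nrow, integer(1))
    med_p <- vapply(per_site, function(d) stats::median(d$p), numeric(1))
    best <- names(per_site)[order(-het_n, med_p, names(per_site))][1]
    d <- per_site[[best]]
    data.frame(gene_id = anno$gene_id[g], snp_id = best,
               het_n = nrow(d), ase_n = sum(d$is_ase),
               ratio = sum(d$is_ase) / nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene_id = character(0), snp_id = character(0),
                      het_n = integer(0), ase_n = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Het/ASE ratio as printed in candidate-gene tables
#'
#' @param ase_n heterozygotes with significant allelic imbalance
#' @param het_n total observed heterozygotes at the reporting site
#' @return ase_n / het_n rounded to 2 decimals
#' @export
ase_ratio <- function(ase_n, het_n) {
  if (any(het_n <= 0)) stopf("het_n must be positive")
  if (any(ase_n > het_n)) stopf("ase_n cannot exceed het_n")
  round(ase_n / het_n, 2)
}
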