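#' Top principal components of the genotype matrix
#'
#' Missing dosages are mean-imputed per SNP and monomorphic SNPs dropped
#' before column-standardization; scores come from the eigen-decomposition of
#' the sample covariance of the standardized dosages (computed via SVD).
#' These PCs act as ancestry/structure covariates in the association models.
#'
#' @param gt a [genotype_matrix()]
#' @param k number of components, default 5
#' @return matrix of scores (samples x k, rownames = sample ids, columns
#'   PC1..PCk) with attribute "sdev" (singular values / sqrt(n - 1))
#' @export
genotype_pcs <- function(gt, k = 5) {
  dos <- gt$dosage
  n <- ncol(dos)
  dos <- t(dos)                       # samples x SNPs
  for (j in seq_len(ncol(dos))) {
    nas <- is.na(dos[, j])
    if (any(nas)) dos[nas, j] <- mean(dos[, j], na.rm = TRUE)
  }
  sds <- apply(dos, 2, stats::sd)
  dos <- dos[, sds > 0, drop = FALSE]
  if (k >= min(n, ncol(dos))) stopf("k = %d too large for %d samples x %d polymorphic SNPs",
                                    k, n, ncol(dos))
  z <- scale(dos)
  sv <- svd(z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(dos)
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "sdev") <- sv$d[seq_len(k)] / sqrt(n - 1)
  scores
}

# residualize SNP dosages (mean-imputed) on a design matrix; returns
# list(res = SNP x sample residual matrix, keep = logical non-monomorphic)
prep_dosages <- function(dosage, X) {
  d <- dosage
  for (i in seq_len(nrow(d))) {
    nas <- is.na(d[i, ])
    if (any(nas)) d[i, nas] <- mean(d[i, ], na.rm = TRUE)
  }
  keep <- apply(d, 1, stats::sd) > 0
  qrX <- qr(X)
  res <- t(qr.resid(qrX, t(d)))
  list(res = res, keep = keep, imputed = d)
}

#' Per-SNP linear association of a response with allele dosage
#'
#' Fits, for each SNP, OLS of `y` on dosage plus the design covariates and
#' t-tests the dosage slope. Computed by the Frisch-Waugh-Lovell route:
#' both `y` and the dosages are residualized on the design, the slope of the
#' residual regression equals the full-model dosage slope, and the t-test
#' uses df = n - ncol(design) - 1. `r_assoc = sign(t) * sqrt(t^2/(t^2 + df))`
#' is the correlation-scale effect statistic reported by MatrixEQTL-style
#' tools. Missing dosages are mean-imputed per SNP inside this function only;
#' monomorphic SNPs are skipped with a flag.
#'
#' @param y numeric response vector (phenotype or one gene's log2 expression)
#'   aligned with the columns of the dosage matrix
#' @param gt a [genotype_matrix()] whose samples match `y`
#' @param design design matrix (list from [build_design()] or plain matrix)
#' @return data.frame: snp_id, beta, se, t, r_assoc, p, skipped
#' @export
linear_assoc <- function(y, gt, design) {
  X <- if (is.list(design)) design$X else design
  dos <- gt$dosage
  n <- length(y)
  if (ncol(dos) != n || nrow(X) != n) stopf("sample dimensions do not align")
  pd <- prep_dosages(dos, X)
  qrX <- qr(X)
  yr <- qr.resid(qrX, y)
  df <- n - ncol(X) - 1L
  if (df < 1) stopf("not enough samples for the model degrees of freedom")
  gss <- rowSums(pd$res^2)
  beta <- as.numeric(pd$res %*% yr) / gss
  rss <- sum(yr^2) - beta^2 * gss
  se <- sqrt(pmax(rss, 0) / df / gss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  r_assoc <- sign(tval) * sqrt(tval^2 / (tval^2 + df))
  out <- data.frame(snp_id = rownames(dos), beta = beta, se = se, t = tval,
                    r_assoc = r_assoc, p = p, skipped = !pd$keep,
                    stringsAsFactors = FALSE)
  out[!pd$keep, c("beta", "se", "t", "r_assoc", "p")] <- NA_real_
  rownames(out) <- NULL
  out
}

#' All-pairs SNP x gene association (eQTL kernel)
#'
#' Same model as [linear_assoc()] applied to every (SNP, gene) pair at once:
#' dosages and expression rows are residualized on the design and the
#' cross-correlation matrix gives every slope t-statistic in one matrix
#' product. Returns a long table restricted to `pairs` when given (a
#' data.frame of snp_id, gene_id), otherwise all pairs.
#'
#' @param expr_log2 genes x samples matrix of log2 expression
#' @param gt a [genotype_matrix()]
#' @param design design matrix; for eQTL runs this should include the
#'   genotype PCs and age in addition to the categorical covariates
#' @param pairs optional data.frame (snp_id, gene_id) limiting the tests
#' @return data.frame: snp_id, gene_id, beta, r_assoc, p
#' @export
eqtl_assoc <- function(expr_log2, gt, design, pairs = NULL) {
  X <- if (is.list(design)) design$X else design
  n <- ncol(expr_log2)
  if (ncol(gt$dosage) != n || nrow(X) != n) stopf("sample dimensions do not align")
  pd <- prep_dosages(gt$dosage, X)
  qrX <- qr(X)
  er <- t(qr.resid(qrX, t(expr_log2)))
  df <- n - ncol(X) - 1L
  gres <- pd$res
  gss <- rowSums(gres^2)
  ess <- rowSums(er^2)
  cross <- gres %*% t(er)                      # SNP x gene sums of products
  rmat <- cross / sqrt(outer(gss, ess))        # partial correlation given X
  rmat[!pd$keep | gss == 0, ] <- NA_real_
  rmat[, ess == 0] <- NA_real_
  if (is.null(pairs)) {
    idx <- cbind(rep(seq_len(nrow(rmat)), times = ncol(rmat)),
                 rep(seq_len(ncol(rmat)), each = nrow(rmat)))
    snp_id <- rownames(gt$dosage)[idx[, 1]]
    gene_id <- rownames(expr_log2)[idx[, 2]]
  } else {
    i <- match(pairs$snp_id, rownames(gt$dosage))
    j <- match(pairs$gene_id, rownames(expr_log2))
    if (any(is.na(i)) || any(is.na(j))) stopf("pairs reference unknown snp/gene ids")
    idx <- cbind(i, j)
    snp_id <- pairs$snp_id
    gene_id <- pairs$gene_id
  }
  r <- rmat[idx]
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = df)
  beta <- cross[idx] / gss[idx[, 1]]
  data.frame(snp_id = snp_id, gene_id = gene_id, beta = beta,
             r_assoc = r, p = p, stringsAsFactors = FALSE)
}

#' Classify a SNP-gene pair as cis or trans
#'
#' cis iff the SNP lies on the gene's chromosome and its distance to the
#' gene body interval [start, end] is at most `window` (inclusive; a SNP
#' inside the gene has distance 0). Strand is ignored: the window is
#' symmetric around the gene.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors allowed)
#' @param gene one row of a [gene_annotation()] table, or a data.frame
#'   recycled against the SNP vectors
#' @param window cis window in bp, default 1e6
#' @return character vector "cis"/"trans"
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene, window = 1e6) {
  if (any(is.na(snp_chrom)) || any(is.na(snp_pos))) stopf("missing SNP coordinates")
  d <- interval_distance(snp_pos, gene$start, gene$end)
  ifelse(as.character(snp_chrom) == as.character(gene$chrom) & d <= window,
         "cis", "trans")
}

# distance from point(s) to 1-based inclusive interval(s); 0 inside
interval_distance <- function(pos, start, end) {
  pmax(start - pos, pos - end, 0)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate, default 0.05
#' @param n_tests number of tests
#' @return alpha / n_tests
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stopf("n_tests must be >= 1")
  alpha / n_tests
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1); thin wrapper over
#' [stats::p.adjust()] so the pipeline has a single named FDR entry point.
#'
#' @param p vector of p-values in [0, 1]; NAs pass through
#' @return adjusted p-values
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
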