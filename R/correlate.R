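#' Pearson correlation with a t-based two-sided p-value
#'
#' r is the product-moment coefficient; the p-value comes from
#' t = r * sqrt((n - 2) / (1 - r^2)) referred to a Student t distribution
#' with n - 2 degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length (n >= 3), typically residuals
#' @return list with `r` and `p`
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3) stopf("need at least 3 observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stopf("undefined correlation: zero variance input")
  r <- sum(xc * yc) / (sx * sy)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(list(r = r, p = 0))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# correlation of every row of `m` (genes x samples) with vector y, vectorized;
# returns r with NA for zero-variance rows
row_cor <- function(m, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  r <- as.numeric(mc %*% yc) / (sm * sy)
  r[sm == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

cor_p_from_r <- function(r, n) {
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Correlate every gene's residual expression with the residual trait
#'
#' @param expr_resid genes x samples matrix of covariate-adjusted log2
#'   expression (see [residualize_matrix()])
#' @param pheno_resid covariate-adjusted phenotype vector aligned with the
#'   columns of `expr_resid`
#' @return data.frame with one row per gene (ordered by gene id): gene_id, r,
#'   p. Genes with zero expression variance get NA r/p and are flagged in
#'   `zero_variance`; they are excluded from FDR estimation downstream.
#' @export
correlate_all <- function(expr_resid, pheno_resid) {
  n <- ncol(expr_resid)
  if (length(pheno_resid) != n) stopf("phenotype length != number of samples")
  r <- row_cor(expr_resid, pheno_resid)
  p <- ifelse(is.na(r), NA_real_, cor_p_from_r(r, n))
  out <- data.frame(gene_id = rownames(expr_resid), r = r, p = p,
                    zero_variance = is.na(r), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation-based FDR for trait-gene correlations
#'
#' For each permutation the residual phenotype vector is permuted once across
#' samples (a joint permutation, preserving the gene-gene correlation
#' structure) and every gene's correlation p-value is recomputed. The FDR at
#' a gene with observed p-value t is the pooled-null estimate
#' \deqn{FDR(t) = \frac{\mathrm{mean}_b \#\{perm\ p \le t\}}{\#\{obs\ p \le t\}},}
#' made monotone non-decreasing in t and clipped to `[floor, 1]`. The floor
#' (default 1e-5) caps how extreme an empirical FDR can be reported.
#'
#' @param obs_p observed per-gene p-values (NA entries are excluded)
#' @param expr_resid,pheno_resid the residual matrices the p-values came from
#' @param n_perm number of permutations, default 10000
#' @param seed integer seed; mandatory for reproducibility
#' @param floor smallest reportable FDR, default 1e-5
#' @return numeric vector of permutation FDRs aligned with `obs_p`
#' @export
permutation_fdr <- function(obs_p, expr_resid, pheno_resid, n_perm = 10000,
                            seed, floor = 1e-5) {
  if (missing(seed) || is.null(seed)) stopf("seed is mandatory for permutation FDR")
  if (n_perm < 100) warnf("n_perm = %d is very small; FDR estimates will be noisy", n_perm)
  n <- ncol(expr_resid)
  ok <- !is.na(obs_p)
  m <- expr_resid[ok, , drop = FALSE]
  # precompute standardized rows: r = (std rows) %*% (std y) / (n-1)
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  ms <- mc / sm
  set.seed(seed)
  # p <= t is equivalent to |r| >= r_t at fixed n (null r^2 ~ Beta(1/2,(n-2)/2)),
  # so permuted p-values can be counted in |r|-space without recomputing pt()
  obs_r_abs <- sqrt(stats::qbeta(obs_p[ok], 1 / 2, (n - 2) / 2, lower.tail = FALSE))
  block <- max(1L, as.integer(5e6 %/% max(nrow(ms), 1L)))
  counts <- numeric(length(obs_r_abs))
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    P <- vapply(seq_len(b), function(i) {
      y <- pheno_resid[sample.int(n)]
      yc <- y - mean(y)
      yc / sqrt(sum(yc^2))
    }, numeric(n))
    pr <- abs(ms %*% P)
    srt <- sort(as.numeric(pr))
    # count perm |r| >= obs |r| via binary search on the sorted pooled nulls
    counts <- counts + (length(srt) - findInterval(obs_r_abs, srt,
                                                   left.open = TRUE))
    done <- done + b
  }
  n_obs_le <- rank(obs_p[ok], ties.method = "max")  # #{obs p <= t}
  fdr <- (counts / n_perm) / n_obs_le
  # enforce monotone non-decreasing in t (step-up from the largest p)
  ord <- order(obs_p[ok], decreasing = TRUE)
  fdr[ord] <- cummin(fdr[ord])
  fdr <- pmin(pmax(fdr, floor), 1)
  out <- rep(NA_real_, length(obs_p))
  out[ok] <- fdr
  out
}

#' Full trait-gene correlation stage
#'
#' Convenience wrapper: correlations, permutation FDR and the significance
#' flag at `fdr_threshold`.
#'
#' @inheritParams permutation_fdr
#' @param fdr_threshold significance cutoff on the permutation FDR, default 0.01
#' @return data.frame: gene_id, r, p, fdr_perm, significant
#' @export
correlation_stage <- function(expr_resid, pheno_resid, n_perm = 10000, seed,
                              floor = 1e-5, fdr_threshold = 0.01) {
  res <- correlate_all(expr_resid, pheno_resid)
  # permutation_fdr works on the gene order of expr_resid; realign to res
  p_aligned <- res$p[match(rownames(expr_resid), res$gene_id)]
  fdr <- permutation_fdr(p_aligned, expr_resid, pheno_resid,
                         n_perm = n_perm, seed = seed, floor = floor)
  res$fdr_perm <- fdr[match(res$gene_id, rownames(expr_resid))]
  res$significant <- !is.na(res$fdr_perm) & res$fdr_perm <= fdr_threshold
  res
}
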