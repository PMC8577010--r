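#' Filter to expressed genes
#'
#' Keeps genes whose TPM is strictly greater than `tpm_min` in strictly more
#' than `sample_frac` of samples. Both inequalities are strict, so a gene
#' passing in exactly 90% of samples is dropped under the defaults.
#'
#' @param expr expression matrix (genes x samples, TPM)
#' @param tpm_min expression floor, default 0.01 TPM
#' @param sample_frac required fraction of samples above the floor, default 0.90
#' @return the filtered expression matrix; warns if no gene survives
#' @export
filter_expressed <- function(expr, tpm_min = 0.01, sample_frac = 0.90) {
  expr <- expression_matrix(expr)
  frac <- rowMeans(expr > tpm_min)
  keep <- frac > sample_frac
  if (!any(keep)) warnf("no gene passed the expression filter")
  expr[keep, , drop = FALSE]
}

#' Log2-transform expression values
#'
#' @param expr expression matrix (TPM)
#' @param offset pseudocount added before taking log2, default 1
#' @return matrix of `log2(value + offset)`
#' @export
log2_transform <- function(expr, offset = 1) {
  if (any(expr < 0)) stopf("negative expression values cannot be log-transformed")
  if (any(expr + offset <= 0)) stopf("offset too small: log2 of non-positive value")
  log2(expr + offset)
}

#' Build the fixed-effects design matrix
#'
#' Columns: intercept, one-hot sex/batch/boar with the first level of each
#' factor dropped, numeric age, plus any extra numeric covariates (e.g.
#' genotype principal components). Samples with missing phenotype or
#' covariates are dropped listwise with a message. A warning is issued when
#' any retained factor level has fewer than 3 samples.
#'
#' @param samples sample table (see [sample_table()])
#' @param covariates covariate column names to include; categorical columns
#'   are one-hot encoded, numeric ones enter as-is
#' @param extra optional numeric matrix of additional covariates with
#'   rownames = sample ids (e.g. genotype PCs)
#' @return list with `X` (design matrix, rownames = sample ids) and
#'   `sample_ids` (samples retained)
#' @export
build_design <- function(samples, covariates = c("sex", "batch", "boar", "age"),
                         extra = NULL) {
  samples <- sample_table(samples)
  miss <- setdiff(covariates, names(samples))
  if (length(miss)) stopf("unknown covariate column(s): %s", paste(miss, collapse = ", "))
  use <- samples[, c("sample_id", covariates, "phenotype"), drop = FALSE]
  complete <- stats::complete.cases(use)
  if (!is.null(extra)) {
    if (is.null(rownames(extra))) stopf("extra covariates need sample rownames")
    complete <- complete & use$sample_id %in% rownames(extra)
  }
  if (sum(!complete) > 0)
    message(sprintf("dropped %d sample(s) with missing phenotype/covariates", sum(!complete)))
  use <- use[complete, , drop = FALSE]
  for (v in covariates) {
    if (is.factor(use[[v]])) {
      use[[v]] <- droplevels(use[[v]])
      tab <- table(use[[v]])
      if (any(tab < 3))
        warnf("factor '%s' has level(s) with < 3 samples: %s", v,
              paste(names(tab)[tab < 3], collapse = ", "))
    }
  }
  fml <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(fml, data = use)
  rownames(X) <- use$sample_id
  if (!is.null(extra)) {
    X <- cbind(X, extra[use$sample_id, , drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  list(X = X, sample_ids = use$sample_id)
}

#' OLS residuals of a vector on a design matrix
#'
#' @param y numeric vector (one gene's log2 expression, or the phenotype),
#'   aligned with the rows of `design`
#' @param design design matrix as returned by [build_design()], or a plain
#'   numeric matrix
#' @return list with `residuals` and the fitted `coefficients`
#' @export
residualize <- function(y, design) {
  X <- if (is.list(design)) design$X else design
  if (length(y) != nrow(X)) stopf("length(y) != nrow(design)")
  if (any(!is.finite(y))) stopf("y contains non-finite values")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  list(residuals = as.numeric(qr.resid(qrX, y)),
       coefficients = qr.coef(qrX, y))
}

#' OLS residuals of every row of a matrix on a design matrix
#'
#' @param m numeric matrix (e.g. genes x samples of log2 expression) whose
#'   columns align with the rows of `design`
#' @inheritParams residualize
#' @return matrix of residuals, same shape and dimnames as `m`
#' @export
residualize_matrix <- function(m, design) {
  X <- if (is.list(design)) design$X else design
  if (ncol(m) != nrow(X)) stopf("ncol(m) != nrow(design)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("design matrix is rank deficient")
  res <- t(qr.resid(qrX, t(m)))
  dimnames(res) <- dimnames(m)
  res
}
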