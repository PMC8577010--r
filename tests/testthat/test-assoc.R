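make_sim_gt <- function(n_snps, n_samples, seed = 1, maf = c(0.1, 0.5)) {
  set.seed(seed)
  dos <- matrix(stats::rbinom(n_snps * n_samples, 2,
                              rep(stats::runif(n_snps, maf[1], maf[2]),
                                  each = n_samples)),
                nrow = n_snps, byrow = TRUE,
                dimnames = list(sprintf("s%04d", seq_len(n_snps)),
                                sprintf("i%04d", seq_len(n_samples))))
  map <- data.frame(snp_id = rownames(dos), chrom = "1",
                    pos = seq_len(n_snps) * 1000L, ref = "A", alt = "T",
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

test_that("genotype PCs match a direct SVD and are orthogonal", {
  gt <- make_sim_gt(50, 20, seed = 2)
  pcs <- genotype_pcs(gt, k = 4)
  expect_equal(dim(pcs), c(20L, 4L))
  # orthogonality
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # oracle: direct SVD of the standardized sample x SNP matrix
  z <- scale(t(gt$dosage))
  z <- z[, apply(t(gt$dosage), 2, stats::sd) > 0, drop = FALSE]
  sv <- svd(z)
  oracle <- sv$u[, 1:4] %*% diag(sv$d[1:4])
  for (j in 1:4) expect_equal(unname(abs(pcs[, j])), unname(abs(oracle[, j])),
                              tolerance = 1e-8)
})

test_that("duplicated samples get identical PC score rows", {
  gt <- make_sim_gt(40, 10, seed = 3)
  gt$dosage[, 2] <- gt$dosage[, 1]
  pcs <- genotype_pcs(gt, k = 3)
  expect_equal(unname(pcs[1, ]), unname(pcs[2, ]), tolerance = 1e-10)
  expect_error(genotype_pcs(gt, k = 10), "too large")
})

test_that("linear_assoc recovers exact and noisy slopes", {
  gt <- make_sim_gt(5, 60, seed = 4)
  X <- matrix(1, 60, 1, dimnames = list(colnames(gt$dosage), "(Intercept)"))
  y <- 0.5 * gt$dosage[3, ]
  res <- linear_assoc(y, gt, X)
  expect_equal(res$beta[3], 0.5, tolerance = 1e-12)
  expect_lt(res$p[3], 1e-12)
  # noiseless response: r_assoc is +/-1 and the residual variance ratio is 0
  expect_equal(abs(res$r_assoc[3]), 1, tolerance = 1e-10)
})

test_that("single-SNP association matches an explicit OLS + t computation", {
  set.seed(6)
  n <- 50
  gt <- make_sim_gt(1, n, seed = 6)
  covar <- stats::rnorm(n)
  X <- cbind(`(Intercept)` = 1, covar = covar)
  rownames(X) <- colnames(gt$dosage)
  y <- 0.4 * gt$dosage[1, ] + 0.8 * covar + stats::rnorm(n)
  res <- linear_assoc(y, gt, X)
  # oracle: full design normal equations and t distribution
  Xf <- cbind(gt$dosage[1, ], X)
  bh <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  resid <- y - Xf %*% bh
  df <- n - ncol(Xf)
  se <- sqrt(sum(resid^2) / df * solve(t(Xf) %*% Xf)[1, 1])
  tval <- bh[1] / se
  expect_equal(res$beta[1], bh[1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$se[1], se, tolerance = 1e-10)
  expect_equal(res$p[1], 2 * stats::pt(-abs(tval), df), tolerance = 1e-12)
  expect_equal(res$r_assoc[1], sign(tval) * sqrt(tval^2 / (tval^2 + df)),
               tolerance = 1e-12)
})

test_that("monomorphic SNPs are skipped with a flag", {
  gt <- make_sim_gt(3, 30, seed = 7)
  gt$dosage[2, ] <- 2
  X <- matrix(1, 30, 1, dimnames = list(colnames(gt$dosage), "(Intercept)"))
  res <- linear_assoc(stats::rnorm(30), gt, X)
  expect_true(res$skipped[2])
  expect_true(is.na(res$p[2]))
  expect_false(any(res$skipped[-2]))
})

test_that("association p-values are uniform under a permuted phenotype", {
  set.seed(8)
  gt <- make_sim_gt(800, 150, seed = 8)
  X <- matrix(1, 150, 1, dimnames = list(colnames(gt$dosage), "(Intercept)"))
  y <- sample(stats::rnorm(150))
  res <- linear_assoc(y, gt, X)
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("eqtl kernel agrees with per-SNP lm fits", {
  set.seed(9)
  n <- 40
  gt <- make_sim_gt(6, n, seed = 9)
  expr <- matrix(stats::rnorm(3 * n), nrow = 3,
                 dimnames = list(c("gA", "gB", "gC"), colnames(gt$dosage)))
  covar <- stats::rnorm(n)
  X <- cbind(`(Intercept)` = 1, covar = covar)
  rownames(X) <- colnames(gt$dosage)
  eq <- eqtl_assoc(expr, gt, X)
  expect_equal(nrow(eq), 18L)
  for (k in c(1, 8, 17)) {
    fit <- summary(stats::lm(expr[eq$gene_id[k], ] ~ gt$dosage[eq$snp_id[k], ] + covar))
    expect_equal(eq$beta[k], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(eq$p[k], fit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("cis/trans classification uses an inclusive symmetric window", {
  gene <- data.frame(gene_id = "g", chrom = "5", start = 2e6, end = 2.1e6)
  expect_equal(classify_cis_trans("5", 2.05e6, gene), "cis")        # inside: distance 0
  expect_equal(classify_cis_trans("5", 2.1e6 + 1e6, gene), "cis")   # exactly window away
  expect_equal(classify_cis_trans("5", 2.1e6 + 1e6 + 1, gene), "trans")
  expect_equal(classify_cis_trans("6", 2.05e6, gene), "trans")      # other chromosome
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 50000), 1e-6)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  set.seed(10)
  p <- stats::runif(25)
  # oracle: min over j >= i of p_(j) * m / j, mapped back to input order
  m <- length(p)
  ord <- order(p)
  stepup <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  expected <- pmin(stepup, 1)[order(ord)]
  expect_equal(bh_fdr(p), expected)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
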