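test_that("pearson matches hand evaluation of the product-moment formula", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)
  got <- pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$r, 0.6)
  # p from t = r sqrt((n-2)/(1-r^2)) with n - 2 df, cross-checked with cor.test
  ct <- stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("correlate_all is gene-ordered and flags zero-variance genes", {
  set.seed(5)
  ph <- stats::rnorm(30)
  m <- rbind(gB = ph, gA = stats::rnorm(30), gC = rep(0, 30))
  res <- correlate_all(m, ph)
  expect_equal(res$gene_id, c("gA", "gB", "gC"))
  expect_equal(res$r[res$gene_id == "gB"], 1)
  expect_true(res$zero_variance[res$gene_id == "gC"])
  expect_true(is.na(res$r[res$gene_id == "gC"]))
})

test_that("permutation FDR equals brute-force enumeration of the estimator", {
  # 3 genes x small n, 2 permutations: reproduce the pooled-null estimator
  # from its definition using cor.test p-values and the same permutation draws
  set.seed(9)
  n <- 12
  m <- matrix(stats::rnorm(3 * n), nrow = 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  ph <- stats::rnorm(n)
  m[1, ] <- ph + stats::rnorm(n, 0, 0.3)   # one strong gene
  obs_p <- vapply(1:3, function(i) stats::cor.test(m[i, ], ph)$p.value, numeric(1))

  seed <- 123
  n_perm <- 2
  got <- suppressWarnings(
    permutation_fdr(obs_p, m, ph, n_perm = n_perm, seed = seed, floor = 1e-5))

  set.seed(seed)  # replay the same joint permutations
  perm_p <- matrix(NA_real_, 3, n_perm)
  for (b in seq_len(n_perm)) {
    yp <- ph[sample.int(n)]
    for (i in 1:3) perm_p[i, b] <- stats::cor.test(m[i, ], yp)$p.value
  }
  raw <- vapply(obs_p, function(t) {
    mean(colSums(perm_p <= t)) / sum(obs_p <= t)
  }, numeric(1))
  ord <- order(obs_p, decreasing = TRUE)   # enforce monotone non-decreasing in t
  raw[ord] <- cummin(raw[ord])
  expected <- pmin(pmax(raw, 1e-5), 1)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("an observed p below every permuted p hits the FDR floor", {
  set.seed(31)
  n <- 50
  ph <- stats::rnorm(n)
  m <- rbind(hit = ph, miss1 = stats::rnorm(n), miss2 = stats::rnorm(n))
  res <- correlate_all(m, ph)
  p_aligned <- res$p[match(rownames(m), res$gene_id)]
  fdr <- permutation_fdr(p_aligned, m, ph, n_perm = 200, seed = 4)
  expect_equal(fdr[1], 1e-5)
})

test_that("permutation FDR is seed-reproducible and gene-label invariant", {
  set.seed(41)
  n <- 40
  m <- matrix(stats::rnorm(20 * n), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  ph <- stats::rnorm(n)
  res <- correlate_all(m, ph)
  p <- res$p[match(rownames(m), res$gene_id)]
  f1 <- permutation_fdr(p, m, ph, n_perm = 300, seed = 7)
  f2 <- permutation_fdr(p, m, ph, n_perm = 300, seed = 7)
  expect_identical(f1, f2)
  # relabeling genes permutes the FDR vector identically
  ord <- sample(20)
  f3 <- permutation_fdr(p[ord], m[ord, ], ph, n_perm = 300, seed = 7)
  expect_equal(f3, f1[ord], tolerance = 1e-12)
})

test_that("permutation FDR stabilizes as permutations grow", {
  set.seed(51)
  n <- 60
  m <- matrix(stats::rnorm(50 * n), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  m[1, ] <- 0.5 * stats::rnorm(n) + 0.5 * (ph <- stats::rnorm(n))
  res <- correlate_all(m, ph)
  p <- res$p[match(rownames(m), res$gene_id)]
  reps <- vapply(1:4, function(s)
    permutation_fdr(p, m, ph, n_perm = 5000, seed = s)[1], numeric(1))
  expect_lt(stats::sd(reps), 0.015)
})

test_that("fdr is monotone non-increasing in |r| across genes", {
  set.seed(61)
  n <- 80
  m <- matrix(stats::rnorm(30 * n), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  ph <- stats::rnorm(n)
  st <- correlation_stage(m, ph, n_perm = 500, seed = 3)
  ord <- order(abs(st$r), decreasing = TRUE)
  expect_true(all(diff(st$fdr_perm[ord]) >= -1e-12))
})
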