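small_cfg <- function(...) {
  sim_config(n_samples = 120, n_genes = 300, n_snps = 300, ...)
}

test_that("configuration validation guards planted-set arithmetic", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(n_genes = 20, n_cis_genes = 10, n_trans_genes = 10,
                          n_ase_genes = 5), "exceed")
  expect_error(sim_config(n_mediated = 5, n_qtl = 2), "n_mediated")
  expect_error(sim_config(qtl_h2 = 1.2), "\\[0, 1\\]")
})

test_that("the same configuration reproduces the dataset field by field", {
  a <- simulate_population(small_cfg(seed = 42))
  b <- simulate_population(small_cfg(seed = 42))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  expect_identical(a$allele_counts, b$allele_counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth$effects, b$truth$effects)
  d <- simulate_population(small_cfg(seed = 43))
  expect_false(identical(a$expression, d$expression))
})

test_that("empirical MAF tracks the drawn MAF", {
  sim <- simulate_population(sim_config(n_samples = 250, n_genes = 50,
                                        n_snps = 400, seed = 5))
  emp <- rowMeans(sim$genotypes$dosage) / 2
  emp_maf <- pmin(emp, 1 - emp)
  drawn <- pmin(sim$truth$maf, 1 - sim$truth$maf)
  expect_lt(max(abs(emp_maf - drawn)), 0.1)
})

test_that("allele counts exist only at heterozygous sites", {
  sim <- simulate_population(small_cfg(seed = 6))
  ac <- sim$allele_counts
  expect_gt(nrow(ac), 0)
  dos <- sim$genotypes$dosage[cbind(ac$snp_id, ac$sample_id)]
  expect_true(all(dos == 1))
})

test_that("every planted effect appears once and references real ids", {
  sim <- simulate_population(small_cfg(seed = 7))
  eff <- sim$truth$effects
  expect_false(any(duplicated(eff[, c("kind", "gene_id", "snp_id")])))
  expect_true(all(stats::na.omit(eff$gene_id) %in% rownames(sim$expression)))
  expect_true(all(stats::na.omit(eff$snp_id) %in% rownames(sim$genotypes$dosage)))
  # planted cis SNPs sit within the cis window of their gene
  cis <- eff[eff$kind == "cis-eQTL", ]
  anno <- sim$annotation
  for (i in seq_len(nrow(cis))) {
    g <- anno[anno$gene_id == cis$gene_id[i], ]
    s <- sim$genotypes$map[sim$genotypes$map$snp_id == cis$snp_id[i], ]
    expect_equal(classify_cis_trans(s$chrom, s$pos, g), "cis")
  }
  # trans SNPs lie on a different chromosome from their gene
  trans <- eff[eff$kind == "trans-eQTL", ]
  for (i in seq_len(nrow(trans))) {
    g <- anno[anno$gene_id == trans$gene_id[i], ]
    s <- sim$genotypes$map[sim$genotypes$map$snp_id == trans$snp_id[i], ]
    expect_false(s$chrom == g$chrom)
  }
})

test_that("a null configuration yields essentially no discoveries", {
  sim <- simulate_population(small_cfg(frac_correlated_genes = 0, n_cis_genes = 0,
                                       n_trans_genes = 0, n_qtl = 0, n_mediated = 0,
                                       seed = 8))
  st <- resid_stage(sim)
  res <- correlation_stage(st$er, st$ph, n_perm = 500, seed = 9)
  expect_lte(sum(res$significant), 3)
})

test_that("planted cis effects are recovered by direct OLS on the truth pairing", {
  sim <- simulate_population(sim_config(n_samples = 200, n_genes = 300,
                                        n_snps = 300, cis_beta = 1.0, seed = 10))
  eff <- sim$truth$effects
  cis <- eff[eff$kind == "cis-eQTL", ][1:4, ]
  lg <- log2_transform(sim$expression)
  covered <- vapply(seq_len(nrow(cis)), function(i) {
    y <- lg[cis$gene_id[i], ]
    d <- sim$genotypes$dosage[cis$snp_id[i], ]
    ci <- stats::confint(stats::lm(y ~ d))["d", ]
    ci[1] <= cis$value[i] && cis$value[i] <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.75)
})

test_that("planted trait-gene correlations are recovered on average", {
  errs <- vapply(1:5, function(s) {
    sim <- simulate_population(sim_config(n_samples = 200, n_genes = 200,
                                          n_snps = 100,
                                          rho_range = c(0.3, 0.3), seed = s))
    st <- resid_stage(sim)
    res <- correlate_all(st$er, st$ph)
    eff <- sim$truth$effects
    pl <- eff[eff$kind == "trait-correlation", ]
    est <- res$r[match(pl$gene_id, res$gene_id)]
    mean(est * sign(pl$value)) - 0.3
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.15)
})

test_that("block-LD mode induces correlation between adjacent SNPs", {
  sim <- simulate_population(small_cfg(seed = 11, n_cis_genes = 0,
                                       n_trans_genes = 0, n_ase_genes = 0,
                                       n_exonic_null = 0, n_qtl = 0, n_mediated = 0,
                                       ld = list(block_size = 10, rho = 0.9)))
  map <- sim$genotypes$map
  ord <- order(map$chrom, map$pos)
  dos <- sim$genotypes$dosage[ord, ]
  cors <- vapply(seq(2, 100), function(i) {
    if (map$chrom[ord[i]] != map$chrom[ord[i - 1]]) return(NA_real_)
    suppressWarnings(stats::cor(dos[i, ], dos[i - 1, ]))
  }, numeric(1))
  expect_gt(mean(cors, na.rm = TRUE), 0.3)
})

test_that("simulated directories are pipeline-readable", {
  sim <- simulate_population(small_cfg(seed = 12))
  dir <- file.path(tempdir(), "simdir")
  write_simulation(sim, dir)
  gt <- read_genotypes(file.path(dir, "genotypes.vcf"), dialect = "vcf")
  expect_equal(sort(rownames(gt$dosage)), sort(rownames(sim$genotypes$dosage)))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), dim(sim$expression))
  expect_equal(expr, sim$expression, tolerance = 1e-6)
  expect_equal(nrow(read_sample_table(file.path(dir, "samples.tsv"))),
               nrow(sim$samples))
})
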