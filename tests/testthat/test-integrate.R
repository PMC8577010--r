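test_that("overlap sets compute exact intersections", {
  ov <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"), c("c"), character(0))
  expect_equal(unname(ov$counts), c(2L, 1L, 1L, 0L))
  expect_equal(ov$members$correlated_cis, c("b", "c"))
  expect_equal(ov$members$correlated_cis_ase, "c")
  ov0 <- overlap_sets(c("x"), c("y"), c("z"), c("w"))
  expect_true(all(ov0$counts == 0))
})

test_that("overlap counts equal brute-force membership loops", {
  set.seed(15)
  pool <- sprintf("g%03d", 1:60)
  for (rep in 1:5) {
    A <- sample(pool, 20); B <- sample(pool, 25)
    C <- sample(pool, 10); D <- sample(pool, 15)
    ov <- overlap_sets(A, B, C, D)
    brute <- function(...) {
      sets <- list(...)
      out <- character(0)
      for (g in pool) {
        inall <- TRUE
        for (s in sets) {
          found <- FALSE
          for (x in s) if (x == g) found <- TRUE
          if (!found) inall <- FALSE
        }
        if (inall) out <- c(out, g)
      }
      sort(out)
    }
    expect_equal(ov$members$correlated_cis, brute(A, B))
    expect_equal(ov$members$correlated_ase, brute(A, C))
    expect_equal(ov$members$correlated_cis_ase, brute(A, B, C))
    expect_equal(ov$members$correlated_trans, brute(A, D))
    expect_true(ov$counts["correlated_cis_ase"] <= min(ov$counts["correlated_cis"],
                                                       ov$counts["correlated_ase"]))
  }
})

toy_tables <- function() {
  cor_res <- data.frame(gene_id = c("g1", "g2", "g3"),
                        r = c(0.3, 0.25, -0.2),
                        p = c(1e-5, 2e-4, 3e-3),
                        fdr_perm = c(1e-3, 5e-3, 0.2),
                        stringsAsFactors = FALSE)
  eqtl_res <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                         gene_id = c("g1", "g1", "g2", "g3"),
                         r_assoc = c(0.5, -0.4, 0.3, 0.2),
                         p = c(1e-8, 1e-6, 1e-4, 1e-2),
                         fdr = c(1e-6, 1e-4, 0.01, 0.3),
                         type = c("cis", "trans", "cis", "cis"),
                         stringsAsFactors = FALSE)
  gwas_res <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                         r_assoc = c(0.31, 0.28, -0.1, 0.05),
                         p = c(1e-4, 2e-3, 0.5, 0.9),
                         stringsAsFactors = FALSE)
  list(cor = cor_res, eqtl = eqtl_res, gwas = gwas_res)
}

test_that("triple candidates require all three filters on the same marker", {
  tt <- toy_tables()
  out <- triple_candidates(tt$cor, tt$eqtl, tt$gwas)
  # s1-g1 passes everything; s2-g1 fails GWAS p (2e-3 > 1e-3);
  # s3-g2 fails GWAS; s4-g3 fails correlation FDR and eQTL FDR
  expect_equal(nrow(out), 1L)
  expect_equal(out$snp_id, "s1")
  expect_equal(out$gene_id, "g1")
  # component statistics byte-match the upstream rows
  expect_identical(out$cor, tt$cor$r[1])
  expect_identical(out$cor_fdr, tt$cor$fdr_perm[1])
  expect_identical(out$eqtl_r, tt$eqtl$r_assoc[1])
  expect_identical(out$gwas_p, tt$gwas$p[1])
  expect_error(triple_candidates(NULL, tt$eqtl, tt$gwas), "correlation")
})

test_that("triple join equals a brute-force filter-and-join oracle", {
  set.seed(16)
  genes <- sprintf("g%02d", 1:15)
  snps <- sprintf("s%02d", 1:25)
  cor_res <- data.frame(gene_id = genes, r = stats::runif(15, -0.4, 0.4),
                        p = stats::runif(15), fdr_perm = stats::runif(15, 0, 0.05),
                        stringsAsFactors = FALSE)
  eqtl_res <- data.frame(snp_id = sample(snps, 40, TRUE),
                         gene_id = sample(genes, 40, TRUE),
                         r_assoc = stats::runif(40, -1, 1),
                         p = stats::runif(40), fdr = stats::runif(40, 0, 0.2),
                         type = sample(c("cis", "trans"), 40, TRUE),
                         stringsAsFactors = FALSE)
  eqtl_res <- eqtl_res[!duplicated(eqtl_res[, c("snp_id", "gene_id")]), ]
  gwas_res <- data.frame(snp_id = snps, r_assoc = stats::runif(25, -0.5, 0.5),
                         p = stats::runif(25, 0, 0.01), stringsAsFactors = FALSE)
  out <- triple_candidates(cor_res, eqtl_res, gwas_res,
                           cor_fdr = 0.02, eqtl_fdr = 0.1, gwas_p = 5e-3)
  brute <- list()
  for (i in seq_len(nrow(eqtl_res))) {
    g <- eqtl_res$gene_id[i]; s <- eqtl_res$snp_id[i]
    crow <- cor_res[cor_res$gene_id == g, ]
    grow <- gwas_res[gwas_res$snp_id == s, ]
    if (nrow(crow) == 1 && nrow(grow) == 1 &&
        crow$fdr_perm <= 0.02 && eqtl_res$fdr[i] < 0.1 && grow$p <= 5e-3) {
      brute[[length(brute) + 1]] <- paste(s, g)
    }
  }
  expect_setequal(paste(out$snp_id, out$gene_id), unlist(brute))
  # ordering: by gene, then GWAS p
  expect_equal(out$gene_id, sort(out$gene_id))
})

test_that("nearest correlated gene uses distance then FDR tie-breaks", {
  anno <- data.frame(gene_id = c("near", "far", "othchr", "tie_hi", "tie_lo"),
                     chrom = c("3", "3", "4", "3", "3"),
                     start = c(1.9e6, 5.0e6, 1.9e6, 9.0e6, 11.0e6),
                     end = c(2.0e6, 5.1e6, 2.0e6, 9.1e6, 11.1e6),
                     stringsAsFactors = FALSE)
  correlated <- data.frame(gene_id = c("near", "far", "othchr", "tie_hi", "tie_lo"),
                           fdr_perm = c(1e-3, 1e-4, 1e-5, 0.01, 0.002),
                           stringsAsFactors = FALSE)
  # correlated gene 0.9 Mb away beats one 2.1 Mb away
  hit <- nearest_correlated_gene("3", 2.9e6, anno, correlated)
  expect_equal(hit$gene_id, "near")
  expect_equal(hit$distance, 9e5)
  # nothing within range
  expect_null(nearest_correlated_gene("3", 2.9e6, anno,
                                      correlated[correlated$gene_id == "far", ],
                                      max_dist = 1e6))
  # equidistant genes: smaller FDR wins (lead at 10.05e6: both 0.95 Mb away)
  tie <- nearest_correlated_gene("3", 10.05e6, anno, correlated)
  expect_equal(tie$gene_id, "tie_lo")
})
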