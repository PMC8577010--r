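# shared fixtures built in code

# filter -> log2 -> covariate residualization for a simulated dataset
resid_stage <- function(sim) {
  lg <- log2_transform(filter_expressed(sim$expression))
  des <- suppressWarnings(build_design(sim$samples))
  er <- residualize_matrix(lg[, des$sample_ids, drop = FALSE], des)
  ph <- residualize(sim$samples$phenotype[match(des$sample_ids,
                                                sim$samples$sample_id)],
                    des)$residuals
  list(er = er, ph = ph, des = des, lg = lg)
}

# tiny deterministic expression TSV fixture on disk; returns the path
tiny_expression_tsv <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny_expr.tsv")
  writeLines(c("gene_id\tS1\tS2\tS3",
               "GA\t0.5\t1.25\t3",
               "GB\t0\t10\t2.5"), path)
  path
}

# small genotype matrix fixture built in code
tiny_genotypes <- function() {
  dos <- matrix(c(0, 1, 2,
                  1, 1, 0,
                  2, NA, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("snpA", "snpB", "snpC"), c("S1", "S2", "S3")))
  map <- data.frame(snp_id = c("snpA", "snpB", "snpC"),
                    chrom = c("1", "1", "2"),
                    pos = c(100L, 5000L, 200L),
                    ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}
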