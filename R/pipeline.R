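#' Default stage thresholds for the full pipeline
#'
#' @return named list of every tunable threshold with its default:
#'   expression filter (tpm_min 0.01, sample_frac 0.90, log_offset 1),
#'   correlation stage (cor_n_perm 10000, cor_fdr 0.01, fdr_floor 1e-5),
#'   association (n_pcs 5, cis_window 1e6 bp, eqtl_fdr 0.05, gwas_p 1e-3,
#'   gwas_alpha 0.05, gwas_normalize "standardize" or "inverse_normal"),
#'   ASE (ase_min_depth 10, ase_p0 0.5, ase_site_fdr 0.05), GSEA
#'   (gsea_n_perm 1000, gsea_fdr 0.25, gsea_weight 1), integration
#'   (max_nearest_dist 2e6 bp)
#' @export
default_thresholds <- function() {
  list(tpm_min = 0.01, sample_frac = 0.90, log_offset = 1,
       cor_n_perm = 10000, cor_fdr = 0.01, fdr_floor = 1e-5,
       n_pcs = 5, cis_window = 1e6, eqtl_fdr = 0.05,
       gwas_p = 1e-3, gwas_alpha = 0.05, gwas_normalize = "standardize",
       ase_min_depth = 10, ase_p0 = 0.5, ase_site_fdr = 0.05,
       gsea_n_perm = 1000, gsea_fdr = 0.25, gsea_weight = 1,
       max_nearest_dist = 2e6)
}

validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stopf("config error: out_dir is required")
  if (is.null(config$seed)) stopf("config error: seed is mandatory (permutation stages)")
  if (is.null(config$simulate)) {
    p <- config$paths
    if (is.null(p)) stopf("config error: either a simulate block or input paths are required")
    need <- c("genotypes", "expression", "samples", "annotation", "allele_counts")
    for (nm in need) {
      if (is.null(p[[nm]])) stopf("config error: missing input path '%s'", nm)
      if (!file.exists(p[[nm]])) stopf("config error: input path '%s' does not exist: %s",
                                       nm, p[[nm]])
    }
  }
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  config$thresholds <- th
  config
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
    sim <- simulate_population(cfg)
    sim$gene_sets <- toy_gene_sets(sim, seed = config$seed)
    return(sim)
  }
  p <- config$paths
  gt <- read_genotypes(p$genotypes, dialect = p$genotype_dialect %||% "vcf",
                       map_path = p$genotype_map)
  list(genotypes = gt,
       expression = read_expression(p$expression),
       samples = read_sample_table(p$samples),
       annotation = read_gene_annotation(p$annotation),
       allele_counts = read_allele_counts(p$allele_counts),
       gene_sets = if (!is.null(p$gene_sets)) read_gmt(p$gene_sets),
       truth = NULL)
}

# toy gene-set collection for simulated runs: the planted trait-correlated
# genes as one set plus random same-sized sets as background
toy_gene_sets <- function(sim, seed, n_random = 9, set_size = 20) {
  set.seed(seed + 17L)
  genes <- rownames(sim$expression)
  planted <- sim$truth$effects$gene_id[sim$truth$effects$kind == "trait-correlation"]
  sets <- list()
  if (length(planted) >= 3) sets$planted_correlated <- planted
  for (i in seq_len(n_random))
    sets[[paste0("random_set_", i)]] <- sample(genes, min(set_size, length(genes) - 1))
  sets
}

#' Run the full integrative analysis
#'
#' Stage order: expression filter -> log2 -> covariate residualization ->
#' trait-gene correlation with permutation FDR -> genotype PCs -> cis/trans
#' eQTL -> GWAS -> ASE -> overlaps -> SNP-gene-trait triples -> nearest
#' correlated gene to the lead GWAS SNP -> preranked GSEA. Writes a
#' deterministic directory of TSVs plus a run log and a JSON config echo;
#' identical config + seed gives byte-identical outputs.
#'
#' @param config list with `out_dir`, `seed`, either a `simulate` block
#'   ([sim_config()] or a plain list of its arguments) or a `paths` list
#'   (genotypes, genotype_dialect, genotype_map, expression, samples,
#'   annotation, allele_counts, optional gene_sets GMT), and an optional
#'   `thresholds` list overriding [default_thresholds()]
#' @return (invisibly) list of in-memory stage results; files are written
#'   under `config$out_dir`
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  th <- config$thresholds
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("pipeline seed: %d", config$seed),
                 sprintf("threshold %s = %s", names(th),
                         vapply(th, function(x) paste(format(x), collapse = ","),
                                character(1))))

  dat <- load_pipeline_inputs(config)
  gt <- dat$genotypes
  anno <- dat$annotation
  samples <- dat$samples

  shared <- align_samples(samples$sample_id, colnames(dat$expression),
                          colnames(gt$dosage), context = "pipeline")
  samples <- samples[match(shared, samples$sample_id), , drop = FALSE]
  expr <- dat$expression[, shared, drop = FALSE]
  gt$dosage <- gt$dosage[, shared, drop = FALSE]

  ## preprocess
  expr_f <- filter_expressed(expr, th$tpm_min, th$sample_frac)
  log_lines <- c(log_lines, sprintf("expression filter: %d of %d genes kept",
                                    nrow(expr_f), nrow(expr)))
  expr_log2 <- log2_transform(expr_f, th$log_offset)
  design <- build_design(samples)
  expr_resid <- residualize_matrix(expr_log2[, design$sample_ids, drop = FALSE], design)
  pheno <- samples$phenotype[match(design$sample_ids, samples$sample_id)]
  pheno_resid <- residualize(pheno, design)$residuals

  ## correlation stage
  cor_res <- correlation_stage(expr_resid, pheno_resid, n_perm = th$cor_n_perm,
                               seed = config$seed + 1L, floor = th$fdr_floor,
                               fdr_threshold = th$cor_fdr)
  correlated_genes <- cor_res$gene_id[cor_res$significant]
  log_lines <- c(log_lines, sprintf("correlation: %d significant gene(s) at FDR <= %g",
                                    length(correlated_genes), th$cor_fdr))

  ## association designs: categorical covariates + age + genotype PCs
  pcs <- genotype_pcs(gt, k = th$n_pcs)
  design_assoc <- build_design(samples, extra = pcs)
  ids_a <- design_assoc$sample_ids
  gt_a <- gt
  gt_a$dosage <- gt$dosage[, ids_a, drop = FALSE]

  ## eQTL: all SNP x gene pairs, BH within cis and trans scopes separately
  eq <- eqtl_assoc(expr_log2[, ids_a, drop = FALSE], gt_a, design_assoc)
  si <- match(eq$snp_id, gt$map$snp_id)
  gi <- match(eq$gene_id, anno$gene_id)
  eq$type <- classify_cis_trans(gt$map$chrom[si], gt$map$pos[si],
                                anno[gi, , drop = FALSE], window = th$cis_window)
  eq$fdr <- NA_real_
  for (tp in c("cis", "trans")) {
    rows <- which(eq$type == tp & !is.na(eq$p))
    eq$fdr[rows] <- bh_fdr(eq$p[rows])
  }
  eqtl_cis <- eq[eq$type == "cis", , drop = FALSE]
  eqtl_trans <- eq[eq$type == "trans", , drop = FALSE]
  cis_genes <- sort(unique(eqtl_cis$gene_id[!is.na(eqtl_cis$fdr) &
                                              eqtl_cis$fdr < th$eqtl_fdr]))
  trans_sig <- sort(unique(eqtl_trans$gene_id[!is.na(eqtl_trans$fdr) &
                                                eqtl_trans$fdr < th$eqtl_fdr]))
  trans_specific <- setdiff(trans_sig, cis_genes)
  log_lines <- c(log_lines, sprintf("eQTL: %d cis gene(s), %d specific trans gene(s) at FDR < %g",
                                    length(cis_genes), length(trans_specific), th$eqtl_fdr))

  ## GWAS: normalized phenotype on dosage + same covariates as eQTL
  pheno_a <- samples$phenotype[match(ids_a, samples$sample_id)]
  pheno_r <- residualize(pheno_a, design_assoc)$residuals
  y_norm <- if (identical(th$gwas_normalize, "inverse_normal")) {
    stats::qnorm((rank(pheno_r) - 0.5) / length(pheno_r))
  } else {
    as.numeric(scale(pheno_r))
  }
  gwas <- linear_assoc(y_norm, gt_a, design_assoc)
  gwas$chrom <- gt$map$chrom[match(gwas$snp_id, gt$map$snp_id)]
  gwas$pos <- gt$map$pos[match(gwas$snp_id, gt$map$snp_id)]
  n_tests <- sum(!gwas$skipped)
  gw_thresh <- bonferroni_threshold(th$gwas_alpha, n_tests)
  log_lines <- c(log_lines,
                 sprintf("GWAS: %d SNP(s) tested; genome-wide threshold %s; %d SNP(s) at p <= %g",
                         n_tests, format_sci3(gw_thresh),
                         sum(gwas$p <= th$gwas_p, na.rm = TRUE), th$gwas_p))
  ord_p <- sort(gwas$p[!is.na(gwas$p)])
  gwas_qq <- data.frame(expected = -log10(stats::ppoints(length(ord_p))),
                        observed = -log10(ord_p))

  ## ASE
  calls <- ase_calls(dat$allele_counts, gt = gt, min_depth = th$ase_min_depth,
                     p0 = th$ase_p0, site_fdr = th$ase_site_fdr)
  ase_genes_tab <- summarize_gene_ase(calls, gt, anno)
  ase_genes <- sort(ase_genes_tab$gene_id[ase_genes_tab$ase_n >= 1])
  log_lines <- c(log_lines, sprintf("ASE: %d gene(s) with >= 1 imbalanced heterozygote",
                                    length(ase_genes)))

  ## integration
  overlaps <- overlap_sets(correlated_genes, cis_genes, ase_genes, trans_specific)
  triples <- triple_candidates(cor_res, eq, gwas, cor_fdr = th$cor_fdr,
                               eqtl_fdr = th$eqtl_fdr, gwas_p = th$gwas_p)
  lead <- gwas[which.min(gwas$p), , drop = FALSE]
  nearest <- if (nrow(lead) == 1)
    nearest_correlated_gene(lead$chrom, lead$pos, anno,
                            cor_res[cor_res$significant, , drop = FALSE],
                            max_dist = th$max_nearest_dist)

  ## GSEA on the correlation-ranked list
  gsea_res <- NULL
  ranked <- stats::setNames(cor_res$r[!cor_res$zero_variance],
                            cor_res$gene_id[!cor_res$zero_variance])
  if (!is.null(dat$gene_sets) && length(dat$gene_sets) >= 2) {
    gsea_res <- nes_fdr(ranked, dat$gene_sets, n_perm = th$gsea_n_perm,
                        seed = config$seed + 3L, weight_exp = th$gsea_weight,
                        fdr_threshold = th$gsea_fdr)
  }

  overlap_df <- data.frame(set = names(overlaps$counts),
                           n = as.integer(overlaps$counts),
                           members = vapply(overlaps$members, paste,
                                            character(1), collapse = "/"),
                           stringsAsFactors = FALSE)
  results <- list(correlation = cor_res,
                  eqtl_cis = eqtl_cis[!is.na(eqtl_cis$fdr) &
                                        eqtl_cis$fdr < th$eqtl_fdr, , drop = FALSE],
                  eqtl_trans = eqtl_trans[!is.na(eqtl_trans$fdr) &
                                            eqtl_trans$fdr < th$eqtl_fdr, , drop = FALSE],
                  gwas = gwas[, c("snp_id", "chrom", "pos", "beta", "r_assoc", "p")],
                  gwas_qq = gwas_qq,
                  ase_genes = ase_genes_tab,
                  overlaps = overlap_df,
                  triples = triples,
                  nearest_gene = nearest %||% data.frame(gene_id = character(0),
                                                         distance = numeric(0),
                                                         fdr_perm = numeric(0)))
  if (!is.null(gsea_res))
    results$gsea <- gsea_res[, c("set_name", "size", "es", "nes", "p_perm",
                                 "fdr", "significant")]
  write_result_tables(results, out_dir)
  writeLines(log_lines, file.path(out_dir, "run_log"))
  echo <- config
  echo$simulate <- if (!is.null(config$simulate)) unclass(
    if (inherits(config$simulate, "sim_config")) config$simulate
    else do.call(sim_config, config$simulate))
  jsonlite::write_json(echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results, list(truth = dat$truth, genome_wide_threshold = gw_thresh,
                            correlated_genes = correlated_genes,
                            design = design, thresholds = th)))
}
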