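#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline is built for: 189 animals
#' with sex, slaughter batch (4 levels), boar (8 sires) and age (210 +/- 6
#' days, uniform) as covariates, a percent-scale phenotype centred near
#' 3.35, SNP-chip-like genotypes in Hardy-Weinberg proportions, and TPM
#' expression with a small fraction of trait-correlated genes whose
#' covariate-adjusted correlations fall in the magnitude band reported for
#' such studies (0.20-0.37).
#'
#' @param n_samples number of animals, default 189
#' @param n_genes number of genes, default 2000
#' @param n_snps number of SNPs, default 2000
#' @param n_chromosomes autosome count positions are spread over, default 18
#' @param maf_range minor-allele-frequency range, drawn per SNP uniform
#' @param frac_correlated_genes fraction of genes with a planted
#'   trait-expression correlation, default 0.015
#' @param rho_range magnitude band for planted trait-gene partial
#'   correlations (signs are random), default c(0.20, 0.37)
#' @param n_cis_genes genes with a planted cis-eQTL, default 10
#' @param n_trans_genes genes with a planted trans-eQTL (causal SNP on
#'   another chromosome), default 5
#' @param cis_beta dosage effect on log2 expression for planted eQTLs
#' @param n_qtl SNPs with a phenotype effect, default 3; the first
#'   `n_mediated` of them act through a cis gene's expression
#' @param n_mediated QTLs mediated through a planted cis gene (yielding a
#'   full SNP-gene-trait triple), default 1; must be <= min(n_qtl, n_cis_genes)
#' @param qtl_h2 fraction of the phenotype's non-covariate variance
#'   explained by the planted QTLs, default 0.2
#' @param n_ase_genes genes with planted allelic imbalance, default 5
#' @param n_exonic_null extra genes given a heterozygous exonic site with
#'   balanced (0.5) allele expression, default 10
#' @param ase_depth mean read depth at heterozygous sites (Poisson), default 30
#' @param ase_imbalance reference-allele fraction at planted ASE sites,
#'   default 0.8
#' @param noise_sd residual SD of log2 expression and of the phenotype's
#'   non-genetic residual, default 1
#' @param ld optional list(block_size, rho) switching on block-LD genotypes
#'   (adjacent SNPs correlated within blocks); default NULL = independent SNPs
#' @param seed integer seed; the same config is bit-reproducible
#' @return validated config list of class "sim_config"
#' @export
sim_config <- function(n_samples = 189, n_genes = 2000, n_snps = 2000,
                       n_chromosomes = 18, maf_range = c(0.05, 0.5),
                       frac_correlated_genes = 0.015,
                       rho_range = c(0.20, 0.37),
                       n_cis_genes = 10, n_trans_genes = 5, cis_beta = 1.0,
                       n_qtl = 3, n_mediated = 1, qtl_h2 = 0.2,
                       n_ase_genes = 5, n_exonic_null = 10,
                       ase_depth = 30, ase_imbalance = 0.8,
                       noise_sd = 1, ld = NULL, seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes, n_snps = n_snps,
              n_chromosomes = n_chromosomes, maf_range = maf_range,
              frac_correlated_genes = frac_correlated_genes,
              rho_range = rho_range, n_cis_genes = n_cis_genes,
              n_trans_genes = n_trans_genes, cis_beta = cis_beta,
              n_qtl = n_qtl, n_mediated = n_mediated, qtl_h2 = qtl_h2,
              n_ase_genes = n_ase_genes, n_exonic_null = n_exonic_null,
              ase_depth = ase_depth, ase_imbalance = ase_imbalance,
              noise_sd = noise_sd, ld = ld, seed = seed)
  counts <- c("n_samples", "n_genes", "n_snps", "n_chromosomes")
  for (v in counts) if (cfg[[v]] < 1) stopf("%s must be a positive count", v)
  for (v in c("frac_correlated_genes", "qtl_h2"))
    if (cfg[[v]] < 0 || cfg[[v]] > 1) stopf("%s must lie in [0, 1]", v)
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stopf("maf_range must be an increasing pair within (0, 0.5]")
  if (ase_imbalance < 0 || ase_imbalance > 1) stopf("ase_imbalance must lie in [0, 1]")
  if (n_mediated > min(n_qtl, n_cis_genes))
    stopf("n_mediated cannot exceed min(n_qtl, n_cis_genes)")
  n_corr <- round(frac_correlated_genes * n_genes)
  if (n_cis_genes + n_trans_genes + n_corr + n_ase_genes + n_exonic_null > n_genes)
    stopf("planted gene sets (%d) exceed n_genes (%d)",
          n_cis_genes + n_trans_genes + n_corr + n_ase_genes + n_exonic_null, n_genes)
  if (n_qtl + n_cis_genes + n_trans_genes + n_ase_genes + n_exonic_null > n_snps)
    stopf("planted SNP roles exceed n_snps")
  structure(cfg, class = "sim_config")
}

#' Simulate a full study dataset with planted, recorded effects
#'
#' Generates genotypes (Hardy-Weinberg at per-SNP MAF), sample covariates,
#' a phenotype built from QTL dosage effects (direct or mediated through a
#' cis gene's expression) scaled to `qtl_h2`, TPM expression with planted
#' trait-correlated, cis-eQTL and trans-eQTL genes, and heterozygote allele
#' read counts with planted imbalance. Every planted effect is recorded in
#' the returned truth table, and the covariate coefficients used for the
#' phenotype and for each gene are returned so residualization tests have a
#' known answer.
#'
#' Construction of planted correlations: the phenotype's non-covariate part
#' z is standardized, and a correlated gene's residual expression is
#' `noise_sd * (rho * z + sqrt(1 - rho^2) * w)` with iid standard normal w,
#' so the population partial correlation given the covariates equals rho.
#'
#' @param config a [sim_config()]
#' @return list with elements `genotypes` ([genotype_matrix()]),
#'   `expression` (TPM [expression_matrix()]), `samples` ([sample_table()]),
#'   `allele_counts` ([allele_count_table()]), `annotation`
#'   ([gene_annotation()]), and `truth` — a list holding `effects` (one row
#'   per planted effect: kind, gene_id, snp_id, value), `pheno_covariates`,
#'   `gene_covariates`, and the latent standardized phenotype component `z`
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_samples
  ng <- config$n_genes
  ns <- config$n_snps
  chrom_len <- 1e8
  chroms <- as.character(seq_len(config$n_chromosomes))

  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(ng))
  snp_ids <- sprintf("rs%05d", seq_len(ns))

  ## gene annotation
  g_chrom <- sample(chroms, ng, replace = TRUE)
  g_len <- round(stats::runif(ng, 5e3, 3e4))
  g_start <- round(stats::runif(ng, 1, chrom_len - max(g_len)))
  anno <- data.frame(gene_id = gene_ids, chrom = g_chrom, start = g_start,
                     end = g_start + g_len, strand = sample(c("+", "-"), ng, TRUE),
                     stringsAsFactors = FALSE)

  ## SNP map (positions may be relocated below for planted roles)
  s_chrom <- sample(chroms, ns, replace = TRUE)
  s_pos <- round(stats::runif(ns, 1, chrom_len))
  bases <- c("A", "C", "G", "T")
  s_ref <- sample(bases, ns, replace = TRUE)
  s_alt <- vapply(s_ref, function(b) sample(setdiff(bases, b), 1), character(1))

  ## planted gene roles (disjoint sets)
  n_corr <- round(config$frac_correlated_genes * ng)
  roles <- sample(seq_len(ng),
                  n_corr + config$n_cis_genes + config$n_trans_genes +
                    config$n_ase_genes + config$n_exonic_null)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- roles[seq_len(k)]
    roles <<- roles[-seq_len(k)]
    out
  }
  corr_genes <- take(n_corr)
  cis_genes <- take(config$n_cis_genes)
  trans_genes <- take(config$n_trans_genes)
  ase_genes <- take(config$n_ase_genes)
  null_exonic_genes <- take(config$n_exonic_null)

  ## planted SNP roles (disjoint); cis SNPs are relocated next to their gene,
  ## exonic SNPs inside their gene body
  snp_pool <- sample(seq_len(ns))
  take_snp <- function(k) {
    if (k == 0) return(integer(0))
    out <- snp_pool[seq_len(k)]
    snp_pool <<- snp_pool[-seq_len(k)]
    out
  }
  cis_snps <- take_snp(config$n_cis_genes)
  trans_snps <- take_snp(config$n_trans_genes)
  exonic_genes_all <- c(ase_genes, null_exonic_genes)
  exonic_snps <- take_snp(length(exonic_genes_all))
  n_direct <- config$n_qtl - config$n_mediated
  direct_qtl_snps <- take_snp(n_direct)
  qtl_snps <- c(cis_snps[seq_len(config$n_mediated)], direct_qtl_snps)

  for (i in seq_along(cis_snps)) {
    g <- cis_genes[i]
    s_chrom[cis_snps[i]] <- anno$chrom[g]
    s_pos[cis_snps[i]] <- max(1, anno$start[g] + round(stats::runif(1, -5e4, 5e4)))
  }
  for (i in seq_along(trans_snps)) {
    g <- trans_genes[i]
    other <- setdiff(chroms, anno$chrom[g])
    if (length(other)) s_chrom[trans_snps[i]] <- sample(other, 1)
    s_pos[trans_snps[i]] <- round(stats::runif(1, 1, chrom_len))
  }
  for (i in seq_along(exonic_snps)) {
    g <- exonic_genes_all[i]
    s_chrom[exonic_snps[i]] <- anno$chrom[g]
    s_pos[exonic_snps[i]] <- round(stats::runif(1, anno$start[g], anno$end[g]))
  }
  snp_map <- data.frame(snp_id = snp_ids, chrom = s_chrom, pos = s_pos,
                        ref = s_ref, alt = s_alt, stringsAsFactors = FALSE)

  ## genotypes: HWE draws at per-SNP MAF; optional block-LD
  maf <- stats::runif(ns, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(NA_real_, ns, n, dimnames = list(snp_ids, sample_ids))
  if (is.null(config$ld)) {
    for (i in seq_len(ns)) dosage[i, ] <- stats::rbinom(n, 2, maf[i])
  } else {
    bs <- config$ld$block_size %||% 10
    rho_ld <- config$ld$rho %||% 0.8
    ord <- order(s_chrom, s_pos)
    prev <- NULL
    for (k in seq_along(ord)) {
      i <- ord[k]
      fresh <- stats::rbinom(n, 2, maf[i])
      if (k %% bs == 1 || is.null(prev) || s_chrom[ord[k - 1]] != s_chrom[i]) {
        dosage[i, ] <- fresh
      } else {
        carry <- stats::runif(n) < rho_ld
        dosage[i, ] <- ifelse(carry, prev, fresh)
      }
      prev <- dosage[i, ]
    }
  }

  ## covariates
  sex <- sample(c("F", "M"), n, replace = TRUE)
  batch <- sample(paste0("B", 1:4), n, replace = TRUE)
  boar <- sample(paste0("D", 1:8), n, replace = TRUE)
  age <- round(stats::runif(n, 204, 216))

  pheno_cov <- list(
    sex = c(F = 0, M = stats::rnorm(1, 0, 0.3)),
    batch = c(B1 = 0, stats::rnorm(3, 0, 0.3)),
    boar = c(D1 = 0, stats::rnorm(7, 0, 0.3)),
    age_slope = stats::rnorm(1, 0, 0.02)
  )
  names(pheno_cov$batch) <- paste0("B", 1:4)
  names(pheno_cov$boar) <- paste0("D", 1:8)
  cov_pheno <- pheno_cov$sex[sex] + pheno_cov$batch[batch] +
    pheno_cov$boar[boar] + pheno_cov$age_slope * (age - 210)

  ## gene-level covariate coefficients (recorded for residualization tests)
  gene_cov <- list(
    sex = stats::rnorm(ng, 0, 0.3),
    batch = cbind(0, matrix(stats::rnorm(ng * 3, 0, 0.2), ng, 3)),
    boar = cbind(0, matrix(stats::rnorm(ng * 7, 0, 0.2), ng, 7)),
    age_slope = stats::rnorm(ng, 0, 0.02)
  )
  colnames(gene_cov$batch) <- paste0("B", 1:4)
  colnames(gene_cov$boar) <- paste0("D", 1:8)
  cov_expr <- outer(gene_cov$sex, as.numeric(sex == "M")) +
    gene_cov$batch[, match(batch, colnames(gene_cov$batch))] +
    gene_cov$boar[, match(boar, colnames(gene_cov$boar))] +
    outer(gene_cov$age_slope, age - 210)

  ## expression residual components (non-covariate), log2 scale
  resid_expr <- matrix(stats::rnorm(ng * n, 0, config$noise_sd), ng, n)
  cis_effects <- numeric(config$n_cis_genes)
  for (i in seq_along(cis_genes)) {
    d <- dosage[cis_snps[i], ]
    resid_expr[cis_genes[i], ] <- config$cis_beta * (d - mean(d)) +
      stats::rnorm(n, 0, config$noise_sd)
    cis_effects[i] <- config$cis_beta
  }
  for (i in seq_along(trans_genes)) {
    d <- dosage[trans_snps[i], ]
    resid_expr[trans_genes[i], ] <- config$cis_beta * (d - mean(d)) +
      stats::rnorm(n, 0, config$noise_sd)
  }

  ## phenotype: QTL effects (mediated through cis-gene expression for the
  ## first n_mediated) scaled so the QTL fraction of non-covariate variance
  ## is qtl_h2, plus Gaussian residual
  g_y <- numeric(n)
  qtl_raw <- numeric(config$n_qtl)
  if (config$n_qtl > 0) {
    for (q in seq_len(config$n_qtl)) {
      if (q <= config$n_mediated) {
        g_y <- g_y + resid_expr[cis_genes[q], ]
        qtl_raw[q] <- NA  # mediated: effect size set by the pathway
      } else {
        b <- stats::rnorm(1, 0, 1)
        d <- dosage[qtl_snps[q], ]
        g_y <- g_y + b * (d - mean(d))
        qtl_raw[q] <- b
      }
    }
    sd_g <- stats::sd(g_y)
    scale_g <- if (sd_g > 0)
      sqrt(config$qtl_h2 / max(1 - config$qtl_h2, 1e-12)) * config$noise_sd / sd_g
    else 0
    g_y <- g_y * scale_g
  } else scale_g <- 0
  z_raw <- g_y + stats::rnorm(n, 0, config$noise_sd)
  z <- (z_raw - mean(z_raw)) / stats::sd(z_raw)
  phenotype <- 3.35 + cov_pheno + z_raw

  ## planted trait-correlated genes share the standardized phenotype residual
  rho <- stats::runif(n_corr, config$rho_range[1], config$rho_range[2]) *
    sample(c(-1, 1), n_corr, replace = TRUE)
  for (i in seq_along(corr_genes)) {
    w <- stats::rnorm(n)
    resid_expr[corr_genes[i], ] <- config$noise_sd *
      (rho[i] * z + sqrt(1 - rho[i]^2) * w)
  }

  baseline <- stats::runif(ng, 3, 8)
  log2_expr <- baseline + cov_expr + resid_expr
  tpm <- pmax(2^log2_expr - 1, 0)
  dimnames(tpm) <- list(gene_ids, sample_ids)

  ## allele counts at heterozygous exonic sites
  ac <- list()
  for (i in seq_along(exonic_snps)) {
    s <- exonic_snps[i]
    hets <- which(dosage[s, ] == 1)
    if (length(hets) == 0) next
    depth <- stats::rpois(length(hets), config$ase_depth)
    p_ref <- if (i <= length(ase_genes)) config$ase_imbalance else 0.5
    ref <- stats::rbinom(length(hets), depth, p_ref)
    ac[[length(ac) + 1]] <- data.frame(
      snp_id = snp_ids[s], sample_id = sample_ids[hets],
      ref_count = ref, alt_count = depth - ref, stringsAsFactors = FALSE)
  }
  allele_counts <- if (length(ac)) do.call(rbind, ac) else
    data.frame(snp_id = character(0), sample_id = character(0),
               ref_count = integer(0), alt_count = integer(0))

  samples <- data.frame(sample_id = sample_ids, sex = sex, batch = batch,
                        boar = boar, age = age, phenotype = phenotype,
                        stringsAsFactors = FALSE)

  effects <- rbind(
    if (n_corr) data.frame(kind = "trait-correlation", gene_id = gene_ids[corr_genes],
                           snp_id = NA_character_, value = rho,
                           stringsAsFactors = FALSE),
    if (config$n_cis_genes) data.frame(kind = "cis-eQTL", gene_id = gene_ids[cis_genes],
                                       snp_id = snp_ids[cis_snps],
                                       value = cis_effects, stringsAsFactors = FALSE),
    if (config$n_trans_genes) data.frame(kind = "trans-eQTL",
                                         gene_id = gene_ids[trans_genes],
                                         snp_id = snp_ids[trans_snps],
                                         value = config$cis_beta,
                                         stringsAsFactors = FALSE),
    if (config$n_ase_genes) data.frame(kind = "ASE", gene_id = gene_ids[ase_genes],
                                       snp_id = snp_ids[exonic_snps[seq_along(ase_genes)]],
                                       value = config$ase_imbalance,
                                       stringsAsFactors = FALSE),
    if (config$n_qtl) data.frame(kind = "QTL",
                                 gene_id = c(gene_ids[cis_genes[seq_len(config$n_mediated)]],
                                             rep(NA_character_, n_direct))[seq_len(config$n_qtl)],
                                 snp_id = snp_ids[qtl_snps],
                                 # mediated QTLs: effect size is the pathway
                                 # scaling applied to the gene's cis effect
                                 value = ifelse(is.na(qtl_raw),
                                                scale_g * config$cis_beta,
                                                qtl_raw * scale_g),
                                 stringsAsFactors = FALSE)
  )

  list(
    genotypes = genotype_matrix(dosage, snp_map),
    expression = expression_matrix(tpm),
    samples = sample_table(samples),
    allele_counts = allele_count_table(allele_counts),
    annotation = gene_annotation(anno),
    truth = list(effects = effects, maf = stats::setNames(maf, snp_ids),
                 pheno_covariates = pheno_cov, gene_covariates = gene_cov,
                 z = z, config = config)
  )
}

#' Write a simulated dataset to a directory in pipeline-readable formats
#'
#' Emits genotypes.vcf, expression.tsv, samples.tsv, allele_counts.tsv,
#' annotation.tsv and truth_effects.tsv so any run can be pointed at a
#' simulated directory instead of real study files.
#'
#' @param sim output of [simulate_population()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"), dialect = "vcf")
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  write_allele_counts(sim$allele_counts, file.path(dir, "allele_counts.tsv"))
  write_gene_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(sim$truth$effects, file.path(dir, "truth_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
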