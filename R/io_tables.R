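#' Construct and validate an expression matrix
#'
#' A gene x sample matrix of TPM (transcripts per million) values. Row names
#' are gene ids, column names sample ids; both must be unique, values must be
#' finite and non-negative.
#'
#' @param values numeric matrix, genes in rows, samples in columns
#' @return the validated matrix (invisibly unchanged)
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene id(s): %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample id(s): %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stopf("expression matrix contains non-finite values (first at row '%s')",
          rownames(values)[which(!is.finite(values), arr.ind = TRUE)[1, 1]])
  if (any(values < 0))
    stopf("negative expression value at gene '%s'",
          rownames(values)[which(values < 0, arr.ind = TRUE)[1, 1]])
  values
}

#' Construct and validate a genotype matrix
#'
#' Dosage coding counts alternate alleles: 0, 1, 2 or NA (missing). The SNP
#' map carries 1-based positions and ref/alt alleles.
#'
#' @param dosage numeric matrix, SNPs in rows (named), samples in columns (named)
#' @param map data.frame with columns snp_id, chrom, pos, ref, alt;
#'   one row per row of `dosage`, same order
#' @return list with elements `dosage` and `map`, class "GenotypeMatrix"
#' @export
genotype_matrix <- function(dosage, map) {
  if (!is.matrix(dosage)) stopf("dosage must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stopf("dosage matrix needs SNP row names and sample column names")
  if (anyDuplicated(rownames(dosage))) stopf("duplicate SNP id(s) in dosage matrix")
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map)))
    stopf("SNP map must have columns: %s", paste(need, collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  for (v in c("snp_id", "chrom", "ref", "alt")) map[[v]] <- as.character(map[[v]])
  map$pos <- as.integer(map$pos)
  if (!identical(as.character(map$snp_id), rownames(dosage)))
    stopf("SNP map rows must match dosage rows (same ids, same order)")
  if (any(map$pos < 1)) stopf("SNP positions must be >= 1 (1-based)")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stopf("dosage values must be 0/1/2 or missing; offending SNP '%s'",
          rownames(dosage)[which(matrix(bad, nrow(dosage)), arr.ind = TRUE)[1, 1]])
  structure(list(dosage = dosage, map = map), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples, %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Validate a sample table
#'
#' One row per sample with the study covariates (sex, slaughter batch, boar,
#' age in days) and the phenotype (e.g. intramuscular fat percentage).
#'
#' @param df data.frame with columns sample_id, sex, batch, boar, age, phenotype
#' @return the validated data.frame with categorical columns as factors
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "sex", "batch", "boar", "age", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in sample table")
  if (!is.numeric(df$age)) stopf("age must be numeric (days)")
  if (!is.numeric(df$phenotype)) stopf("phenotype must be numeric")
  if (any(is.infinite(df$phenotype), na.rm = TRUE)) stopf("phenotype contains non-finite values")
  df$sample_id <- as.character(df$sample_id)
  for (v in c("sex", "batch", "boar")) df[[v]] <- factor(df[[v]])
  df
}

#' Validate an allele read-count table
#'
#' Per (SNP, sample) reference and alternate allele read counts at
#' heterozygous sites, in the style of ASEReadCounter output.
#'
#' @param df data.frame with columns snp_id, sample_id, ref_count, alt_count
#' @return the validated data.frame
#' @export
allele_count_table <- function(df) {
  need <- c("snp_id", "sample_id", "ref_count", "alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("allele count table missing column(s): %s", paste(miss, collapse = ", "))
  for (v in c("ref_count", "alt_count")) {
    x <- df[[v]]
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != round(x)))
      stopf("%s must be non-negative integers", v)
  }
  df$snp_id <- as.character(df$snp_id)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Validate a gene annotation table
#'
#' 1-based inclusive coordinates (VCF/GFF convention). Strand is read but
#' ignored by all distance computations.
#'
#' @param df data.frame with columns gene_id, chrom, start, end and optional strand
#' @return the validated data.frame
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene annotation missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in annotation")
  if (any(df$start > df$end)) stopf("annotation has start > end (1-based inclusive expected)")
  if (any(df$start < 1)) stopf("annotation coordinates must be >= 1")
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a gene x sample TPM table
#'
#' Expects TSV with a header row of sample ids and the gene id in the first
#' column. Malformed input (duplicate ids, negative or non-numeric cells) is
#' rejected with an error naming the offending row or column.
#'
#' @param path TSV file path
#' @return validated expression matrix (see [expression_matrix()])
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) stopf("expression table needs a gene id column plus samples")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]))
      stopf("non-numeric expression values in column '%s'", names(vals)[j])
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m)
}

#' Write a gene x sample TPM table
#' @param expr expression matrix
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or TSV
#'
#' For `dialect = "vcf"` the GT field is converted to dosage:
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA` (phased `|`
#' separators are accepted too). Multiallelic records are rejected.
#' For `dialect = "tsv"` a dosage matrix file (first column snp_id, sample
#' columns) and a SNP map file (snp_id, chrom, pos, ref, alt) are required.
#'
#' @param path VCF path, or dosage-TSV path
#' @param dialect "vcf" or "tsv"
#' @param map_path SNP map TSV (tsv dialect only)
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, dialect = c("vcf", "tsv"), map_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    if (any(grepl(",", alt, fixed = TRUE)))
      stopf("multiallelic record(s) not supported (first at %s:%s)",
            fix[which(grepl(",", alt))[1], "CHROM"], fix[which(grepl(",", alt))[1], "POS"])
    gt <- vcfR::extract.gt(v, element = "GT")
    conv <- function(g) {
      g <- gsub("|", "/", g, fixed = TRUE)
      out <- rep(NA_real_, length(g))
      out[g %in% "0/0"] <- 0
      out[g %in% c("0/1", "1/0")] <- 1
      out[g %in% "1/1"] <- 2
      bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./."))
      if (any(bad)) stopf("unsupported GT value '%s'", g[bad][1])
      out
    }
    dos <- apply(gt, 2, conv)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    rownames(dos) <- ids
    map <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = alt, stringsAsFactors = FALSE)
    return(genotype_matrix(dos, map))
  }
  df <- read_tsv_strict(path)
  if (is.null(map_path)) stopf("tsv dialect needs a SNP map file (map_path)")
  map <- read_tsv_strict(map_path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric dosage values in %s", path)
  rownames(m) <- ids
  map$snp_id <- as.character(map$snp_id)
  missing_map <- setdiff(ids, map$snp_id)
  if (length(missing_map))
    stopf("SNP map is missing %d id(s), e.g. '%s'", length(missing_map), missing_map[1])
  map <- map[match(ids, map$snp_id), , drop = FALSE]
  rownames(map) <- NULL
  genotype_matrix(m, map)
}

#' Write genotypes as VCF or TSV
#'
#' The VCF writer emits a minimal VCFv4.2 file with GT-only genotype fields;
#' missing dosages become `./.`. The TSV writer emits the dosage matrix and a
#' companion SNP map file `<path>.map.tsv` (or `map_path`).
#'
#' @param gt a [genotype_matrix()]
#' @param path output path
#' @param dialect "vcf" or "tsv"
#' @param map_path map output path for the tsv dialect
#' @return `path`, invisibly
#' @export
write_genotypes <- function(gt, path, dialect = c("vcf", "tsv"), map_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- data.frame(snp_id = rownames(gt$dosage), gt$dosage, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    map_path <- map_path %||% paste0(path, ".map.tsv")
    utils::write.table(gt$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gts <- matrix(c("0/0", "0/1", "1/1")[gt$dosage + 1], nrow = nrow(gt$dosage))
  gts[is.na(gt$dosage)] <- "./."
  ord <- order(gt$map$chrom, gt$map$pos)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gt$dosage)), collapse = "\t"))
  body <- vapply(ord, function(i) {
    paste(c(gt$map$chrom[i], gt$map$pos[i], gt$map$snp_id[i], gt$map$ref[i],
            gt$map$alt[i], ".", "PASS", ".", "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample covariate/phenotype table
#' @param path TSV with columns sample_id, sex, batch, boar, age, phenotype
#' @return validated data.frame (see [sample_table()])
#' @export
read_sample_table <- function(path) sample_table(read_tsv_strict(path))

#' @rdname read_sample_table
#' @param samples sample table
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele read-count table
#' @param path TSV with columns snp_id, sample_id, ref_count, alt_count
#' @return validated data.frame (see [allele_count_table()])
#' @export
read_allele_counts <- function(path) allele_count_table(read_tsv_strict(path))

#' @rdname read_allele_counts
#' @param counts allele count table
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#' @param path TSV with columns gene_id, chrom, start, end (strand optional)
#' @return validated data.frame (see [gene_annotation()])
#' @export
read_gene_annotation <- function(path) gene_annotation(read_tsv_strict(path))

#' @rdname read_gene_annotation
#' @param anno annotation table
#' @export
write_gene_annotation <- function(anno, path) {
  utils::write.table(anno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline result tables as TSV
#'
#' Serializes a named list of result data.frames into `out_dir`, one file per
#' table, with deterministic column order (as given) and p-value/FDR columns
#' rendered in scientific notation with 3 significant digits. An empty table
#' produces a header-only file. Re-serializing a read-back table is
#' byte-identical because formatting is applied only to the p/FDR columns,
#' which round-trip exactly at 3 significant digits.
#'
#' @param results named list of data.frames
#' @param out_dir output directory (created if needed)
#' @return character vector of files written, invisibly
#' @export
write_result_tables <- function(results, out_dir) {
  if (is.null(names(results)) || any(names(results) == ""))
    stopf("results must be a named list of tables")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sci_cols <- c("p", "fdr", "fdr_perm", "cor_p", "cor_fdr", "eqtl_p",
                "eqtl_fdr", "gwas_p", "p_perm", "site_p")
  files <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]], stringsAsFactors = FALSE)
    for (cc in intersect(names(df), sci_cols))
      if (is.numeric(df[[cc]])) df[[cc]] <- format_sci3(df[[cc]])
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
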