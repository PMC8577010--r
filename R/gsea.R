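#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list (descending weight, e.g. trait-gene Pearson r):
#' hitting a set member increments the running sum by |w|^weight_exp
#' normalized by the sum over all hits; missing decrements by 1/(N - Nh).
#' The enrichment score is the extremum of the running sum (largest absolute
#' deviation from zero). The running sum starts and ends at 0.
#'
#' @param ranked data.frame with columns gene_id and weight, or a named
#'   numeric vector of weights; sorted by descending weight internally
#' @param gene_set character vector of gene ids
#' @param weight_exp exponent on |weight| for hit increments, default 1
#'   (0 gives the classic unweighted KS statistic)
#' @return list with `es` and the `running` sum profile (length N)
#' @export
enrichment_score <- function(ranked, gene_set, weight_exp = 1) {
  rk <- as_ranked_list(ranked)
  hit <- rk$gene_id %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stopf("gene set has no overlap with the ranked list")
  if (nh == length(hit)) stopf("gene set covers the entire ranked list")
  w <- abs(rk$weight)^weight_exp
  inc <- numeric(length(hit))
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (length(hit) - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

# normalize user input into a ranked list: data.frame(gene_id, weight),
# sorted by descending weight, unique genes, finite weights
as_ranked_list <- function(ranked) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- data.frame(gene_id = names(ranked), weight = as.numeric(ranked),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("gene_id", "weight") %in% names(ranked)))
    stopf("ranked list needs gene_id and weight columns (or a named vector)")
  if (anyDuplicated(ranked$gene_id)) stopf("duplicate genes in ranked list")
  if (any(!is.finite(ranked$weight))) stopf("non-finite ranking weights")
  ranked[order(-ranked$weight, ranked$gene_id), , drop = FALSE]
}

#' Preranked GSEA with permutation NES and FDR
#'
#' The null is gene-label permutation: for each permutation the weights stay
#' in place and each set's members are redrawn uniformly among the ranked
#' genes, preserving set size. NES = ES / mean(|null ES|) over null ES of the
#' same sign as the observed ES. FDR follows the standard pooled
#' positive/negative procedure: for a set with NES* > 0 it is the fraction
#' of positive null NES >= NES* divided by the fraction of positive observed
#' NES >= NES* (mirrored for negative scores), capped at 1.
#'
#' @param ranked ranked list (see [enrichment_score()])
#' @param gene_sets named list of character vectors
#' @param n_perm permutations per set, default 1000
#' @param seed integer seed (mandatory)
#' @param weight_exp see [enrichment_score()]
#' @param fdr_threshold significance flag cutoff, default 0.25
#' @return data.frame: set_name, size, es, nes, p_perm, fdr, significant,
#'   leading_edge (slash-separated gene ids)
#' @export
nes_fdr <- function(ranked, gene_sets, n_perm = 1000, seed, weight_exp = 1,
                    fdr_threshold = 0.25) {
  if (missing(seed) || is.null(seed)) stopf("seed is mandatory for GSEA permutations")
  if (length(gene_sets) < 2) stopf("need >= 2 gene sets for pooled FDR estimation")
  if (n_perm < 100) warnf("n_perm = %d is very small for FDR estimation", n_perm)
  rk <- as_ranked_list(ranked)
  ng <- nrow(rk)
  set.seed(seed)
  res <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], rk$gene_id)
    if (length(gs) == 0 || length(gs) == ng)
      stopf("gene set '%s' has degenerate overlap with the ranked list", nm)
    obs <- enrichment_score(rk, gs, weight_exp)
    null_es <- vapply(seq_len(n_perm), function(b) {
      fake <- sample(rk$gene_id, length(gs))
      enrichment_score(rk, fake, weight_exp)$es
    }, numeric(1))
    same <- null_es * sign(obs$es) > 0
    denom <- if (any(same)) mean(abs(null_es[same])) else mean(abs(null_es))
    nes <- obs$es / denom
    p_perm <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + sum(same))
    null_nes <- null_es
    null_nes[null_es > 0] <- null_es[null_es > 0] /
      (if (any(null_es > 0)) mean(null_es[null_es > 0]) else 1)
    null_nes[null_es < 0] <- null_es[null_es < 0] /
      (if (any(null_es < 0)) mean(abs(null_es[null_es < 0])) else 1)
    # leading edge: hits at or before the running-sum extremum (after, for
    # negative scores)
    hitpos <- which(rk$gene_id %in% gs)
    peak <- which.max(abs(obs$running))
    le <- if (obs$es >= 0) rk$gene_id[intersect(hitpos, seq_len(peak))]
          else rk$gene_id[intersect(hitpos, peak:ng)]
    list(set_name = nm, size = length(gs), es = obs$es, nes = nes,
         p_perm = p_perm, null_nes = null_nes,
         leading_edge = paste(le, collapse = "/"))
  })
  nes_obs <- vapply(res, `[[`, numeric(1), "nes")
  null_pool <- unlist(lapply(res, `[[`, "null_nes"))
  fdr <- vapply(seq_along(res), function(i) {
    s <- nes_obs[i]
    if (s >= 0) {
      num <- mean(null_pool[null_pool >= 0] >= s)
      den <- mean(nes_obs[nes_obs >= 0] >= s)
    } else {
      num <- mean(null_pool[null_pool <= 0] <= s)
      den <- mean(nes_obs[nes_obs <= 0] <= s)
    }
    if (is.nan(num)) num <- 0
    min(num / max(den, .Machine$double.eps), 1)
  }, numeric(1))
  out <- data.frame(
    set_name = vapply(res, `[[`, character(1), "set_name"),
    size = vapply(res, `[[`, numeric(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = nes_obs,
    p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
    fdr = fdr,
    leading_edge = vapply(res, `[[`, character(1), "leading_edge"),
    stringsAsFactors = FALSE)
  out$significant <- out$fdr < fdr_threshold
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name<TAB>description<TAB>`
#' then member gene ids.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: '%s'", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                        character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors
#' @param descriptions optional character vector (defaults to the set names)
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
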