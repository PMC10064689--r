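# Taxa <-> transcriptome integration: highly-variable-gene selection,
# taxon x gene correlation, per-taxon preranked GSEA, and the filtered NES
# matrix relating every taxon to every gene set.

#' Select highly variable genes
#'
#' Top-`n` genes by variance of `log2(CPM + 1)`, with deterministic
#' tie-breaking by gene identifier.
#'
#' @param expr An [expression_matrix()] of counts, or a numeric
#'   gene x sample matrix.
#' @param n Number of genes to keep.
#' @return Character vector of gene identifiers, highest variance first.
#' @export
select_hvg <- function(expr, n = 5000L) {
  m <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (n > nrow(m)) {
    ct_input_error(sprintf("n = %d exceeds the %d available genes", n, nrow(m)))
  }
  cpm <- sweep(m, 2L, colSums(m), "/") * 1e6
  v <- apply(log2(cpm + 1), 1L, stats::var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Taxon x gene correlation matrix
#'
#' Pearson (or Spearman) correlation between each taxon's log2[CP1K+1]
#' abundance and each gene's log-scale expression over the shared samples.
#' Taxa must be present (abundance > 0) in at least `taxa_min_samples`
#' samples; constant vectors yield `NA`, which downstream ranking drops.
#'
#' @param taxa_log Samples x taxa matrix of log2[CP1K+1] values.
#' @param expr_log Genes x samples matrix of log-scale expression.
#' @param taxa_min_samples Presence filter (default 2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Numeric taxa x genes correlation matrix.
#' @export
taxa_gene_correlation <- function(taxa_log, expr_log, taxa_min_samples = 2L,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(expr_log, "expression_matrix")) expr_log <- expr_log$values
  shared <- intersect(rownames(taxa_log), colnames(expr_log))
  if (length(shared) < 3L) ct_input_error("need >= 3 shared samples")
  tl <- taxa_log[shared, , drop = FALSE]
  keep <- colSums(tl > 0) >= taxa_min_samples
  if (!any(keep)) ct_input_error("no taxon passes the presence filter")
  tl <- tl[, keep, drop = FALSE]
  el <- t(expr_log[, shared, drop = FALSE])
  suppressWarnings(stats::cor(tl, el, method = method))
}

#' Rank genes by score
#'
#' @param scores Named numeric vector (e.g. one row of the correlation
#'   matrix); `NA` scores are dropped. Order is descending by score with
#'   deterministic tie-breaking by gene identifier.
#' @return Data frame with columns `gene` and `score`.
#' @export
ranked_list <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) ct_input_error("no finite scores to rank")
  ord <- order(-scores, names(scores))
  data.frame(gene = names(scores)[ord], score = unname(scores)[ord],
             stringsAsFactors = FALSE)
}

# Enrichment score from sorted hit positions in a ranked list.
# absw: |score|^p over the whole list; h: sorted hit positions.
es_from_positions <- function(absw, h) {
  N <- length(absw); k <- length(h)
  if (k == N) return(1)          # degenerate: every gene is a hit
  w <- absw[h]
  W <- sum(w)
  cum <- if (W > 0) cumsum(w) / W else cumsum(rep(1 / k, k))
  m <- 1 / (N - k)
  miss_before <- h - seq_len(k)
  after <- cum - miss_before * m               # value just after each hit
  before <- c(0, cum[-k]) - miss_before * m    # value just before each hit
  hi <- max(after)
  lo <- min(c(before, 0))
  if (hi >= abs(lo)) hi else lo
}

#' Preranked gene set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Walks the ranked list accumulating `|score|^p / sum(hit |score|^p)` at
#' set members and `-1/(N - N_hits)` elsewhere; the enrichment score ES is
#' the extremum of this running sum. The null distribution is built by
#' random gene-label permutation with a fixed seed; NES is ES divided by
#' the mean |null ES| of matching sign, and the permutation p-value is
#' `(1 + #{same-sign nulls with |null| >= |ES|}) / (1 + #same-sign nulls)`.
#'
#' @param ranked Data frame from [ranked_list()].
#' @param gene_set Character vector of member genes.
#' @param n_perm Number of permutations (>= 100).
#' @param weight_p Score weighting exponent (default 1).
#' @param seed Integer seed.
#' @return A list (`gsea_result`): `es`, `nes`, `p_value`, `size`
#'   (set members present in the list), `n_perm`, `degenerate`.
#' @export
preranked_gsea <- function(ranked, gene_set, n_perm = 1000L, weight_p = 1,
                           seed = 1L) {
  if (n_perm < 100L) ct_config_error("n_perm must be >= 100")
  hits <- which(ranked$gene %in% gene_set)
  if (!length(hits)) ct_input_error("gene set has no members in the ranked list")
  N <- nrow(ranked)
  absw <- abs(ranked$score)^weight_p
  es <- es_from_positions(absw, hits)
  if (length(hits) == N) {
    return(structure(list(es = 1, nes = NA_real_, p_value = NA_real_,
                          size = N, n_perm = 0L, degenerate = TRUE),
                     class = "gsea_result"))
  }
  k <- length(hits)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    es_from_positions(absw, sort.int(sample.int(N, k)))
  }, numeric(1)))
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same)) {
    nes <- es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  } else {
    nes <- NA_real_
    p <- 1 / (1 + 0)
  }
  structure(list(es = es, nes = nes, p_value = p, size = k,
                 n_perm = n_perm, degenerate = FALSE),
            class = "gsea_result")
}

#' Taxa x gene-set NES matrix with significance filtering
#'
#' For every taxon, genes are ranked by their correlation with that taxon
#' and preranked GSEA is run against every library set (restricted to
#' sets with `set_size[1]`-`set_size[2]` members present among the ranked
#' genes). Entries with `p >= alpha` are masked; taxa (rows) and sets
#' (columns) with fewer than `min_significant` significant entries are
#' dropped.
#'
#' @param corr Taxa x genes correlation matrix from
#'   [taxa_gene_correlation()].
#' @param library A [gene_set_library()].
#' @param min_significant Row/column inclusion threshold (default 10).
#' @param alpha Significance level on the permutation p (default 0.05).
#' @param n_perm Permutations per test.
#' @param seed Integer seed (per-taxon seeds are derived deterministically).
#' @param set_size Length-2 inclusive bounds on gene-set size.
#' @return A `nes_matrix` object: `nes` and `p` matrices (full, unfiltered
#'   masked with NA where the set was untestable), `significant` logical
#'   mask, `kept_taxa`, `kept_sets`, and the filter parameters.
#' @export
nes_matrix <- function(corr, library, min_significant = 10L, alpha = 0.05,
                       n_perm = 1000L, seed = 1L, set_size = c(10L, 500L)) {
  stopifnot(inherits(library, "gene_set_library"))
  genes <- colnames(corr)
  sizes <- vapply(library, function(s) sum(genes %in% s), integer(1))
  keep_sets <- sizes >= set_size[1L] & sizes <= set_size[2L]
  if (!any(keep_sets)) ct_input_error("library empty after size filtering")
  lib <- library[keep_sets]
  nes <- p <- matrix(NA_real_, nrow(corr), length(lib),
                     dimnames = list(rownames(corr), names(lib)))
  for (i in seq_len(nrow(corr))) {
    rl <- ranked_list(corr[i, ])
    for (j in seq_along(lib)) {
      r <- preranked_gsea(rl, lib[[j]], n_perm = n_perm,
                          seed = seed + i * 1000L + j)
      if (!r$degenerate) { nes[i, j] <- r$nes; p[i, j] <- r$p_value }
    }
  }
  sig <- !is.na(p) & p < alpha
  keep_r <- rowSums(sig) >= min_significant
  keep_c <- colSums(sig) >= min_significant
  structure(list(nes = nes, p = p, significant = sig,
                 kept_taxa = rownames(corr)[keep_r],
                 kept_sets = names(lib)[keep_c],
                 min_significant = min_significant, alpha = alpha),
            class = "nes_matrix")
}

#' @export
print.nes_matrix <- function(x, ...) {
  cat(sprintf("nes_matrix: %d x %d tested, %d taxa and %d sets pass the >= %d significant-entry filter (alpha = %s)\n",
              nrow(x$nes), ncol(x$nes), length(x$kept_taxa),
              length(x$kept_sets), x$min_significant, format(x$alpha)))
  invisible(x)
}
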