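# Normalization, taxa filtering, alpha diversity, paired diversity tests,
# and luminal-vs-tissue differential abundance.

#' Filter low-count taxa
#'
#' Retains taxa with more than `min_count` reads in at least one sample
#' (strict inequality: a taxon whose best sample has exactly `min_count`
#' reads is removed). The sample set is unchanged.
#'
#' @param table A [taxa_table()].
#' @param min_count Count threshold (default 3).
#' @return A filtered [taxa_table()].
#' @export
filter_taxa <- function(table, min_count = 3L) {
  stopifnot(inherits(table, "taxa_table"))
  keep <- apply(table$counts, 2L, max) > min_count
  if (!any(keep)) ct_input_error("all taxa removed by the count filter")
  taxa_table(table$counts[, keep, drop = FALSE], table$site)
}

#' Total-sum scaling to relative abundances
#'
#' @param table A [taxa_table()].
#' @return Numeric samples x taxa matrix of fractions; every row sums to 1.
#' @export
tss_normalize <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  depth <- rowSums(table$counts)
  zero <- which(depth == 0)
  if (length(zero)) {
    ct_input_error(sprintf("sample '%s' has zero sequencing depth",
                           rownames(table$counts)[zero[1L]]))
  }
  sweep(table$counts, 1L, depth, "/")
}

#' log2 counts-per-thousand transform
#'
#' The working transform of all downstream microbiome statistics:
#' `log2(count / depth * 1000 + 1)` per cell, i.e. log2 of counts per
#' thousand reads plus one.
#'
#' @param table A [taxa_table()].
#' @return Numeric samples x taxa matrix; entries are >= 0 and monotone in
#'   the count at fixed depth.
#' @export
log2_cp1k <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  depth <- rowSums(table$counts)
  zero <- which(depth == 0)
  if (length(zero)) {
    ct_input_error(sprintf("sample '%s' has zero sequencing depth",
                           rownames(table$counts)[zero[1L]]))
  }
  log2(sweep(table$counts, 1L, depth, "/") * 1000 + 1)
}

# Per-sample upper-quartile of counts scaled by library size.
uq_scaled <- function(counts, lib.size) {
  apply(sweep(counts, 2L, lib.size, "/"), 2L,
        stats::quantile, probs = 0.75, names = FALSE)
}

# Trimmed mean of M-values between one sample and the reference.
tmm_pair <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05,
                     a_cutoff = -1e10) {
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))          # M values
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2  # A values
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref  # delta-method precision
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  f <- 2^f
  if (!is.finite(f)) f <- 1
  f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scale factors for a count matrix: the reference is
#' the sample whose library-size-scaled upper quartile is closest to the
#' mean upper quartile; for every sample, gene-wise log ratios (M) against
#' the reference are trimmed by 30% on M and 5% on average abundance (A),
#' and averaged with delta-method precision weights. Factors are
#' renormalized to have geometric mean 1.
#'
#' @param counts An [expression_matrix()] of raw counts, or a numeric
#'   gene x sample count matrix.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts) {
  m <- if (inherits(counts, "expression_matrix")) counts$values else counts
  if (!is.matrix(m) || ncol(m) < 2L) {
    ct_input_error("TMM needs a count matrix with at least 2 samples")
  }
  lib.size <- colSums(m)
  if (any(lib.size == 0)) {
    ct_input_error(sprintf("sample '%s' has all-zero counts",
                           colnames(m)[which(lib.size == 0)[1L]]))
  }
  f75 <- uq_scaled(m, lib.size)
  ref <- if (stats::median(f75) < 1e-20) {
    which.max(colSums(sqrt(m)))
  } else {
    which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(m)), function(j) tmm_pair(m[, j], m[, ref]),
              numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

#' Alpha diversity indices per sample
#'
#' Shannon entropy (nats), Simpson index (1 - sum p^2) and inverse Simpson
#' (1 / sum p^2) on a relative-abundance matrix.
#'
#' @param relabund Samples x taxa matrix of fractions; rows must sum to 1.
#' @return Data frame with columns `sample`, `shannon`, `simpson`,
#'   `inv_simpson`.
#' @export
alpha_diversity <- function(relabund) {
  if (any(relabund < 0)) ct_input_error("negative relative abundances")
  if (any(abs(rowSums(relabund) - 1) > 1e-6)) {
    ct_input_error("rows must sum to 1 (run tss_normalize first)")
  }
  shannon <- apply(relabund, 1L, function(p) {
    p <- p[p > 0]; -sum(p * log(p))
  })
  sumsq <- rowSums(relabund^2)
  data.frame(sample = rownames(relabund),
             shannon = shannon,
             simpson = 1 - sumsq,
             inv_simpson = 1 / sumsq,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired luminal-vs-tissue diversity test
#'
#' Wilcoxon signed-rank test per diversity index over participants present
#' at both sites. Zero differences are dropped (the signed-rank
#' convention); if no nonzero differences remain the p-value is reported
#' as 1 with a warning. Exact p-values for up to 25 informative pairs,
#' normal approximation with continuity correction beyond.
#'
#' @param lum,tis Data frames from [alpha_diversity()], matched by `sample`.
#' @return Data frame with one row per index: `index`, `statistic` (V),
#'   `p_value`, `direction` (sign of the median paired difference),
#'   `n_pairs`.
#' @export
paired_diversity_test <- function(lum, tis) {
  shared <- intersect(lum$sample, tis$sample)
  if (!length(shared)) ct_input_error("no overlapping participants")
  lum <- lum[match(shared, lum$sample), ]
  tis <- tis[match(shared, tis$sample), ]
  idx <- c("shannon", "simpson", "inv_simpson")
  out <- lapply(idx, function(ix) {
    d <- tis[[ix]] - lum[[ix]]
    nz <- sum(d != 0)
    if (nz == 0L) {
      warning(sprintf("all paired differences are zero for %s; p = 1", ix))
      return(data.frame(index = ix, statistic = NA_real_, p_value = 1,
                        direction = "none", n_pairs = length(d)))
    }
    wt <- suppressWarnings(stats::wilcox.test(
      tis[[ix]], lum[[ix]], paired = TRUE, exact = nz <= 25, correct = TRUE))
    md <- stats::median(d[d != 0])
    data.frame(index = ix, statistic = unname(wt$statistic),
               p_value = wt$p.value,
               direction = if (md > 0) "tissue higher"
                           else if (md < 0) "luminal higher" else "none",
               n_pairs = length(d))
  })
  do.call(rbind, out)
}

#' Differential abundance between sites (Mann-Whitney U)
#'
#' Unpaired two-sided Mann-Whitney U test per taxon on log2[CP1K+1]
#' abundances, with `log2FC = mean(tissue) - mean(luminal)` of the
#' transformed values. A taxon is flagged significant when
#' `|log2FC| > fc_threshold` and `p < p_threshold`. Exact p-values where
#' the sample sizes permit and no ties occur; otherwise the normal
#' approximation with mid-ranks, tie correction and continuity correction.
#'
#' @param lum_log,tis_log Samples x taxa matrices of log2[CP1K+1] values
#'   over an identical taxon panel.
#' @param fc_threshold Absolute log2 fold-change threshold (default 0.25).
#' @param p_threshold p-value threshold (default 0.01).
#' @return Data frame (one row per taxon, significant taxa first, ordered
#'   by descending |log2FC|): `taxon`, `U`, `p_value`, `log2fc`,
#'   `significant`.
#' @export
differential_abundance <- function(lum_log, tis_log,
                                   fc_threshold = 0.25, p_threshold = 0.01) {
  if (!setequal(colnames(lum_log), colnames(tis_log))) {
    miss <- c(setdiff(colnames(lum_log), colnames(tis_log)),
              setdiff(colnames(tis_log), colnames(lum_log)))
    ct_input_error(sprintf("taxon '%s' absent from one matrix", miss[1L]))
  }
  tis_log <- tis_log[, colnames(lum_log), drop = FALSE]
  res <- lapply(colnames(lum_log), function(tx) {
    x <- tis_log[, tx]; y <- lum_log[, tx]
    wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    data.frame(taxon = tx, U = unname(wt$statistic), p_value = wt$p.value,
               log2fc = mean(x) - mean(y), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant <- abs(res$log2fc) > fc_threshold & res$p_value < p_threshold
  res[order(-res$significant, -abs(res$log2fc)), , drop = FALSE]
}
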