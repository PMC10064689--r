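# Differential feature analysis across community groups (genes or KO
# terms), module discovery by hierarchical clustering, and hypergeometric
# set enrichment (GO/KEGG/TF-PPI style).

as_group_factor <- function(labels, samples) {
  if (is.data.frame(labels)) {
    if (!all(c("sample", "label") %in% names(labels))) {
      ct_input_error("labels data frame needs `sample` and `label` columns")
    }
    v <- stats::setNames(as.character(labels$label), labels$sample)
  } else {
    v <- stats::setNames(as.character(labels), names(labels))
  }
  miss <- setdiff(samples, names(v))
  if (length(miss)) ct_input_error(sprintf("no label for sample '%s'", miss[1L]))
  factor(v[samples])
}

# Moment-based NB dispersion per feature, pooled within groups, shrunk
# toward the common value with weight n / (n + 20).
moment_dispersions <- function(counts, grp, eff_lib) {
  scaled <- sweep(counts, 2L, eff_lib / mean(eff_lib), "/")
  tag <- apply(scaled, 1L, function(y) {
    num <- 0; den <- 0
    for (lv in levels(grp)) {
      yi <- y[grp == lv]
      if (length(yi) < 2L) next
      m <- mean(yi); v <- stats::var(yi)
      if (m > 0) { num <- num + (length(yi) - 1) * (v - m) / m^2; den <- den + (length(yi) - 1) }
    }
    if (den > 0) max(num / den, 1e-4) else NA_real_
  })
  common <- stats::median(tag, na.rm = TRUE)
  if (!is.finite(common)) common <- 0.1
  tag[is.na(tag)] <- common
  w <- ncol(counts) / (ncol(counts) + 20)
  pmax(w * tag + (1 - w) * common, 1e-4)
}

#' Differential features across community groups (NB log-linear model)
#'
#' A deliberately simple negative-binomial workhorse: per-feature NB
#' log-linear model with the group factor plus blocking covariates, TMM
#' library-size offsets, moment-based tagwise dispersion shrunk toward the
#' common value (weight `n/(n+20)`), a likelihood-ratio omnibus test of the
#' group factor, and Wald pairwise contrasts between all group pairs.
#' Features with counts below `min_count` in at least `min_samples`
#' samples are removed before testing.
#'
#' @param expr An [expression_matrix()] of raw counts (or count matrix).
#' @param labels Group labels: a named vector or a data frame with
#'   `sample` and `label` columns (e.g. from [classify_luminal()], using
#'   the `label` column).
#' @param blocking Optional data frame with a `sample` column plus blocking
#'   covariates (e.g. `hiv`, `dmpa`).
#' @param min_count,min_samples Low-count filter parameters (defaults 5
#'   and 3: drop features with counts < 5 in >= 3 samples).
#' @param p_threshold Omnibus significance threshold (default 0.01).
#' @param fdr_threshold Pairwise BH threshold (default 0.05).
#' @return List of class `de_result`: `omnibus` (feature, p, fdr, lfc of
#'   the widest pairwise contrast, significant flag), `pairwise` (feature,
#'   contrast, log2fc, p, fdr), `dispersion`, `kept_features`.
#' @export
differential_features <- function(expr, labels, blocking = NULL,
                                  min_count = 5L, min_samples = 3L,
                                  p_threshold = 0.01, fdr_threshold = 0.05) {
  counts <- if (inherits(expr, "expression_matrix")) expr$values else expr
  grp <- as_group_factor(labels, colnames(counts))
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L) ct_input_error("need >= 2 groups")
  if (any(table(grp) < 2L)) {
    ct_input_error(sprintf("group '%s' has fewer than 2 samples",
                           names(which(table(grp) < 2L))[1L]))
  }
  keep <- rowSums(counts < min_count) < min_samples
  if (!any(keep)) ct_input_error("no feature passes the low-count filter")
  counts <- counts[keep, , drop = FALSE]

  tmm <- tmm_factors(counts)
  eff_lib <- colSums(counts) * tmm
  off <- log(eff_lib)

  covars <- data.frame(group = grp)
  if (!is.null(blocking)) {
    bl <- blocking[match(colnames(counts), blocking$sample), , drop = FALSE]
    for (cn in setdiff(names(bl), "sample")) covars[[cn]] <- bl[[cn]]
  }
  X_full <- stats::model.matrix(~ ., covars)
  X_red <- if (ncol(covars) > 1L) {
    stats::model.matrix(~ ., covars[, -1L, drop = FALSE])
  } else {
    stats::model.matrix(~ 1, covars)
  }
  df_grp <- nlevels(grp) - 1L

  disp <- moment_dispersions(counts, grp, eff_lib)
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2L)
  coef_names <- colnames(X_full)

  one_feature <- function(y, theta) {
    if (stats::var(y) == 0) {
      pw <- data.frame(contrast = paste(pairs[2L, ], "vs", pairs[1L, ]),
                       log2fc = 0, p = 1)
      return(list(p = 1, pairwise = pw))
    }
    fam <- MASS::negative.binomial(theta = theta)
    f1 <- suppressWarnings(stats::glm.fit(X_full, y, family = fam, offset = off))
    f0 <- suppressWarnings(stats::glm.fit(X_red, y, family = fam, offset = off))
    lrt <- max(0, f0$deviance - f1$deviance)
    p <- stats::pchisq(lrt, df = df_grp, lower.tail = FALSE)
    beta <- stats::setNames(rep(0, nlevels(grp)), lv)
    cf <- f1$coefficients
    for (l in lv[-1L]) beta[l] <- cf[paste0("group", l)]
    R <- qr.R(f1$qr)
    V <- tryCatch(chol2inv(R), error = function(e) NULL)
    pw <- apply(pairs, 2L, function(pr) {
      a <- pr[1L]; b <- pr[2L]
      d <- beta[b] - beta[a]
      se <- NA_real_
      if (!is.null(V)) {
        cvec <- rep(0, length(cf))
        names(cvec) <- colnames(X_full)[f1$qr$pivot]
        if (a != lv[1L]) cvec[paste0("group", a)] <- -1
        if (b != lv[1L]) cvec[paste0("group", b)] <- 1
        se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      }
      z <- if (is.finite(se) && se > 0) d / se else 0
      data.frame(contrast = paste(b, "vs", a), log2fc = d / log(2),
                 p = 2 * stats::pnorm(-abs(z)))
    })
    list(p = p, pairwise = do.call(rbind, pw))
  }

  feats <- rownames(counts)
  res <- lapply(seq_along(feats), function(i) one_feature(counts[i, ], 1 / disp[i]))
  omnibus_p <- vapply(res, `[[`, numeric(1), "p")
  pairwise <- do.call(rbind, lapply(seq_along(feats), function(i) {
    cbind(feature = feats[i], res[[i]]$pairwise)
  }))
  rownames(pairwise) <- NULL
  pairwise$fdr <- stats::ave(pairwise$p, pairwise$contrast,
                             FUN = function(p) stats::p.adjust(p, "BH"))
  max_lfc <- vapply(split(pairwise$log2fc, pairwise$feature)[feats],
                    function(l) l[which.max(abs(l))], numeric(1))
  omnibus <- data.frame(feature = feats, p = omnibus_p,
                        fdr = stats::p.adjust(omnibus_p, "BH"),
                        log2fc = max_lfc,
                        significant = omnibus_p < p_threshold,
                        stringsAsFactors = FALSE)
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 dispersion = disp, kept_features = feats,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d features tested, %d significant (omnibus p < %s)\n",
              nrow(x$omnibus), sum(x$omnibus$significant),
              format(x$p_threshold)))
  invisible(x)
}

#' Cluster features into co-expression modules
#'
#' Hierarchical agglomerative clustering of feature profiles with
#' `1 - Pearson r` as the distance and Ward's method ("ward.D2"); the tree
#' is cut either at a fixed number of modules `k` or at a fixed `height`.
#' Constant features (undefined correlation) are excluded with a warning.
#'
#' @param values Numeric features x samples matrix (typically the
#'   significant features).
#' @param k Number of modules (exclusive with `height`).
#' @param height Cut height (exclusive with `k`).
#' @return A `module_assignment`: `membership` (named integer vector),
#'   `hclust` (the dendrogram), `excluded` (constant features).
#' @export
cluster_modules <- function(values, k = NULL, height = NULL) {
  if (is.null(k) == is.null(height)) {
    ct_config_error("supply exactly one of `k` or `height`")
  }
  sds <- apply(values, 1L, stats::sd)
  excluded <- rownames(values)[sds == 0]
  if (length(excluded)) {
    warning(sprintf("excluding %d constant feature(s) with undefined correlation",
                    length(excluded)))
    values <- values[sds > 0, , drop = FALSE]
  }
  if (nrow(values) < 2L) ct_input_error("need >= 2 non-constant features")
  d <- stats::as.dist(1 - stats::cor(t(values)))
  hc <- stats::hclust(d, method = "ward.D2")
  memb <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = height)
  structure(list(membership = memb, hclust = hc, excluded = excluded),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d features in %d modules\n",
              length(x$membership), length(unique(x$membership))))
  invisible(x)
}

#' Hypergeometric set enrichment of a feature module
#'
#' One-sided upper-tail hypergeometric test of the overlap between a
#' module and every library term (terms intersected with the universe),
#' BH-adjusted across terms and sorted by p.
#'
#' @param module Character vector of module features (must be contained in
#'   `universe`).
#' @param library A [gene_set_library()].
#' @param universe Character vector: all features eligible for selection
#'   (conventionally, everything surviving the low-count filter).
#' @return Data frame: `term`, `overlap` (k), `term_size` (K),
#'   `module_size` (n), `universe_size` (N), `p`, `fdr`.
#' @export
enrich <- function(module, library, universe) {
  stopifnot(inherits(library, "gene_set_library"))
  if (!length(module)) ct_input_error("empty module")
  if (!all(module %in% universe)) {
    ct_input_error("module must be a subset of the universe")
  }
  module <- unique(module); universe <- unique(universe)
  N <- length(universe); n <- length(module)
  rows <- lapply(names(library), function(tn) {
    term <- intersect(library[[tn]], universe)
    K <- length(term)
    k <- length(intersect(term, module))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tn, overlap = k, term_size = K, module_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Top enriched terms per module
#'
#' Convenience view mirroring the three-most-significant-terms annotation
#' of module heatmaps.
#'
#' @param modules A `module_assignment` from [cluster_modules()].
#' @param library A [gene_set_library()].
#' @param universe Feature universe.
#' @param top_n Terms per module (default 3).
#' @return Data frame of per-module top terms (adds a `module` column).
#' @export
top_module_terms <- function(modules, library, universe, top_n = 3L) {
  out <- lapply(sort(unique(modules$membership)), function(m) {
    feats <- names(modules$membership)[modules$membership == m]
    e <- enrich(feats, library, universe)
    cbind(module = m, utils::head(e, top_n))
  })
  do.call(rbind, out)
}

#' Transcription-factor enrichment of up/down feature lists
#'
#' Applies [enrich()] separately to the up- and downregulated features of
#' a pairwise comparison against a TF-target-style library, reporting the
#' top `top_n` factors with raw `p < p_max` per direction.
#'
#' @param up_features,down_features Character vectors (either may be
#'   empty; an empty list gives an empty report, not an error).
#' @param tf_library A [gene_set_library()] of TF target sets.
#' @param universe Feature universe.
#' @param top_n Factors reported per direction (default 10).
#' @param p_max Raw p-value cutoff (default 0.01).
#' @return List with data frames `up` and `down`.
#' @export
tf_enrich <- function(up_features, down_features, tf_library, universe,
                      top_n = 10L, p_max = 0.01) {
  one <- function(feats) {
    if (!length(feats)) {
      return(data.frame(term = character(0), overlap = integer(0),
                        term_size = integer(0), module_size = integer(0),
                        universe_size = integer(0), p = numeric(0),
                        fdr = numeric(0)))
    }
    e <- enrich(feats, tf_library, universe)
    utils::head(e[e$p < p_max, , drop = FALSE], top_n)
  }
  list(up = one(up_features), down = one(down_features))
}
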