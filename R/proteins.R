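# Group statistics for protein panels (per-protein linear models with a
# blocking covariate) and cytokines (LOD substitution, Kruskal-Wallis +
# Dunn post hoc, BH correction).

#' Per-protein linear-model group test
#'
#' Ordinary least squares per protein on the log10 scale with the group
#' factor plus optional blocking covariates, an omnibus F-test for the
#' group factor (blocking fitted first), pairwise contrasts from the full
#' fit, and BH adjustment across proteins. Optional empirical-Bayes
#' variance moderation (posterior variance pooling toward the mean
#' residual variance) is available behind a flag and off by default.
#'
#' @param proteins A [protein_table()] (log10 values) or analyte x sample
#'   matrix.
#' @param labels Group labels (named vector or data frame with `sample`
#'   and `label`).
#' @param blocking Optional data frame with `sample` plus blocking columns
#'   (e.g. `dmpa`). A blocking covariate perfectly confounded with the
#'   group factor raises a rank-deficiency error naming it.
#' @param moderate Logical; apply simple empirical-Bayes variance
#'   moderation (default `FALSE`).
#' @param fdr_threshold Adjusted-p significance level (default 0.05).
#' @return List of class `protein_stats`: `omnibus` (protein, F, p, fdr,
#'   significant, per-group means), `pairwise` (protein, contrast,
#'   difference, p, fdr).
#' @export
protein_group_test <- function(proteins, labels, blocking = NULL,
                               moderate = FALSE, fdr_threshold = 0.05) {
  v <- if (inherits(proteins, "protein_table")) proteins$values else proteins
  grp <- as_group_factor(labels, colnames(v))
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L) ct_input_error("need >= 2 groups")
  covars <- data.frame(group = grp)
  if (!is.null(blocking)) {
    bl <- blocking[match(colnames(v), blocking$sample), , drop = FALSE]
    for (cn in setdiff(names(bl), "sample")) covars[[cn]] <- bl[[cn]]
  }
  X_red <- if (ncol(covars) > 1L) {
    stats::model.matrix(~ ., covars[, -1L, drop = FALSE])
  } else {
    stats::model.matrix(~ 1, covars)
  }
  X_full <- stats::model.matrix(~ ., covars[, c(setdiff(names(covars), "group"), "group"), drop = FALSE])
  # rank check: each blocking covariate must add information beyond group
  grp_only <- stats::model.matrix(~ group, covars)
  for (cn in setdiff(names(covars), "group")) {
    Xc <- stats::model.matrix(~ ., covars[, c("group", cn), drop = FALSE])
    if (qr(Xc)$rank <= qr(grp_only)$rank) {
      ct_input_error(sprintf("blocking covariate '%s' is confounded with the group factor", cn))
    }
  }
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2L)
  df_grp <- nlevels(grp) - 1L
  n <- ncol(v)
  df_res <- n - qr(X_full)$rank

  qr_full <- qr(X_full); qr_red <- qr(X_red)
  XtXinv <- chol2inv(qr.R(qr_full))
  cn_full <- colnames(X_full)

  fits <- lapply(rownames(v), function(pn) {
    y <- v[pn, ]
    if (stats::sd(y) == 0) {
      return(list(F = 0, p = 1, flag = "zero variance", beta = NULL, s2 = 0,
                  means = tapply(y, grp, mean)))
    }
    r_full <- qr.resid(qr_full, y)
    r_red <- qr.resid(qr_red, y)
    rss1 <- sum(r_full^2); rss0 <- sum(r_red^2)
    Fstat <- ((rss0 - rss1) / df_grp) / (rss1 / df_res)
    p <- stats::pf(Fstat, df_grp, df_res, lower.tail = FALSE)
    list(F = Fstat, p = p, flag = "", beta = qr.coef(qr_full, y),
         s2 = rss1 / df_res, means = tapply(y, grp, mean))
  })
  names(fits) <- rownames(v)

  s2 <- vapply(fits, `[[`, numeric(1), "s2")
  if (moderate) {
    # pool residual variances toward their mean with prior df = residual df
    s2_prior <- mean(s2[s2 > 0])
    s2_post <- (df_res * s2 + df_res * s2_prior) / (2 * df_res)
    for (pn in names(fits)) {
      f <- fits[[pn]]
      if (f$flag == "" && s2_post[pn] > 0) {
        f$F <- f$F * f$s2 / s2_post[pn]
        f$p <- stats::pf(f$F, df_grp, 2 * df_res, lower.tail = FALSE)
        fits[[pn]] <- f
      }
    }
  }

  means <- t(vapply(fits, `[[`, numeric(nlevels(grp)), "means"))
  colnames(means) <- paste0("mean_", lv)
  omnibus <- data.frame(protein = rownames(v),
                        F = vapply(fits, `[[`, numeric(1), "F"),
                        p = vapply(fits, `[[`, numeric(1), "p"),
                        flag = vapply(fits, `[[`, character(1), "flag"),
                        stringsAsFactors = FALSE, row.names = NULL)
  omnibus$fdr <- stats::p.adjust(omnibus$p, "BH")
  omnibus$significant <- omnibus$fdr < fdr_threshold
  omnibus <- cbind(omnibus, means)

  pairwise <- do.call(rbind, lapply(rownames(v), function(pn) {
    f <- fits[[pn]]
    do.call(rbind, apply(pairs, 2L, function(pr) {
      a <- pr[1L]; b <- pr[2L]
      if (is.null(f$beta)) {
        return(data.frame(protein = pn, contrast = paste(b, "vs", a),
                          difference = 0, p = 1))
      }
      cvec <- stats::setNames(rep(0, length(f$beta)), cn_full)
      if (a != lv[1L]) cvec[paste0("group", a)] <- -1
      if (b != lv[1L]) cvec[paste0("group", b)] <- 1
      d <- sum(cvec * f$beta, na.rm = TRUE)
      se <- sqrt(drop(t(cvec) %*% XtXinv %*% cvec) * f$s2)
      tt <- if (se > 0) d / se else 0
      data.frame(protein = pn, contrast = paste(b, "vs", a), difference = d,
                 p = 2 * stats::pt(-abs(tt), df_res))
    }))
  }))
  rownames(pairwise) <- NULL
  pairwise$fdr <- stats::ave(pairwise$p, pairwise$contrast,
                             FUN = function(p) stats::p.adjust(p, "BH"))
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 fdr_threshold = fdr_threshold),
            class = "protein_stats")
}

#' @export
print.protein_stats <- function(x, ...) {
  cat(sprintf("protein_stats: %d proteins, %d significant (adj. p < %s)\n",
              nrow(x$omnibus), sum(x$omnibus$significant),
              format(x$fdr_threshold)))
  invisible(x)
}

#' Cluster significant proteins for presentation
#'
#' The heatmap convention for protein panels: rows are scaled (z-scored),
#' clustered with correlation distance and Ward linkage, and the tree is
#' cut at height 1.
#'
#' @param proteins A [protein_table()] or matrix.
#' @param which Protein names to include (e.g. the significant set).
#' @param height Cut height (default 1).
#' @return A `module_assignment` from [cluster_modules()].
#' @export
protein_clusters <- function(proteins, which = NULL, height = 1) {
  v <- if (inherits(proteins, "protein_table")) proteins$values else proteins
  if (!is.null(which)) v <- v[which, , drop = FALSE]
  scaled <- t(scale(t(v)))
  cluster_modules(scaled, height = height)
}

#' Cytokine LOD/zero substitution and log2 transform
#'
#' Exact zeros are replaced with 0.01, censored (below-LOD) values with
#' LOD/2, and the matrix is then log2-transformed. An audit of the
#' substitution counts is attached, and the result carries a "transformed"
#' marker: feeding an already-transformed matrix back in is refused.
#'
#' @param cyt A [cytokine_table()].
#' @return List of class `cytokine_log2`: `log2` (analyte x sample
#'   matrix) and `audit` (data frame with per-cytokine counts of zero and
#'   LOD/2 substitutions).
#' @export
cytokine_transform <- function(cyt) {
  if (inherits(cyt, "cytokine_log2")) {
    ct_input_error("matrix already carries the transformed marker; refusing to re-transform")
  }
  stopifnot(inherits(cyt, "cytokine_table"))
  v <- cyt$values
  if (any(v < 0, na.rm = TRUE)) ct_input_error("negative cytokine concentrations")
  zeros <- v == 0
  cens <- cyt$censored & !zeros
  out <- v
  out[zeros] <- 0.01
  out[cens] <- (cyt$lod / 2)[row(v)[cens]]
  audit <- data.frame(cytokine = rownames(v),
                      n_zero_substituted = rowSums(zeros, na.rm = TRUE),
                      n_lod_substituted = rowSums(cens, na.rm = TRUE),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(log2 = log2(out), audit = audit), class = "cytokine_log2")
}

# Dunn's pairwise z-tests on pooled ranks, with tie correction.
dunn_test <- function(x, g) {
  g <- droplevels(factor(g))
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- table(g)
  pairs <- utils::combn(levels(g), 2L)
  do.call(rbind, apply(pairs, 2L, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[a] + 1 / ns[b]))
    z <- (rbar[b] - rbar[a]) / se
    data.frame(contrast = paste(b, "vs", a), z = unname(z),
               p = 2 * stats::pnorm(-abs(unname(z))))
  }))
}

#' Kruskal-Wallis + Dunn group test per cytokine
#'
#' Kruskal-Wallis rank sum test (with tie correction) per cytokine on the
#' log2-transformed values, BH-adjusted across cytokines, followed by
#' Dunn's pairwise z-tests on the pooled ranks, BH-adjusted across pairs
#' within each cytokine. Groups with fewer than 2 samples are excluded
#' with a warning.
#'
#' @param log2cyt A `cytokine_log2` from [cytokine_transform()], or an
#'   analyte x sample matrix of log2 values.
#' @param labels Group labels (named vector or `sample`/`label` data
#'   frame).
#' @return List of class `cytokine_stats`: `omnibus` (cytokine, H, p,
#'   fdr), `pairwise` (cytokine, contrast, z, p, fdr).
#' @export
cytokine_group_test <- function(log2cyt, labels) {
  v <- if (inherits(log2cyt, "cytokine_log2")) log2cyt$log2 else log2cyt
  grp <- as_group_factor(labels, colnames(v))
  grp <- droplevels(grp)
  small <- names(which(table(grp) < 2L))
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 samples: %s",
                    paste(small, collapse = ", ")))
    keep <- !grp %in% small
    v <- v[, keep, drop = FALSE]
    grp <- droplevels(grp[keep])
  }
  if (nlevels(grp) < 2L) ct_input_error("need >= 2 groups with >= 2 samples")
  omnibus <- do.call(rbind, lapply(rownames(v), function(cn) {
    x <- v[cn, ]
    if (length(unique(x)) == 1L) {
      return(data.frame(cytokine = cn, H = 0, p = 1))
    }
    kw <- stats::kruskal.test(x, grp)
    data.frame(cytokine = cn, H = unname(kw$statistic), p = kw$p.value)
  }))
  omnibus$fdr <- stats::p.adjust(omnibus$p, "BH")
  pairwise <- do.call(rbind, lapply(rownames(v), function(cn) {
    x <- v[cn, ]
    if (length(unique(x)) == 1L) return(NULL)
    d <- dunn_test(x, grp)
    d$fdr <- stats::p.adjust(d$p, "BH")   # within-cytokine family
    cbind(cytokine = cn, d)
  }))
  rownames(pairwise) <- NULL
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "cytokine_stats")
}

#' @export
print.cytokine_stats <- function(x, ...) {
  cat(sprintf("cytokine_stats: %d cytokines, %d significant (BH p < 0.05)\n",
              nrow(x$omnibus), sum(x$omnibus$fdr < 0.05)))
  invisible(x)
}
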