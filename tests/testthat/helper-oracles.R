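# Independent oracles used across the suite. Each is a literal, brute-force
# or step-by-step computation kept deliberately separate from the package's
# own code paths.

# Literal weighted Kolmogorov-Smirnov running sum over the full list.
# Extremum of largest magnitude; positive branch preferred on an exact tie.
es_brute <- function(scores, hit_logical, p = 1) {
  N <- length(scores)
  w <- abs(scores)^p
  inc <- ifelse(hit_logical, w / sum(w[hit_logical]), -1 / (N - sum(hit_logical)))
  rs <- cumsum(inc)
  hi <- max(rs); lo <- min(c(rs, 0))
  if (hi >= abs(lo)) hi else lo
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2L, u_stat)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Naive Lance-Williams Ward ("ward.D2") agglomeration returning merge heights.
ward_lw_heights <- function(d) {
  dm <- as.matrix(d)^2   # work with squared distances
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  diag(dm) <- Inf
  while (length(active) > 1L) {
    sub <- dm[active, active, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    i <- active[ij[1L]]; j <- active[ij[2L]]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    heights <- c(heights, sqrt(dm[i, j]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      dm[i, k] <- dm[k, i] <-
        ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * dm[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    dm[j, ] <- dm[, j] <- Inf
  }
  heights
}

# Literal weighted-modularity formula on an edge list.
modularity_formula <- function(nodes, edges, membership) {
  W <- sum(edges$weight)
  deg <- stats::setNames(rep(0, length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    deg[edges$from[r]] <- deg[edges$from[r]] + edges$weight[r]
    deg[edges$to[r]] <- deg[edges$to[r]] + edges$weight[r]
  }
  q <- 0
  for (com in unique(membership)) {
    inc <- names(membership)[membership == com]
    w_in <- sum(edges$weight[edges$from %in% inc & edges$to %in% inc])
    w_tot <- sum(deg[inc])
    q <- q + w_in / W - (w_tot / (2 * W))^2
  }
  q
}

# Complete weighted graph with four planted 10-node blocks.
make_block_graph <- function(within = 0.8, between = 0.02) {
  nodes <- sprintf("n%02d", 1:40)
  blocks <- rep(1:4, each = 10)
  e <- t(utils::combn(40L, 2L))
  w <- ifelse(blocks[e[, 1L]] == blocks[e[, 2L]], within, between)
  list(graph = snn_graph(nodes, data.frame(from = nodes[e[, 1L]],
                                           to = nodes[e[, 2L]],
                                           weight = w,
                                           stringsAsFactors = FALSE)),
       blocks = stats::setNames(blocks, nodes))
}

# Does a partition reproduce the planted blocks exactly (up to relabeling)?
recovers_blocks <- function(membership, blocks) {
  tab <- table(membership[names(blocks)], blocks)
  nrow(tab) == length(unique(blocks)) && all(rowSums(tab > 0) == 1)
}

# Small default config for quick simulations.
quick_config <- function(...) {
  synth_config(n_participants = 30L, n_genes = 200L, n_de_genes = 20L, ...)
}

# Single-sample relative-abundance row with named taxa, remainder assigned
# to a filler taxon.
relrow <- function(..., filler = "Corynebacterium") {
  v <- c(...)
  stopifnot(sum(v) <= 1 + 1e-12)
  if (sum(v) < 1) v[filler] <- 1 - sum(v)
  for (tx in c("Lactobacillus crispatus", "Lactobacillus jensenii",
               "Gardnerella", "Prevotella")) {
    if (!tx %in% names(v)) v[tx] <- 0
  }
  matrix(v, nrow = 1, dimnames = list("s1", names(v)))
}

# Printed cohort characteristics used as inputs: per-group sample counts of
# the binned Nugent (BV) category.
table1_bv_metadata <- function() {
  nonpos <- c(L1 = 9, L2 = 30, L3 = 18, L4 = 11, L5 = 6)
  pos <- c(L1 = 0, L2 = 0, L3 = 3, L4 = 28, L5 = 1)
  grp <- rep(names(nonpos), times = nonpos + pos)
  bv <- unlist(lapply(names(nonpos), function(g) {
    c(rep("no", nonpos[g]), rep("yes", pos[g]))
  }))
  ids <- sprintf("S%03d", seq_along(grp))
  list(meta = sample_metadata(data.frame(sample = ids, bv = bv,
                                         stringsAsFactors = FALSE)),
       labels = data.frame(sample = ids, label = grp,
                           type = as.integer(substring(grp, 2L)),
                           stringsAsFactors = FALSE))
}
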