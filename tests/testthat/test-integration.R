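# HVG selection, taxon-gene correlation, preranked GSEA, NES matrix.

test_that("highly variable gene selection ranks by log-CPM variance", {
  m <- rbind(const = rep(50, 6), varies = c(1, 200, 3, 150, 9, 300))
  colnames(m) <- paste0("s", 1:6)
  expect_identical(select_hvg(m, 1), "varies")
  expect_setequal(select_hvg(m, 2), rownames(m))
  expect_error(select_hvg(m, 3), class = "cervotype_input_error")
  set.seed(1)
  base <- matrix(rpois(400 * 20, 50), 400, 20,
                 dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:20)))
  hv_rows <- sample(400, 100)
  for (g in hv_rows) {   # each planted gene high in its own half of samples
    on <- sample(20, 10)
    base[g, on] <- base[g, on] * 40L
  }
  top <- select_hvg(base, 100)
  expect_gte(length(intersect(top, rownames(base)[hv_rows])), 99)
})

test_that("taxon-gene correlations match the literal formula", {
  set.seed(2)
  n <- 20
  taxa <- matrix(abs(rnorm(n * 3)) + 0.1, n, 3,
                 dimnames = list(paste0("s", 1:n), c("A", "B", "C")))
  genes <- matrix(rnorm(5 * n), 5, n,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  genes[1, ] <- taxa[, "A"]
  genes[2, ] <- -taxa[, "A"]
  r <- taxa_gene_correlation(taxa, genes)
  expect_equal(unname(r["A", "g1"]), 1)
  expect_equal(unname(r["A", "g2"]), -1)
  lit <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  for (tx in colnames(taxa)) for (g in rownames(genes)) {
    expect_equal(unname(r[tx, g]), lit(taxa[, tx], genes[g, ]),
                 tolerance = 1e-12)
  }
  expect_error(taxa_gene_correlation(taxa[1:2, ], genes[, 1:2]),
               class = "cervotype_input_error")
})

test_that("enrichment score equals hand-computed running sums", {
  sc <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 0.5)
  rl <- ranked_list(sc)
  # set = top gene: +1 then three miss steps of 1/3 -> extremum 1
  r1 <- preranked_gsea(rl, "g1", n_perm = 100, seed = 1)
  expect_equal(r1$es, 1)
  # set = second gene: -1/3, then +1 -> extremum 2/3
  r2 <- preranked_gsea(rl, "g2", n_perm = 100, seed = 1)
  expect_equal(r2$es, 2 / 3)
  # set = everything: degenerate
  rall <- preranked_gsea(rl, names(sc), n_perm = 100, seed = 1)
  expect_true(rall$degenerate)
  expect_equal(rall$es, 1)
  expect_error(preranked_gsea(rl, "absent", n_perm = 100),
               class = "cervotype_input_error")
  expect_error(preranked_gsea(rl, "g1", n_perm = 10),
               class = "cervotype_config_error")
})

test_that("ES matches the brute-force oracle (and fgsea) on random lists", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    sc <- stats::setNames(sort(rnorm(n), decreasing = TRUE), paste0("g", 1:n))
    rl <- ranked_list(sc)
    k <- sample(2:(n - 1), 1)
    gs <- sample(rl$gene, k)
    r <- preranked_gsea(rl, gs, n_perm = 100, seed = i)
    expect_equal(r$es, es_brute(rl$score, rl$gene %in% gs), tolerance = 1e-12)
    if (requireNamespace("fgsea", quietly = TRUE) && abs(r$es) > 1e-9) {
      # fgsea returns 0 on an exact positive/negative-extremum tie; skip ties
      f <- fgsea::calcGseaStat(stats::setNames(rl$score, rl$gene),
                               which(rl$gene %in% gs), gseaParam = 1)
      if (abs(f) > 1e-9) expect_equal(r$es, f, tolerance = 1e-12)
    }
  }
})

test_that("negating scores and reversing the ranking negates ES", {
  set.seed(4)
  sc <- stats::setNames(rnorm(50), sprintf("g%02d", 1:50))
  rl <- ranked_list(sc)
  rl_neg <- ranked_list(-sc)
  gs <- sample(names(sc), 12)
  a <- preranked_gsea(rl, gs, n_perm = 100, seed = 1)
  b <- preranked_gsea(rl_neg, gs, n_perm = 100, seed = 1)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("NES matrix filtering and determinism behave as specified", {
  set.seed(5)
  n <- 40
  taxa_log <- matrix(abs(rnorm(n * 3)) + 0.1, n, 3,
                     dimnames = list(paste0("s", 1:n), c("X", "Y", "Z")))
  expr <- matrix(rnorm(200 * n), 200, n,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:n)))
  # gene set G members track taxon X
  members <- sprintf("g%03d", 1:30)
  expr[members, ] <- matrix(rep(taxa_log[, "X"], each = 30), 30, n) +
    matrix(rnorm(30 * n, 0, 0.4), 30, n)
  lib <- gene_set_library(list(
    G = members,
    null1 = sprintf("g%03d", 31:60),
    null2 = sprintf("g%03d", 61:90),
    tiny = c("g091", "g092")))
  corr <- taxa_gene_correlation(taxa_log, expr)
  nm <- nes_matrix(corr, lib, min_significant = 0, n_perm = 200, seed = 1)
  expect_false("tiny" %in% colnames(nm$nes))   # below the size bounds
  expect_gt(nm$nes["X", "G"], 0)
  expect_true(nm$significant["X", "G"])
  nm2 <- nes_matrix(corr, lib, min_significant = 0, n_perm = 200, seed = 1)
  expect_identical(nm$nes, nm2$nes)
  # alpha = 1 marks everything testable as significant
  nm3 <- nes_matrix(corr, lib, min_significant = 0, alpha = 1,
                    n_perm = 200, seed = 1)
  expect_true(all(nm3$significant | is.na(nm3$p)))
  expect_error(nes_matrix(corr, gene_set_library(list(s = c("a", "b"))),
                          n_perm = 200), class = "cervotype_input_error")
})

test_that("a planted taxon-pathway association is detected across seeds", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 30
    tax <- abs(rnorm(n)) + 0.1
    expr <- matrix(rnorm(150 * n), 150, n,
                   dimnames = list(sprintf("g%03d", 1:150), paste0("s", 1:n)))
    members <- sprintf("g%03d", 1:25)
    expr[members, ] <- matrix(rep(tax, each = 25), 25, n) +
      matrix(rnorm(25 * n, 0, 0.5), 25, n)
    corr <- stats::cor(tax, t(expr))[1, ]
    rl <- ranked_list(corr)
    r <- preranked_gsea(rl, members, n_perm = 100, seed = s)
    if (r$es > 0 && r$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
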