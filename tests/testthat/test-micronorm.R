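# Normalization, diversity and differential abundance, each checked
# against closed forms or independent oracles.

mk_table <- function(m, site = "luminal") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  taxa_table(m, site)
}

test_that("taxa filter uses a strict > threshold and keeps samples", {
  m <- rbind(c(3L, 4L, 0L), c(1L, 0L, 0L))
  tt <- mk_table(m)
  f <- filter_taxa(tt, min_count = 3)
  expect_identical(colnames(f$counts), "t2")   # max 3 removed, max 4 kept
  expect_identical(rownames(f$counts), rownames(tt$counts))
  f0 <- filter_taxa(mk_table(matrix(rpois(300, 2), 3, 100) + 1L), min_count = 0)
  expect_equal(ncol(f0$counts), 100L)
  expect_error(filter_taxa(tt, min_count = 100), class = "cervotype_input_error")
})

test_that("TSS yields exact fractions and flags zero-depth samples", {
  tt <- mk_table(rbind(c(10L, 30L, 60L)))
  expect_equal(unname(tss_normalize(tt)[1, ]), c(0.1, 0.3, 0.6))
  one <- mk_table(matrix(5L, 1, 1))
  expect_equal(unname(tss_normalize(one)[1, 1]), 1)
  r <- tss_normalize(mk_table(matrix(rpois(1500, 4), 50, 30) + 1L))
  expect_true(all(abs(rowSums(r) - 1) < 1e-9))
  bad <- matrix(c(1L, 0L, 0L, 0L), 2, 2, dimnames = list(c("ok", "empty"), c("a", "b")))
  err <- tryCatch(tss_normalize(taxa_table(bad, "luminal")), error = identity)
  expect_s3_class(err, "cervotype_input_error")
  expect_match(conditionMessage(err), "empty")
})

test_that("log2 CP1K matches the closed form and is monotone in counts", {
  tt <- mk_table(rbind(c(999L, 1L)))
  expect_equal(log2_cp1k(tt)[1, 1], log2(999 / 1000 * 1000 + 1))
  expect_equal(log2_cp1k(mk_table(rbind(c(0L, 5L))))[1, 1], 0)
  set.seed(1)
  m <- matrix(rpois(200, 10), 10, 20) + 1L
  lg <- log2_cp1k(mk_table(m))
  for (i in 1:10) expect_identical(order(lg[i, ]), order(m[i, ]))
})

test_that("TSS and log2 CP1K are equivariant under sample permutation", {
  set.seed(2)
  m <- matrix(rpois(600, 6), 20, 30) + 1L
  tt <- mk_table(m)
  perm <- sample(20)
  tt_p <- taxa_table(tt$counts[perm, ], "luminal")
  expect_equal(tss_normalize(tt)[perm, ], tss_normalize(tt_p))
  expect_equal(log2_cp1k(tt)[perm, ], log2_cp1k(tt_p))
})

test_that("TMM factors are 1 for identical and purely-scaled libraries", {
  set.seed(3)
  y <- rnbinom(1000, mu = exp(runif(1000, 1, 7)), size = 5) + 1L
  m <- cbind(a = y, b = y); rownames(m) <- paste0("g", 1:1000)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(a = y, b = 2L * y); rownames(m2) <- paste0("g", 1:1000)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
  mz <- cbind(a = y, b = 0L * y); rownames(mz) <- paste0("g", 1:1000)
  expect_error(tmm_factors(mz), class = "cervotype_input_error")
})

test_that("TMM factors match the independent reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  for (rep in 1:3) {
    m <- matrix(rnbinom(2000 * 6, mu = rep(exp(runif(2000, 2, 8)), 6), size = 5),
                2000, 6, dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
    ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
    expect_equal(unname(tmm_factors(m)), ref, tolerance = 1e-6)
  }
})

test_that("diversity indices match closed forms and the literal formula", {
  u4 <- matrix(0.25, 1, 4, dimnames = list("s1", paste0("t", 1:4)))
  d <- alpha_diversity(u4)
  expect_equal(d$shannon, log(4))
  expect_equal(d$simpson, 0.75)
  expect_equal(d$inv_simpson, 4)
  single <- matrix(1, 1, 1, dimnames = list("s1", "t1"))
  d1 <- alpha_diversity(single)
  expect_equal(unlist(d1[, -1]), c(shannon = 0, simpson = 0, inv_simpson = 1))
  half <- matrix(0.5, 1, 2, dimnames = list("s1", c("a", "b")))
  expect_equal(alpha_diversity(half)$shannon, log(2))
  # random compositions vs literal formula (and vegan as second opinion)
  set.seed(5)
  p <- matrix(rgamma(200, 1), 10, 20)
  p <- p / rowSums(p)
  dimnames(p) <- list(paste0("s", 1:10), paste0("t", 1:20))
  d <- alpha_diversity(p)
  lit_h <- apply(p, 1, function(q) -sum(q[q > 0] * log(q[q > 0])))
  expect_equal(d$shannon, unname(lit_h), tolerance = 1e-10)
  expect_equal(d$simpson, unname(1 - rowSums(p^2)), tolerance = 1e-10)
  if (requireNamespace("vegan", quietly = TRUE)) {
    expect_equal(d$shannon, unname(vegan::diversity(p, "shannon")),
                 tolerance = 1e-10)
    expect_equal(d$inv_simpson, unname(vegan::diversity(p, "invsimpson")),
                 tolerance = 1e-10)
  }
})

test_that("paired diversity test handles one-signed, tied and planted shifts", {
  mkdiv <- function(h) data.frame(sample = paste0("p", seq_along(h)),
                                  shannon = h, simpson = h / 10,
                                  inv_simpson = 1 + h)
  set.seed(99)
  lum <- mkdiv(seq(0.5, 2, length.out = 10))
  tis <- mkdiv(seq(0.5, 2, length.out = 10) + runif(10, 0.3, 0.7))
  r <- paired_diversity_test(lum, tis)
  expect_equal(r$p_value[r$index == "shannon"], 2 / 2^10)  # minimal attainable
  expect_true(all(r$direction == "tissue higher"))
  w <- capture_warnings(r0 <- paired_diversity_test(lum, lum))
  expect_length(w, 3)
  expect_match(w, "zero", all = TRUE)
  expect_true(all(r0$p_value == 1))
  # power: planted +0.3 shift, sigma 0.2, n = 20 -> p < 0.05 in >= 95% of 200
  set.seed(6)
  hits <- replicate(200, {
    base <- rnorm(20, 1.5, 0.5)
    lum <- mkdiv(base)
    tis <- mkdiv(base + 0.3 + rnorm(20, 0, 0.2))
    paired_diversity_test(lum, tis)$p_value[1] < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Mann-Whitney differential abundance matches exact enumeration", {
  # U = 0 arrangement: exact two-sided p = 0.1 over all 20 assignments
  lum <- matrix(c(4, 5, 6), 3, 1, dimnames = list(paste0("l", 1:3), "tax"))
  tis <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("t", 1:3), "tax"))
  r <- differential_abundance(lum, tis)
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  # identical groups: zero fold change, not significant
  same <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), c("a", "b")))
  r2 <- differential_abundance(same, same)
  expect_equal(r2$log2fc, c(0, 0))
  expect_false(any(r2$significant))
  # exact-enumeration oracle on random small groups
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)   # continuous draws: no ties, exact branch
    lm1 <- matrix(y, 6, 1, dimnames = list(paste0("l", 1:6), "tax"))
    tm1 <- matrix(x, 5, 1, dimnames = list(paste0("t", 1:5), "tax"))
    expect_equal(differential_abundance(lm1, tm1)$p_value, mw_exact_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(differential_abundance(lum, matrix(1, 1, 1,
    dimnames = list("x", "other"))), class = "cervotype_input_error")
})

test_that("differential abundance has power at planted shifts and controls nulls", {
  set.seed(8)
  n <- 40; reps <- 200
  shifted <- matrix(rnorm(n * reps, 1), n, reps)
  null <- matrix(rnorm(n * reps, 0), n, reps)
  lum <- cbind(matrix(rnorm(n * reps, 0), n, reps), null)
  tis <- cbind(shifted, matrix(rnorm(n * reps, 0), n, reps))
  colnames(lum) <- colnames(tis) <- paste0("tax", 1:(2 * reps))
  rownames(lum) <- paste0("l", 1:n); rownames(tis) <- paste0("t", 1:n)
  r <- differential_abundance(lum, tis)
  r <- r[match(paste0("tax", 1:(2 * reps)), r$taxon), ]
  expect_gte(mean(r$significant[1:reps]), 0.95)          # planted shift of 1.0
  expect_lte(mean(r$significant[(reps + 1):(2 * reps)]), 0.02)  # null taxa
})
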