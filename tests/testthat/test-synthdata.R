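# Synthetic paired multi-omics generator: degenerate limits, planted
# parameter recovery, and seed reproducibility.

test_that("config invariants are enforced", {
  expect_error(synth_config(n_participants = 0), class = "cervotype_config_error")
  bad_tm <- default_transition_matrix(); bad_tm[1, 1] <- 0.9
  expect_error(synth_config(transition_matrix = bad_tm),
               class = "cervotype_config_error")
  bad_prof <- default_taxa_profiles(); bad_prof[1, 1] <- bad_prof[1, 1] + 0.1
  expect_error(synth_config(taxa_profiles = bad_prof),
               class = "cervotype_config_error")
  expect_error(synth_config(n_de_genes = 10, n_genes = 5),
               class = "cervotype_config_error")
  expect_error(synth_config(cytokine_lod = -1),
               class = "cervotype_config_error")
  expect_true(all(abs(rowSums(default_taxa_profiles()) - 1) < 1e-9))
  expect_true(all(abs(rowSums(default_transition_matrix()) - 1) < 1e-9))
})

test_that("degenerate Dirichlet sends every read to the dominant taxon", {
  prof <- default_taxa_profiles()
  pure <- matrix(0, 5, ncol(prof), dimnames = dimnames(prof))
  pure[, "Lactobacillus crispatus"] <- 1
  cfg <- synth_config(n_participants = 10, taxa_profiles = pure,
                      concentration = 1e9, seed = 1)
  sim <- generate_paired_microbiome(cfg)
  for (tab in list(sim$luminal, sim$tissue)) {
    expect_equal(unname(tab$counts[, "Lactobacillus crispatus"]),
                 unname(rowSums(tab$counts)))
  }
})

test_that("identity transition matrix keeps every tissue type equal to luminal", {
  cfg <- synth_config(n_participants = 50, transition_matrix = diag(5), seed = 2)
  sim <- generate_paired_microbiome(cfg)
  expect_identical(unname(sim$truth$tissue_type), unname(sim$truth$luminal_type))
})

test_that("planted type-2 to type-3 transition probability is recovered at n = 500", {
  cfg <- synth_config(n_participants = 500, seed = 1)
  sim <- generate_paired_microbiome(cfg)
  expect_equal(unname(cfg$transition_matrix[2, ]), c(0, 0.41, 0.56, 0.03, 0))
  l2 <- sim$truth$luminal_type == 2
  phat <- mean(sim$truth$tissue_type[l2] == 3)
  # 99% binomial CI around 0.56 at the realized number of type-2 lumina
  n2 <- sum(l2)
  half <- stats::qnorm(0.995) * sqrt(0.56 * 0.44 / n2)
  expect_gt(phat, 0.56 - half)
  expect_lt(phat, 0.56 + half)
})

test_that("identical seeds give bit-identical output; different seeds differ", {
  cfg <- quick_config(seed = 9)
  a <- generate_paired_microbiome(cfg)
  b <- generate_paired_microbiome(cfg)
  expect_identical(a, b)
  c <- generate_paired_microbiome(quick_config(seed = 10))
  expect_identical(dim(a$luminal$counts), dim(c$luminal$counts))
  expect_false(identical(a$luminal$counts, c$luminal$counts))
  expect_identical(colnames(a$luminal$counts), colnames(a$tissue$counts))
  expect_identical(rownames(a$luminal$counts), rownames(a$tissue$counts))
})

test_that("per-type mean composition converges to the planted profiles", {
  cfg <- synth_config(n_participants = 1000, seed = 4)
  sim <- generate_paired_microbiome(cfg)
  rel <- sim$luminal$counts / rowSums(sim$luminal$counts)
  for (t in 1:5) {
    sel <- sim$truth$luminal_type == t
    emp <- colMeans(rel[sel, , drop = FALSE])
    expect_lt(max(abs(emp - cfg$taxa_profiles[t, ])), 0.02)
  }
})

test_that("zero effect size plants no differentially expressed genes", {
  cfg <- quick_config(de_log2fc = 0, seed = 3)
  sim <- generate_paired_microbiome(cfg)
  expr <- generate_host_expression(sim$truth, cfg)
  expect_length(attr(expr, "de_genes"), 0)
})

test_that("vanishing dispersion approaches the Poisson mean-variance relation", {
  cfg <- synth_config(n_participants = 50, n_genes = 1000, n_de_genes = 0,
                      nb_dispersion = 1e-12, hiv_prevalence = 0,
                      dmpa_prevalence = 0, expr_depth_log_sd = 0, seed = 6)
  sim <- generate_paired_microbiome(cfg)
  expr <- generate_host_expression(sim$truth, cfg)
  m <- rowMeans(expr$values)
  v <- apply(expr$values, 1, stats::var)
  keep <- m > 20
  # index of dispersion centered on 1 for Poisson counts
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.05)
})

test_that("planted expression log2FC of 2 is recovered within 0.3", {
  cfg <- synth_config(n_participants = 150, n_genes = 500, n_de_genes = 50,
                      de_log2fc = 2, type_prevalence = rep(0.2, 5), seed = 7)
  sim <- generate_paired_microbiome(cfg)
  expr <- generate_host_expression(sim$truth, cfg)
  de <- attr(expr, "de_genes")
  cpm <- sweep(expr$values, 2, colSums(expr$values), "/") * 1e6
  lfc <- vapply(names(de), function(g) {
    tgt <- sim$truth$luminal_type == de[g]
    log2(mean(cpm[g, tgt]) + 0.5) - log2(mean(cpm[g, !tgt]) + 0.5)
  }, numeric(1))
  expect_lt(abs(mean(lfc) - 2), 0.3)
})

test_that("protein and cytokine generation honors shifts and censoring", {
  cfg <- synth_config(n_participants = 200, type_prevalence = rep(0.2, 5),
                      seed = 8)
  sim <- generate_paired_microbiome(cfg)
  pc <- generate_protein_cytokine(sim$truth, cfg)
  shifted <- sim$truth$luminal_type == 4
  # planted 1.0 log10 shift recovered within 0.2
  d <- rowMeans(pc$proteins$values[1:20, shifted]) -
       rowMeans(pc$proteins$values[1:20, !shifted])
  expect_lt(max(abs(d - 1)), 0.2)
  # unshifted proteins: group means equal within sampling error
  d0 <- rowMeans(pc$proteins$values[21:74, shifted]) -
        rowMeans(pc$proteins$values[21:74, !shifted])
  expect_lt(max(abs(d0)), 0.2)
  # LOD above everything censors every entry
  cfg2 <- synth_config(n_participants = 20, cytokine_lod = 1e9, seed = 8)
  sim2 <- generate_paired_microbiome(cfg2)
  pc2 <- generate_protein_cytokine(sim2$truth, cfg2)
  expect_true(all(pc2$cytokines$censored))
})
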