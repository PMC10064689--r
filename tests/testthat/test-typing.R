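# Rule-based community typing, paired shift table, covariate association.

test_that("luminal rule cascade reproduces the documented assignments", {
  expect_identical(classify_luminal(relrow(`Lactobacillus crispatus` = 0.85))$label, "L1")
  expect_identical(classify_luminal(relrow(`Atopobium` = 0.99))$label, "L5")
  r <- classify_luminal(relrow(`Lactobacillus iners` = 0.58,
                               `Gardnerella` = 0.40, `Prevotella` = 0.02))
  expect_identical(r$label, "L3")   # fails L2 at 0.58, passes G > 0.10 & P < 0.05
  expect_identical(classify_luminal(relrow(`Prevotella` = 0.06))$label, "L4")
  # strict comparators: boundary values fall through
  expect_identical(classify_luminal(relrow(`Lactobacillus crispatus` = 0.80,
                                           `Lactobacillus iners` = 0.20))$label, "L2")
  expect_identical(classify_luminal(relrow(`Gardnerella` = 0.10))$label, "L5")
})

test_that("tissue rule cascade reproduces the documented assignments", {
  r <- classify_tissue(relrow(`Lactobacillus iners` = 0.55, `Gardnerella` = 0.35))
  expect_identical(r$label, "T3")   # T2 blocked by Gardnerella >= 0.30
  expect_identical(classify_tissue(relrow(`Atopobium` = 0.72))$label, "T5")
  expect_identical(classify_tissue(relrow(`Lactobacillus crispatus` = 0.51))$label, "T1")
  expect_identical(classify_tissue(relrow(`Lactobacillus iners` = 0.55,
                                          `Gardnerella` = 0.25))$label, "T2")
})

test_that("classification is deterministic and permutation-equivariant", {
  sim <- generate_paired_microbiome(synth_config(n_participants = 40, seed = 5))
  rel <- tss_normalize(sim$luminal)
  a <- classify_luminal(rel)
  b <- classify_luminal(rel)
  expect_identical(a, b)
  perm <- sample(nrow(rel))
  cp <- classify_luminal(rel[perm, ])
  expect_identical(cp$label, a$label[perm])
  expect_error(classify_luminal(rel * 2), class = "cervotype_input_error")
})

test_that("missing rule-group members contribute zero with a warning", {
  m <- matrix(c(0.5, 0.02, 0.48), 1,
              dimnames = list("s1", c("Gardnerella", "Prevotella", "Atopobium")))
  expect_warning(r <- classify_luminal(m), "Lactobacillus crispatus")
  expect_identical(r$label, "L3")
})

test_that("planted community types are recovered at high concentration", {
  cfg <- synth_config(n_participants = 200, concentration = 200, seed = 6)
  sim <- generate_paired_microbiome(cfg)
  lum <- classify_luminal(tss_normalize(sim$luminal))
  tis <- classify_tissue(tss_normalize(sim$tissue))
  expect_gte(mean(lum$type == sim$truth$luminal_type), 0.98)
  expect_gte(mean(tis$type == sim$truth$tissue_type), 0.98)
})

test_that("shift table counts pairs, concordance and transition fractions", {
  mk <- function(types, prefix) data.frame(
    sample = sprintf("p%03d", seq_along(types)),
    label = paste0(prefix, types), type = types)
  ident <- mk(rep(1:5, times = 4), "L")
  st <- shift_table(ident, mk(rep(1:5, times = 4), "T"))
  expect_equal(st$concordant, 20L)
  expect_equal(sum(st$table) - sum(diag(st$table)), 0L)
  # the published pairing: 60 concordant of 93 (5, 11, 14, 28, 2 on the
  # diagonal), discordant pairs spread off-diagonal
  conc <- c(5L, 11L, 14L, 28L, 2L)
  lum_types <- c(rep(1:5, conc), rep(1, 5), rep(2, 19), rep(3, 1), rep(4, 6),
                 rep(5, 2))
  tis_types <- c(rep(1:5, conc), rep(3, 5), rep(3, 19), rep(4, 1), rep(3, 6),
                 rep(4, 2))
  st2 <- shift_table(mk(lum_types, "L"), mk(tis_types, "T"))
  expect_equal(st2$n_pairs, 93L)
  expect_equal(st2$concordant, 60L)
  expect_equal(sum(st2$table), st2$n_pairs)
  expect_equal(unname(rowSums(st2$fractions)), rep(1, 5))
  expect_error(shift_table(mk(1, "L")[0, ], mk(1, "T")),
               class = "cervotype_input_error")
})

test_that("planted transition probabilities are recovered through the classifier", {
  cfg <- synth_config(n_participants = 500, concentration = 200, seed = 7)
  sim <- generate_paired_microbiome(cfg)
  st <- shift_table(classify_luminal(tss_normalize(sim$luminal)),
                    classify_tissue(tss_normalize(sim$tissue)))
  phat <- st$fractions[2, 3]
  n2 <- sum(st$table[2, ])
  half <- stats::qnorm(0.995) * sqrt(0.56 * 0.44 / n2)
  expect_gt(phat, 0.56 - half)
  expect_lt(phat, 0.56 + half)
})

test_that("covariate association tests match their closed forms", {
  # 2x2 perfect separation: Fisher two-sided p = 2 / choose(10, 5)
  meta <- sample_metadata(data.frame(sample = sprintf("s%02d", 1:10),
                                     grp_cov = rep(c("x", "y"), each = 5)))
  labels <- data.frame(sample = sprintf("s%02d", 1:10),
                       label = rep(c("L1", "L2"), each = 5),
                       type = rep(1:2, each = 5))
  r <- metadata_association(meta, labels)
  expect_equal(r$p_value, 2 / choose(10, 5))
  expect_identical(r$test, "fisher")
  # constant continuous covariate -> p = 1 with flag, no error
  meta2 <- sample_metadata(data.frame(sample = sprintf("s%02d", 1:10),
                                      age = rep(30, 10)))
  r2 <- metadata_association(meta2, labels)
  expect_equal(r2$p_value, 1)
  expect_identical(r2$flag, "constant")
  # continuous covariate identical across groups
  meta3 <- sample_metadata(data.frame(sample = sprintf("s%02d", 1:10),
                                      age = rep(c(25, 30, 35, 40, 45), 2)))
  r3 <- metadata_association(meta3, labels)
  expect_identical(r3$test, "kruskal-wallis")
  expect_equal(r3$p_value, 1)
})

test_that("the published BV x group table is strongly associated", {
  tb <- table1_bv_metadata()
  r <- metadata_association(tb$meta, tb$labels)
  expect_identical(r$test, "fisher")
  expect_lt(r$p_value, 0.001)
})
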