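# End-to-end orchestration: simulate (or load) -> classify -> diversity /
# differential abundance -> graphs -> DE / modules / enrichment ->
# integration -> proteins / cytokines, with a JSON manifest of outputs.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed, mandatory for all stochastic stages.
#' @param simulate Either `NULL` or a [synth_config()]; when given, all
#'   inputs are generated synthetically and written to `out_dir`.
#' @param luminal,tissue,metadata,expression,gmt,proteins,cytokines
#'   Optional input file paths used when `simulate` is `NULL`. Stages
#'   whose inputs are absent are skipped with a logged notice.
#' @param k_samples,k_taxa,prune SNN graph parameters.
#' @param n_perm GSEA permutations.
#' @param de_k Number of gene modules to cut (default 6).
#' @param p_threshold,fdr_threshold,fc_threshold Test thresholds.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, simulate = NULL,
                            luminal = NULL, tissue = NULL, metadata = NULL,
                            expression = NULL, gmt = NULL,
                            proteins = NULL, cytokines = NULL,
                            k_samples = 12L, k_taxa = 5L, prune = 1 / 15,
                            n_perm = 200L, de_k = 6L,
                            p_threshold = 0.01, fdr_threshold = 0.05,
                            fc_threshold = 0.25) {
  if (missing(seed)) ct_config_error("a seed is mandatory")
  for (p in c(luminal, tissue, metadata, expression, gmt, proteins, cytokines)) {
    if (!is.null(p) && !file.exists(p)) {
      ct_config_error(sprintf("input path does not exist: %s", p))
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (`simulate: true` uses the default [synth_config()] with
#'   the pipeline seed).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (isTRUE(y$simulate)) y$simulate <- synth_config(seed = y$seed)
  do.call(pipeline_config, y)
}

log_stage <- function(stage, msg, t0) {
  message(sprintf("[%s] %s (%.2fs)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing every output as TSV/
#' JSON under `config$out_dir` plus a `manifest.json` listing each file
#' with its MD5 hash, the input hashes and the seed. Rerunning with the
#' same config reproduces byte-identical outputs for all stochastic
#' stages. Stages whose inputs are absent are skipped with a logged
#' notice; any stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  outputs <- character(0)
  skipped <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      ct_stop("cervotype_stage_error",
              sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # --- inputs -------------------------------------------------------------
  lum <- tis <- meta <- expr <- gmt <- prot <- cyt <- NULL
  if (!is.null(config$simulate)) {
    run_stage("simulate", {
      sim <- generate_paired_microbiome(config$simulate)
      lum <- sim$luminal; tis <- sim$tissue; meta <- sim$metadata
      expr <- generate_host_expression(sim$truth, config$simulate)
      pc <- generate_protein_cytokine(sim$truth, config$simulate)
      prot <- pc$proteins; cyt <- pc$cytokines
      emit("luminal_counts.tsv", function(p) write_taxa_table(lum, p))
      emit("tissue_counts.tsv", function(p) write_taxa_table(tis, p))
      emit("metadata.tsv", function(p) write_sample_metadata(meta, p))
      emit("expression_counts.tsv", function(p) write_expression_matrix(expr, p))
      emit("proteins.tsv", function(p) write_protein_table(prot, p))
      emit("cytokines.tsv", function(p) write_cytokine_table(cyt, p))
      emit("truth.json", function(p) jsonlite::write_json(
        list(luminal_type = as.list(sim$truth$luminal_type),
             tissue_type = as.list(sim$truth$tissue_type),
             seed = sim$truth$seed), p, auto_unbox = TRUE))
    })
    log_stage("simulate", "synthetic inputs generated", t0)
  } else {
    run_stage("load", {
      if (!is.null(config$luminal)) lum <- read_taxa_table(config$luminal, "luminal")
      if (!is.null(config$tissue)) tis <- read_taxa_table(config$tissue, "tissue")
      if (!is.null(config$metadata)) meta <- read_sample_metadata(config$metadata)
      if (!is.null(config$expression)) expr <- read_expression_matrix(config$expression)
      if (!is.null(config$proteins)) prot <- read_protein_table(config$proteins)
      if (!is.null(config$cytokines)) cyt <- read_cytokine_table(config$cytokines)
    })
  }
  if (!is.null(config$gmt)) gmt <- read_gmt(config$gmt)
  if (is.null(lum)) ct_config_error("a luminal taxa table is required")

  # --- microbiome stages --------------------------------------------------
  lum_f <- run_stage("filter", filter_taxa(lum))
  lum_rel <- tss_normalize(lum_f)
  lum_log <- log2_cp1k(lum_f)
  lum_cls <- run_stage("classify", classify_luminal(lum_rel))
  emit("luminal_assignments.tsv", function(p)
    utils::write.table(lum_cls, p, sep = "\t", quote = FALSE, row.names = FALSE))
  lum_div <- alpha_diversity(lum_rel)
  emit("luminal_diversity.tsv", function(p)
    utils::write.table(lum_div, p, sep = "\t", quote = FALSE, row.names = FALSE))

  tis_cls <- NULL
  if (!is.null(tis)) {
    tis_f <- run_stage("filter", filter_taxa(tis))
    tis_rel <- tss_normalize(tis_f)
    tis_log <- log2_cp1k(tis_f)
    tis_cls <- run_stage("classify", classify_tissue(tis_rel))
    emit("tissue_assignments.tsv", function(p)
      utils::write.table(tis_cls, p, sep = "\t", quote = FALSE, row.names = FALSE))
    tis_div <- alpha_diversity(tis_rel)
    emit("tissue_diversity.tsv", function(p)
      utils::write.table(tis_div, p, sep = "\t", quote = FALSE, row.names = FALSE))
    pd <- run_stage("paired_diversity", paired_diversity_test(lum_div, tis_div))
    emit("paired_diversity.tsv", function(p)
      utils::write.table(pd, p, sep = "\t", quote = FALSE, row.names = FALSE))
    st <- run_stage("shift", shift_table(lum_cls, tis_cls))
    emit("shift_table.tsv", function(p)
      utils::write.table(data.frame(luminal = rownames(st$table), st$table),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    shared_taxa <- intersect(colnames(lum_log), colnames(tis_log))
    da <- run_stage("diff_abundance", differential_abundance(
      lum_log[, shared_taxa, drop = FALSE], tis_log[, shared_taxa, drop = FALSE],
      fc_threshold = config$fc_threshold))
    emit("differential_abundance.tsv", function(p)
      utils::write.table(da, p, sep = "\t", quote = FALSE, row.names = FALSE))
    log_stage("microbiome", "typing, diversity and differential abundance done", t0)
  }

  if (!is.null(meta)) {
    ma <- run_stage("metadata_association",
                    metadata_association(meta, lum_cls, seed = config$seed))
    emit("metadata_association.tsv", function(p)
      utils::write.table(ma, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  # --- graphs -------------------------------------------------------------
  sg <- run_stage("sample_graph", {
    g <- build_snn(lum_log, "samples",
                   k = min(config$k_samples, nrow(lum_log) - 1L),
                   threshold = config$prune)
    louvain(g, seed = config$seed)
  })
  emit("sample_partition.tsv", function(p)
    utils::write.table(data.frame(sample = names(sg$membership),
                                  community = sg$membership),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  tg <- run_stage("taxon_graph", {
    g <- build_snn(lum_log, "taxa",
                   k = min(config$k_taxa, ncol(lum_log) - 1L),
                   threshold = config$prune)
    louvain(g, seed = config$seed)
  })
  emit("taxon_communities.tsv", function(p)
    utils::write.table(data.frame(taxon = names(tg$membership),
                                  community = tg$membership),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  log_stage("graphs", sprintf("sample Q = %.3f, taxon Q = %.3f",
                              sg$modularity, tg$modularity), t0)

  # --- host expression ----------------------------------------------------
  de <- NULL
  if (!is.null(expr)) {
    blocking <- if (!is.null(meta) && all(c("hiv", "dmpa") %in% names(meta))) {
      meta[, c("sample", "hiv", "dmpa")]
    } else NULL
    de <- run_stage("differential_expression", differential_features(
      expr, stats::setNames(lum_cls$label, lum_cls$sample), blocking,
      p_threshold = config$p_threshold, fdr_threshold = config$fdr_threshold))
    emit("de_omnibus.tsv", function(p)
      utils::write.table(de$omnibus, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("de_pairwise.tsv", function(p)
      utils::write.table(de$pairwise, p, sep = "\t", quote = FALSE, row.names = FALSE))
    sig <- de$omnibus$feature[de$omnibus$significant]
    if (length(sig) >= 2L) {
      cpm <- sweep(expr$values, 2L, colSums(expr$values), "/") * 1e6
      mods <- run_stage("modules", cluster_modules(
        log2(cpm[sig, , drop = FALSE] + 1),
        k = min(config$de_k, length(sig))))
      emit("gene_modules.tsv", function(p)
        utils::write.table(data.frame(feature = names(mods$membership),
                                      module = mods$membership),
                           p, sep = "\t", quote = FALSE, row.names = FALSE))
      if (!is.null(gmt)) {
        tt <- run_stage("enrichment",
                        top_module_terms(mods, gmt, de$kept_features))
        emit("module_enrichment.tsv", function(p)
          utils::write.table(tt, p, sep = "\t", quote = FALSE, row.names = FALSE))
      }
    }
    log_stage("expression", sprintf("%d significant features",
                                    sum(de$omnibus$significant)), t0)
    if (!is.null(gmt)) {
      nm <- run_stage("integration", {
        corr <- taxa_gene_correlation(lum_log, log2(
          sweep(expr$values, 2L, colSums(expr$values), "/") * 1e6 + 1))
        nes_matrix(corr, gmt, min_significant = 0L,
                   n_perm = config$n_perm, seed = config$seed)
      })
      emit("nes_matrix.tsv", function(p)
        utils::write.table(data.frame(taxon = rownames(nm$nes), nm$nes,
                                      check.names = FALSE),
                           p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("nes_pvalues.tsv", function(p)
        utils::write.table(data.frame(taxon = rownames(nm$p), nm$p,
                                      check.names = FALSE),
                           p, sep = "\t", quote = FALSE, row.names = FALSE))
      log_stage("integration", "NES matrix written", t0)
    } else {
      skipped <- c(skipped, "integration (no gene-set library)")
      message("[integration] skipped: no gene-set library provided")
    }
  } else {
    skipped <- c(skipped, "expression stages (no expression table)")
    message("[expression] skipped: no expression table provided")
  }

  # --- proteins / cytokines ----------------------------------------------
  if (!is.null(prot)) {
    blocking <- if (!is.null(meta) && "dmpa" %in% names(meta)) {
      meta[, c("sample", "dmpa")]
    } else NULL
    ps <- run_stage("proteins", protein_group_test(
      prot, stats::setNames(lum_cls$label, lum_cls$sample), blocking,
      fdr_threshold = config$fdr_threshold))
    emit("protein_stats.tsv", function(p)
      utils::write.table(ps$omnibus, p, sep = "\t", quote = FALSE, row.names = FALSE))
  } else skipped <- c(skipped, "proteins")
  if (!is.null(cyt)) {
    cs <- run_stage("cytokines", cytokine_group_test(
      cytokine_transform(cyt), stats::setNames(lum_cls$label, lum_cls$sample)))
    emit("cytokine_stats.tsv", function(p)
      utils::write.table(cs$omnibus, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("cytokine_pairwise.tsv", function(p)
      utils::write.table(cs$pairwise, p, sep = "\t", quote = FALSE, row.names = FALSE))
  } else skipped <- c(skipped, "cytokines")

  manifest <- list(
    seed = config$seed,
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    skipped = as.list(skipped)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done", sprintf("%d outputs, %d stages skipped",
                            length(outputs), length(skipped)), t0)
  invisible(manifest)
}
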