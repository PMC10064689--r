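# Synthetic paired multi-omics generator. Emulates the statistical structure
# the downstream analysis assumes: five community types per site with
# Dirichlet-multinomial compositional noise, a lumen->tissue type transition,
# community-type-linked host gene / protein / cytokine effects, HIV/DMPA
# nuisance effects, and LOD-censored cytokines. Ground truth is returned so
# recovery of planted parameters can be tested.

#' Generate paired luminal and tissue microbiome count tables
#'
#' Each participant receives a planted luminal community type (drawn from
#' `type_prevalence`), a tissue type drawn from the corresponding row of the
#' transition matrix, and Dirichlet-multinomial counts from the planted
#' type's composition profile at a site-specific lognormal sequencing depth.
#' Participant metadata (Nugent category linked to the luminal type, HIV,
#' DMPA, age) is generated alongside and recorded in the truth object.
#'
#' @param config A [synth_config()].
#' @return List with elements `luminal` and `tissue` (both [taxa_table()]
#'   over the identical taxon panel and participant set), `metadata`
#'   (a [sample_metadata()] data frame), and `truth` (`synth_truth`:
#'   planted types, transition matrix, effect sizes, seed).
#' @examples
#' sim <- generate_paired_microbiome(synth_config(n_participants = 20, seed = 7))
#' table(sim$truth$luminal_type, sim$truth$tissue_type)
#' @export
generate_paired_microbiome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    ids <- sprintf("P%03d", seq_len(n))
    lum_type <- sample.int(5L, n, replace = TRUE, prob = config$type_prevalence)
    tis_type <- vapply(lum_type, function(t) {
      sample.int(5L, 1L, prob = config$transition_matrix[t, ])
    }, integer(1))

    draw_site <- function(types, site_idx) {
      depth <- pmax(1, round(stats::rlnorm(n,
        meanlog = config$depth_log_mean[site_idx],
        sdlog = config$depth_log_sd[site_idx])))
      counts <- t(vapply(seq_len(n), function(i) {
        p <- rdirichlet1(config$concentration * config$taxa_profiles[types[i], ])
        stats::rmultinom(1L, size = depth[i], prob = p)[, 1L]
      }, numeric(ncol(config$taxa_profiles))))
      dimnames(counts) <- list(ids, colnames(config$taxa_profiles))
      counts
    }
    lum_counts <- draw_site(lum_type, 1L)
    tis_counts <- draw_site(tis_type, 2L)

    nugent <- vapply(lum_type, function(t) {
      sample(c("positive", "intermediate", "negative"), 1L,
             prob = c(config$bv_link[t], config$intermediate_link[t],
                      1 - config$bv_link[t] - config$intermediate_link[t]))
    }, character(1))
    meta <- sample_metadata(data.frame(
      sample = ids,
      nugent = nugent,
      hiv = stats::runif(n) < config$hiv_prevalence,
      dmpa = stats::runif(n) < config$dmpa_prevalence,
      age = round(stats::runif(n, 20, 50)),
      stringsAsFactors = FALSE
    ))

    truth <- structure(list(
      participants = ids,
      luminal_type = stats::setNames(lum_type, ids),
      tissue_type = stats::setNames(tis_type, ids),
      transition_matrix = config$transition_matrix,
      metadata = meta,
      seed = config$seed
    ), class = "synth_truth")

    list(luminal = taxa_table(lum_counts, "luminal"),
         tissue = taxa_table(tis_counts, "tissue"),
         metadata = meta,
         truth = truth)
  })
}

#' Generate a host expression count matrix with planted group effects
#'
#' Negative-binomial gene counts whose means follow a lognormal abundance
#' spectrum. The first `n_de_genes` genes are planted differentially
#' expressed: each is assigned a target community type (round-robin over
#' types 1-5) and its mean is multiplied by `2^de_log2fc` in participants
#' whose planted luminal type matches. Disjoint nuisance gene sets are
#' shifted by HIV status and DMPA use so blocking covariates matter.
#'
#' @param truth A `synth_truth` from [generate_paired_microbiome()].
#' @param config The same [synth_config()].
#' @return An [expression_matrix()] of counts (genes x participants). The
#'   planted structure is appended to `truth` fields via attributes
#'   `de_genes` (named integer vector gene -> target type) and
#'   `nuisance_genes` (list with `hiv` and `dmpa` members).
#' @export
generate_host_expression <- function(truth, config) {
  stopifnot(inherits(truth, "synth_truth"), inherits(config, "synth_config"))
  if (length(truth$participants) == 0L) {
    ct_config_error("truth contains no participants")
  }
  if (config$n_de_genes > config$n_genes) {
    ct_config_error("`n_de_genes` cannot exceed `n_genes`")
  }
  with_seed(config$seed + 101L, {
    n <- length(truth$participants)
    g <- config$n_genes
    genes <- sprintf("G%05d", seq_len(g))
    base <- stats::rlnorm(g, meanlog = 4, sdlog = 1)      # relative expression
    base <- base / sum(base)
    depth <- stats::rlnorm(n, config$expr_depth_log_mean, config$expr_depth_log_sd)

    nde <- config$n_de_genes
    de_genes <- integer(0)
    if (nde > 0 && config$de_log2fc != 0) {
      de_genes <- stats::setNames(rep_len(1:5, nde), genes[seq_len(nde)])
    }
    # nuisance genes: disjoint block after the DE block
    n_nuis <- min(50L, max(0L, (g - nde) %/% 2L))
    hiv_genes <- genes[nde + seq_len(n_nuis)]
    dmpa_genes <- genes[nde + n_nuis + seq_len(n_nuis)]

    lfc <- matrix(0, nrow = g, ncol = n, dimnames = list(genes, truth$participants))
    if (length(de_genes)) {
      for (j in seq_len(n)) {
        hit <- de_genes == truth$luminal_type[j]
        lfc[seq_len(nde)[hit], j] <- config$de_log2fc
      }
    }
    meta <- truth$metadata
    lfc[hiv_genes, meta$hiv] <- lfc[hiv_genes, meta$hiv] + 1
    lfc[dmpa_genes, meta$dmpa] <- lfc[dmpa_genes, meta$dmpa] + 1

    mu <- outer(base, depth) * 2^lfc
    counts <- if (config$nb_dispersion < 1e-8) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = g)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
             nrow = g)
    }
    dimnames(counts) <- list(genes, truth$participants)
    out <- expression_matrix(counts, normalized = FALSE)
    attr(out, "de_genes") <- de_genes
    attr(out, "nuisance_genes") <- list(hiv = hiv_genes, dmpa = dmpa_genes)
    out
  })
}

#' Generate protein and cytokine panels with planted shifts
#'
#' Proteins are Gaussian on the log10 scale; the first 20 proteins are
#' shifted by `protein_shift` log10 units in participants of luminal
#' type 4 (the highly diverse group). Cytokines are Gaussian on the linear
#' pg/mL scale; the first 4 cytokines are shifted by `cytokine_shift` in
#' type-4 participants. Negative cytokine draws are clamped to exact zero
#' (true zeros); values below `cytokine_lod` carry a censoring flag while
#' retaining the raw value, so the downstream LOD transform is testable.
#'
#' @param truth A `synth_truth`.
#' @param config The same [synth_config()].
#' @return List with `proteins` (a [protein_table()]), `cytokines`
#'   (a [cytokine_table()]), and `shifts` (the planted shift bookkeeping).
#' @export
generate_protein_cytokine <- function(truth, config) {
  stopifnot(inherits(truth, "synth_truth"), inherits(config, "synth_config"))
  if (config$cytokine_lod < 0) ct_config_error("`cytokine_lod` must be >= 0")
  with_seed(config$seed + 202L, {
    n <- length(truth$participants)
    shifted <- truth$luminal_type == 4L

    prot_names <- sprintf("PROT%02d", seq_len(config$n_proteins))
    prot_base <- stats::rnorm(config$n_proteins, mean = 2, sd = 0.5)
    n_pshift <- min(20L, config$n_proteins)
    pshift <- stats::setNames(rep(0, config$n_proteins), prot_names)
    pshift[seq_len(n_pshift)] <- config$protein_shift
    pv <- matrix(stats::rnorm(config$n_proteins * n,
                              mean = prot_base, sd = 0.3),
                 nrow = config$n_proteins,
                 dimnames = list(prot_names, truth$participants))
    pv[, shifted] <- pv[, shifted] + pshift

    cyt_names <- sprintf("CYT%02d", seq_len(config$n_cytokines))
    cyt_base <- stats::runif(config$n_cytokines, 10, 200)
    n_cshift <- min(4L, config$n_cytokines)
    cshift <- stats::setNames(rep(0, config$n_cytokines), cyt_names)
    cshift[seq_len(n_cshift)] <- config$cytokine_shift
    cv <- matrix(stats::rnorm(config$n_cytokines * n,
                              mean = cyt_base, sd = 0.4 * cyt_base),
                 nrow = config$n_cytokines,
                 dimnames = list(cyt_names, truth$participants))
    cv[, shifted] <- cv[, shifted] + cshift
    cv[cv < 0] <- 0                                   # true zeros
    lod <- stats::setNames(rep(max(config$cytokine_lod, .Machine$double.eps),
                               config$n_cytokines), cyt_names)
    censored <- sweep(cv, 1L, lod, "<")   # exact zeros get their own transform rule

    list(proteins = protein_table(pv),
         cytokines = cytokine_table(cv, lod, censored),
         shifts = list(protein = pshift, cytokine = cshift,
                       shifted_type = 4L))
  })
}
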