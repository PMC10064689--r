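# Configuration of the synthetic paired multi-omics generator.

# The 30-taxon panel covers the dominant cervicovaginal genera, with species
# resolution for Lactobacillus and the uncultivated BVAB taxa.
default_taxa_panel <- function() {
  c("Lactobacillus crispatus", "Lactobacillus jensenii", "Lactobacillus iners",
    "Lactobacillus gasseri", "Gardnerella", "Prevotella", "Atopobium",
    "Sneathia", "Megasphaera", "Mobiluncus", "BVAB1", "BVAB2", "BVAB3",
    "Dialister", "Porphyromonas", "Ureaplasma", "Mycoplasma", "Streptococcus",
    "Escherichia/Shigella", "Pseudomonas", "Bifidobacterium", "Aerococcus",
    "Anaerococcus", "Peptoniphilus", "Finegoldia", "Fusobacterium",
    "Corynebacterium", "Staphylococcus", "Enterococcus", "Parvimonas")
}

# Mean relative-abundance profile for one community type: named major
# components, remainder spread uniformly over the unnamed panel taxa.
profile_from_majors <- function(majors, panel = default_taxa_panel()) {
  p <- stats::setNames(rep(0, length(panel)), panel)
  p[names(majors)] <- majors
  rest <- setdiff(panel, names(majors))
  leftover <- max(0, 1 - sum(majors))
  p[rest] <- leftover / length(rest)
  p / sum(p)
}

# Five community archetypes: L. crispatus-dominated, L. iners-dominated,
# Gardnerella-dominated, highly diverse (Prevotella-rich), and "other".
default_taxa_profiles <- function(panel = default_taxa_panel()) {
  profs <- rbind(
    profile_from_majors(c("Lactobacillus crispatus" = 0.70,
                          "Lactobacillus jensenii" = 0.16,
                          "Lactobacillus iners" = 0.05,
                          "Lactobacillus gasseri" = 0.02,
                          "Gardnerella" = 0.03, "Atopobium" = 0.01), panel),
    profile_from_majors(c("Lactobacillus iners" = 0.82,
                          "Lactobacillus gasseri" = 0.04,
                          "Lactobacillus crispatus" = 0.01,
                          "Lactobacillus jensenii" = 0.01,
                          "Gardnerella" = 0.05, "Atopobium" = 0.02,
                          "Prevotella" = 0.01), panel),
    profile_from_majors(c("Gardnerella" = 0.46, "Lactobacillus iners" = 0.24,
                          "Atopobium" = 0.10, "Sneathia" = 0.02,
                          "Megasphaera" = 0.02, "Prevotella" = 0.015,
                          "Mobiluncus" = 0.015), panel),
    profile_from_majors(c("Prevotella" = 0.22, "Gardnerella" = 0.18,
                          "Lactobacillus iners" = 0.08, "Atopobium" = 0.08,
                          "Sneathia" = 0.07, "Megasphaera" = 0.05,
                          "Mobiluncus" = 0.03, "BVAB1" = 0.03, "BVAB2" = 0.02,
                          "Dialister" = 0.03, "Porphyromonas" = 0.02), panel),
    profile_from_majors(c("Atopobium" = 0.30, "Streptococcus" = 0.18,
                          "Escherichia/Shigella" = 0.14,
                          "Bifidobacterium" = 0.12,
                          "Lactobacillus gasseri" = 0.05,
                          "Mycoplasma" = 0.04, "Ureaplasma" = 0.03,
                          "Lactobacillus iners" = 0.03,
                          "Gardnerella" = 0.015, "Prevotella" = 0.012), panel)
  )
  rownames(profs) <- paste0("type", 1:5)
  profs
}

# Lumen -> tissue community-type transition probabilities. Rows 2-4 are
# anchored to the reported transitions (56% of L. iners-dominated lumina
# pair with a Gardnerella-dominated tissue community; 93% of type-3 and
# 76% of type-4 lumina keep their type); rows 1 and 5 reflect the reported
# concordant fractions for those groups.
default_transition_matrix <- function() {
  m <- rbind(
    c(0.50, 0.05, 0.30, 0.10, 0.05),
    c(0.00, 0.41, 0.56, 0.03, 0.00),
    c(0.00, 0.02, 0.93, 0.04, 0.01),
    c(0.00, 0.01, 0.20, 0.76, 0.03),
    c(0.00, 0.05, 0.35, 0.30, 0.30)
  )
  dimnames(m) <- list(paste0("L", 1:5), paste0("T", 1:5))
  m
}

#' Configuration for the synthetic paired multi-omics generator
#'
#' Bundles every tunable of the generator: the community-type composition
#' profiles and their Dirichlet concentration, sequencing depths per site,
#' the lumen-to-tissue community-type transition matrix, host expression
#' effect sizes, protein/cytokine panel sizes and the cytokine limit of
#' detection, and the community-type prevalences and their link to the
#' Nugent (bacterial vaginosis) category.
#'
#' @param n_participants Number of participants (each yields one luminal and
#'   one tissue sample).
#' @param taxa_profiles 5 x taxa matrix of per-community-type mean relative
#'   abundances; every row must sum to 1 (within 1e-9).
#' @param concentration Dirichlet concentration scalar (> 0); larger values
#'   give compositions closer to the type profile.
#' @param depth_log_mean,depth_log_sd Length-2 numeric vectors
#'   (luminal, tissue) of lognormal sequencing-depth parameters, in reads.
#' @param transition_matrix 5x5 row-stochastic matrix of tissue-type
#'   probabilities given the luminal type.
#' @param type_prevalence Length-5 probability vector of luminal community
#'   types.
#' @param n_genes,n_de_genes Host gene panel size and number of planted
#'   differentially expressed genes.
#' @param de_log2fc Planted expression effect size (log2 units).
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param n_proteins,n_cytokines Analyte panel sizes.
#' @param protein_shift Planted protein shift (log10 units).
#' @param cytokine_shift Planted cytokine shift (pg/mL).
#' @param cytokine_lod Cytokine limit of detection (pg/mL, >= 0).
#' @param bv_link Length-5 vector: probability of a positive Nugent category
#'   (score 7-10) per luminal community type.
#' @param intermediate_link Length-5 vector: probability of an intermediate
#'   Nugent category per luminal community type.
#' @param hiv_prevalence,dmpa_prevalence Participant-level probabilities.
#' @param expr_depth_log_mean,expr_depth_log_sd Lognormal parameters for
#'   host RNA library sizes.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_participants = 108,
                         taxa_profiles = default_taxa_profiles(),
                         concentration = 50,
                         depth_log_mean = c(luminal = log(40000), tissue = log(2500)),
                         depth_log_sd = c(luminal = 0.5, tissue = 0.7),
                         transition_matrix = default_transition_matrix(),
                         type_prevalence = c(10, 30, 21, 39, 8) / 108,
                         n_genes = 2000,
                         n_de_genes = 100,
                         de_log2fc = 2,
                         nb_dispersion = 0.1,
                         n_proteins = 74,
                         n_cytokines = 16,
                         protein_shift = 1.0,
                         cytokine_shift = 50,
                         cytokine_lod = 3,
                         bv_link = c(0, 0, 0.14, 0.72, 0.12),
                         intermediate_link = c(0.20, 0, 0.43, 0.26, 0.50),
                         hiv_prevalence = 0.12,
                         dmpa_prevalence = 0.31,
                         expr_depth_log_mean = log(5e5),
                         expr_depth_log_sd = 0.2,
                         seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1 ||
      n_participants != round(n_participants)) {
    ct_config_error("`n_participants` must be a positive integer")
  }
  if (!is.matrix(taxa_profiles) || nrow(taxa_profiles) != 5L ||
      is.null(colnames(taxa_profiles))) {
    ct_config_error("`taxa_profiles` must be a 5 x taxa matrix with taxon names")
  }
  if (any(taxa_profiles < 0) ||
      any(abs(rowSums(taxa_profiles) - 1) > 1e-9)) {
    ct_config_error("every `taxa_profiles` row must be non-negative and sum to 1")
  }
  stopifnot_scalar_number(concentration, "concentration", positive = TRUE)
  if (length(depth_log_mean) != 2L || length(depth_log_sd) != 2L ||
      any(!is.finite(depth_log_mean)) || any(depth_log_sd < 0) ||
      any(exp(depth_log_mean) <= 0)) {
    ct_config_error("depth parameters must be length-2 (luminal, tissue) with positive depth")
  }
  if (!is.matrix(transition_matrix) || !all(dim(transition_matrix) == 5L) ||
      any(transition_matrix < 0) || any(transition_matrix > 1) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    ct_config_error("`transition_matrix` must be 5x5 row-stochastic")
  }
  if (length(type_prevalence) != 5L || any(type_prevalence < 0) ||
      abs(sum(type_prevalence) - 1) > 1e-9) {
    ct_config_error("`type_prevalence` must be a length-5 probability vector")
  }
  if (n_de_genes > n_genes) {
    ct_config_error("`n_de_genes` cannot exceed `n_genes`")
  }
  if (cytokine_lod < 0) ct_config_error("`cytokine_lod` must be >= 0")
  stopifnot_scalar_number(nb_dispersion, "nb_dispersion")
  if (nb_dispersion < 0) ct_config_error("`nb_dispersion` must be >= 0")
  for (p in list(bv_link, intermediate_link)) {
    if (length(p) != 5L || any(p < 0) || any(p > 1)) {
      ct_config_error("Nugent link probabilities must be length-5 in [0,1]")
    }
  }
  if (any(bv_link + intermediate_link > 1)) {
    ct_config_error("per-type Nugent category probabilities exceed 1")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    taxa_profiles = taxa_profiles, concentration = concentration,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    transition_matrix = transition_matrix, type_prevalence = type_prevalence,
    n_genes = as.integer(n_genes), n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
    n_proteins = as.integer(n_proteins), n_cytokines = as.integer(n_cytokines),
    protein_shift = protein_shift, cytokine_shift = cytokine_shift,
    cytokine_lod = cytokine_lod, bv_link = bv_link,
    intermediate_link = intermediate_link,
    hiv_prevalence = hiv_prevalence, dmpa_prevalence = dmpa_prevalence,
    expr_depth_log_mean = expr_depth_log_mean,
    expr_depth_log_sd = expr_depth_log_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}
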