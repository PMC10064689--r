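# Rule-based community-state classification (L1-L5 / T1-T5), paired
# shift/concordance analysis, and covariate association tests.

#' Define a community-typing rule set
#'
#' A rule set is an ordered cascade: each rule assigns its target label to
#' the first sample satisfying every one of its (group, comparator,
#' threshold) conditions; samples matching no rule fall through to label 5.
#' Taxon groups are named lists of exact taxon names plus optional name
#' prefixes (e.g. all `Lactobacillus` species); their relative abundances
#' are summed before rule evaluation.
#'
#' @param groups Named list; each element a list with members `taxa`
#'   (character, exact column names) and/or `prefixes` (character,
#'   matched with `startsWith`).
#' @param rules List of rules; each a list with `label` (integer 1-4) and
#'   `conditions`, itself a list of `list(group =, op = ">" or "<",
#'   threshold =)` conjunctions. All comparators are strict; boundary
#'   values fall through.
#' @return A `rule_set` object.
#' @export
rule_set <- function(groups, rules) {
  if (!length(rules)) ct_config_error("empty ruleset")
  if (is.null(names(groups))) ct_config_error("groups must be named")
  for (r in rules) {
    if (!r$label %in% 1:4) ct_config_error("explicit rules must target labels 1-4")
    for (cond in r$conditions) {
      if (!cond$group %in% names(groups)) {
        ct_config_error(sprintf("rule references unknown group '%s'", cond$group))
      }
      if (!cond$op %in% c(">", "<")) ct_config_error("comparator must be '>' or '<'")
    }
  }
  structure(list(groups = groups, rules = rules), class = "rule_set")
}

#' Default luminal community-typing rules
#'
#' L1: > 80% L. crispatus and/or L. jensenii; L2: > 80% total Lactobacillus;
#' L3: > 10% Gardnerella and < 5% Prevotella; L4: > 5% Prevotella;
#' otherwise L5. First match wins, evaluated in that order.
#'
#' @param lactobacillus_prefixes Prefix list defining the "all
#'   Lactobacillus" group (species resolution varies between datasets).
#' @return A [rule_set()].
#' @export
default_luminal_rules <- function(lactobacillus_prefixes = "Lactobacillus") {
  rule_set(
    groups = list(
      crispatus_jensenii = list(taxa = c("Lactobacillus crispatus",
                                         "Lactobacillus jensenii")),
      lactobacillus_all = list(prefixes = lactobacillus_prefixes),
      gardnerella = list(taxa = "Gardnerella"),
      prevotella = list(taxa = "Prevotella")
    ),
    rules = list(
      list(label = 1L, conditions = list(
        list(group = "crispatus_jensenii", op = ">", threshold = 0.80))),
      list(label = 2L, conditions = list(
        list(group = "lactobacillus_all", op = ">", threshold = 0.80))),
      list(label = 3L, conditions = list(
        list(group = "gardnerella", op = ">", threshold = 0.10),
        list(group = "prevotella", op = "<", threshold = 0.05))),
      list(label = 4L, conditions = list(
        list(group = "prevotella", op = ">", threshold = 0.05)))
    )
  )
}

#' Default tissue community-typing rules
#'
#' T1: > 50% L. crispatus and/or L. jensenii; T2: > 50% total Lactobacillus
#' and < 30% Gardnerella; T3: > 30% Gardnerella and < 10% Prevotella;
#' T4: > 10% Prevotella; otherwise T5.
#'
#' @inheritParams default_luminal_rules
#' @return A [rule_set()].
#' @export
default_tissue_rules <- function(lactobacillus_prefixes = "Lactobacillus") {
  rule_set(
    groups = list(
      crispatus_jensenii = list(taxa = c("Lactobacillus crispatus",
                                         "Lactobacillus jensenii")),
      lactobacillus_all = list(prefixes = lactobacillus_prefixes),
      gardnerella = list(taxa = "Gardnerella"),
      prevotella = list(taxa = "Prevotella")
    ),
    rules = list(
      list(label = 1L, conditions = list(
        list(group = "crispatus_jensenii", op = ">", threshold = 0.50))),
      list(label = 2L, conditions = list(
        list(group = "lactobacillus_all", op = ">", threshold = 0.50),
        list(group = "gardnerella", op = "<", threshold = 0.30))),
      list(label = 3L, conditions = list(
        list(group = "gardnerella", op = ">", threshold = 0.30),
        list(group = "prevotella", op = "<", threshold = 0.10))),
      list(label = 4L, conditions = list(
        list(group = "prevotella", op = ">", threshold = 0.10)))
    )
  )
}

# Sum the relative abundance of each taxon group; unknown members
# contribute 0 with a warning.
resolve_groups <- function(relabund, rules) {
  cols <- colnames(relabund)
  g <- vapply(names(rules$groups), function(gn) {
    def <- rules$groups[[gn]]
    hit <- logical(length(cols))
    if (!is.null(def$taxa)) {
      missing <- setdiff(def$taxa, cols)
      if (length(missing)) {
        warning(sprintf("group '%s': member(s) %s not in table, contributing 0",
                        gn, paste(missing, collapse = ", ")))
      }
      hit <- hit | cols %in% def$taxa
    }
    if (!is.null(def$prefixes)) {
      for (p in def$prefixes) hit <- hit | startsWith(cols, p)
    }
    rowSums(relabund[, hit, drop = FALSE])
  }, numeric(nrow(relabund)))
  if (nrow(relabund) == 1L) g <- matrix(g, nrow = 1L, dimnames = list(rownames(relabund), names(rules$groups)))
  g
}

classify_samples <- function(relabund, rules, prefix) {
  if (!inherits(rules, "rule_set")) ct_config_error("`rules` must be a rule_set")
  if (any(abs(rowSums(relabund) - 1) > 1e-6)) {
    ct_input_error("rows must sum to 1 (run tss_normalize first)")
  }
  ga <- resolve_groups(relabund, rules)
  n <- nrow(relabund)
  type <- rep(5L, n)
  fired <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (ri in seq_along(rules$rules)) {
      r <- rules$rules[[ri]]
      ok <- all(vapply(r$conditions, function(cond) {
        v <- ga[i, cond$group]
        if (cond$op == ">") v > cond$threshold else v < cond$threshold
      }, logical(1)))
      if (ok) { type[i] <- r$label; fired[i] <- ri; break }
    }
  }
  out <- data.frame(sample = rownames(relabund),
                    label = paste0(prefix, type),
                    type = type,
                    fired_rule = fired,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(ga))
}

#' Classify luminal samples into community-state groups L1-L5
#'
#' @param relabund Samples x taxa relative-abundance matrix (rows sum
#'   to 1).
#' @param rules A [rule_set()]; defaults to [default_luminal_rules()].
#' @return Data frame with columns `sample`, `label` (`L1`..`L5`), `type`
#'   (1-5), `fired_rule` (NA for the fall-through group), and the
#'   evaluated group abundances.
#' @examples
#' m <- matrix(c(0.85, 0.15), 1, dimnames = list("s1",
#'        c("Lactobacillus crispatus", "Gardnerella")))
#' classify_luminal(m)$label  # "L1"
#' @export
classify_luminal <- function(relabund, rules = default_luminal_rules()) {
  classify_samples(relabund, rules, "L")
}

#' Classify tissue samples into community-state groups T1-T5
#'
#' @inheritParams classify_luminal
#' @param rules A [rule_set()]; defaults to [default_tissue_rules()].
#' @return As [classify_luminal()], with `T` labels.
#' @export
classify_tissue <- function(relabund, rules = default_tissue_rules()) {
  classify_samples(relabund, rules, "T")
}

#' Paired community-type shift table
#'
#' 5x5 contingency of luminal x tissue community type over the paired
#' participant intersection, with the concordant count (the trace) and
#' per-luminal-row transition fractions.
#'
#' @param lum,tis Assignment data frames from [classify_luminal()] /
#'   [classify_tissue()].
#' @return A `shift_table` object: `table` (5x5 counts), `fractions`
#'   (row-conditional transition fractions), `concordant`, `n_pairs`.
#' @export
shift_table <- function(lum, tis) {
  shared <- intersect(lum$sample, tis$sample)
  if (!length(shared)) ct_input_error("no participant present in both assignments")
  lt <- lum$type[match(shared, lum$sample)]
  tt <- tis$type[match(shared, tis$sample)]
  tab <- matrix(0L, 5L, 5L, dimnames = list(paste0("L", 1:5), paste0("T", 1:5)))
  for (i in seq_along(shared)) tab[lt[i], tt[i]] <- tab[lt[i], tt[i]] + 1L
  rs <- rowSums(tab)
  frac <- sweep(tab, 1L, ifelse(rs == 0, 1, rs), "/")
  structure(list(table = tab, fractions = frac,
                 concordant = sum(diag(tab)), n_pairs = length(shared)),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("shift_table: %d pairs, %d concordant (%.0f%%)\n",
              x$n_pairs, x$concordant, 100 * x$concordant / x$n_pairs))
  print(x$table)
  invisible(x)
}

#' Covariate association with community groups
#'
#' For each metadata covariate, tests association with the community-type
#' labels: continuous covariates with the Kruskal-Wallis rank sum test,
#' categorical covariates with Fisher's exact test (exact network
#' enumeration for tables with n <= 200, Monte Carlo with 1e6 draws and a
#' fixed seed beyond). Missing values (NA, or the `"missing"` Nugent
#' category) are excluded per covariate. A covariate constant across all
#' samples is reported with p = 1 and a flag rather than an error.
#'
#' @param meta A [sample_metadata()] data frame.
#' @param labels Assignment data frame from [classify_luminal()] or
#'   [classify_tissue()].
#' @param covariates Covariate columns to test (default: all except
#'   `sample`).
#' @param seed Seed for Monte Carlo Fisher p-values.
#' @return Data frame: `covariate`, `test`, `p_value`, `n_used`, `flag`.
#' @export
metadata_association <- function(meta, labels,
                                 covariates = setdiff(names(meta), "sample"),
                                 seed = 1L) {
  shared <- intersect(meta$sample, labels$sample)
  if (!length(shared)) ct_input_error("no overlap between metadata and labels")
  meta <- meta[match(shared, meta$sample), , drop = FALSE]
  grp <- factor(labels$type[match(shared, labels$sample)])
  if (nlevels(droplevels(grp)) < 2L) ct_input_error("need >= 2 groups")
  rows <- lapply(covariates, function(cv) {
    x <- meta[[cv]]
    miss <- is.na(x) | (is.character(x) & x == "missing")
    x <- x[!miss]; g <- droplevels(grp[!miss])
    flag <- ""
    if (length(unique(x)) < 2L || nlevels(g) < 2L) {
      return(data.frame(covariate = cv, test = "none", p_value = 1,
                        n_used = length(x), flag = "constant"))
    }
    if (is.numeric(x)) {
      kw <- stats::kruskal.test(x, g)
      p <- if (is.nan(kw$p.value)) 1 else kw$p.value
      data.frame(covariate = cv, test = "kruskal-wallis", p_value = p,
                 n_used = length(x), flag = flag)
    } else {
      tab <- table(as.character(x), g)
      ft <- if (sum(tab) <= 200) {
        stats::fisher.test(tab, workspace = 2e7)
      } else {
        with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e6))
      }
      data.frame(covariate = cv, test = "fisher", p_value = ft$p.value,
                 n_used = length(x), flag = flag)
    }
  })
  do.call(rbind, rows)
}
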