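---
title: "cervotype: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cervotype: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervotype)
```

This vignette is the package's own account of its statistical machinery:
what each stage assumes, which tunables matter, what the synthetic
generator does and does not emulate, and where a genuinely open design
choice was settled.

## The analysis problem

Cervicovaginal health is strongly shaped by the bacterial community of
the lower genital tract. A *Lactobacillus*-dominated lumen is considered
optimal; *Gardnerella*- and *Prevotella*-rich communities are associated
with bacterial vaginosis (BV), inflammation and epithelial disruption.
Beyond the familiar luminal (lavage) community, a distinct
**tissue-adherent** community can exist on the ectocervical epithelium.
The questions this package operationalizes are: how do paired luminal and
tissue-adherent communities relate (concordance and typed "shifts"), and
how do the communities at each site associate with host gene expression,
secreted proteins and cytokines.

## Community-state typing

Classification is a deterministic, ordered rule cascade on relative
abundances (`tss_normalize()` output). Each rule sums named taxon groups
and compares against a threshold with a **strict** comparator; the first
matching rule assigns the label and label 5 is the fall-through
("other"). The default luminal cascade is L1 (> 80%
*L. crispatus*/*L. jensenii*), L2 (> 80% total *Lactobacillus*), L3
(> 10% *Gardnerella* and < 5% *Prevotella*), L4 (> 5% *Prevotella*); the
tissue cascade relaxes to > 50%, > 50% with < 30% *Gardnerella*, > 30%
with < 10% *Prevotella*, and > 10% respectively, reflecting the higher
*Gardnerella* background of tissue samples.

Two choices here were genuinely open and are settled as follows:

* **Rule overlap.** A sample with 85% *L. crispatus* also satisfies the
  total-*Lactobacillus* rule. The cascade is evaluated in listing order
  with first-match-wins, so such a sample is L1. This mirrors how the
  group definitions are stated — as a sequence of progressively weaker
  criteria.
* **Species resolution of "all *Lactobacillus*".** Taxon naming varies
  between classifiers, so the group is defined by a configurable name
  *prefix list* (default: any taxon starting with "Lactobacillus")
  rather than a hard-coded species list. Ambiguous names (e.g.
  "Lactobacillus unclassified") are therefore included by default, and
  the choice is visible in the rule set rather than hidden.

Rule-group members missing from a table contribute zero with a warning —
a dataset without *L. jensenii* should classify, not crash.

## Normalization and microbiome statistics

All downstream microbiome statistics run on the
`log2(count / depth × 1000 + 1)` transform (log₂ counts-per-thousand,
`log2_cp1k()`): a depth-robust, sparsity-friendly transform appropriate
for the characteristic 16S depths of lavage (~40,000 reads) versus tissue
(~2,500 reads) samples. Taxa are pre-filtered to those with **more than
3 reads in at least one sample** (strict inequality).

* **Alpha diversity** uses the literal formulas (Shannon in nats,
  Simpson 1 − Σp², inverse Simpson). The paired site comparison is a
  Wilcoxon signed-rank test: the test type for the paired comparison was
  not dictated by the analysis design, and the signed-rank test is the
  nonparametric choice consistent with the rank-based style of the other
  tests. Zero differences are dropped (the signed-rank convention); if
  none remain the p-value is 1 with a warning. Exact p-values are used up
  to 25 informative pairs, the normal approximation with continuity
  correction beyond.
* **Differential abundance** is an unpaired two-sided Mann-Whitney U per
  taxon with significance at |log₂FC| > 0.25 and p < 0.01. The fold
  change is defined as the **difference of means of the transformed
  values** (mean log, not log of mean): the transform is applied before
  all analysis, so effect sizes live on the transformed scale. The
  absolute value is used so both directions are reportable. Ties are
  handled by mid-ranks with tie correction under the normal
  approximation.
* **TMM normalization factors** for expression counts follow the
  standard trimmed-mean-of-M-values recipe: reference sample = the one
  whose library-scaled upper quartile is closest to the mean; 30% trim on
  M, 5% on A; delta-method precision weights; geometric-mean-1
  renormalization. The test suite verifies equality with an independent
  reference implementation to 1e-6.

## SNN graphs and Louvain

Sample graphs and taxon co-occurrence graphs are built identically:
k-nearest neighbors by Euclidean distance on log₂[CP1K+1] features
(samples as rows; the transposed matrix for taxa), then a
shared-nearest-neighbor graph whose edges carry the Jaccard index of the
two k-neighbor sets, pruned at 1/15. Louvain community detection runs on
the Jaccard weights; modularity Q is evaluated with the weighted formula.

Three defaults deserve a note. The source analyses used k = 5 and k = 12
with conflicting text about which k belongs to which graph; the figure
captions are unambiguous (12-SNN for samples, 5-SNN for taxa) and are
followed here, with both configurable. The Jaccard pruning threshold was
unstated; 1/15 is the convention of the SNN-Louvain tooling ecosystem
this workflow descends from. The distance metric was unstated; Euclidean
distance on the analysis transform is used. Neighborhoods are
symmetrized before pruning. Ties in neighbor distance are broken by
ascending node index so graphs are bit-reproducible.

## Preranked GSEA integration

For each taxon (present in ≥ 2 samples), genes are ranked by the Pearson
correlation between the taxon's log abundance and log₂(CPM+1) expression
of the top 5000 highly variable genes. The enrichment score of a gene set
is the extremum of the weighted Kolmogorov–Smirnov running sum (hits
contribute |r|¹ normalized over hits; misses −1/(N − N_hits)). The null
is random gene-label permutation; NES divides ES by the mean |null ES| of
matching sign, and p = (1 + #{same-sign nulls ≥ |ES|}) / (1 + #same-sign
nulls). The taxa × set matrix is masked at p ≥ 0.05 and filtered to rows
and columns with at least 10 significant entries.

Open choices settled here: the correlation type (Pearson on the stated
log transforms, with Spearman behind a flag), the highly-variable-gene
criterion (variance of log₂(CPM+1) — the simplest defensible reading),
GSEA weight p = 1 with 1000 permutations, gene-set size bounds 10–500,
and the sign-matched one-tailed permutation p (documented as this
package's convention, since one- versus two-tailedness was unstated). If
the positive and negative running-sum extremes tie exactly in magnitude
the positive branch is reported. No multiple-testing correction is
applied across the NES matrix — the raw p < 0.05 mask plus the
≥ 10-entry rule replicate the upstream filtering as stated, which is a
known limitation.

## Differential expression and modules

The expression workhorse is a deliberately simple negative-binomial
log-linear model, **not** a re-implementation of edgeR: per-feature NB
GLM with group + blocking covariates (HIV, DMPA), TMM offsets,
moment-based tagwise dispersion shrunk toward the common (median) value
with weight n/(n+20), a likelihood-ratio omnibus test and Wald pairwise
contrasts. Its contracts are behavioral, verified by simulation: type-I
error at p < 0.01 stays at or below 0.02 on NB nulls, and planted
log₂FC = 2 effects are recovered with ≥ 90% sensitivity at 15 samples
per group. Features with counts below 5 in three or more samples are
removed first — an aggressive filter for sparse designs, retained
deliberately and configurable.

Significant features are clustered with 1 − Pearson r distance and Ward
"ward.D2" linkage. Because correlation distance is scale-invariant, row
scaling would only affect heatmap display, not module membership. Module
counts in real analyses (six luminal, five tissue modules) came without
a stated cut rule, so both fixed-k and fixed-height cuts are exposed;
the pipeline default is fixed k. Enrichment is an upper-tail
hypergeometric test per term with BH across terms; the universe is
**everything surviving the low-count filter**, the conservative choice
(enriching against the whole annotation universe inflates significance).
TF enrichment reports the top-10 factors with raw p < 0.01 per
direction.

## Proteins and cytokines

Protein panels (log₁₀ scale) are tested per protein by OLS with the
group factor and DMPA blocking, an F test for the group factor, and BH
across proteins at adjusted p < 0.05. The empirical-Bayes variance
moderation used by limma-style workflows is replaced by ordinary OLS —
a documented stand-in whose null behavior the suite verifies — with a
simple posterior-variance moderation available behind a flag (default
off). A blocking covariate perfectly confounded with the groups raises a
rank-deficiency error naming the covariate. For presentation, the
significant proteins are row-scaled and cut at dendrogram height 1
(correlation distance, Ward linkage) — the height-1 convention operates
on that scaled correlation dendrogram, which is the natural reading
since the clustering itself is scale-invariant.

Cytokines (pg/mL) are transformed before testing: exact zeros → 0.01,
below-LOD values → LOD/2, then log₂. The transform records an audit of
both substitution counts and stamps its output; re-transforming a
stamped object is refused rather than silently double-transformed.
Group tests are Kruskal-Wallis with tie correction (BH across
cytokines) followed by Dunn z-tests on pooled ranks. The Dunn BH family
is **within cytokine across pairs** — matching per-panel annotation of
pairwise significance — and can be switched to a global family.

## The synthetic generator

`generate_paired_microbiome()` and its companions emulate the
statistical structure the analysis assumes, with planted ground truth:

* Five community-type composition profiles over a 30-taxon panel
  (the dominant cervicovaginal genera; species resolution for
  *Lactobacillus* and BVAB taxa), drawn **Dirichlet-multinomial**.
  The compositional noise model was an open choice; the
  Dirichlet-multinomial is the standard overdispersed model for 16S
  compositions. The concentration default is 50 — within-type abundance
  variance is a free parameter with no published value, so it was chosen
  once as a realistic between-subject spread and documented, not
  inferred.
* Luminal type prevalences default to the observed group sizes
  (10/30/21/39/8 of 108); the lumen→tissue **transition matrix** rows
  are anchored to the reported transitions — row 2 = (0, 0.41, 0.56,
  0.03, 0) so that 56% of *L. iners*-type lumina pair with a
  *Gardnerella*-type tissue community, 93% of type 3 and 76% of type 4
  keep their type — with rows 1 and 5 reflecting the reported concordant
  fractions.
* Sequencing depths are lognormal with medians 40,000 (luminal) and
  2,500 (tissue) reads, reproducing the realistic sparsity contrast
  between sites.
* Host expression is NB with a lognormal mean spectrum; planted DE genes
  (round-robin over target types) are shifted by `de_log2fc` (default 2)
  in matching participants; disjoint nuisance gene sets respond to HIV
  and DMPA so blocking matters. The default panel is 2000 genes with 100
  DE — a deliberately compact panel chosen as this package's standard
  simulation size; sensitivity and calibration results at this size are
  what the test suite asserts.
* Proteins are Gaussian on log₁₀ (planted 1.0-unit shifts in the
  highly diverse type), cytokines Gaussian on the linear scale with
  negative draws clamped to exact zero (true zeros) and sub-LOD values
  flagged censored while keeping the raw value, so the LOD transform is
  separately testable. The BV (Nugent category) link per community type
  uses the observed per-group category proportions.

What the generator does **not** emulate: taxonomic assignment error,
chimeras or read-level artifacts; phylogenetic correlation between taxa;
zero-inflation beyond what the Dirichlet-multinomial induces; batch or
plate effects in the protein panel; longitudinal structure. Passing
tests therefore demonstrate that the statistical machinery recovers
planted effects under the assumed models — not that those models capture
every feature of real amplicon data.

## Numerical conventions and problem sizes

Determinism: every stochastic operation takes a seed and restores the
caller's RNG state; pipeline outputs are pure functions of (inputs,
config, seed) and manifests carry MD5 hashes. Tie-breaks are
deterministic everywhere (neighbor ties by node index, gene-rank ties by
identifier). Degenerate inputs have defined behavior rather than
exceptions where a result is still meaningful: constant covariates
report p = 1 with a flag, zero-variance proteins are flagged,
all-zero-difference paired tests warn and report p = 1, edgeless graphs
return singleton partitions with Q = 0.

The simulation sizes used by the test suite and the acceptance script —
500 participants for transition recovery, 300 at concentration 200 for
type recovery, 75 participants × 600 genes for DE sensitivity, 500–1000
replicates for null calibrations — are the package's standard desk-scale
verification sizes, chosen so each property is measured with useful
Monte-Carlo precision.

## Known limitations

* The NB differential-expression model is a simplified stand-in; exact
  agreement with edgeR's dispersion machinery is a non-goal.
* No compositional log-ratio methods (CLR/ALR) or zero-imputation
  models; rarefaction is out of scope.
* The NES matrix is uncorrected for multiplicity by design (see above).
* Probabilistic community-state inference (mixture models) is out of
  scope; the typing is intentionally rule-based and auditable.
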