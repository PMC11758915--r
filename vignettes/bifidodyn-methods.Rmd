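---
title: "Methods: modeling B. longum subspecies succession in the infant gut"
author: "bifidodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling B. longum subspecies succession in the infant gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifidodyn)
```

## Scope and scientific background

*Bifidobacterium longum* dominates the gut of healthy breastfed infants, but
its two human-associated subspecies follow different trajectories:
subsp. *longum* (BLlongum) typically dominates around one month of age and is
replaced by subsp. *infantis* (BLinfantis) around six months. Three classes
of factors are thought to govern this replacement: priority effects (who
colonizes first, proxied by maternal dominance and mother-to-infant strain
sharing), nutrition (breast milk versus formula, feeding frequency), and the
genomic potential to use human milk glycans (HMGs) — free human milk
oligosaccharides (HMOs) and milk glycoprotein N-glycans.

`bifidodyn` implements the downstream statistical pipeline for this question:

1. **HMG profiling** — per-genome copy-number profiles of HMG-utilizing
   glycoside hydrolases (GHs) and glycan transporters, clustering of genomes
   into utilization types, and per-gene enrichment tests across types.
2. **Subspecies typing** — marker-gene copy-number clustering into BLlongum
   versus BLinfantis.
3. **Dynamics** — presence/prevalence/abundance summaries and the
   priority-effect strength statistic.
4. **Feature selection** — cross-validated LASSO regression of subspecies
   abundance on maternal, nutritional, metabolic and community covariates.
5. **Synthetic cohorts** — a seeded generator of mother–infant cohorts and
   genome repertoires with planted ground truth, making every downstream
   stage testable without sequencing data.

The pipeline starts from tabular intermediates — taxonomic relative-abundance
tables, strain-sharing booleans, alignment hit tables, pairwise protein
identity matrices, gene count matrices. Producing those intermediates (read
QC, assembly, binning, taxonomic and functional annotation, SNV-based strain
tracking) is out of scope.

## The priority-effect statistic

For a focal taxon, let $\bar B_{\mathrm{early}}$ be its mean relative
abundance among infants whose arrival proxy is true and
$\bar B_{\mathrm{late}}$ the mean among the remaining infants. The strength
of priority effects is

$$P' = \ln\!\left(\bar B_{\mathrm{late}} / \bar B_{\mathrm{early}}\right),$$

negative when early arrival is associated with higher abundance. Because
exact arrival order is unobservable in stool samples, three proxies are
used: (i) *maternal dominance* — the taxon is the strictly most abundant
bifidobacterial taxon in the reference sample (the mother's prenatal sample;
for six-month infants, falling back to the infant's own one-month sample when
no maternal sample exists) **and** exceeds 0.1% there; (ii) *strain
sharing* — a maternal strain was detected in the infant; (iii) *either*.

Numerical conventions:

* Group means include infants where the taxon is absent (abundance 0); the
  statistic describes the abundance *reached*, and a presence filter would
  condition on the outcome. A zero group mean makes $P'$ infinite; it is
  returned flagged as non-finite rather than silently dropped.
* Ties for "most abundant" count as *not* dominant (strict maximum), the
  conservative reading.
* The group difference is tested with an **unpaired Wilcoxon rank-sum test**.
  The early and late groups are disjoint infants, so a signed-rank (paired)
  test is not applicable; Benjamini–Hochberg FDR is applied across the
  criterion × timepoint family.

$P'$ is antisymmetric under swapping the groups and invariant to rescaling
all abundances — both properties are tested.

## HMG profiling

**Variant clustering.** Within one GH family, protein sequences are grouped
into variants by agglomerative hierarchical clustering with Ward (D2)
linkage on percent dissimilarity ($100 - \text{identity}$). The tree is cut
at the smallest number of clusters such that every multi-member cluster has
**mean pairwise identity ≥ 60%**; the rule is enforced on final clusters
(whether it should instead constrain individual merges is ambiguous — final
clusters is the interpretation implemented, and the brute-force oracle in the
test suite uses the same definition). Singletons and variants carried by
fewer than 5% of genomes are excluded from the reported repertoire (and
listed separately). Agglomerative merge ties are resolved by `stats::hclust`'s
deterministic lowest-index ordering, so results are reproducible.

**Transporter hits.** BLAST-style tabular alignments are filtered at
bitscore ≥ 50, e-value ≤ 0.001 and identity ≥ 60% (all inclusive), then only
the highest-identity surviving hit per query is kept (ties: first
occurrence).

**Profile clustering.** Copy-number columns are standardized to zero mean
and unit variance (zero-variance columns are dropped with a warning), and
genomes are clustered with Ward.D2 on euclidean distances. When the number
of clusters is not forced, it is chosen by maximal mean silhouette width
over $k \in \{2, \dots, \min(8, n-1)\}$; the cluster count is an open
modeling choice and a forced `k` is always available.

**Enrichment.** Per gene: a Kruskal–Wallis test on $\log_2(\text{count}+1)$
across profile clusters, unpaired pairwise Wilcoxon rank-sum post-hoc tests
(the same unpaired reasoning as above — clusters contain different genomes),
and a cluster-of-interest versus remaining-clusters comparison with

$$\log_2 \mathrm{FC} = \log_2\frac{\bar c_{\mathrm{in}} + 0.5}
{\bar c_{\mathrm{rest}} + 0.5}.$$

The 0.5 pseudocount keeps the fold change finite for absent genes while
preserving the "4-fold" interpretation for nonzero means. A gene is
*enriched* in a cluster when the BH-adjusted cluster-vs-rest $q < 0.05$
**and** $\log_2 \mathrm{FC} \ge 2$ (depleted at $\le -2$); both cutoffs are
inclusive on the fold-change side, so an exact 4-fold change qualifies.
The log transform uses a +1 pseudocount because copy numbers include zeros.

**Reference target set.** The bundled profiling targets are 13 GH families
(8 HMO-active, 5 N-glycan-active) and 37 transporter genes encoding 11 HMO
and 3 N-glycan uptake systems (`hmg_gh_families()`, `hmg_transporters()`).
Family names and system names follow the bifidobacterial HMG literature; the
per-system gene breakdown is a synthetic reconstruction constrained to those
totals, as the package ships no third-party sequence data.

## Subspecies typing

Genome genes are aligned against subspecies-specific marker genes (roster
sizes 119 BLinfantis / 128 BLlongum in the simulated fixtures), filtered at
≥ 90% identity and ≥ 50% coverage (inclusive), counted into a genome ×
marker copy-number matrix, and clustered (euclidean, Ward.D2) with the tree
cut at $k = 2$ — the two human-associated subspecies; the pig-associated
subspecies are out of scope. Each cluster is labeled by the subspecies whose
marker set has the larger mean total copy number among members. An exact tie,
or both clusters resolving to one label, raises an error instead of guessing:
a marker matrix that cannot separate the subspecies should fail loudly.

## Feature selection

Per model (taxon × age group) a design matrix is assembled from the feature
vocabulary in `encode_features()`: maternal abundance, sharing booleans,
feeding type and frequency, other-taxon presence/abundance, bifidobacterial
diversity (number of taxa above the 0.01% presence threshold), and optional
per-pair extras such as HMG-profile assignments. Conventions:

* Categorical features are **fully one-hot encoded** (no reference level
  dropped). The L1 penalty resolves the induced redundancy, and full
  indicators keep every level interpretable in the coefficient report.
* Missing numeric cells are imputed with the column mean and flagged in the
  returned `imputed` matrix.
* Predictor pairs with $|r| > 0.70$ (strict; evaluated with a $10^{-10}$
  tolerance so an engineered exact-boundary correlation is not flagged by
  floating-point noise) are reported, and the later-listed column of each
  flagged pair is dropped deterministically. Callers can override the
  retained set — the screen assists, rather than replaces, judgment.

The LASSO is fit over a 100-point log-spaced penalty grid spanning four
decades below $\lambda_{\max}$ (the smallest penalty with all coefficients
zero; this is `glmnet`'s default grid, adopted since no grid is otherwise
canonical). Cross-validation is ten-times-repeated 10-fold (fold assignments
redrawn per repeat; per-repeat MSE curves averaged **before** selecting
$\lambda_{\min}$) for the larger one-month models, and leave-one-out for the
small six-month models. LOOCV folds are deterministic, so repeating LOOCV
would reproduce the same curve; it is run once. Predictors are standardized
internally and coefficients reported on the original scale. Features with
nonzero $\beta$ at $\lambda_{\min}$ are reported as *important*, ordered by
$|\beta|$ — the models are used for feature identification, not prediction,
and no predictive accuracy is claimed. A constant response short-circuits to
an intercept-only result rather than an error, since degenerate strata occur
in small cohorts.

## The synthetic cohort generator

The generator (`simulate_cohort()`) emulates the statistical structure the
analysis assumes, with planted, recoverable effects. Per pair:

* The mother's prenatal abundances are log-normal draws around per-taxon
  baselines, conditional on independent per-taxon carriage indicators.
* Strain sharing is Bernoulli per taxon: transmission probability × maternal
  carriage at one month (default 0.29 for BLlongum, the detected
  vertical-transmission rate; 0 for BLinfantis and *B. breve*, which show no
  detectable sharing at one month), with persistence to six months.
* Infant abundances are generated on the log scale —
  $\exp(\log b_{t,\mathrm{tp}} + m \cdot A_{\mathrm{mother},t} +
  \varepsilon)$, with baseline $b$, maternal effect $m$ (default 0.15
  log-units per percentage point) and noise SD 0.5 — then shifted additively
  (percentage points) by the pair's feeding-type effect and by a +10 pp bonus
  for transmitted strains, truncated at zero and closed to 100% with an
  `other_bacteria` remainder. Additive percentage-point effects make planted
  group differences directly recoverable as differences of group means.
* A taxon is simply absent (abundance 0) when neither carried nor
  transmitted; carriage defaults approximate the prevalence structure of a
  one/six-month cohort (e.g. BLlongum 0.85 at 1m and 0.67 at 6m, BLinfantis
  0.08 at 1m and 0.71 at 6m).

Effect sizes for maternal influence, feeding and the sharing bonus are free
parameters of the generator, not estimates of any cohort — no published
effect sizes exist for them. The defaults were chosen once, at design time,
to produce effects a cohort of ~200 pairs can detect, and are documented in
`simulation_config()`.

**Genome repertoires.** `simulate_mag_repertoires()` draws copy numbers
around one of three archetype mean vectors (mixing proportions 14 : 25 : 24,
the relative sizes of the three observed utilization types), adds normal
noise, rounds to integers and clips at zero — copy numbers are integers.
The default archetypes are resolved at the GH-*variant* level (31 variants
of the 13 families) plus the 14 uptake systems, with the two BLlongum
lineages carrying partly disjoint variants of the shared HMO families:

* `BLinfantis-HMG` — broad fucosidase/sialidase/hexosaminidase repertoire
  plus the full transporter arsenal;
* `BLlongum-HMGcomplex` — core HMO repertoire plus the oligomannose
  N-glycan module (GH5_18, GH38, GH85, GH125, mnaABC/ngtABC uptake);
* `BLlongum-HMGsimple` — the core HMO repertoire only.

Variant-level resolution matters: at family level the BLinfantis split
dominates the standardized euclidean geometry and mean silhouette collapses
the two BLlongum lineages into one cluster, whereas the variant-level
archetypes give three comparably separated clusters that silhouette
recovers ($k = 3$, ARI ≥ 0.9 at noise SD 0.3, $n = 60$).

**Alignment fixtures.** `simulate_alignment_hits()` emits outfmt-6-style
hit rows realizing intended pass/fail statuses for each filter, and
block-structured identity matrices (symmetric, unit diagonal) for variant
clustering, so filter boundaries and clustering behavior are verifiable by
construction.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: phylogenetic correlation between taxa,
overdispersed or zero-inflated compositional noise beyond the log-normal ×
carriage mixture, temporal autocorrelation within infants beyond the planted
maternal/sharing effects, read-depth-dependent detection limits, and strain-
level haplotype structure. Recovery results on synthetic cohorts demonstrate
the estimators are correctly implemented and calibrated, not that real
cohorts carry effects of the planted size.

## Problem sizes and determinism

All simulation-backed checks run at desk scale, chosen to keep Monte-Carlo
error small relative to the assertions: cohort recovery at 200 pairs across
tens of seeds, repertoire recovery at 60 genomes, enrichment power at 3 × 20
genomes × 50 genes across 20 seeds, LASSO recovery at $n = 200$, $p = 9$
across 20 seeds. Every stochastic function takes an explicit seed
(`simulation_config(seed = )`, `fit_lasso_cv(seed = )`), restores the
caller's RNG state, and reproduces byte-identical outputs for identical
configurations; the pipeline records the resolved configuration, seed and
package version in `provenance.yaml`, which suffices to reproduce a run.

## Known limitations

* The variant-cluster cut rule guarantees every reported cluster meets the
  mean-identity threshold but, like any average-based rule, can admit
  heterogeneous clusters on adversarial identity structures; the brute-force
  oracle agreement is therefore asserted on well-separated instances.
* Mean silhouette tends to prefer coarse partitions when cluster separations
  are strongly unbalanced; `cluster_profiles(k = )` exists precisely for
  that case.
* Mean imputation underestimates predictor variance; imputed cells are
  flagged so users can inspect or refit.
* The collinearity auto-drop is order-dependent by design (deterministic,
  later column dropped); domain knowledge may prefer the other member of a
  pair, hence the override.
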