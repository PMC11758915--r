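# bifidodyn

Statistical pipeline for early-life gut colonization and succession of
*Bifidobacterium longum* subspecies.

In healthy breastfed infants, *B. longum* subsp. *longum* (BLlongum)
typically dominates the gut around one month of age and is replaced by
subsp. *infantis* (BLinfantis) by six months. Three classes of factors are
implicated in that replacement: **priority effects** (who colonizes first),
**nutrition** (breast milk vs. formula), and the genomic potential to use
**human milk glycans** (HMGs: human milk oligosaccharides and milk
N-glycans). `bifidodyn` is for microbiome researchers who have the standard
tabular intermediates of such a study — relative-abundance tables,
strain-sharing booleans, protein alignment hits, pairwise identity matrices,
gene count matrices — and want the downstream analysis as tested, reusable,
seeded code.

## What it computes

* **HMG-utilization profiling** — clusters glycoside hydrolase (GH)
  sequences into variants (Ward.D2 on percent dissimilarity; clusters must
  reach ≥ 60% mean within-cluster identity; singletons and < 5%-prevalence
  variants dropped), filters transporter hits (bitscore ≥ 50, e ≤ 0.001,
  identity ≥ 60%, best hit per query), builds per-genome copy-number
  profiles, clusters genomes into utilization types (scaled counts,
  euclidean, Ward.D2, silhouette-selected k), and tests per-gene enrichment
  (Kruskal–Wallis on log₂ counts, unpaired Wilcoxon post-hocs, BH FDR,
  verdicts at q < 0.05 and |log₂FC| ≥ 2 for cluster vs. rest).
* **Subspecies typing** — marker-gene hits filtered at ≥ 90% identity /
  ≥ 50% coverage, copy-number clustering (euclidean, Ward.D2, k = 2), labels
  by marker-total dominance.
* **Dynamics** — presence calls (> 0.01% relative abundance), prevalence and
  abundance-when-present summaries, arrival-order proxies (maternal
  dominance above a 0.1% floor; strain sharing; either), and the
  priority-effect strength

  *P′* = ln( B̄_late / B̄_early ),

  negative when early arrival is associated with higher abundance, with
  unpaired Wilcoxon group tests and BH correction.
* **Feature selection** — design matrices from cohort features (full one-hot
  dummy coding, mean imputation, ±0.70 collinearity screen) and
  cross-validated LASSO (`glmnet`; 10×10-fold or LOOCV; coefficients at
  λ_min; nonzero-β features reported as important).
* **Synthetic cohorts** — a seeded mother–infant cohort and genome-repertoire
  generator with planted transmission, feeding, maternal and archetype
  effects, so every stage above is testable end to end without sequencing
  data.

## Worked example

```r
library(bifidodyn)

cfg <- simulation_config(n_pairs = 24, seed = 1)   # study-scale synthetic cohort
sim <- simulate_cohort(cfg)

summarize_prevalence_abundance(sim$cohort, "BLlongum",
                               role = "infant", timepoint = "1m")
#>      taxon  n prevalence mean_when_present sd_when_present
#> 1 BLlongum 24   79.16667          43.64526        23.65662

priority_effect_analysis(sim$cohort, sim$metadata, "BLlongum")
#>      taxon timepoint          criterion mean_early mean_late n_early n_late
#> 1 BLlongum        1m maternal_dominance       45.6     19.09      14     10
#> 2 BLlongum        1m     strain_sharing       67.3     23.63       6     18
#> 3 BLlongum        1m             either       46.4     14.84      15      9
#> 4 BLlongum        6m maternal_dominance       12.8     10.08      14     10
#> 5 BLlongum        6m     strain_sharing       21.1      9.79       4     20
#> 6 BLlongum        6m             either       13.4      8.78      15      9
#>   pprime       p       q
#> 1 -0.871 0.02018 0.04036
#> 2 -1.047 0.00147 0.00882
#> 3 -1.139 0.00841 0.02523
#> 4 -0.239 0.74284 0.74284
#> 5 -0.766 0.04419 0.06628
#> 6 -0.422 0.39506 0.47407
```

Every `pprime` is negative: infants whose arrival proxies are true (the
taxon dominated the mother's gut, or a maternal strain was transmitted)
reach higher BLlongum abundance — the planted priority effect. At one month
the proxies are individually significant after FDR correction; `mean_early`
vs. `mean_late` are the group means the statistic is built from.

Profile clustering on synthetic genome repertoires recovers the three
planted HMG-utilization types:

```r
m  <- simulate_mag_repertoires(simulation_config(seed = 1, noise_sd = 0.3),
                               n_mags = 60)
pr <- cluster_profiles(m$counts)
pr$k
#> [1] 3
table(pr$assignment, m$labels)
#>     BLinfantis-HMG BLlongum-HMGcomplex BLlongum-HMGsimple
#>   1              0                  22                  0
#>   2              0                   0                 26
#>   3             12                   0                  0
```

The hand-computable case of the priority-effect statistic:

```r
priority_effect_strength(c(30, 10, 10, 10), c(TRUE, TRUE, FALSE, FALSE),
                         taxon = "BLlongum")
#> Priority effect [BLlongum, criterion = either]
#>   P' = -0.6931 (mean early 20.000, n = 2; mean late 10.000, n = 2)
```

A full pipeline run (`run_pipeline(list(seed = 1, out_dir = "run"))`) writes
every stage's outputs as TSV plus a `provenance.yaml` that reproduces the
run bit for bit; `inst/cli/bifido-succession.R` wraps the same stages as a
command-line tool.

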