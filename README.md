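# methaplo

Methylation haplotype blocks, MHL scoring and epi-cluster discovery from
read-level bisulfite methylation haplotypes.

## What it is for

Whole-genome bisulfite sequencing reads carry the *joint* methylation
pattern of consecutive CpGs on single molecules. `methaplo` is for
epigenomics analysts who want to exploit that read-level structure for
tumour subtype discovery:

1. **Block detection** — partition CpG sites into methylation haplotype
   blocks (MHBs): maximal runs of consecutive sites whose adjacent pairs
   are tightly coupled, measured by two-locus linkage
   *r*² = *D*² / (*p*₁•(1−*p*₁•) *p*•₁(1−*p*•₁)) with
   *D* = *p*₁₁ − *p*₁• *p*•₁, computed from pooled reads covering both
   sites.
2. **MHL scoring** — the methylation haplotype load of a block in a
   sample is a length-weighted mean of the fractions *m*ₗ of fully
   methylated ℓ-CpG windows within reads:
   MHL = Σₗ ℓ·*m*ₗ / Σₗ ℓ.
   MHL ≤ mean methylation, with equality structure that rewards long
   concordant stretches.
3. **Epi-clustering** — rank-2 non-negative matrix factorization
   (multiplicative updates, Frobenius loss, 100 seeded restarts) of the
   most variable blocks; the hypermethylated cluster is labelled
   **Methy-High**, the other **Methy-Low**.
4. **Cross-platform projection** — probes overlapping the selected blocks
   summarize array beta values into block regions, so external array
   cohorts can be classified with the same recipe.
5. **Differential blocks & enrichment** — Wilcoxon + Benjamini–Hochberg +
   effect-size calls between groups; log2(obs/exp) annotation enrichment
   against the tested-block background.
6. **Survival** — Kaplan–Meier, log-rank, and Cox proportional hazards
   (via the `survival` package) linking epi-clusters to outcome.

A first-class synthetic-cohort generator (`generate_cohort()`) emulates
two latent subtypes, signature blocks, tunable read concordance, Poisson
coverage, survival with a subtype hazard ratio, and a paired array arm —
so the entire pipeline runs and is tested without any data download.

## Worked example

```r
library(methaplo)

cfg    <- simulation_config()              # 50 samples, 500 blocks, 60 signature
cohort <- generate_cohort(cfg, seed = 42)  # blocks shifted by delta = 0.3

mhl <- build_mhl_matrix(cohort$haplotypes, cohort$blocks)
dim(mhl)
#> [1] 500  50

clusters <- classify_epiclusters(mhl, seed = 42)
table(clusters$label)
#> Methy-High  Methy-Low
#>         25         25
cluster_proportions(table(clusters$label))
#> Methy-High  Methy-Low
#>         50         50
```

The two recovered epi-clusters coincide with the generator's truth (25
hypermethylated, 25 baseline samples; the percentages are each cluster's
share of the cohort). Survival separates accordingly — the Methy-High
cluster was simulated with hazard ratio 3:

```r
surv <- subtype_survival(cohort$clinical, clusters, endpoint = "os",
                         covariates = "age")
surv$logrank$p_value
#> [1] 0.0004085753
surv$cox[surv$cox$term == "subtype_high", c("term", "hr", "ci_lo", "ci_hi", "p")]
#>           term       hr    ci_lo    ci_hi            p
#> 1 subtype_high 3.710149 1.719797 8.003969 0.0008313608
```

The Cox hazard-ratio estimate (3.71, 95% CI 1.72–8.00) brackets the
simulated value of 3. Differential calling between the two clusters
recovers exactly the planted signature blocks:

```r
hi <- clusters$sample[clusters$label == "Methy-High"]
lo <- clusters$sample[clusters$label == "Methy-Low"]
table(differential_blocks(mhl, hi, lo)$call)
#> hyper  none
#>    60   440
```

See `vignettes/methaplo-methods.Rmd` for the model, parameter meanings,
and the generator's assumptions.

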