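---
title: "Methylation haplotype blocks, MHL scoring and epi-cluster discovery"
author: "methaplo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation haplotype blocks, MHL scoring and epi-cluster discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaplo)
```

# The problem

Whole-genome bisulfite sequencing (WGBS) reports the methylation state of
individual CpG sites on individual reads. Because each read is a physical
molecule, the *joint* pattern of consecutive CpGs on a read — the
methylation haplotype — carries information that per-site averages discard:
tightly co-regulated CpG runs tend to be methylated or unmethylated as a
unit, and the degree of such concordance differs between cell populations
and tumour subtypes. `methaplo` implements a complete block-level analysis
built on that observation:

1. partition the genome into **methylation haplotype blocks (MHBs)** —
   maximal runs of tightly coupled CpG sites;
2. score each block in each sample with the **methylation haplotype load
   (MHL)**;
3. discover two **epi-clusters** (Methy-High vs Methy-Low) by rank-2
   non-negative matrix factorization (NMF) of the most variable blocks;
4. project the block classifier onto **array beta values** to classify
   external cohorts that lack sequencing data;
5. call **differential blocks** between groups and measure their
   **annotation enrichment**;
6. associate epi-clusters with **survival** (Kaplan–Meier, log-rank, Cox).

A synthetic-cohort generator reproduces the statistical structure these
steps assume, so the full pipeline is testable without any sequencing
download.

# Block detection: methylation linkage of adjacent CpG pairs

For every adjacent pair of CpG sites we pool reads across all samples and
tabulate the four joint haplotypes (`11`, `10`, `01`, `00`). Coupling is the
standard two-locus linkage measure
$$ r^2 = \frac{D^2}{p_{1\bullet}(1-p_{1\bullet})\,p_{\bullet 1}(1-p_{\bullet 1})},
\qquad D = p_{11} - p_{1\bullet}p_{\bullet 1}, $$
computed only from reads covering both sites. An MHB is a maximal run of
consecutive sites in which every adjacent pair has a *defined* $r^2 \ge$
`r2_min`.

Tunable parameters, with defaults chosen to follow the published convention
of the block-detection method this implements:

| parameter | default | meaning |
|---|---|---|
| `r2_min` | 0.5 | minimum adjacent-pair coupling inside a block |
| `min_cpgs` | 3 | minimum member CpGs per block |
| `min_pair_reads` | 10 | reads covering a pair for a defined $r^2$ |

Two conventions matter and are deliberate:

* **Monomorphic pairs break runs.** If either site's marginal is 0 or 1
  there is no linkage evidence; treating such pairs as $r^2 = 1$ would
  glue unrelated runs together. We mark them undefined, which terminates
  the run — the conservative choice.
* **Adjacent pairs only.** Runs are fully determined by adjacent-pair
  coupling; all-pairs or sliding-window definitions are out of scope.

`partition_blocks()` is checked against an exhaustive enumerator of all
maximal qualifying runs, and is monotone: raising `r2_min` can only shrink
the block-covered CpG count.

# MHL: the block score

For one block in one sample, consider every contiguous window of $\ell$
member CpGs inside a single read ($\ell = 1,\dots,L$, with $L$ the longest
within-block stretch observed). Let $m_\ell$ be the fraction of those
windows that are fully methylated. Then
$$ \mathrm{MHL} = \frac{\sum_{\ell=1}^{L} \ell \, m_\ell}{\sum_{\ell=1}^{L} \ell}. $$

Linear weights $w_\ell = \ell$ follow the metric's originating publication;
they make long fully methylated stretches count more than the same calls
scattered across molecules. Two properties anchor intuition and the test
suite:

* $m_1$ is the plain mean methylation, and $\mathrm{MHL} \le m_1$ always;
* if every read spans the block and is all-`1` or all-`0` (fully
  concordant reads), MHL equals the fraction of methylated reads exactly.

Windows are formed **within reads only** and a read contributes only the
windows it fully contains — no state is ever imputed. An entry is missing
(`NA`) when fewer than `min_support = 5` single-CpG observations cover the
block; the threshold controls variance at low coverage, as no value is
stated by convention. The implementation aggregates run-length-encoded
window counts over unique patterns; a brute-force enumerator of every
window is kept in the tests as the independent reference for small blocks.

Missingness before factorization: `filter_missing_blocks()` supports both
readings of "blocks with NA values across all samples" — `any` (drop a
block missing in at least one sample) and `all` (drop only blocks missing
everywhere). The NMF input must be complete, so the pipeline default is
`any`; neither policy is claimed to be the original study's.

# Epi-cluster discovery by NMF

The `k = 20000` blocks with the largest across-sample standard deviation
enter a rank-2 NMF under the Frobenius objective, fitted by Lee–Seung
multiplicative updates. Numerical choices:

* 100 random restarts (`runs`), keeping the run with minimum reconstruction
  error — a best-of-runs consensus; full consensus clustering across runs
  is intentionally out of scope.
* 500 maximum iterations per run; convergence when the relative error
  change falls below $10^{-6}$; a machine-epsilon guard in each
  multiplicative denominator prevents division by zero.
* One master seed spawns a per-run seed stream, so `runs = r` results are a
  prefix of `runs = r' > r` results and every fit is bit-reproducible.

**Signature extraction.** Each basis row is normalized to sum 1; a block is
a component's signature when its normalized weight on that component is at
least 0.75 *and* its unnormalized row maximum is at least the median row
maximum. The magnitude gate removes rows the factorization barely uses; the
threshold form keeps the rule deterministic and exposed. On data where only
one subtype is hypermethylated, the opposite component can legitimately end
up with an empty signature set; labelling then falls back (with a warning)
to the mean over all selected blocks.

**Assignment and labelling.** A sample joins the component with its larger
coefficient (ties to the lower index, for determinism). The cluster with
the higher mean MHL over the union of signature blocks is **Methy-High**,
the other **Methy-Low** — hypermethylation defines the label, not the
component index. Assignments are invariant to positive rescaling of the
input matrix.

# Cross-platform projection

Array cohorts carry no haplotype information, so blocks are scored on
arrays by the plain mean beta of the probes whose positions fall inside the
block interval (half-open containment; a probe at the block end is
outside). The mean is missing-aware, and a region value is missing only
when every probe is missing. External cohorts are then **re-factorized
independently** with the same NMF recipe and labelled by the same
hypermethylation rule — mirroring how array validation cohorts are
classified in practice, rather than projecting onto the discovery basis.
Whether probes should be intersected with block intervals or with member
CpG positions exactly is genuinely open; interval containment was chosen as
the standard semantics of interval overlap.

# Differential blocks and annotation enrichment

Between two groups, each block with at least 2 non-missing values per group
gets a two-sided Wilcoxon rank-sum test; Benjamini–Hochberg adjustment runs
across tested blocks; a call requires both adjusted $p \le$ `alpha` (0.05)
and an absolute group-mean difference of at least `delta_min` (0.2). These
are conventional differentially-methylated-region thresholds, fully
exposed, declared rather than inferred — no specific criteria are fixed by
convention for block-level calls.

Enrichment of a differential set against an annotation class is
$$ \log_2 \frac{\text{obs}}{\text{exp}}, $$
where *obs* is the fraction of differential blocks overlapping the class
(any overlap of at least 1 bp, half-open) and *exp* the same fraction among
**all tested blocks**. Using tested blocks — not the genome — as background
controls for block ascertainment. `exp = 0` yields an undefined, flagged
ratio; an empty differential set is an error.

# Survival association

Kaplan–Meier estimation, the log-rank test, and Cox proportional-hazards
fits are delegated to the `survival` package: events precede censorings at
tied times in the product-limit estimator, Cox uses the Efron tie
approximation by default (`ties = "breslow"` is exposed; duplication
invariance of the partial-likelihood maximizer is exact under Breslow),
and Wald 95% intervals are reported. Follow-up truncation
(`truncate_followup()`) implements administrative censoring at a horizon,
applied when cohorts have very different follow-up lengths. The
`subtype_survival()` recipe screens covariates univariately (inclusion at
$p < 0.05$ by default) before the multivariate fit — a workflow
convention, not hard-coded behaviour.

# The synthetic cohort generator

`generate_cohort()` draws, from a single `simulation_config()` and seed:

* **Geometry** — 500 disjoint blocks of 4–8 CpGs (~15–45 bp spacing, 1 kb
  gaps) on one synthetic chromosome.
* **Truth** — two subtypes in exact 50/50 proportions (deterministic
  allocation); 60 signature blocks whose High-subtype target level is the
  baseline plus `delta = 0.3`. Baselines are Beta(2,2); signature-block
  baselines are rescaled into $[0.05, 0.65]$ so the shift never clips at 1.
* **Reads** — per sample and block, Poisson(30) reads; each read draws a
  latent state from the block's target level and each CpG copies it with
  probability `rho = 0.9`, otherwise re-draws independently. The single
  mixing parameter `rho` spans the two regimes MHL distinguishes:
  `rho = 1` gives fully concordant haplotypes (MHL = methylated-read
  fraction), `rho = 0` independent CpGs (MHL well below the mean). An
  explicit per-CpG correlation matrix would add knobs without adding a
  testable regime.
* **Survival** — exponential event times at 0.02/month baseline hazard
  (median ~35 months, a realistic urothelial-carcinoma scale), hazard ratio
  3 for the High subtype; exponential censoring at rate
  `hazard * 0.3/0.7` scaled to each subject's hazard, which gives exactly
  30% censoring probability per subject and keeps censoring conditionally
  independent given subtype.
* **Array arm** — `generate_array_cohort()` places 10 probes per block at
  member CpG positions (sampled with replacement when a block has fewer
  CpGs than probes — distinct probes may share a coordinate, as dense
  array designs do) and sets beta to the sample's target level plus
  truncated Gaussian noise (SD 0.05), clipped to $[0,1]$.

`generate_null_cohort()` removes the signature blocks and sets the hazard
ratio to 1, for type-I-error and false-labelling checks.

**What the generator does *not* emulate:** bisulfite conversion error,
mapping artefacts, copy-number-driven coverage waves, correlated
missingness, batch effects between platforms, or non-proportional hazards.
Passing tests therefore demonstrate correctness of the pipeline's
computations and its behaviour under the assumed generative structure —
not robustness to the technical noise of real WGBS or array data.

# Problem sizes used in the checks

The package's own verification uses: 1,000 random block/read instances
(≤ 6 CpGs, ≤ 20 reads) for exact MHL-oracle agreement; 500 random coupling
tracks (≤ 50 sites) for partition-oracle agreement; 20 replicate cohorts at
the default configuration for subtype recovery (adjusted Rand index),
array label transfer and planted 2× enrichment recovery; 2,000 null
replicates for log-rank type-I error; and 200 replicates at hazard ratio 3
for Cox interval coverage. These sizes give stable Monte-Carlo estimates
while keeping the default suite fast on a single core.

# Known limitations

* Rank is fixed at 2; rank selection (e.g. cophenetic correlation) is out
  of scope, as are >2-cluster solutions.
* The signature-extraction rule is this package's deterministic stand-in
  for a library default whose exact behaviour is not publicly specified;
  signature *counts* therefore should not be compared across
  implementations.
* Block detection uses adjacent-pair coupling only and will split blocks at
  single low-coverage pairs; with sparse data, consider lowering
  `min_pair_reads` deliberately rather than imputing.
* MHL entries at low coverage are suppressed rather than shrunk; no
  empirical-Bayes smoothing is attempted.
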