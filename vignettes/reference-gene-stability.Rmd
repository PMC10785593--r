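---
title: "Selecting stable reference genes for miRNA qPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes for miRNA qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgstab)
```

## The problem

Relative qPCR quantification divides every target measurement by the
signal of one or more reference genes (RGs), so the whole analysis is
only as good as the references: an RG whose own expression moves with
the condition under study silently biases every normalized value.
`rgstab` implements the complete selection workflow for miRNA panels in
designs with grouped samples — wound-healing time courses (posttraumatic
intervals, PTI), post-mortem intervals (PMI), paired human biopsies —
where both systematic regulation and RNA degradation threaten RG
stability.

The workflow has four stages:

1. **Preselection** from small-RNA sequencing: abundance gating plus
   coefficient-of-variation (CV) ranking on two bases (raw counts and
   TPM).
2. **Stability scoring** of the candidate panel on qPCR Ct tables with
   four independent algorithms: geNorm, NormFinder, BestKeeper and the
   comparative Delta Ct method.
3. **Consensus** by the geometric mean of the four per-algorithm ranks,
   and the pairwise-variation rule for how many RGs to use.
4. **Combination assessment**: multi-gene normalizers built as
   per-sample geometric means of Ct values, ranked against each other
   with the same four algorithms.

## Data model

A `ct_table` is a complete genes x samples matrix of Ct values (PCR
cycles), a group label per sample and a per-gene amplification
efficiency $E$ (default 2, perfect doubling; configurable per gene from
1 to 2 exclusive/inclusive). Ct is inversely proportional to
log2 template abundance, which the algorithms exploit: Ct *is* the log
scale, so no further transformation is applied where a log scale is
needed.

Missing Ct values (failed wells, no amplification) are a hard error,
not an imputation target: all four algorithms assume complete matrices,
and pairwise deletion would silently change what geNorm and NormFinder
estimate. `validate_complete(x, drop_incomplete_genes = TRUE)` is the
explicit escape hatch — it removes offending genes, never single cells.
A plausibility band (default $0 < Ct < 45$) catches sentinel values
such as 999. Technical replicates are collapsed to their arithmetic
mean before analysis (`average_technical_replicates()`).

## Preselection

TPM normalization is `count / library total * 1e6`; the CV is
$\mathrm{CV} = 100 \cdot s/\bar{x}$ with the sample ($n-1$) SD.
A gene passes the abundance gate when its *mean* across all samples
strictly exceeds the threshold (defaults 8000 counts, 5000 TPM). Among
passing genes, the `k` lowest-CV genes on the count basis and the `k`
lowest-CV genes on the TPM basis are selected; the union is the
candidate set, with provenance recorded per gene.

Two choices here were genuinely open and are exposed as options:

* **CV scope** (`cv_scope`): the default pools all samples into one CV;
  `group_means` computes the CV of per-group means instead. Pooled CV
  is the stricter and simpler reading and is less noisy than group
  means of 3–5 replicates.
* **Abundance statistic**: the mean across samples (strict `>`). With
  heavy-tailed counts the mean is generous to spiky genes — the
  documented `[16001, 1]` case passes an 8000 threshold — but "higher
  expression abundance" is a statement about average level, and the CV
  gate penalizes spikiness anyway.

Ties at the k-th CV rank are broken by higher mean abundance, then
lexicographic gene id, so output is deterministic.

## The four stability algorithms

All four return a score per gene where **lower = more stable**, plus
within-algorithm average ranks.

### geNorm

Relative quantities $Q_{ij} = E_i^{\min_j Ct_{ij} - Ct_{ij}}$ map each
gene to $(0, 1]$ with its best-expressed sample at 1. For genes $j,k$
the pairwise variation $V_{jk}$ is the SD over samples of
$\log_2(Q_j/Q_k)$, and the stability measure $M_j$ is the mean of
$V_{jk}$ over all $k \ne j$. The stepwise ranking repeatedly removes
the highest-M gene and recomputes until two genes remain; that final
pair is reported tied (rank 1.5 each) because the procedure cannot
distinguish them. Each gene's score is its M at the step of its
exclusion. Equal maximal M (degenerate panels) excludes the
lexicographically last id — deterministic, documented.

With $E = 2$ for both genes, $V_{jk}$ equals the SD of the per-sample
Ct difference exactly; this "bridge identity" to the Delta Ct method is
asserted to 1e-9 in the tests.

The pairwise-variation series decides how many RGs to use: with
$NF_n$ the per-sample geometric mean of $Q$ over the $n$ most stable
genes, $V_{n,n+1}$ is the SD of $\log_2(NF_n/NF_{n+1})$, and the
recommended count is the smallest $n$ with $V_{n,n+1}$ below 0.15
(configurable), falling back to all $N$ genes with a warning flag when
no $V$ passes.

### NormFinder

The model-based estimator of Andersen and colleagues, reconstructed
from the cited publication and applied to Ct directly. Per sample the
across-gene mean is subtracted (removing sample scaling); gene-specific
within-group variances come from two-way residuals with the
small-sample bias correction
$\hat\sigma^2_{ig} = \tfrac{I}{I-2}\big(u_{ig} - \sum_k u_{kg}/(I(I-1))\big)$,
$u_{ig} = \mathrm{RSS}_{ig}/(n_g-1)$, floored at zero; intergroup
deviations $d_{ig}$ are shrunken toward zero by
$\gamma^2/(\gamma^2 + \hat\sigma^2_{ig}/n_g)$ where $\gamma^2$ is the
method-of-moments intergroup variance; the stability value averages
$|\tilde d_{ig}| + \sqrt{(\hat\sigma^2_{ig}/n_g)\,\gamma^2/(\gamma^2+\hat\sigma^2_{ig}/n_g)}$
over groups. All constants sit in one place
(`normfinder_stability()`); the ungrouped variant reduces to
$\sqrt{\hat\sigma^2_i}$ of the sample-centered values.

Grouping defaults to the metadata labels (the description of the method
stresses intra- and inter-group variation); `use_groups = FALSE` gives
the single-group variant. Groups of one sample are rejected.

Two behaviours of this estimator are worth knowing. First, because
deviations are measured against the *panel average*, a gene whose
regulation happens to track the average regulation of the panel scores
deceptively well — a reason to keep obviously regulated genes out of
the candidate set before scoring. Second, the stability value is not
jointly monotone in (group shift, noise): at a large shift, extra noise
shrinks the deviation term faster than the intragroup term grows. The
ranking behaviour that matters — a clearly unstable gene lands last,
and with growing group sizes the generative order is recovered — holds
and is what the tests assert.

### BestKeeper

Descriptive and deliberately simple: each gene's dispersion of raw Ct
across samples — the sample SD by default, or the mean absolute
deviation about the mean (`dispersion = "mad"`), which is what the
original BestKeeper spreadsheet reports. Details carry per-gene
min/max/arithmetic/geometric means and, with at least 3 samples, each
gene's Pearson correlation (with two-sided p) against the BestKeeper
index, the per-sample geometric mean of all candidate Ct values.
Ranking is by dispersion only; the correlations are reported as
details. Note BestKeeper is the one method that does *not* discount
shared sample-scaling effects: a gene can have the lowest raw SD yet
poor co-regulation with the panel.

### Comparative Delta Ct

For every gene pair, the SD across samples of the per-sample Ct
difference; a gene's score is the mean of these SDs over all pairs
containing it. Equivalent to geNorm's M at $E=2$ (no iterative
exclusion), and a useful cross-check precisely because it is so plain.

### Conventions shared by all four

Every SD uses the $n-1$ denominator unless `sd_denominator = "n"` is
selected — one global setting. Scores are invariant to adding a
constant to a gene's row (geNorm, NormFinder, Delta Ct, BestKeeper
dispersion) and to per-sample constants (all but BestKeeper); sample
and gene permutations never change scores or ranks. These invariances
are asserted as properties in the test suite.

## Consensus and combinations

Per-algorithm ranks (average ranks on ties; geNorm's final pair enters
as 1.5 each rather than an arbitrary 1/2 split, to avoid injecting a
fake distinction) are aggregated as
$\bar r_g = (r_1 r_2 r_3 r_4)^{1/4}$; the final ranking is by ascending
geometric mean with ties broken by best single-algorithm rank, then
gene id. The geometric mean never exceeds the arithmetic mean (AM–GM)
and always lies within the per-gene rank range — both asserted
numerically.

`evaluate_combinations()` builds every nonempty subset (default up to 3
members) of the selected RGs as a pseudo-gene — per-sample geometric
mean of member Ct values, the literal multi-RG normalizer rule; an
arithmetic option exists — and runs the full four-algorithm consensus
over the pseudo-genes as if they were genes. Overlapping membership
makes combinations correlated by construction; no correction is
attempted (none is standard), and the comparison is only ever between
the combinations themselves. With a trio of references carrying
independent noise, the three-gene combination is the most stable in the
Delta Ct view in the overwhelming majority of simulated studies (noise
averaging); the tests quantify this.

## The synthetic-data generator

`sim_config()` describes a grouped design; `simulate_ct_table()` draws

$$Ct_{ij} = \mu_i + s_j + g_{i,\mathrm{grp}(j)} +
  \beta_i\,(t_{\mathrm{grp}(j)} - o_i)_+ + \varepsilon_{ij}$$

with shared per-sample offsets $s_j \sim N(0, \sigma_s^2)$, per-gene
group effects $g$, linear degradation at $\beta_i$ cycles/day past an
onset day $o_i$, and Gaussian noise on the Ct (log) scale — the
standard qPCR error model; heavier tails are deliberately out of scope.
This additive structure is exactly what the four algorithms decompose,
which is what makes the generator a fair test bed. One integer seed
drives everything; the count generator uses `seed + 1` as its derived
substream, and identical config + seed is bit-identical.

`simulate_count_matrix()` converts the expected Ct surface to relative
abundances ($2^{-Ct}$), scales to per-sample library sizes and draws
negative-binomial counts (`dispersion = 0` gives Poisson) for testing
the preselection stage.

### The presets and what they (don't) show

Three presets encode the emulated study designs, with sizes chosen as
typical of such animal studies:

* `sim_config_pti()`: 15 genes (nine stable miRNA candidates, six
  commonly used RGs) over 11 groups (uninjured control + ten
  post-injury time points) x 5 replicates. Baseline Ct values follow
  the published abundance spectrum of such panels (18S near 8.6 cycles,
  rare miRNAs near 25.8). The planted most-stable trio
  (miR-26a-5p/miR-30d-5p/miR-152-3p) has residual noise 0.25 cycles;
  the other miRNA candidates 0.48–0.65; the comRGs carry *individual*
  phase-specific healing trends of mixed sign (amplitudes 0.6–1.2
  cycles) plus larger noise. Giving each comRG its own temporal profile
  matters: if all trends share one shape, the panel-average trend is
  itself that shape, and NormFinder — which scores deviation from the
  panel average — would spuriously reward whichever gene's trend sits
  closest to the average.
* `sim_config_pmi()`: 11 genes over six post-mortem intervals (0–7.5
  days) x 5. Degradation slopes are class-bimodal: 0.08 cycles/day for
  every miRNA (they differ by onset — day 1.5 vs day 3 — not rate),
  0.35–0.6 for the long RNAs. With a shared deterministic drift this
  uniformity is the realistic regime: miRNA post-mortem robustness is a
  class property, and graded miRNA slopes would again let the
  panel-average artifact pick the fastest-degrading miRNA.
* `sim_config_ngs()`: 150 genes over 5 groups x 3 sequencing
  libraries, with a planted block of abundant stable genes among
  trend-carrying competitors, for the preselection stage.

What passing tests on these presets shows: the pipeline recovers
planted structure through all four algorithms, the consensus and the
combination assessment, at realistic effect and noise scales. What it
does not show: performance under features the generator omits —
non-Gaussian wells, amplification failures, efficiency
mis-specification, partially shared (RNA-class-specific) sample
effects, nonlinear degradation. Real-data behaviour on those axes is
not certified by this suite.

## Numerical choices and edge cases

* Tie-breaks are deterministic everywhere: geNorm exclusion ties drop
  the lexicographically last id; consensus ties use best single rank
  then id; CV ties use higher abundance then id.
* Degenerate inputs: constant genes give SD 0 (BestKeeper rank 1,
  undefined index correlation — flagged `NA`, not an error); zero-mean
  genes have undefined CV and are excluded from CV ranking with a
  warning; zero-variance panels rank by the documented tie-breaks.
* The V-threshold 0.15 and the Ct band (0, 45) are configurable
  defaults, not hard-coded.
* Floating-point: oracle equivalence and the bridge identity are held
  to 1e-9; the geNorm tie tolerance is 1e-12.
* Problem sizes in the test suite (6–15 genes, 15–55 samples, 200–500
  simulation replicates) were chosen as the smallest sizes at which the
  planted-structure recovery rates stabilize, keeping the full suite
  under a minute.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config_pti(seed = 7)
ct  <- simulate_ct_table(cfg)
fit <- rg_stability(ct)
fit
summary(fit)
plot(fit)

combos <- evaluate_combinations(
  ct, c("miR-26a-5p", "miR-30d-5p", "miR-152-3p"))
combos
```

The same analysis as a reproducible pipeline with files on disk:

```{r pipeline, eval = FALSE}
run_pipeline(list(seed = 7, simulate = list(preset = "pti")),
             out_dir = "pti_run")
```

which writes `ct.tsv`, `samples.tsv`, `counts.tsv`, `candidates.tsv`,
`stability.tsv`, `genorm_trace.tsv`, `v_series.tsv`,
`combinations.tsv` and a `report.json` whose input/output digests,
config echo and seed fully determine a re-run.

## Known limitations

* NormFinder's panel-average reference point (discussed above) is
  inherent to the method, not to this implementation.
* The combination assessment inherits geNorm's tied top pair, so a
  two-member combination occasionally shares rank 1 with the triple in
  individual runs; conclusions should rest on repeated designs, not a
  single table.
* Efficiency correction is applied in the geNorm transform only; Ct
  values themselves are never efficiency-rescaled for BestKeeper,
  NormFinder or Delta Ct, matching common usage of those tools on raw
  Ct.
* No support for partially missing panels (by design — see the data
  model).
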