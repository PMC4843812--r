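---
title: "Reference gene stability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference gene stability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative real-time PCR measures a target transcript relative to one or
more reference ("housekeeping") genes, on the assumption that the references
are stably expressed across the tissues and treatments being compared. That
assumption fails often enough — classic references such as tubulins or
*GAPDH* drift under stress or across tissues — that candidate references must
be validated per species and per experimental condition. refstab implements
the standard validation toolkit: three stability algorithms computed from a
Ct table, a consensus of their rankings, an RNA-seq (FPKM) pre-screen, and a
fold-change validation of a target gene under alternative reference choices.

All algorithms work per *subset*: one experimental slice (a stress
time-course, a tissue panel, or all samples pooled) analysed independently.

## Relative quantification

For gene $i$ and sample $j$ within a subset, Ct values are converted to
relative quantities

$$q_{ij} = E_i^{-(Ct_{ij} - \min_{j'} Ct_{ij'})},$$

so each gene's best-expressed sample has $q = 1$ and $\log_{E}$ differences
in $q$ are Ct differences. The default base is $E = 2$ (perfect doubling per
cycle), which is the convention the downstream algorithms assume even when
measured efficiencies are slightly lower (typical assays run $E \approx
1.8$–$1.9$); per-gene efficiencies can be supplied via the `base` argument
of `delta_ct_transform()`. The per-gene minimum is taken *within* the
analysed subset, keeping subsets self-contained; geNorm and NormFinder
statistics are invariant to per-gene rescaling, so this choice affects only
the convenience scaling of $q$, never the rankings.

## geNorm

The pairwise variation of genes $j,k$ is the sample standard deviation
(always $n-1$ denominator in this package) of their log2 expression ratio
across samples,
$V_{jk} = \mathrm{sd}_{s}\!\left(\log_2 q_{js}/q_{ks}\right)$,
and a gene's expression stability is
$M_j = \frac{1}{k-1}\sum_{k \ne j} V_{jk}$. Lower $M$ = more stable; two
perfectly co-regulated genes have $V = 0$, which is also why geNorm rewards
co-regulated pairs — a known caveat. `genorm()` eliminates the highest-$M$
gene, recomputes $M$ on the survivors, and repeats until two genes remain.
Those two cannot be ranked against each other (their mutual $V$ is all that
is left), so both are reported at ordinal rank 1 and the next gene at rank 3.
Ties at the maximal $M$ are broken by removing the later-listed gene, making
the procedure deterministic in the input gene order.

The normalization factor $NF_n$ is the per-sample geometric mean of the top
$n$ genes' quantities, and the pairwise variation series
$V_{n/n+1} = \mathrm{sd}_s\!\left(\log_2 NF_n/NF_{n+1}\right)$ measures what
the $(n+1)$-th gene adds. The smallest $n$ with $V_{n/n+1}$ below the cutoff
(default 0.15, the conventional threshold) is the recommended number of
reference genes; when no $n$ qualifies the recommendation is reported as
"none" rather than forced. Genes with $M$ above 1.5 in the full set are
flagged as unstable; both thresholds are arguments.

## NormFinder

NormFinder scores each gene by a variance-component model on the log2 scale,
$y_{ij} = \alpha_i + \beta_j + \varepsilon_{ij}$, with gene level
$\alpha_i$, per-sample loading effect $\beta_j$ (template amount, RT
efficiency — shared by all genes of a sample) and gene-specific error with
variance $\sigma_i^2$. Centering each sample across genes,
$z_{ij} = y_{ij} - \bar y_{\cdot j}$, removes $\beta_j$ but mixes the gene
variances: writing $v_i$ for the sample variance over samples of the
centred residuals and $S = \sum_i \sigma_i^2$,

$$E(v_i) = \Bigl(1 - \tfrac{2}{k}\Bigr)\sigma_i^2 + \frac{S}{k^2},
\qquad
E\Bigl(\sum_i v_i\Bigr) = \frac{k-1}{k}\,S ,$$

because $z_{ij}$ contains $(1 - 1/k)\varepsilon_{ij} - \frac{1}{k}
\sum_{i' \neq i}\varepsilon_{i'j}$. Solving gives the bias-corrected
estimator used by `normfinder()`:

$$\hat\sigma_i^2 = \max\!\left(0,\;
\frac{k}{k-2}\Bigl(v_i - \frac{\sum_{i'} v_{i'}}{k(k-1)}\Bigr)\right),
\qquad SV_i = \hat\sigma_i \quad \text{(ungrouped)} .$$

The correction divides by $k - 2$, hence the $k \ge 3$ requirement; negative
estimates are clamped to zero before the square root. The package verifies
this estimator by simulation: under the generating model the mean of
$\hat\sigma^2$ over 1000 simulated tables stays within 10% of the true
$\sigma^2$, and the $SV$ ordering recovers a known noise-SD ladder.

With sample groups, the same estimate is formed within each group $g$ (size
$n_g$), along with group means $a_{ig}$ of $z$ and deviations
$d_{ig} = a_{ig} - \bar a_{i\cdot}$. The variance of true inter-group
effects is estimated as
$\hat\gamma^2 = \max\bigl(0, \sum_{ig} d_{ig}^2 / ((k-1)(G-1)) -
\overline{\hat\sigma^2_{ig}/n_g}\bigr)$, each deviation is shrunk by its
reliability, $\tilde d_{ig} = d_{ig}\,\hat\gamma^2 / (\hat\gamma^2 +
\hat\sigma^2_{ig}/n_g)$, and

$$SV_i = \frac{1}{G}\sum_g \left( |\tilde d_{ig}| +
\sqrt{\frac{\hat\sigma_{ig}^2}{n_g}\cdot
\frac{\hat\gamma^2}{\hat\gamma^2 + \hat\sigma_{ig}^2/n_g}} \right).$$

When $\hat\gamma^2 = 0$ (no detectable group structure) the shrinkage factor
is defined as 0. A single group label, or no labels, falls back to the
ungrouped analysis. Because typical stability studies analyse each
time-course subset separately without a natural grouping, ungrouped mode is
the default; grouping is opt-in through the `groups` argument.

## BestKeeper

BestKeeper works on raw Ct, not relative quantities. Its "SD" is the mean
absolute deviation about the arithmetic mean Ct (in cycles, $1/n$
denominator — the convention of the original spreadsheet tool, available
as `sd_method = "sample"` for sensitivity analysis), and CV is that SD as a
percent of the mean Ct. Genes with SD above 1 cycle are flagged unacceptable
but remain in the ranking, after all acceptable genes — real studies often
have subsets (pooled samples, tissue panels) where *every* candidate exceeds
the threshold and must still be ordered. The primary sort key is SD, then
CV, then input order; SD-first was chosen because the exclusion rule is
stated on SD, and `rank_by = "cv"` provides the alternative reading. The
BestKeeper index is the per-sample geometric mean Ct over retained genes;
per-gene Pearson correlations (with two-sided p) against the index are
reported when at least three samples and two retained genes exist. Note
that because BestKeeper measures raw Ct spread, a shared loading effect
inflates every gene's SD — the main mechanism by which BestKeeper rankings
diverge from geNorm/NormFinder rankings on the same data.

## Consensus ranking

`consensus_rank()` aggregates two or more rankings by the geometric mean of
each gene's ordinal ranks (competition ranking: a tied pair at the top is
1, 1, 3 — geNorm's final pair enters as two rank-1 genes). Genes are ordered
by ascending geometric mean. Ties are resolved minimax-style: the gene whose
worst ranks are smaller (per-algorithm ranks sorted in decreasing order,
compared lexicographically) wins, with input gene order as the final
fallback. This tie policy was chosen because it is the unique simple rule
consistent with published comprehensive rankings that we use as regression
fixtures; alternatives (best single rank first, or plain input order) fail
on real tied cases. The aggregation accepts any number of rankings ≥ 2, so
an RNA-seq CV ranking can be mixed in experimentally.

## RNA-seq screen and validation

`fpkm_stats()` computes per-unigene mean (MV), SD ($n-1$) and CV = SD/MV;
`screen_candidates()` filters by a minimum MV (default 1 FPKM — a
conventional, deliberately arbitrary floor, since "adequately expressed" is
study-specific), a maximum CV and an optional annotation whitelist, and
sorts by CV ascending. `ranking_correlation()` compares two rankings by
Pearson correlation of the rank vectors (Kendall's tau optional).

`normalized_expression()` divides the target's relative quantity by the
geometric mean of the reference quantities per sample, then averages
biological replicates per condition before forming fold changes against the
control condition — so the control is exactly 1 and shared loading effects
cancel, which is the entire premise of reference-gene normalization.
`reference_choice_distortion()` reports the per-condition ratio of two such
series, quantifying the bias introduced by an unstable reference.

## The synthetic generator

`simulate_ct()` draws
$Ct_{ij} = b_i + \ell_j + e_i(\text{cond}_j) + \varepsilon_{ij}$: per-gene
baselines $b_i$ (uniform on 13–25 cycles by default, matching the Ct span
typical of abundantly-to-moderately expressed candidates), a shared
per-sample loading effect $\ell_j \sim N(0, 0.5^2)$ cycles, optional
per-condition shifts $e_i$ for designated unstable genes, per-gene Gaussian
noise (default SD 0.2 cycles), and independent technical-replicate jitter
(SD 0.05 cycles). Additive Gaussian noise on the cycle scale is
multiplicative log-normal noise on abundance, the standard qPCR error
model. The default design (`simulate_study()`) mirrors a typical stress
study: seven treatment time courses (NaCl, PEG, cold, heat, ABA, MeJA, SNP;
0/1/6/24 h), a nine-tissue panel, three biological replicates, and the
pooled set — nine analysis subsets. The generator reports its ground truth:
each gene's true stability score
$\sqrt{\sigma_i^2 + \mathrm{var}(e_i)}$ and the implied true order.

`benchmark_config()` fixes the reference benchmark: 14 genes × 12 samples
with two designed-stable genes (noise SD 0.05), one treatment-responsive
gene (shifts 0/+1/+2/+2 cycles), one high-noise gene (SD 1.5) and 0.2-cycle
noise elsewhere. The test suite requires the designed-stable pair in the
consensus top 3 and the designed-unstable pair in the bottom 3 of every
algorithm in at least 95% of 100 seeds.

What the generator does *not* emulate: amplification-curve artefacts,
primer-dimer products, inter-plate calibration shifts, non-Gaussian
outliers, and co-regulated gene modules. Passing the recovery tests
therefore shows the algorithms are implemented and wired correctly — not
that they are robust to every pathology of real plates. `simulate_fpkm()`
draws log-normal FPKM moment-matched to a requested mean and CV
($\sigma_{\log}^2 = \log(1+cv^2)$), sufficient for exercising the CV
screen, but it ignores count noise at low expression.

## Numerical choices and degenerate inputs

* Sample SD uses the $n-1$ denominator everywhere except BestKeeper's MAD,
  which is $1/n$ by that tool's convention.
* Log base 2 throughout; SV and M values are in log2-cycle equivalents.
* Variance estimates clamp at 0 before square roots; $\hat\gamma^2 = 0$
  short-circuits shrinkage to avoid 0/0.
* Ct values must be finite, in (0, 45]; values above 40 are accepted with a
  near-floor note. Missing cells are an error unless explicitly allowed.
* All-identical genes are legal inputs: every $V$, $M$, $SV$ is 0, rankings
  fall back to documented tie-breaks, and the recommended reference count
  is 2.
* Correlations are skipped (NA) with fewer than 3 samples or zero variance.

## Problem sizes

The test suite runs on deliberately small designs: oracle equivalence on
200 random 5-gene × 8-sample tables, NormFinder recovery at 10 genes × 100
samples (50 seeds), unbiasedness over 1000 tables of 10 genes × 20 samples,
and the end-to-end benchmark at 14 genes × 12 samples over 100 seeds. These
sizes give stable pass/fail behaviour at interactive runtimes while staying
in the regime (tens of samples, ~14 candidates) the methods are designed
for.

## Known limitations

* geNorm's M rewards co-regulation; refstab reports near-zero pairwise V
  values but does not attempt to detect co-regulated modules.
* The NormFinder grouped-mode degrees-of-freedom constants follow the
  variance-component derivation above; other implementations differ in
  small-sample details, so grouped SV values are comparable within refstab,
  not across tools.
* BestKeeper statistics conflate loading variation with instability by
  construction; that is a property of the method, not a bug, and is
  demonstrated in the test suite.
* No confidence intervals on SV or M, and no NormFinder "best pair"
  combination value.
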