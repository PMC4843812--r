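# refstab

Validation of reference (housekeeping) genes for qRT-PCR normalization.

Quantifying a transcript by qRT-PCR requires dividing out sample-to-sample
differences in template amount and reverse-transcription efficiency, which
is done by normalizing against reference genes assumed to be stably
expressed. That assumption has to be checked per species and per condition:
classic references (*GAPDH*, tubulins, *ACT*) are often unstable under
stress or across tissues. refstab implements the standard validation
workflow for anyone choosing references for a new system:

* **2^−ΔCt relative quantification** — `delta_ct_transform()`, with
  optional per-gene efficiency correction;
* **geNorm** — `genorm()`: expression stability
  *M*<sub>j</sub> = mean<sub>k≠j</sub> sd(log₂ q<sub>j</sub>/q<sub>k</sub>),
  stepwise elimination, normalization factors, and the pairwise-variation
  series V<sub>n/n+1</sub> with the 0.15 cutoff for the optimal number of
  references;
* **NormFinder** — `normfinder()`: a variance-components model on log₂
  expression with bias-corrected per-gene variance
  σ̂²ᵢ = max(0, k/(k−2)·(vᵢ − Σv/(k(k−1)))) and, with sample groups, shrunk
  inter-group deviations combined into a stability value (SV);
* **BestKeeper** — `bestkeeper()`: descriptive Ct statistics (the
  BestKeeper "SD" is the mean absolute deviation in cycles), SD > 1
  exclusion, the geometric-mean index and per-gene correlations;
* **consensus** — `consensus_rank()`: the comprehensive ranking by the
  geometric mean of per-algorithm ordinal ranks (geNorm's unrankable final
  pair both at rank 1);
* **RNA-seq screening** — `fpkm_stats()` / `screen_candidates()`: mean,
  SD and CV of FPKM per unigene, CV-ascending candidate lists, and
  `ranking_correlation()` against qPCR rankings;
* **target validation** — `normalized_expression()` /
  `reference_choice_distortion()`: fold changes of a target gene under
  stable vs unstable reference choices;
* **synthetic data** — `simulate_ct()` / `simulate_study()` /
  `simulate_fpkm()`: generators with known ground truth (baselines,
  loading effects, destabilization shifts, noise SDs) backing every
  recovery test;
* **pipeline** — `run_pipeline()` / `render_report()`: one-call analysis
  of every subset with tidy CSV outputs and a run manifest.

## Worked example

Simulate the benchmark scenario — 14 genes over a 0/1/6/24 h time course
with 3 biological replicates, where gene01/gene02 are designed stable
(noise SD 0.05 cycles), gene13 responds to treatment (0/+1/+2/+2 cycles)
and gene14 is noisy (SD 1.5 cycles) — then run all three algorithms and
aggregate:

```r
library(refstab)
sim <- simulate_ct(benchmark_config(seed = 7))
q   <- delta_ct_transform(sim$table)
gn  <- genorm(q)
nf  <- normfinder(q)
bk  <- bestkeeper(sim$table)
consensus_rank(list(gn, nf, bk), genes = sim$table$genes)
```

```
geNorm stability analysis (14 genes)
  best pair (tied at rank 1): gene01 / gene02
  ranking: gene01 > gene02 > gene06 > gene03 > gene07 > gene11 > gene08 > gene12 > gene04 > gene09 > gene10 > gene05 > gene13 > gene14
  M > 1.5: gene14
  recommended n: 2
NormFinder stability analysis (ungrouped mode, 14 genes)
  most stable: gene02, gene01, gene10
  least stable: gene13, gene14
BestKeeper analysis (14 genes, SD = mean absolute deviation)
  most stable: gene04 (CV 2.90 +/- SD 0.41)
  excluded (SD > 1): gene14
Comprehensive (geometric-mean) ranking of 14 genes over 3 algorithms
  gene02 > gene01 > gene04 > gene10 > gene03 > gene06 > gene09 > gene07 > gene08 > gene11 > gene12 > gene05 > gene13 > gene14
```

The designed-stable pair tops geNorm, NormFinder and the consensus; the two
designed-unstable genes land at the bottom of every ranking, and geNorm's
V(2/3) < 0.15 says two references suffice. BestKeeper disagrees about the
top (it measures raw Ct spread, so the shared loading effect penalises all
genes about equally while its MAD statistic is noisier at n = 12) — exactly
the kind of disagreement the geometric-mean consensus is there to settle.
`sim$truth$true_order` confirms the recovery: the generator's true order
starts gene01, gene02 and ends gene13, gene14.

The same analysis over a full multi-subset study, written to tidy CSVs:

```r
man <- run_pipeline(list(seed = 1, output_dir = "out",
                         simulate = list(n_genes = 14)))
writeLines(render_report(man))
```

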