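# mixdecon

Bulk molecular profiles of tumors mix signals from many cell populations.
`mixdecon` is an R toolkit for developing and benchmarking **reference-free
cell-type deconvolution** methods on controlled data: it simulates paired
bulk DNA-methylation and transcriptome profiles with *known* cell-type
proportions, ships the standard reference-free pipelines built from ICA and
constrained NMF, and scores every method with a permutation-matched error
metric on a replicated, fully seed-reproducible benchmark.

## The model

A bulk profile is a linear mixture of cell-type-specific profiles:

```
D_MET = T_MET · A        D_RNA = T_RNA · A
```

`D` is the observed feature-by-sample matrix (beta-values in [0,1], or
non-negative log2 expression), `T` the reference-profile matrix (features ×
K cell types), and `A` the K × N proportion matrix — non-negative with
columns summing to 1, shared between the two omics of a sample. Methods
estimate `A` (and possibly `T`) from `D` alone and are scored by

```
MAE = Σₙ Σₖ |Âₖₙ − Aₖₙ| / (N·K)
```

minimized over the K! assignments of anonymous components to true cell
types (`matched_mae()`).

The simulator emulates a pancreatic tumor with five populations
(fibroblast, immune, normal epithelial, and basal-like / classic cancer
subtypes): hierarchical Dirichlet compositions (precision 10 for the global
composition, 1 for the cancer-subtype split), marker-structured reference
profiles, and additive Gaussian noise (sd 0.05). Built-in methods:

| id | data | pipeline |
|---|---|---|
| `r_WIC` | RNA | ICA-stability gene selection → weighted-ICA proportions |
| `r_WNM` | RNA | ICA selection (duplicates kept) → sparse NMF |
| `m_EDC` | DNAm | 5000 most-variable probes → constrained NMF |
| `m_MDC` | DNAm | 5000 most-variable probes → regularized constrained NMF |
| `m_WIC` | DNAm | probe filter → weighted-ICA proportions |
| `b_WIC` | both | RNA + DNAm weighted-ICA → match components → average |
| `b_COM` | both | `r_WNM` estimate warm-starts the DNAm factorization |
| `b_MEA` | both | `r_WNM` + `m_MDC` → match components → average |
| `ref_OLS` / `ref_RLR` | RNA | per-sample (robust) regression on known profiles |
| `external` | both | any program run on a truth-hidden bundle |

## Worked example

```r
library(mixdecon)

scfg   <- simulation_config(seed = 1, n_datasets = 3)   # 3 paired datasets
sets   <- simulate_benchmark(scfg)
report <- run_benchmark(
  list(method_spec("m_MDC"), method_spec("m_WIC"), method_spec("ref_OLS")),
  sets, n_runs = 2, root_seed = 7)
make_leaderboard(report)
```

```
  rank method_id modality_use mean_mae   sd_mae mean_elapsed n_ok n_failed status
1    1   ref_OLS          rna 0.000817 7.98e-06      0.00383    6        0     ok
2    2     m_MDC         dnam 0.032073 1.54e-02      5.84817    6        0     ok
3    3     m_WIC         dnam 0.105237 7.59e-03      0.01883    6        0     ok
```

Reading the numbers: `ref_OLS` knows the true reference profiles, so its
mean matched MAE (~0.0008) is essentially the noise floor. The
reference-free `m_MDC` recovers the five proportions to about 3 points of
MAE per cell type; the lighter weighted-ICA pipeline trails at ~0.11.
`render_report(report, "out/")` writes the MAE boxplots, heatmaps of each
matched `A` estimate and of its absolute error, plus `leaderboard.csv` and
`records.csv`.

A thin CLI over the same functions lives at `inst/cli/mixdecon`
(`simulate`, `run`, `score`, `bench` subcommands).

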