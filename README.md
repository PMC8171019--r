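# cafw — cluster-aware feature weighting and gene selection for scRNA-seq

Single-cell RNA-seq clustering stands or falls with the genes the cell–cell
similarity is computed over. `cafw` selects genes *from the perspective of the
clusters themselves*: it fits a feature-weighted k-medians model whose
objective

```
J = Σ_k Σ_{i∈χ_k} Σ_j w_kj |x_ij − c_kj|  +  Σ_k δ_k Σ_j w_kj²,
    w_kj ∈ [0,1],  Σ_j w_kj = 1  for every cluster k
```

yields a K×n weight matrix `W` (cluster-specific gene importances, updated in
closed form from the Lagrangian stationarity condition, with per-cluster
median centers and weighted Manhattan assignment). Genes are then screened in
two stages: an iterative Sturges-binned cut on each gene's maximum weight,
and a cut on one-sided normal p-values of the residuals of a
`log(CV²) ~ log10(mean)` trend fitted to each gene's weights across clusters
(marker-like genes sit above the trend). Adjusted Rand index and
Davies–Bouldin index evaluate the result, and a negative-binomial + dropout
simulator with planted markers makes every stage testable offline.

## Worked example

```r
library(cafw)

# 5 clusters of 100 cells; 50 planted marker genes among 2000
ds  <- simulate_expression(seed = 1)
run <- run_pipeline(ds, K = 5, seed = 1)
#> #Genes 2000 | #Genes-S1 2000 (100.0%) | #Genes-S2 53 (2.6%)
print(run)
#> <cafw_run> #Genes 2000 | #Genes-S1 2000 (100.0%) | #Genes-S2 53 (2.6%)
#>   ARI 0.510 | DBI all genes 2.897 | DBI selected 1.288
mean(ds$informative_genes %in% run$selected_genes)
#> [1] 0.92
```

Reading the numbers: of 2,000 genes the weight screen keeps all (the matrix
is already below the 10,000-gene target), the deviation screen keeps 53
(2.6%), and 92% of the 50 planted markers are among them. The clustering fit
on all genes reaches ARI 0.51 against the planted labels, and the
Davies–Bouldin index (printed `min` form; smaller = tighter, better-separated
clusters under the true labels) drops from 2.90 on all genes to 1.29 on the
selected genes — the selected set exposes the cluster structure more clearly.
Refitting the clustering on the selected genes raises the mean ARI
substantially (0.46 → 0.76 across ten simulation seeds in the test suite).

Lower-level entry points: `load_expression()` / `preprocess()` (TSV/CSV/MTX
input, rare-gene and redundancy filters), `weighted_kmedians()` (the model;
`tidy()`, `glance()`, `autoplot()` methods), `select_genes()` (both screens +
`screening_report`), `adjusted_rand_index()` / `davies_bouldin_index()`,
`simulate_expression()`. A thin command-line driver with `run`, `preprocess`,
`weight`, `cluster`, `select`, `evaluate` and `simulate` subcommands lives at
`inst/cli/cafw.R` (exit codes: 2 io, 3 preprocessing, 4 clustering,
5 selection).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the default synthetic fixture —
simulate, preprocess, fit the weighted model, screen genes, evaluate ARI/DBI
and planted-marker recall — logging the per-stage gene counts, and writes the
acceptance JSON to `--out`.
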