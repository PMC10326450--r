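# spatinfo

Detection of spatially variable genes (SVGs) in spatial transcriptomics data
— Visium spots, MERFISH/CosMx cells, or any counts-plus-coordinates table —
by scoring each gene's *spatial information*: a variational lower bound on
the Jensen–Shannon divergence between expression pairs sampled from spatial
neighborhoods and pairs sampled uniformly at random.

## The idea

Let `p_N(x, x′)` be the joint distribution of a gene's expression at the two
ends of a k-step random walk on a spatial neighbor graph (Delaunay, knn,
radius, or lattice adjacency), and `p(x)p(x′)` the product of marginals. For
any classifier logit `f_θ(x, x′, d)`,

```
D_JS( p_N ‖ p⊗p )  ≥  E_pN[ −σ(−f_θ) ] − E_p⊗p[ σ(f_θ) ],     σ(t) = log(1 + e^t)
```

so training a classifier to tell "near" pairs from shuffled "far" pairs
tightens a bound on how much spatial structure the gene carries. The
classifier is deliberately small,

```
f(x, x′, d) = exp(−d/α) · ( w_s·|x + x′ + s| − w_d·|x − x′| + b ),   w_s, w_d > 0
```

with a per-gene learned distance-decay length α. The per-pair objective is
the log probability of the true near/far labels: random guessing scores
`log 0.25 ≈ −1.386` nats, perfect classification approaches 0. The score
decomposes over cells into a saliency map (who contributes), sums to a
per-gene score in `[0, n]`, and — because scoring is classification — yields
an exact Binomial(n, ½) significance test. Training optionally resamples
expression each iteration from Gamma-Poisson / Dirichlet-Multinomial /
Gaussian posteriors so sparse counts are treated as uncertain, and jointly
fits multi-resolution exact-size spatial bins to help sparse genes.

The package also provides pairwise gene–gene spatial information with
complete-linkage clustering, Moran's I / Geary's C baselines, PR-AUC
benchmarking, and two labeled simulators (a cellular Potts model with
negative-binomial expression, and streak/hotspot geometric patterns).

## Worked example

```r
library(spatinfo)

sim <- simulate_pattern(n_cells = 1000, n_genes = 50, n_svg = 5,
                        fold_change = 4, seed = 1)   # 5 true SVGs (vertical streak)
fit <- spatinfo(sim$dataset, seed = 1)
fit
#> spatinfo fit: 50 genes x 1000 cells (graph: delaunay, walk length 10)
#>   uncertainty model: gamma_poisson; bin sizes: 4,8,16
#>   normalized score range: [0.92, 16]; 6 gene(s) with q < 0.05
#>   top genes: gene47, gene34, gene42, gene10, gene41

cols <- c("gene_id", "raw_score", "normalized_score", "accuracy", "p_value", "q_value")
head(summary(fit)[, cols], 6)
#>    gene_id raw_score normalized_score accuracy  p_value  q_value
#> 47  gene47     -1.38            15.95    0.526 4.76e-14 2.38e-12
#> 34  gene34     -1.38            14.92    0.523 1.56e-11 1.95e-10
#> 42  gene42     -1.38            13.96    0.524 2.20e-12 4.05e-11
#> 10  gene10     -1.38            13.62    0.520 8.00e-09 8.00e-08
#> 41  gene41     -1.38            13.51    0.524 2.43e-12 4.05e-11
#> 28  gene28     -1.39             2.72    0.505 7.56e-02 4.89e-01
```

The five truly spatial genes (gene10, gene34, gene41, gene42, gene47) occupy
the top five rows: their normalized scores (≈ 14–16, i.e. the equivalent of
14–16 perfectly classified cells' worth of information) and q values `< 1e-7`
separate cleanly from the null genes (scores ≈ 1–3, q ≈ 0.5). `raw_score` is
the mean per-pair log probability, just above the −1.386 guessing baseline —
typical for subtle per-pair signal spread over many cells. `plot(fit, "gene47")`
draws the saliency map; `coef(fit)` returns the fitted classifier parameters.

Benchmarking against the classical baseline on the same graph:

```r
bl <- baseline_scores(sim$dataset)
delta_pr_auc(fit$scores$normalized_score, bl$rank_score, sim$is_svg)
#> [1] 0   # both methods rank this easy benchmark perfectly (PR-AUC 1.0)
```

A shell entry point wrapping the same functions lives at
`inst/cli/spatinfo.R` (subcommands `run`, `pairwise`, `simulate-potts`,
`simulate-geo`, `eval`).

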