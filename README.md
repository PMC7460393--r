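# lactoclust

Shape-based clustering and parametric modelling of dairy lactation
curves.

A lactation curve (LC) — daily milk yield against days in milk (DIM,
calving day = DIM 0) — summarises the milking potential of a dairy cow:
it typically rises to a peak within ten weeks and then declines slowly.
Mean curves of large herds are well described by classical parametric
models, but individual curves are diverse, and a sizeable fraction are
atypical (flat, peakless, or dipping mid-lactation). Rather than
discarding those as outliers or pre-grouping cows by parity or
production level, `lactoclust` groups lactations objectively by the
*shape* of their curve and then characterises each group with the
classical models. It is aimed at dairy scientists and precision-farming
analysts working with daily robot- or parlour-recorded milk yields.

## What it does

1. **Filter & preprocess** daily records: three sequential exclusion
   rules (Type-I late recording start, Type-II missing days in DIM
   10–70, Type-III >10 consecutive missing days in DIM 70–280), trimming
   to the DIM 10–280 window (271 points), linear gap interpolation,
   10-day moving-average smoothing, and per-curve Z-score normalization.
2. **Cluster** the Z-normalized curves with k-medoids under the
   root-mean-square Euclidean distance

   d(A, B) = sqrt( (1/N) Σᵢ (m_{A,i} − m_{B,i})² ),

   minimising Σ_clusters Σ_members d(X, μ) with squared-distance-weighted
   (k-means++-style) initialization, and select k by the elbow method.
3. **Model** each cluster's representative (mean) curve y(t) with

   * Wood: y = a·t^b·e^(−c·t)
   * Wilmink: y = a + b·e^(−k·t) + c·t
   * Dijkstra: y = a·exp[b(1 − e^(−c·t))/c − d·t]

   by bounded nonlinear least squares, and derive closed-form features —
   peak yield, peak DIM, and persistency (the relative decline rate at
   the midpoint t_h between peak and end of lactation): Wood peak DIM =
   b/c, peak yield = a(b/c)^b e^(−b), persistency = b/t_h − c; Dijkstra
   peak DIM = ln(b/d)/c, peak yield = a(d/b)^(d/c) e^((b−d)/c),
   persistency = b·e^(−c·t_h) − d.
4. **Compare** clusters: ε_f (RMSE of fitted model vs cluster mean
   curve, L) and ε_c (mean Z-space RMSE vs each member curve), observed
   peaks, and per-cluster summaries with one-way ANOVA and Fisher's LSD
   compact letters.
5. **Simulate**: a synthetic herd generator with four curve archetypes
   (typical multiparous, flat primiparous, undulating mid-lactation dip,
   flat no-peak), parity mixing, multiplicative noise and structured
   missingness, plus ground-truth labels — so the whole pipeline is
   testable without farm data.

## Worked example

```r
library(lactoclust)

config <- pipeline_config(
  out_dir = "demo",
  herd = herd_spec(n_lactations = 150, seed = 11),
  missing = default_missingness(),
  k = NULL, k_range = 2:8, restarts = 5, seed = 11
)
res <- pipeline_run_all(config)
res$preprocess$report
#> Lactation filter: 150 in, 66 kept | Type-I 18, Type-II 2, Type-III 64
res$clustering
#> k-medoids: k = 3, objective = 11.4455, 2 iteration(s), 5 restart(s)
#> cluster sizes: 10, 35, 21
read.csv("demo/features.csv")
#>       group    model peak_yield_l peak_dim_days persistency computable
#> 1 cluster_1     wood           NA            NA          NA      FALSE
#> 2 cluster_1 dijkstra           NA            NA          NA      FALSE
#> 3 cluster_2     wood        47.02         54.01  -0.0026201       TRUE
#> 4 cluster_2 dijkstra        47.08         58.84  -0.0026917       TRUE
#> 5 cluster_3     wood        37.03        153.28  -0.0005071       TRUE
#> 6 cluster_3 dijkstra        37.01        140.47  -0.0004130       TRUE
#> 7     total     wood        41.62         62.35  -0.0016367       TRUE
#> 8     total dijkstra        42.04         61.18  -0.0015992       TRUE
```

Of 150 simulated lactations, 84 are excluded by the three rules (the
generator injects late starts and long gaps on purpose). The elbow picks
k = 3 on this herd: a flat no-peak cluster whose Wood/Dijkstra fits pin
`b` and `c` at the sign bound and therefore report *no computable peak*
(`computable = FALSE`); a typical early-peaking cluster (peak ≈ 47 L at
≈ 54–59 DIM, strongly negative persistency, i.e. fast decline); and a
flat late-peaking cluster (≈ 37 L at ≈ 140–153 DIM, persistency near
zero — the primiparous signature). Full fit tables with standard errors,
ε_f/ε_c, the elbow profile, labels, medoids and an ANOVA/LSD summary are
written as CSVs to `demo/`, with a `manifest.json` recording the seed
and options needed to re-run the analysis bit-identically.

A thin command-line wrapper with the same stages is installed at
`inst/scripts/lactoclust.R`
(`Rscript lactoclust.R run-all --out demo --seed 11`).

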