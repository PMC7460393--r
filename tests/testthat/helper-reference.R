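# Published Wood/Dijkstra parameter estimates for six shape clusters
# ((a)..(f)) and the pooled herd ("total") of a commercial Holstein
# dataset, with the peak features reported alongside them.  Used to check
# the closed-form feature formulas against independently published
# arithmetic.  Cluster (f) is the published degenerate fit (flat, no peak)
# and has no feature values.

ref_wood_params <- list(
  a     = c(a = 24.6645, b = 0.2142, c = 0.0039),
  b     = c(a = 15.9437, b = 0.2738, c = 0.0033),
  c     = c(a = 12.5155, b = 0.3406, c = 0.0035),
  d     = c(a = 44.8198, b = 0.0170, c = 0.0016),
  e     = c(a = 12.2953, b = 0.2743, c = 0.0018),
  total = c(a = 22.1761, b = 0.2000, c = 0.0029)
)

ref_wood_features <- data.frame(
  column     = c("a", "b", "c", "d", "e", "total"),
  peak_yield = c(46.96, 40.65, 42.34, 45.87, 37.10, 42.34),
  peak_dim   = c(54.92, 82.97, 97.31, 10.63, 152.39, 68.97)
)

ref_dijkstra_params <- list(
  a     = c(a = 34.0962, b = 0.0197, c = 0.0357, d = 0.0026),
  b     = c(a = 18.8021, b = 0.0467, c = 0.0506, d = 0.0015),
  c     = c(a = 28.2765, b = 0.0126, c = 0.0124, d = 0.0032),
  d     = c(a = 13.6532, b = 0.1950, c = 0.1525, d = 0.0016),
  e     = c(a = 21.3504, b = 0.0152, c = 0.0230, d = 0.0006),
  total = c(a = 25.1318, b = 0.0346, c = 0.0520, d = 0.0016)
)

ref_dijkstra_features <- data.frame(
  column     = c("a", "b", "c", "d", "e", "total"),
  peak_yield = c(47.50, 41.48, 42.37, 46.14, 37.02, 43.13),
  peak_dim   = c(56.73, 67.95, 110.53, 31.50, 140.53, 59.11)
)

# Wood cluster (a) persistency as published (tf = 280).
ref_wood_a_persistency <- -0.0026
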