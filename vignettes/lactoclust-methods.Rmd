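---
title: "Methods: shape clustering and parametric modelling of lactation curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape clustering and parametric modelling of lactation curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactoclust)
```

## The problem

Daily milk yield over one lactation — the lactation curve (LC) — rises
to a peak within roughly ten weeks of calving and then declines until
dry-off. Its shape (peak yield, peak time, persistency of decline)
feeds feeding, health and breeding decisions. Individual curves,
however, vary widely with parity, health and management, and a
substantial minority are atypical: flat with no discernible peak, or
dipping mid-lactation. Fitting one parametric model to a pre-defined
group (all cows, or all primiparous cows) averages those shapes away.
`lactoclust` instead groups lactations by curve shape first, with a
distance-based clustering that makes no parametric assumption, and only
then fits classical LC models to each group's mean curve.

## Preprocessing model and assumptions

The analysis window is DIM 10–280 inclusive (271 daily points; calving
day is DIM 0). Records outside it are discarded: both tails of a
lactation are the most error-prone part of on-farm recording, and 280
days is safely inside typical lactation lengths, so every retained
curve is directly comparable.

Three sequential exclusion rules (`filter_lactations()`) remove
lactations the window cannot represent faithfully:

* **Type-I** — no record at any DIM ≤ 10 (recording started late, so
  the rise to peak is unobserved).
* **Type-II** — any missing day in DIM 10–70. The peak usually falls in
  this range; interpolating across it would manufacture the single most
  important feature of the curve, so no interpolation is allowed there.
* **Type-III** — more than 10 consecutive missing days in DIM 70–280,
  where linear interpolation would span too long a gap. A lactation
  whose last record precedes DIM 270 necessarily fails this rule.

Rules fire in order I → II → III and each excluded lactation carries
exactly one reason, the first that applies; a late-start lactation also
has missing days in 10–70, but is counted as Type-I. This keeps the
per-rule counts disjoint and interpretable. Filtering is evaluated per
lactation independently, so it is invariant to record order.

Surviving gaps are filled by linear interpolation between the flanking
observed days; the ≤10-day tail that Type-III permits at the window end
has no right-hand anchor and is filled by carrying the last observation
forward — the minimal-assumption choice, affecting at most 10 of 271
points. Curves are then smoothed with a 10-day moving average, centred
(offsets −4..+5) so the peak is not phase-shifted, and truncated at the
grid edges so the grid length is preserved. Smoothing never leaves the
min/max envelope of the input.

Finally each curve is Z-score transformed (mean 0, SD 1, population SD)
*per lactation*, so that distances compare curve shape rather than
production level: a high-yielding and a low-yielding cow with the same
relative trajectory coincide in Z-space. The pipeline order is
interpolate → smooth → normalize; model fitting always uses the
original-unit curves, clustering the normalized ones. Constant curves
cannot be Z-normalized and are dropped with a warning.

## Clustering

The dissimilarity between two aligned curves is the root-mean-square
Euclidean distance, d(A,B) = sqrt((1/N) Σ (m_A,i − m_B,i)²), a metric
proportional to the Euclidean distance (N = 271). k-medoids is used
rather than k-means because a medoid — the member minimising the sum of
distances to its cluster — is robust to the outlier curves that survive
filtering, and the cluster centre is always a real lactation one can
plot and inspect.

The implementation is the alternating (Voronoi) scheme: assign every
curve to its nearest medoid, then recompute each cluster's medoid;
repeat until the medoid set is stable. The objective never increases
(asserted internally on every sweep). Initial medoids are drawn
k-means++-style: the first uniformly, each next with probability
proportional to the squared distance to the nearest already-chosen
centre, which spreads the starting centres and speeds convergence. Ten
restarts are kept by default, best objective wins. All ties — nearest
medoid, medoid update, best restart — break to the lowest index, making
results deterministic for a given seed on any platform. Alternation was
chosen over PAM's swap search for speed and simplicity; on small
instances (n ≤ 8, k ≤ 3) the test suite verifies that the best run over
all possible initial medoid subsets attains the exhaustive-search
optimum, bounding the optimality loss of the simpler scheme, and on
well-separated synthetic herds the partition matches PAM exactly.

The number of clusters is chosen by the elbow method: run k-medoids for
k in a candidate range, plot the best objective J(k), and take the
point of diminishing returns. Since the published use of the elbow is a
visual call, the automated rule here is the chord (kneedle-style)
criterion: after min–max scaling both axes, choose the k whose point
lies farthest from the straight line joining the profile's endpoints;
a curvature-free profile degenerates to the smallest candidate k. The
full profile is always returned and written to CSV so the user can
override k, which remains an explicit option throughout.

## Lactation-curve models and features

Three classical models are fitted to each cluster's representative
curve (the pointwise mean of member smoothed curves, in litres):
Wood's incomplete gamma y = a·t^b·e^(−ct); Wilmink's exponential-plus-
linear y = a + b·e^(−kt) + c·t; and Dijkstra's mechanistic
proliferation/death model y = a·exp[b(1 − e^(−ct))/c − d·t]. Sign
constraints define each family: all parameters positive for Wood and
Dijkstra; a, k positive and b, c negative for Wilmink. They are
enforced as box bounds ([1e−8, ∞) or (−∞, −1e−8]) in a
Levenberg–Marquardt least-squares fit (`minpack.lm`). Starting values
are scaled from the data (Wood: mean yield, 0.2, 0.003; Wilmink: max
yield, −25, −0.05, 0.05; Dijkstra: first-day yield, 0.03, 0.05, 0.002 —
magnitudes typical of Holstein daily yields); if the first fit fails or
stalls, a 16-point Latin-hypercube multi-start over plausible ranges is
tried. Fitting never raises for numerical reasons: non-convergence is
flagged and the best parameters seen are reported, and parameters
pinned at a bound are flagged separately — the signature of a flat
curve forced through a peaked model. Standard errors are the usual
asymptotic sqrt(diag(σ̂²(JᵀJ)⁻¹)), σ̂² = RSS/(N − p).

Peak and persistency features come from closed forms (Wood: peak DIM
b/c, peak yield a(b/c)^b e^(−b), persistency b/t_h − c; Dijkstra: peak
DIM ln(b/d)/c, peak yield a(d/b)^(d/c)e^((b−d)/c), persistency
b·e^(−c·t_h) − d), with t_h = (peak DIM + t_f)/2 halfway between peak
and end of lactation. The Wilmink model has no standard closed forms
and is excluded from feature extraction, though its fit still enters
the error comparison. `t_f` defaults to 280 d, the analysis-window end:
the features describe the curve the models were actually fitted to.
Persistency is the most sensitive feature to this convention (peak
yield and peak DIM do not involve t_f at all), which is worth
remembering when comparing persistency values across studies that used
full lactation lengths. A parameter set without a usable interior peak
— b or c at the numerical sign bound for Wood, peak outside (0, t_f),
or b ≤ d for Dijkstra — yields an explicit "not computable" state
rather than an error or a nonsense number. The test suite checks, for
random valid parameter sets of both families, that the model evaluated
at the closed-form peak DIM equals the closed-form peak yield to 1e−9
and exceeds the values one day to either side — an analytic cross-check
that the feature formulas and the model equations implement the same
curve.

## Fit errors and group comparison

Two errors summarise model adequacy per cluster: ε_f, the RMSE in
litres between the fitted curve and the cluster's mean curve; and ε_c,
the mean over members of the RMSE between the Z-normalized member and
the Z-normalized fitted curve. Z-transforming *both* sides of ε_c is
deliberate: comparing a raw model curve to Z-scored members would be
dimensionally inconsistent, and the double transform makes ε_c a pure
shape discrepancy, invariant to positive affine rescaling of any
member.

Cluster summaries report per-cluster mean and SE (SD/√n) of parity,
mean daily yield, total yield over DIM 10–280 (the sum of the 271
interpolated daily values — no finer integration rule is warranted for
daily data), observed peak DIM and observed peak yield. Observed peaks
are read from the smoothed curves (the smoothing exists precisely to
stabilise single-day spikes), ties to the earliest day. Differences are
tested by one-way ANOVA (via `stats::aov`, with explicit conventions
for degenerate inputs) and unprotected Fisher's LSD with a compact
letter display built by insert-and-absorb, which guarantees two groups
share a letter exactly when their pairwise test is non-significant at
α = 0.05. Unprotected LSD is anti-conservative with many groups; it is
retained as the field-standard presentation, and the caveat stands.
Per-lactation peaks are summarised (rather than peaks of mean curves)
so that each row has a genuine SE.

## Synthetic herd generator

No commercial-farm data ship with the package; the generator exists so
every pipeline stage can be validated against known ground truth. It
emulates the statistical structure the analysis assumes: four curve
archetypes — typical multiparous (Wood, a = 24.66, b = 0.214,
c = 0.0039: peak ≈ 47 L near DIM 55), flat primiparous (Wood,
a = 12.30, b = 0.274, c = 0.0018: gentle peak ≈ 37 L near DIM 152),
undulating (a high flat Wood base times a Gaussian mid-lactation dip,
22% deep at DIM 160), and flat no-peak (constant ≈ 36 L with a slight
negative trend) — mixed 45/25/20/10%, with parity distributions
skewing the flat archetypes primiparous and the typical archetype
multiparous, reproducing the parity–shape association seen in herd
data. Default herd size is 330 lactations, the scale of a multi-farm
three-year collection after filtering. Noise is multiplicative by
default (yield × (1 + ε), ε ~ N(0, cv²), cv = 0.05), matching the
heteroscedastic look of raw milking records; additive noise is
available. Lactation length is drawn uniformly within ±30 d of a 360-d
default last DIM. Structured missingness injects each exclusion
trigger independently — late starts (p = 0.17), short early gaps
(p = 0.03), long mid-lactation gaps of 11–25 d (p = 0.55) — retaining
roughly a third of lactations under the defaults, comparable to the
heavy attrition of real robot-milking datasets where most losses are
long gaps rather than isolated missing days. Every lactation carries
ground-truth archetype and missingness tags.

What the generator does *not* emulate: milk-component dynamics, health
events, calendar seasonality, pregnancy effects, within-archetype
parameter variation (all members of an archetype share one base
curve; only noise and length vary), or autocorrelated day-to-day
noise. Consequently, passing recovery tests (ARI ≥ 0.9 at cv = 0.02,
n = 90, three archetypes) demonstrates the pipeline's correctness on
data satisfying its assumptions, not clustering performance on real
herds, where shape variation is continuous and cluster boundaries are
soft.

## Numerical choices and problem sizes

Population SD (divide by N) in Z-scores — either convention works, one
is fixed for reproducibility. All tie-breaks to the lowest index.
Clustering determinism is guaranteed by a single integer seed; the
elbow uses seed + k per candidate so profiles are reproducible
independently of the range evaluated. Degenerate inputs have defined
behaviour throughout: empty herds produce empty outputs; constant
curves are dropped (normalization) or flagged (features); identical
groups give F = 0, p = 1; zero within-group variance with distinct
means gives F = ∞, p = 0. The test suite runs on deliberately small
problem sizes — herds of 45–150 for pipeline tests, n ≤ 8 for
exhaustive clustering oracles, 1000 replicates for the ANOVA
type-I-error calibration — chosen so the whole suite completes in well
under a minute while still exercising every code path; the elbow and
recovery tests use 60–90 lactations, ample for three well-separated
archetypes.

## Known limitations

The alternating k-medoids can stop in a local optimum that PAM's swap
search would escape; restarts mitigate but do not eliminate this. The
elbow chord rule inherits the elbow method's ambiguity when J(k) bends
gently. Unprotected LSD inflates family-wise error. The residuals of
LC model fits to mean curves are autocorrelated, so the reported
asymptotic SEs understate uncertainty somewhat. And persistency values
depend on the t_f convention, as noted above.
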