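# Shared fixtures and tiny independent oracles used across test files.

# A complete lactation record: every integer DIM in dims, yields from f(dim).
make_record <- function(id, dims, yields, parity = 2L) {
  list(animal_id = id, parity = parity,
       dim = as.integer(dims), yield = as.numeric(yields))
}

# 10-lactation herd with designed filter violations:
# 4 complete, 2 late starts (Type-I), 1 gap at DIM 40 (Type-II),
# 3 with a 15-day gap at DIM 150 (Type-III).
fixture_filter_herd <- function() {
  base <- function(d) 30 + 10 * sin(d / 50)
  full <- 0:300
  recs <- list()
  for (i in 1:4) {
    recs[[length(recs) + 1]] <- make_record(sprintf("ok%d", i), full,
                                            base(full) + i)
  }
  for (i in 1:2) {
    d <- 25:300
    recs[[length(recs) + 1]] <- make_record(sprintf("late%d", i), d, base(d))
  }
  d <- setdiff(full, 40)
  recs[[length(recs) + 1]] <- make_record("gap40", d, base(d))
  for (i in 1:3) {
    d <- setdiff(full, 150:164)  # 15 consecutive missing days
    recs[[length(recs) + 1]] <- make_record(sprintf("longgap%d", i), d,
                                            base(d))
  }
  recs
}

# Brute-force RMS distance (independent of distance_rms()).
brute_rms <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

# Exhaustive k-medoids oracle: minimum objective over all C(n, k) medoid
# subsets, where the objective assigns each point to its nearest medoid.
brute_kmedoids_objective <- function(D, k) {
  n <- nrow(D)
  subsets <- utils::combn(n, k)
  best <- Inf
  for (s in seq_len(ncol(subsets))) {
    obj <- sum(apply(D[, subsets[, s], drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Best kmedoids() objective over every possible initial medoid subset.
# Starting from the optimal subset the alternating scheme cannot worsen, so
# this equals the global optimum whenever the implementation is correct.
all_init_kmedoids_objective <- function(D, k) {
  subsets <- utils::combn(nrow(D), k)
  best <- Inf
  for (s in seq_len(ncol(subsets))) {
    obj <- kmedoids(D, k, init = subsets[, s])$objective
    if (obj < best) best <- obj
  }
  best
}

# Random valid parameter sets with an interior peak on DIM 10..280.
random_wood_params <- function() {
  b <- runif(1, 0.05, 0.35)
  tm <- runif(1, 20, 250)
  c(a = runif(1, 10, 40), b = b, c = b / tm)
}

random_dijkstra_params <- function() {
  d <- runif(1, 5e-4, 5e-3)
  b <- d * runif(1, 3, 40)
  tm <- runif(1, 20, 250)
  c(a = runif(1, 10, 40), b = b, c = log(b / d) / tm, d = d)
}

# Three well-separated archetypes for clustering-recovery tests.
fixture_three_archetypes <- function() {
  a <- default_archetypes()
  a[c("typical_multiparous", "flat_primiparous", "undulating_dip")]
}

fixture_recovery_herd <- function(n = 90, noise_cv = 0.02, seed = 7) {
  herd_spec(n_lactations = n,
            archetype_mix = fixture_three_archetypes(),
            proportions = c(1, 1, 1) / 3,
            noise_cv = noise_cv, dim_range = c(0, 360), seed = seed)
}
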