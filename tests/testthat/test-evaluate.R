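test_that("representative curve is the pointwise mean of its members", {
  x <- matrix(runif(20), 4, 5)
  expect_equal(representative_curve(x[1, , drop = FALSE]), x[1, ])
  # symmetric pair averaging to a constant
  a <- runif(5)
  expect_equal(representative_curve(rbind(a, 2 - a)), rep(1, 5))
  # loop oracle
  set.seed(25)
  m <- matrix(rnorm(5 * 271), 5)
  oracle <- sapply(seq_len(271), function(j) {
    s <- 0
    for (i in 1:5) s <- s + m[i, j]
    s / 5
  })
  expect_equal(representative_curve(m), oracle, tolerance = 1e-12)
  expect_error(representative_curve(m[0, , drop = FALSE]), "members")
})

test_that("epsilon_f is the RMSE against the representative curve", {
  grid <- dim_grid()
  p <- ref_wood_params$a
  fit <- list(model = "wood", params = p)
  curve <- eval_lc("wood", p, grid)
  expect_equal(epsilon_f(fit, curve, grid), 0)
  # constant offset delta gives eps_f = |delta|
  expect_equal(epsilon_f(fit, curve + 1.7, grid), 1.7, tolerance = 1e-12)
  expect_equal(epsilon_f(fit, curve - 2.5, grid), 2.5, tolerance = 1e-12)
  # random case against a loop oracle
  set.seed(26)
  rep_curve <- curve + rnorm(length(grid))
  expect_equal(epsilon_f(fit, rep_curve, grid),
               brute_rms(curve, rep_curve), tolerance = 1e-12)
})

test_that("epsilon_c compares shapes: invariant to positive affine members", {
  grid <- dim_grid()
  p <- ref_dijkstra_params$a
  fit <- list(model = "dijkstra", params = p)
  curve <- eval_lc("dijkstra", p, grid)
  # members that are positive affine maps of the model have zero shape error
  members <- rbind(curve, 2.5 * curve + 10, 0.3 * curve - 1)
  expect_equal(epsilon_c(fit, members, grid), 0, tolerance = 1e-9)
  expect_equal(epsilon_c(fit, rbind(curve), grid), 0, tolerance = 1e-12)

  # loop oracle on perturbed members, and member-order invariance
  set.seed(27)
  noisy <- t(sapply(1:4, function(i) curve * runif(1, 0.5, 2) +
                      rnorm(length(grid), 0, 2)))
  zc <- znormalize(curve)
  oracle <- mean(apply(noisy, 1, function(m) brute_rms(znormalize(m), zc)))
  expect_equal(epsilon_c(fit, noisy, grid), oracle, tolerance = 1e-12)
  expect_equal(epsilon_c(fit, noisy[4:1, ], grid),
               epsilon_c(fit, noisy, grid))

  # degenerate member is skipped with a warning
  expect_warning(
    ec <- epsilon_c(fit, rbind(curve, rep(5, length(grid))), grid),
    "degenerate")
  expect_equal(ec, 0, tolerance = 1e-12)
})

test_that("observed peak takes the maximum, ties to the earliest day", {
  grid <- dim_grid()
  # strictly increasing: boundary peak at DIM 280
  inc <- seq_along(grid)
  expect_equal(observed_peak(inc, grid)$peak_dim, 280)
  # noiseless typical curve peaks at the grid point nearest its analytic peak
  p <- ref_wood_params$a
  curve <- eval_lc("wood", p, grid)
  pk <- observed_peak(curve, grid)
  expect_equal(pk$peak_dim, 55)  # analytic peak at 54.92 days
  expect_equal(pk$peak_yield, max(curve))
  # flat curve: earliest DIM wins
  expect_equal(observed_peak(rep(3, length(grid)), grid)$peak_dim, 10)
  expect_error(observed_peak(numeric(0), grid), "empty")
})

test_that("one-way ANOVA: F equals pooled t-squared for two groups", {
  set.seed(28)
  for (i in 1:10) {
    g1 <- rnorm(sample(5:15, 1), 10, 2)
    g2 <- rnorm(sample(5:15, 1), 11, 2)
    av <- anova_oneway(list(g1, g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(av$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("ANOVA degenerate conventions and input validation", {
  expect_equal(anova_oneway(list(c(1, 1), c(1, 1)))[c("F", "p")],
               list(F = 0, p = 1))
  av <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_equal(av$F, Inf)
  expect_equal(av$p, 0)
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
  expect_error(anova_oneway(list(1, c(1, 2))), "2 groups")
})

test_that("ANOVA type-I error is calibrated at the nominal 5% level", {
  set.seed(29)
  rejections <- replicate(1000, {
    groups <- lapply(1:3, function(i) rnorm(10))
    anova_oneway(groups)$p < 0.05
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("LSD letters separate clear groups and share under equality", {
  # deterministic groups: spread 0.05 makes a 0.01 mean gap non-significant
  tiny <- function(mu) mu + 0.05 * rep(c(-1, 1), 4)
  lett <- fisher_lsd_letters(list(tiny(10), tiny(10.01), tiny(50)))
  expect_equal(lett[3], "a")          # highest mean gets 'a'
  expect_equal(lett[1], lett[2])      # near-identical means share
  expect_false(lett[1] == lett[3])

  same <- fisher_lsd_letters(list(tiny(10), tiny(10), tiny(10)))
  expect_true(all(same == same[1]))
  expect_equal(fisher_lsd_letters(list(rnorm(5))), "a")
})

test_that("letters reconstruct the pairwise LSD decisions exactly", {
  set.seed(33)
  for (rep in 1:25) {
    ng <- sample(3:6, 1)
    groups <- lapply(seq_len(ng), function(i) {
      rnorm(sample(4:10, 1), mean = sample(0:4, 1), sd = 1)
    })
    lett <- fisher_lsd_letters(groups)
    av <- anova_oneway(groups)
    means <- vapply(groups, mean, numeric(1))
    ns <- lengths(groups)
    for (i in seq_len(ng - 1)) {
      for (j in (i + 1):ng) {
        lsd <- qt(0.975, av$df_within) *
          sqrt(av$ms_within * (1 / ns[i] + 1 / ns[j]))
        sig <- abs(means[i] - means[j]) > lsd
        share <- any(strsplit(lett[i], "")[[1]] %in%
                       strsplit(lett[j], "")[[1]])
        expect_equal(share, !sig,
                     label = sprintf("rep %d pair (%d,%d) share", rep, i, j))
      }
    }
  }
})

test_that("letters are invariant to group order up to relabeling", {
  set.seed(34)
  groups <- list(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 3), rnorm(8, 3.1))
  lett <- fisher_lsd_letters(groups)
  perm <- c(3, 1, 4, 2)
  lett_p <- fisher_lsd_letters(groups[perm])
  share <- function(l, i, j) any(strsplit(l[i], "")[[1]] %in%
                                   strsplit(l[j], "")[[1]])
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(share(lett_p, i, j),
                 share(lett, perm[i], perm[j]))
  }
})

test_that("cluster summary matches hand-computed means, SEs and totals", {
  grid <- dim_grid()
  n <- length(grid)
  # two clusters of three constant-yield lactations each, known by hand
  levels1 <- c(30, 32, 34); levels2 <- c(20, 21, 22)
  curves <- rbind(matrix(rep(levels1, each = n), 3, n, byrow = TRUE),
                  matrix(rep(levels2, each = n), 3, n, byrow = TRUE))
  cm <- structure(list(grid = grid, raw = curves, smoothed = curves,
                       znorm = NULL, ids = paste0("c", 1:6),
                       parities = c(1, 2, 3, 1, 1, 2)),
                  class = "curve_matrix")
  labels <- c(1, 1, 1, 2, 2, 2)
  summ <- cluster_summary(cm, labels)

  row_of <- function(v, s) summ[summ$variable == v & summ$statistic == s, ]
  m <- row_of("mean_daily_my_l", "mean")
  expect_equal(as.numeric(m$cluster_1), 32)
  expect_equal(as.numeric(m$cluster_2), 21)
  expect_equal(as.numeric(m$total), mean(c(levels1, levels2)))
  s <- row_of("mean_daily_my_l", "se")
  expect_equal(as.numeric(s$cluster_1), sd(levels1) / sqrt(3))
  tot <- row_of("total_my_l", "mean")
  expect_equal(as.numeric(tot$cluster_1), 32 * n)  # sum of daily yields
  par <- row_of("parity", "mean")
  expect_equal(as.numeric(par$cluster_1), 2)
  expect_equal(as.numeric(par$total), mean(c(1, 2, 3, 1, 1, 2)))
  # constant curves peak at the earliest grid day
  pk <- row_of("peak_dim_days", "mean")
  expect_equal(as.numeric(pk$cluster_1), 10)
  # clearly separated clusters earn distinct letters
  lett <- row_of("mean_daily_my_l", "letters")
  expect_equal(lett$cluster_1, "a")
  expect_equal(lett$cluster_2, "b")
})
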