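#' Cluster-representative curve
#'
#' The representative lactation curve of a cluster is the pointwise
#' arithmetic mean of its members' smoothed curves in original units (L).
#'
#' @param members numeric matrix of member curves (rows) in L.
#' @return numeric mean curve.
#' @export
representative_curve <- function(members) {
  members <- as.matrix(members)
  if (nrow(members) < 1) stop("cluster has no members", call. = FALSE)
  colMeans(members)
}

#' Fit-error statistics for a cluster
#'
#' Two complementary errors quantify how well a fitted parametric model
#' describes a cluster:
#'
#' * `epsilon_f` — RMSE (L) between the fitted model curve and the
#'   cluster-representative (mean) curve on the analysis grid; zero iff
#'   the model reproduces the representative curve exactly.
#' * `epsilon_c` — the mean, over cluster members, of the RMSE between the
#'   Z-normalized member curve and the Z-normalized model curve
#'   (unitless).  Z-normalizing both sides compares shape only, so
#'   `epsilon_c` is invariant to positive affine rescaling of any member.
#'
#' Degenerate (constant) members cannot be Z-normalized and are skipped
#' with a warning in `epsilon_c`.
#'
#' @param fit an `"lc_fit"` from [fit_lc()], or any list with `model` and
#'   `params`.
#' @param representative the cluster mean curve (L) on `grid`.
#' @param members matrix of member smoothed curves (L) on `grid`.
#' @param grid days-in-milk grid (default `10:280`).
#' @return scalar error.
#' @name fit_errors
NULL

model_curve <- function(fit, grid) {
  eval_lc(fit$model, fit$params, grid, check = FALSE)
}

#' @rdname fit_errors
#' @export
epsilon_f <- function(fit, representative, grid = dim_grid()) {
  distance_rms(model_curve(fit, grid), representative)
}

#' @rdname fit_errors
#' @export
epsilon_c <- function(fit, members, grid = dim_grid()) {
  members <- as.matrix(members)
  zm <- znormalize(model_curve(fit, grid))
  errs <- apply(members, 1, function(m) {
    s <- sqrt(mean((m - mean(m))^2))
    if (!is.finite(s) || s <= 0) return(NA_real_)
    distance_rms(znormalize(m), zm)
  })
  if (anyNA(errs)) {
    warning(sprintf("%d degenerate member curve(s) skipped in epsilon_c",
                    sum(is.na(errs))))
  }
  mean(errs, na.rm = TRUE)
}

#' Observed peak of a smoothed curve
#'
#' @param curve smoothed yields on `grid`.
#' @param grid days-in-milk grid.
#' @return list with `peak_yield` (L) and `peak_dim` (days); ties go to the
#'   earliest DIM.
#' @export
observed_peak <- function(curve, grid = dim_grid()) {
  if (length(curve) == 0) stop("empty curve", call. = FALSE)
  i <- which.max(curve)
  list(peak_yield = curve[i], peak_dim = grid[i])
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (via [stats::aov()]) comparing group
#' means, with explicit conventions for the degenerate cases that arise in
#' small clustered datasets: zero within-group variance with unequal means
#' gives `F = Inf, p = 0`; completely identical data give `F = 0, p = 1`.
#'
#' @param groups list of numeric vectors, each of length >= 2, at least two
#'   groups.
#' @return list with `F`, `p`, `df_between`, `df_within`, `ms_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  tab <- suppressWarnings(stats::anova(stats::aov(y ~ g)))
  msw <- tab["Residuals", "Mean Sq"]
  msb <- tab["g", "Mean Sq"]
  if (msw <= .Machine$double.eps * max(abs(y), 1)^2) {
    if (msb <= .Machine$double.eps * max(abs(y), 1)^2) {
      return(list(F = 0, p = 1, df_between = df_b, df_within = df_w,
                  ms_within = 0))
    }
    return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w,
                ms_within = 0))
  }
  list(F = tab["g", "F value"], p = tab["g", "Pr(>F)"],
       df_between = df_b, df_within = df_w, ms_within = msw)
}

#' Fisher's LSD compact letter display
#'
#' Unprotected pairwise comparisons: groups i and j differ when
#' `|mean_i - mean_j| > t(1 - alpha/2, df_within) *
#' sqrt(MS_within * (1/n_i + 1/n_j))`, with `MS_within` and `df_within`
#' from the one-way ANOVA over all groups.  Letters are assigned by the
#' insert-and-absorb algorithm over groups sorted by descending mean:
#' groups sharing no letter are significantly different at `alpha`.
#' No multiplicity protection is applied (classic LSD); with many groups
#' this is anti-conservative.
#'
#' @param groups list of numeric vectors (>= 1 group).
#' @param alpha significance level.
#' @return character vector of letter strings, one per group, in input
#'   order.
#' @export
fisher_lsd_letters <- function(groups, alpha = 0.05) {
  ng <- length(groups)
  if (ng == 0) stop("no groups", call. = FALSE)
  if (ng == 1) return("a")
  av <- anova_oneway(groups)
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  differs <- function(i, j) {
    if (av$ms_within == 0) return(abs(means[i] - means[j]) > 0)
    lsd <- stats::qt(1 - alpha / 2, av$df_within) *
      sqrt(av$ms_within * (1 / ns[i] + 1 / ns[j]))
    abs(means[i] - means[j]) > lsd
  }
  # insert-and-absorb: start from one column holding every group, split it
  # on each significant pair, then drop columns contained in another.  This
  # guarantees groups share a letter iff their pairwise test is
  # non-significant.
  cols <- list(seq_len(ng))
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      if (!differs(i, j)) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (i %in% col && j %in% col) {
          cols[[ci]] <- setdiff(col, i)
          cols[[length(cols) + 1L]] <- setdiff(col, j)
        }
      }
      keep <- !vapply(seq_along(cols), function(ci) {
        any(vapply(seq_along(cols), function(cj) {
          ci != cj && all(cols[[ci]] %in% cols[[cj]]) &&
            (length(cols[[ci]]) < length(cols[[cj]]) || ci > cj)
        }, logical(1)))
      }, logical(1))
      cols <- cols[keep]
    }
  }
  # letter 'a' goes to the column led by the highest mean
  cols <- cols[order(-vapply(cols, function(col) max(means[col]),
                             numeric(1)))]
  vapply(seq_len(ng), function(g) {
    ids <- which(vapply(cols, function(col) g %in% col, logical(1)))
    paste(letters[ids], collapse = "")
  }, character(1))
}

#' Per-cluster descriptive summary with group tests
#'
#' Summarizes each cluster and the whole dataset over five milking
#' characteristics — parity, mean daily milk yield (L/day), total milk
#' yield over DIM 10-280 (L, sum of the 271 interpolated daily yields),
#' observed peak DIM (days) and observed peak yield (L, both from smoothed
#' curves, ties to the earliest day) — with per-cluster mean and standard
#' error (SD/sqrt(n)), the pooled SE over all lactations, the one-way
#' ANOVA F and p, and Fisher's LSD letters.  Rows involving a
#' single-member cluster report means but no test.
#'
#' @param cm a `"curve_matrix"`.
#' @param labels integer cluster label per curve-matrix row.
#' @param alpha significance level for the letters.
#' @return data.frame with one row per (variable, statistic) in a
#'   Table-style layout: columns `variable`, `statistic` plus one column
#'   per cluster, `total`, `F`, `p`.
#' @export
cluster_summary <- function(cm, labels, alpha = 0.05) {
  stopifnot(inherits(cm, "curve_matrix"),
            length(labels) == nrow(cm$raw))
  ks <- sort(unique(labels))
  peaks <- lapply(seq_len(nrow(cm$smoothed)), function(i) {
    observed_peak(cm$smoothed[i, ], cm$grid)
  })
  vars <- list(
    parity = as.numeric(cm$parities),
    mean_daily_my_l = rowMeans(cm$raw),
    total_my_l = rowSums(cm$raw),
    peak_dim_days = vapply(peaks, `[[`, numeric(1), "peak_dim"),
    peak_my_l = vapply(peaks, `[[`, numeric(1), "peak_yield")
  )
  se <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    by_k <- lapply(ks, function(k) x[labels == k])
    means <- vapply(by_k, mean, numeric(1))
    ses <- vapply(by_k, function(g) if (length(g) > 1) se(g) else NA_real_,
                  numeric(1))
    testable <- length(ks) >= 2 && all(lengths(by_k) >= 2)
    if (testable) {
      av <- anova_oneway(by_k)
      lett <- fisher_lsd_letters(by_k, alpha = alpha)
    } else {
      av <- list(F = NA_real_, p = NA_real_)
      lett <- rep("", length(ks))
    }
    out <- data.frame(variable = v,
                      statistic = c("mean", "se", "letters"),
                      stringsAsFactors = FALSE)
    num <- function(v) sprintf("%.10g", v)
    for (i in seq_along(ks)) {
      out[[paste0("cluster_", ks[i])]] <- c(num(means[i]), num(ses[i]),
                                            lett[i])
    }
    out$total <- c(num(mean(x)), num(se(x)), "")
    out$F <- c(num(av$F), "", "")
    out$p <- c(num(av$p), "", "")
    out
  })
  do.call(rbind, rows)
}
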