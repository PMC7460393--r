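#' Fit a lactation-curve model by bounded nonlinear least squares
#'
#' Minimises the residual sum of squares of a Wood, Wilmink or Dijkstra
#' model (see [lc_models]) against a single curve in original units (L),
#' subject to the models' parameter sign constraints expressed as box
#' bounds (`[1e-8, Inf)` for positive parameters, `(-Inf, -1e-8]` for the
#' negative Wilmink `b` and `c`).  Optimisation uses the
#' Levenberg-Marquardt algorithm ([minpack.lm::nlsLM()]); if the fit from
#' the default starting values fails or does not converge, a 16-point
#' Latin-hypercube multi-start over plausible parameter ranges is tried and
#' the best converged fit kept.
#'
#' Standard errors are the usual asymptotic least-squares errors,
#' `sqrt(diag(sigma^2 (J'J)^-1))` with `sigma^2 = RSS/(n - p)`.  A fit is
#' never allowed to raise an error for numerical reasons: when no start
#' converges the best parameters seen are returned with
#' `converged = FALSE`.  Parameters that end up pinned at a sign bound
#' (within `1e-6`) are flagged via `boundary`, the typical signature of a
#' flat, peakless curve forced through a peaked model.
#'
#' @inheritParams eval_lc
#' @param dim days-in-milk grid (numeric, strictly positive for Wood).
#' @param yield observed daily yields (L), same length as `dim`, finite.
#' @param init optional named starting values; defaults are scaled from the
#'   data (Wood: mean yield, 0.2, 0.003; Wilmink: max yield, -25, -0.05,
#'   0.05; Dijkstra: first-day yield, 0.03, 0.05, 0.002).
#' @param multistart number of Latin-hypercube fallback starts.
#' @return an object of class `"lc_fit"`: list with `model`, `params`
#'   (named), `se`, `converged`, `boundary` (per-parameter logical),
#'   `residual_rmse` (L), `fitted` (on `dim`), `dim`, `n_obs`.
#' @examples
#' t <- 10:280
#' y <- eval_lc("wood", c(24.66, 0.214, 0.0039), t)
#' fit_lc("wood", t, y)$params
#' @export
fit_lc <- function(model, dim, yield, init = NULL, multistart = 16) {
  model <- match.arg(model, LC_MODELS)
  if (length(dim) != length(yield)) {
    stop("dim and yield must have equal length", call. = FALSE)
  }
  if (any(!is.finite(yield)) || any(!is.finite(dim))) {
    stop("dim and yield must be finite", call. = FALSE)
  }
  nm <- lc_param_names(model)
  if (length(yield) < length(nm) + 1) {
    stop("need at least one more observation than parameters", call. = FALSE)
  }
  dat <- data.frame(t = as.numeric(dim), y = as.numeric(yield))

  eps <- 1e-8
  bounds <- switch(model,
    wood = list(lower = c(eps, eps, eps), upper = c(Inf, Inf, Inf)),
    dijkstra = list(lower = rep(eps, 4), upper = rep(Inf, 4)),
    wilmink = list(lower = c(eps, -Inf, -Inf, eps),
                   upper = c(Inf, -eps, -eps, Inf))
  )
  form <- switch(model,
    wood = y ~ a * t^b * exp(-c * t),
    wilmink = y ~ a + b * exp(-k * t) + c * t,
    dijkstra = y ~ a * exp(b * (1 - exp(-c * t)) / c - d * t)
  )
  if (is.null(init)) {
    init <- switch(model,
      wood = c(a = mean(dat$y), b = 0.2, c = 0.003),
      wilmink = c(a = max(dat$y), b = -25, c = -0.05, k = 0.05),
      dijkstra = c(a = max(dat$y[1], 0.1), b = 0.03, c = 0.05, d = 0.002)
    )
  }
  init <- stats::setNames(as.numeric(init), nm)
  init <- pmin(pmax(init, bounds$lower), bounds$upper)

  one_fit <- function(start) {
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = dat, start = as.list(start),
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
  }

  fit <- one_fit(init)
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
    starts <- lc_multistart_grid(model, dat, n = multistart)
    best <- fit
    best_rss <- if (is.null(fit)) Inf else sum(stats::resid(fit)^2)
    for (i in seq_len(nrow(starts))) {
      f <- one_fit(stats::setNames(starts[i, ], nm))
      if (is.null(f)) next
      rss <- sum(stats::resid(f)^2)
      conv_gain <- isTRUE(f$convInfo$isConv) &&
        !(!is.null(best) && isTRUE(best$convInfo$isConv))
      if (conv_gain || rss < best_rss) {
        best <- f
        best_rss <- rss
      }
    }
    fit <- best
  }

  if (is.null(fit)) {
    return(structure(
      list(model = model, params = init, se = rep(NA_real_, length(nm)),
           converged = FALSE, boundary = rep(FALSE, length(nm)),
           residual_rmse = NA_real_,
           fitted = rep(NA_real_, nrow(dat)), dim = dat$t, n_obs = nrow(dat)),
      class = "lc_fit"
    ))
  }

  params <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(nm)))
  boundary <- abs(params - bounds$lower) < 1e-6 |
    (is.finite(bounds$upper) & abs(params - bounds$upper) < 1e-6)
  res <- stats::resid(fit)
  structure(
    list(model = model,
         params = stats::setNames(as.numeric(params), nm),
         se = stats::setNames(as.numeric(se), nm),
         converged = isTRUE(fit$convInfo$isConv),
         boundary = stats::setNames(as.logical(boundary), nm),
         residual_rmse = sqrt(mean(res^2)),
         fitted = as.numeric(stats::fitted(fit)),
         dim = dat$t, n_obs = nrow(dat)),
    class = "lc_fit"
  )
}

# Latin-hypercube starting grid over data-scaled plausible ranges.
lc_multistart_grid <- function(model, dat, n = 16) {
  ybar <- mean(dat$y)
  ymax <- max(dat$y)
  ranges <- switch(model,
    wood = rbind(a = c(0.1 * ybar, 3 * ybar),
                 b = c(0.01, 0.6),
                 c = c(1e-4, 0.01)),
    wilmink = rbind(a = c(0.5 * ymax, 2 * ymax),
                    b = c(-80, -1),
                    c = c(-0.3, -1e-3),
                    k = c(0.005, 0.3)),
    dijkstra = rbind(a = c(0.1 * ybar, 2 * ybar),
                     b = c(0.005, 0.3),
                     c = c(0.005, 0.3),
                     d = c(1e-4, 0.01))
  )
  u <- lhs::randomLHS(n, nrow(ranges))
  sweep(u, 2, ranges[, 2] - ranges[, 1], `*`) +
    matrix(ranges[, 1], n, nrow(ranges), byrow = TRUE)
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%d points)%s\n", x$model, x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$params, se = x$se, at_bound = x$boundary)
  print(round(tab, 6))
  cat(sprintf("residual RMSE: %.4g L\n", x$residual_rmse))
  invisible(x)
}
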