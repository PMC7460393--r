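#' Lactation-curve model families
#'
#' Three classical parametric descriptions of daily milk yield `y` (litres)
#' as a function of days in milk `t` (calving day = DIM 0):
#'
#' * **Wood** (incomplete gamma): `y = a * t^b * exp(-c*t)`, parameters
#'   `a, b, c`, all strictly positive.
#' * **Wilmink** (exponential rise plus linear decline):
#'   `y = a + b*exp(-k*t) + c*t`, parameters `a, b, c, k`, with `a, k > 0`
#'   and `b, c < 0`.
#' * **Dijkstra** (mechanistic cell proliferation/death):
#'   `y = a * exp(b*(1 - exp(-c*t))/c - d*t)`, parameters `a, b, c, d`, all
#'   strictly positive.
#'
#' `lc_param_names()` gives the ordered parameter vector expected by the
#' other functions; `validate_lc_params()` enforces the sign constraints.
#'
#' @name lc_models
NULL

LC_MODELS <- c("wood", "wilmink", "dijkstra")

#' @rdname lc_models
#' @param model one of `"wood"`, `"wilmink"`, `"dijkstra"`.
#' @export
lc_param_names <- function(model) {
  model <- match.arg(model, LC_MODELS)
  switch(model,
    wood = c("a", "b", "c"),
    wilmink = c("a", "b", "c", "k"),
    dijkstra = c("a", "b", "c", "d")
  )
}

#' @rdname lc_models
#' @param params numeric parameter vector in the order of `lc_param_names()`.
#' @return `validate_lc_params()` returns `params` (named) invisibly; it
#'   throws an error on a length or sign violation.
#' @export
validate_lc_params <- function(model, params) {
  model <- match.arg(model, LC_MODELS)
  nm <- lc_param_names(model)
  if (length(params) != length(nm)) {
    stop(sprintf("'%s' model expects %d parameters (%s), got %d",
                 model, length(nm), paste(nm, collapse = ", "),
                 length(params)), call. = FALSE)
  }
  if (any(!is.finite(params))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  params <- stats::setNames(as.numeric(params), nm)
  bad <- if (model == "wilmink") {
    c(params["a"] <= 0, params["b"] >= 0, params["c"] >= 0, params["k"] <= 0)
  } else {
    params <= 0
  }
  if (any(bad)) {
    stop(sprintf("parameter sign constraint violated for %s model: %s",
                 model, paste(nm[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(params)
}

#' Evaluate a lactation-curve model
#'
#' Pointwise daily milk yield (L) at days in milk `t`, vectorized over `t`.
#' Parameter sign constraints are checked before evaluation (see
#' [lc_models]); use `check = FALSE` to evaluate raw parameter vectors, e.g.
#' during optimisation.
#'
#' @inheritParams lc_param_names
#' @param params ordered parameter vector (see [lc_param_names()]).
#' @param t days in milk, non-negative (strictly positive for Wood).
#' @param check validate parameter signs first (default `TRUE`).
#' @return numeric vector of yields, same length as `t`.
#' @examples
#' eval_lc("wood", c(a = 24.6645, b = 0.2142, c = 0.0039), t = 54.92)
#' @export
eval_lc <- function(model, params, t, check = TRUE) {
  model <- match.arg(model, LC_MODELS)
  if (check) params <- validate_lc_params(model, params)
  p <- as.numeric(params)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (model == "wood" && any(t == 0)) {
    stop("Wood model requires t > 0", call. = FALSE)
  }
  switch(model,
    wood = p[1] * t^p[2] * exp(-p[3] * t),
    wilmink = p[1] + p[2] * exp(-p[4] * t) + p[3] * t,
    dijkstra = p[1] * exp(p[2] * (1 - exp(-p[3] * t)) / p[3] - p[4] * t)
  )
}
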