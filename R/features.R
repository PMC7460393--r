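#' Closed-form lactation-curve features
#'
#' Peak yield, peak time and persistency derived analytically from fitted
#' Wood or Dijkstra parameters (the Wilmink model has no standard closed
#' forms and is excluded).
#'
#' For the Wood model `y = a t^b e^{-c t}`:
#' peak DIM `t_m = b/c`, peak yield `a (b/c)^b e^{-b}`, persistency
#' `b/t_h - c`.  For the Dijkstra model: peak DIM `t_m = ln(b/d)/c`, peak
#' yield `a (d/b)^{d/c} exp[(b-d)/c]`, persistency `b e^{-c t_h} - d`.
#' In both, `t_h = (t_m + t_f)/2` is the midpoint between the peak and the
#' end of lactation `t_f` (days; default 280, the end of the analysis
#' window).  Persistency is the relative rate of decline at `t_h`
#' (per day; negative for a declining curve, more negative = faster
#' decline).
#'
#' A parameter set without an interior peak (Wood: `b` or `c` at or below
#' the numerical sign bound `1e-6`, or peak DIM outside `(0, tf)`;
#' Dijkstra: `b <= d` or `c <= 1e-6`) yields a
#' result with `computable = FALSE` and `NA` features rather than an error,
#' mirroring how flat, peakless curves are reported in practice.
#'
#' @param params named or ordered parameter vector (Wood: a,b,c; Dijkstra:
#'   a,b,c,d).
#' @param tf length of lactation used for the persistency midpoint (days).
#' @return an object of class `"lc_features"`: a list with `model`,
#'   `peak_yield` (L), `peak_dim` (days), `persistency` (per day), `tf`,
#'   `computable` and `reason` (non-`NA` when not computable).
#' @examples
#' wood_features(c(a = 22.1761, b = 0.2000, c = 0.0029))
#' dijkstra_features(c(a = 34.0962, b = 0.0197, c = 0.0357, d = 0.0026))
#' @name lc_features
NULL

new_lc_features <- function(model, peak_yield = NA_real_, peak_dim = NA_real_,
                            persistency = NA_real_, tf = NA_real_,
                            computable = FALSE, reason = NA_character_) {
  structure(
    list(model = model, peak_yield = peak_yield, peak_dim = peak_dim,
         persistency = persistency, tf = tf, computable = computable,
         reason = reason),
    class = "lc_features"
  )
}

#' @export
print.lc_features <- function(x, ...) {
  cat(sprintf("Lactation-curve features (%s model)\n", x$model))
  if (!x$computable) {
    cat("  not computable:", x$reason, "\n")
  } else {
    cat(sprintf("  peak yield:  %.2f L\n", x$peak_yield))
    cat(sprintf("  peak DIM:    %.2f days\n", x$peak_dim))
    cat(sprintf("  persistency: %.4f per day (tf = %g)\n",
                x$persistency, x$tf))
  }
  invisible(x)
}

#' @rdname lc_features
#' @export
wood_features <- function(params, tf = 280) {
  p <- as.numeric(params)
  if (length(p) != 3 || any(!is.finite(p))) {
    stop("Wood features need a finite parameter vector (a, b, c)",
         call. = FALSE)
  }
  a <- p[1]; b <- p[2]; cc <- p[3]
  # parameters at the numerical sign bound (<= 1e-6) are treated as zero:
  # a fit pinned there describes a flat curve with no usable peak
  if (b <= 1e-6 || cc <= 1e-6) {
    return(new_lc_features("wood", tf = tf,
                           reason = "no interior peak: b and c must be > 0"))
  }
  tm <- b / cc
  if (tm <= 0 || tm >= tf) {
    return(new_lc_features("wood", tf = tf,
                           reason = sprintf("peak DIM %.2f outside (0, %g)",
                                            tm, tf)))
  }
  th <- (tm + tf) / 2
  new_lc_features("wood",
                  peak_yield = a * (b / cc)^b * exp(-b),
                  peak_dim = tm,
                  persistency = b / th - cc,
                  tf = tf, computable = TRUE)
}

#' @rdname lc_features
#' @export
dijkstra_features <- function(params, tf = 280) {
  p <- as.numeric(params)
  if (length(p) != 4 || any(!is.finite(p))) {
    stop("Dijkstra features need a finite parameter vector (a, b, c, d)",
         call. = FALSE)
  }
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  if (cc <= 1e-6 || d <= 0 || b <= d) {
    return(new_lc_features("dijkstra", tf = tf,
                           reason = "no peak: requires c > 0 and b > d > 0"))
  }
  tm <- log(b / d) / cc
  th <- (tm + tf) / 2
  new_lc_features("dijkstra",
                  peak_yield = a * (d / b)^(d / cc) * exp((b - d) / cc),
                  peak_dim = tm,
                  persistency = b * exp(-cc * th) - d,
                  tf = tf, computable = TRUE)
}

#' @rdname lc_features
#' @param model `"wood"` or `"dijkstra"` (the Wilmink model has no closed
#'   forms and raises an error).
#' @export
lc_features <- function(model, params, tf = 280) {
  model <- match.arg(model, LC_MODELS)
  switch(model,
    wood = wood_features(params, tf = tf),
    dijkstra = dijkstra_features(params, tf = tf),
    wilmink = stop("closed-form features are not defined for the Wilmink model",
                   call. = FALSE)
  )
}
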