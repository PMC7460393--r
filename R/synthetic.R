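#' Lactation-curve archetype specifications
#'
#' An archetype is a noiseless reference lactation-curve shape from which
#' synthetic daily records are generated.  Four base forms are supported:
#'
#' * `"wood"` / `"dijkstra"` — the parametric models of [lc_models];
#' * `"undulating"` — a Wood base curve multiplied by a Gaussian dip
#'   `1 - dip_depth * exp(-(t - dip_center)^2 / (2 dip_width^2))`, giving a
#'   mid-lactation depression;
#' * `"flat"` — a constant level with a slight linear trend
#'   (`base_params = c(level, slope)`), the "no peak" shape.
#'
#' @param name archetype label.
#' @param base_model one of `"wood"`, `"dijkstra"`, `"flat"`,
#'   `"undulating"`.
#' @param base_params model parameters (Wood/undulating: a,b,c; Dijkstra:
#'   a,b,c,d; flat: level (L), slope (L/day)).
#' @param dip_center,dip_depth,dip_width undulating only: dip centre (days),
#'   fractional depth in `[0, 1)` and Gaussian width (days, > 0).
#' @return an object of class `"archetype_spec"`.
#' @seealso [default_archetypes()], [archetype_curve()]
#' @export
archetype_spec <- function(name, base_model, base_params,
                           dip_center = NULL, dip_depth = NULL,
                           dip_width = NULL) {
  base_model <- match.arg(base_model,
                          c("wood", "dijkstra", "flat", "undulating"))
  if (base_model %in% c("wood", "undulating")) {
    validate_lc_params("wood", base_params)
  } else if (base_model == "dijkstra") {
    validate_lc_params("dijkstra", base_params)
  } else {
    if (length(base_params) != 2 || base_params[1] <= 0) {
      stop("flat archetype needs base_params = c(level > 0, slope)",
           call. = FALSE)
    }
  }
  if (base_model == "undulating") {
    if (is.null(dip_center) || is.null(dip_depth) || is.null(dip_width)) {
      stop("undulating archetype needs dip_center, dip_depth and dip_width",
           call. = FALSE)
    }
    if (dip_depth < 0 || dip_depth >= 1) {
      stop("dip_depth must lie in [0, 1)", call. = FALSE)
    }
    if (dip_width <= 0) stop("dip_width must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, base_model = base_model,
         base_params = as.numeric(base_params),
         dip_center = dip_center, dip_depth = dip_depth,
         dip_width = dip_width),
    class = "archetype_spec"
  )
}

#' Evaluate an archetype's noiseless daily-yield curve
#'
#' @param spec an [archetype_spec()].
#' @param dim_grid integer days in milk, each within 0..500.  For the Wood
#'   and undulating forms, DIM 0 (undefined in the Wood equation) is
#'   evaluated at half a day in milk.
#' @return numeric vector of strictly positive yields (L).
#' @export
archetype_curve <- function(spec, dim_grid) {
  stopifnot(inherits(spec, "archetype_spec"))
  if (any(dim_grid < 0 | dim_grid > 500)) {
    stop("dim_grid must lie within 0..500", call. = FALSE)
  }
  t <- as.numeric(dim_grid)
  y <- switch(spec$base_model,
    wood = ,
    undulating = eval_lc("wood", spec$base_params, pmax(t, 0.5)),
    dijkstra = eval_lc("dijkstra", spec$base_params, t),
    flat = spec$base_params[1] + spec$base_params[2] * t
  )
  if (spec$base_model == "undulating") {
    y <- y * (1 - spec$dip_depth *
                exp(-(t - spec$dip_center)^2 / (2 * spec$dip_width^2)))
  }
  if (any(y <= 0)) {
    stop("archetype curve is not strictly positive on this grid",
         call. = FALSE)
  }
  y
}

#' Default herd archetypes
#'
#' Four shapes spanning what shape clustering of commercial herds
#' typically reveals: a typical multiparous curve (early high peak, steady
#' decline), a flat primiparous curve (late gentle peak, persistent), an
#' undulating curve with a mid-lactation dip after a high early plateau,
#' and a flat no-peak curve.  Parameter magnitudes are realistic for
#' Holstein daily yields in litres.
#'
#' @return named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    typical_multiparous = archetype_spec(
      "typical_multiparous", "wood", c(a = 24.6645, b = 0.2142, c = 0.0039)),
    flat_primiparous = archetype_spec(
      "flat_primiparous", "wood", c(a = 12.2953, b = 0.2743, c = 0.0018)),
    undulating_dip = archetype_spec(
      "undulating_dip", "undulating", c(a = 44.8198, b = 0.0170, c = 0.0016),
      dip_center = 160, dip_depth = 0.22, dip_width = 45),
    flat_no_peak = archetype_spec(
      "flat_no_peak", "flat", c(level = 36, slope = -0.004))
  )
}

#' Structured-missingness specification
#'
#' Controls how recorded days are deleted from each synthetic lactation.
#' Each mechanism is designed to trip one of the three exclusion rules of
#' [filter_lactations()]: a late recording start (first DIM > 10), a short
#' gap inside DIM 10-70, and a > 10-consecutive-day gap inside DIM 70-280.
#'
#' @param p_random_drop per-day independent drop probability.
#' @param p_late_start probability the record starts after DIM 10.
#' @param p_early_gap probability of a 1-5 day gap inside DIM 10-70.
#' @param p_long_gap probability of a long gap inside DIM 70-280.
#' @param gap_length_range length range (days) of the long gap; the lower
#'   bound must exceed 10 so the gap is guaranteed to trigger exclusion.
#' @return an object of class `"missingness_spec"`.
#' @export
missingness_spec <- function(p_random_drop = 0, p_late_start = 0,
                             p_early_gap = 0, p_long_gap = 0,
                             gap_length_range = c(11, 25)) {
  p <- c(p_random_drop, p_late_start, p_early_gap, p_long_gap)
  if (any(p < 0 | p > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(gap_length_range) != 2 || gap_length_range[1] <= 10 ||
      gap_length_range[2] < gap_length_range[1]) {
    stop("gap_length_range must be an increasing pair with lower bound > 10",
         call. = FALSE)
  }
  structure(
    list(p_random_drop = p_random_drop, p_late_start = p_late_start,
         p_early_gap = p_early_gap, p_long_gap = p_long_gap,
         gap_length_range = as.integer(gap_length_range)),
    class = "missingness_spec"
  )
}

#' Default missingness: roughly the exclusion pressure of robot-milking data
#' where most losses are long mid-lactation gaps (sensor outages, early
#' dry-off) rather than isolated missing days.
#' @rdname missingness_spec
#' @export
default_missingness <- function() {
  missingness_spec(p_random_drop = 0, p_late_start = 0.17,
                   p_early_gap = 0.03, p_long_gap = 0.55,
                   gap_length_range = c(11, 25))
}

#' Synthetic herd specification
#'
#' @param n_lactations number of animal-lactations to simulate.
#' @param archetype_mix named list of archetypes ([archetype_spec()]) with a
#'   parallel `proportions` vector summing to 1.
#' @param proportions mixing proportions, one per archetype.
#' @param parity_dist matrix (archetype x parity class 1..4, rows summing to
#'   1) giving the parity distribution per archetype; parity class 4 means
#'   "4 or more".  Defaults skew the flat archetypes primiparous and the
#'   typical archetype multiparous.
#' @param noise_cv multiplicative noise: each day's yield is multiplied by
#'   `1 + e`, `e ~ N(0, noise_cv^2)` (heteroscedastic, like raw milking
#'   data).
#' @param noise_sd additive Gaussian noise SD (L), applied after the
#'   multiplicative term.
#' @param dim_range `c(first, last)` recorded DIM; the actual last recorded
#'   day of each lactation is drawn uniformly from `last +/- 30` days.
#' @param seed integer RNG seed; fixing it makes [generate_herd()] fully
#'   deterministic.
#' @return an object of class `"herd_spec"`.
#' @export
herd_spec <- function(n_lactations = 330,
                      archetype_mix = default_archetypes(),
                      proportions = c(0.45, 0.25, 0.20, 0.10),
                      parity_dist = NULL,
                      noise_cv = 0.05, noise_sd = 0,
                      dim_range = c(0, 360), seed = 1L) {
  if (n_lactations < 0) stop("n_lactations must be >= 0", call. = FALSE)
  if (length(proportions) != length(archetype_mix)) {
    stop("one proportion per archetype required", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (noise_cv < 0 || noise_sd < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (is.null(parity_dist)) {
    parity_dist <- default_parity_dist(names(archetype_mix))
  }
  if (nrow(parity_dist) != length(archetype_mix) ||
      any(abs(rowSums(parity_dist) - 1) > 1e-8)) {
    stop("parity_dist needs one row per archetype, each summing to 1",
         call. = FALSE)
  }
  structure(
    list(n_lactations = as.integer(n_lactations),
         archetype_mix = archetype_mix,
         proportions = as.numeric(proportions),
         parity_dist = parity_dist,
         noise_cv = noise_cv, noise_sd = noise_sd,
         dim_range = as.integer(dim_range), seed = as.integer(seed)),
    class = "herd_spec"
  )
}

default_parity_dist <- function(archetype_names) {
  n <- length(archetype_names)
  # primiparous-heavy for flat shapes, multiparous-heavy for typical ones
  base <- matrix(0.25, n, 4, dimnames = list(archetype_names, 1:4))
  for (i in seq_len(n)) {
    base[i, ] <- if (grepl("primi|no_peak", archetype_names[i])) {
      c(0.70, 0.20, 0.07, 0.03)
    } else if (grepl("typical", archetype_names[i])) {
      c(0.15, 0.35, 0.30, 0.20)
    } else {
      c(0.30, 0.30, 0.25, 0.15)
    }
  }
  base
}

#' Generate a synthetic herd of daily milking records
#'
#' Each lactation is an archetype curve (drawn from the herd's archetype
#' mix) evaluated daily from `dim_range[1]` to a lactation-specific last
#' day, perturbed by noise, with days deleted by the missingness
#' mechanisms.  A ground-truth table records each lactation's archetype and
#' which missingness mechanisms were injected, so downstream filtering and
#' clustering can be validated against known labels.
#'
#' @param herd a [herd_spec()].
#' @param missing a [missingness_spec()]; defaults to no missingness.
#' @return list with `records` (list of lactation records: `animal_id`,
#'   `parity`, `dim`, `yield`) and `truth` (data.frame: `animal_id`,
#'   `parity`, `archetype`, `missingness_tags`, semicolon-separated).
#' @examples
#' h <- herd_spec(n_lactations = 5, noise_cv = 0, seed = 42)
#' herd <- generate_herd(h, missingness_spec())
#' length(herd$records)
#' @export
generate_herd <- function(herd, missing = missingness_spec()) {
  stopifnot(inherits(herd, "herd_spec"), inherits(missing, "missingness_spec"))
  set.seed(herd$seed)
  n <- herd$n_lactations
  if (n == 0) {
    return(list(records = list(),
                truth = data.frame(animal_id = character(),
                                   parity = integer(),
                                   archetype = character(),
                                   missingness_tags = character(),
                                   stringsAsFactors = FALSE)))
  }
  arch_names <- names(herd$archetype_mix)
  arch_idx <- sample.int(length(arch_names), n, replace = TRUE,
                         prob = herd$proportions)
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    a <- arch_idx[i]
    spec <- herd$archetype_mix[[a]]
    parity <- sample.int(4, 1, prob = herd$parity_dist[a, ])
    last_dim <- round(stats::runif(1, herd$dim_range[2] - 30,
                                   herd$dim_range[2] + 30))
    dim <- herd$dim_range[1]:last_dim
    y <- archetype_curve(spec, dim)
    if (herd$noise_cv > 0) {
      y <- y * (1 + stats::rnorm(length(y), 0, herd$noise_cv))
    }
    if (herd$noise_sd > 0) {
      y <- y + stats::rnorm(length(y), 0, herd$noise_sd)
    }
    y <- pmax(y, 0)

    tags <- character(0)
    keep <- rep(TRUE, length(dim))
    if (missing$p_random_drop > 0) {
      drop <- stats::runif(length(dim)) < missing$p_random_drop
      if (any(drop)) {
        keep[drop] <- FALSE
        tags <- c(tags, "random_drop")
      }
    }
    if (stats::runif(1) < missing$p_late_start) {
      start <- sample(11:30, 1)
      keep[dim < start] <- FALSE
      tags <- c(tags, "late_start")
    }
    if (stats::runif(1) < missing$p_early_gap) {
      len <- sample(1:5, 1)
      g0 <- sample(12:(65 - len), 1)
      keep[dim >= g0 & dim < g0 + len] <- FALSE
      tags <- c(tags, "early_gap")
    }
    if (stats::runif(1) < missing$p_long_gap) {
      len <- sample(missing$gap_length_range[1]:missing$gap_length_range[2], 1)
      g0 <- sample(75:(275 - len), 1)
      keep[dim >= g0 & dim < g0 + len] <- FALSE
      tags <- c(tags, "long_gap")
    }

    id <- sprintf("cow%04d", i)
    records[[i]] <- list(animal_id = id, parity = parity,
                         dim = dim[keep], yield = y[keep])
    truth[[i]] <- data.frame(animal_id = id, parity = parity,
                             archetype = spec$name,
                             missingness_tags = paste(tags, collapse = ";"),
                             stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Read and write long-format milking-record CSVs
#'
#' The on-disk format is one row per animal-lactation-day with columns
#' `animal_id`, `parity`, `dim`, `yield_l`.  `read_records_csv()` validates
#' every row (finite non-negative yield, non-negative integer DIM, positive
#' integer parity, no duplicate DIM within a lactation) and reports the
#' 1-based file line number of the first offending row.
#'
#' @param records list of lactation records (see [generate_herd()]).
#' @param path CSV file path.
#' @return `read_records_csv()` returns the list of lactation records in
#'   first-appearance order; `write_records_csv()` returns `path`
#'   invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- records_to_df(records)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "parity", "dim", "yield_l")
  if (!all(need %in% names(df))) {
    stop(sprintf("records CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) return(list())
  bad <- !is.finite(df$yield_l) | df$yield_l < 0 |
    !is.finite(df$dim) | df$dim < 0 | df$dim != floor(df$dim) |
    !is.finite(df$parity) | df$parity < 1
  if (any(bad)) {
    stop(sprintf("invalid record at line %d of %s",
                 which(bad)[1] + 1L, path), call. = FALSE)
  }
  df_to_records(df, path = path)
}

records_to_df <- function(records) {
  if (length(records) == 0) {
    return(data.frame(animal_id = character(), parity = integer(),
                      dim = integer(), yield_l = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(animal_id = r$animal_id, parity = r$parity,
               dim = r$dim, yield_l = r$yield, stringsAsFactors = FALSE)
  }))
}

df_to_records <- function(df, path = "<data.frame>") {
  key <- paste(df$animal_id, df$parity, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(ix) {
    sub <- df[ix, ]
    if (anyDuplicated(sub$dim)) {
      dup <- ix[duplicated(sub$dim)][1]
      stop(sprintf("duplicate DIM within a lactation at line %d of %s",
                   dup + 1L, path), call. = FALSE)
    }
    o <- order(sub$dim)
    list(animal_id = sub$animal_id[1], parity = sub$parity[1],
         dim = as.integer(sub$dim[o]), yield = as.numeric(sub$yield_l[o]))
  })
  names(out) <- NULL
  out
}
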