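#' Default analysis window: days in milk 10 to 280 inclusive (271 points).
#' Records before DIM 10 and after DIM 280 are error-prone on commercial
#' farms and are dropped before any analysis.
#' @return integer vector `10:280`.
#' @export
dim_grid <- function() 10:280

#' Exclusion rules for incomplete lactations
#'
#' Applies three sequential exclusion rules to a set of lactation records
#' and trims survivors to the DIM 10-280 analysis window:
#'
#' * **Type-I** — recording started late: no observed yield at any
#'   DIM <= 10.
#' * **Type-II** — among Type-I survivors: at least one missing day in
#'   DIM 10-70.  The early window must be gap-free because it contains the
#'   peak, which interpolation would distort.
#' * **Type-III** — among survivors: a run of more than 10 consecutive
#'   missing days anywhere in DIM 70-280 (a lactation whose last record
#'   precedes DIM 270 necessarily fails).
#'
#' Rules fire in order I, II, III and each rejected lactation carries
#' exactly one reason — the first rule violated.
#'
#' @param records list of lactation records (see [generate_herd()] /
#'   [read_records_csv()]).
#' @return an object of class `"filter_report"`: list with `kept` (records
#'   trimmed to the window), `rejected` (list of `list(record, reason)`),
#'   `counts` (named: kept, TYPE_I, TYPE_II, TYPE_III) and `n_input`.
#' @export
filter_lactations <- function(records) {
  grid <- dim_grid()
  kept <- list()
  rejected <- list()
  counts <- c(kept = 0L, TYPE_I = 0L, TYPE_II = 0L, TYPE_III = 0L)
  for (r in records) {
    reason <- classify_lactation(r$dim)
    if (is.na(reason)) {
      inside <- r$dim >= 10 & r$dim <= 280
      rt <- r
      rt$dim <- r$dim[inside]
      rt$yield <- r$yield[inside]
      kept[[length(kept) + 1L]] <- rt
      counts["kept"] <- counts["kept"] + 1L
    } else {
      rejected[[length(rejected) + 1L]] <- list(record = r, reason = reason)
      counts[reason] <- counts[reason] + 1L
    }
  }
  structure(
    list(kept = kept, rejected = rejected, counts = counts,
         n_input = length(records)),
    class = "filter_report"
  )
}

# First rule violated (in order I -> II -> III), or NA if the record passes.
classify_lactation <- function(dim) {
  if (!any(dim <= 10)) return("TYPE_I")
  if (length(setdiff(10:70, dim)) > 0) return("TYPE_II")
  present <- 70:280 %in% dim
  runs <- rle(!present)
  if (any(runs$lengths[runs$values] > 10)) return("TYPE_III")
  NA_character_
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Lactation filter: %d in, %d kept | Type-I %d, Type-II %d, Type-III %d\n",
              x$n_input, x$counts["kept"], x$counts["TYPE_I"],
              x$counts["TYPE_II"], x$counts["TYPE_III"]))
  invisible(x)
}

#' @rdname filter_lactations
#' @return `filter_report_df()` returns the report as a data.frame with
#'   columns `animal_id`, `parity`, `status`, `reason`.
#' @param report a `"filter_report"`.
#' @export
filter_report_df <- function(report) {
  rows <- c(
    lapply(report$kept, function(r) {
      data.frame(animal_id = r$animal_id, parity = r$parity,
                 status = "kept", reason = "", stringsAsFactors = FALSE)
    }),
    lapply(report$rejected, function(e) {
      data.frame(animal_id = e$record$animal_id, parity = e$record$parity,
                 status = "rejected", reason = e$reason,
                 stringsAsFactors = FALSE)
    })
  )
  if (length(rows) == 0) {
    return(data.frame(animal_id = character(), parity = integer(),
                      status = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Fill gaps in a filter-passing lactation by linear interpolation
#'
#' Interior missing days on the DIM 10-280 grid are filled linearly between
#' the nearest flanking observations; trailing missing days (at most 10 by
#' the Type-III guarantee) are filled by carrying the last observed value
#' forward.  The filter rules guarantee DIM 10-70 is complete, so no
#' leading extrapolation is ever needed.
#'
#' @param record a lactation record that passed [filter_lactations()].
#' @return numeric vector of yields on the 271-point grid `10:280`.
#' @export
interpolate_gaps <- function(record) {
  grid <- dim_grid()
  inside <- record$dim >= 10 & record$dim <= 280
  d <- record$dim[inside]
  y <- record$yield[inside]
  if (!is.na(classify_lactation(record$dim))) {
    stop("record violates the filter guarantees; run filter_lactations() first",
         call. = FALSE)
  }
  # rule = 2: constant extrapolation = carry-forward for the <=10-day tail
  stats::approx(d, y, xout = grid, method = "linear", rule = 2, ties = "ordered")$y
}

#' Moving-average smoothing
#'
#' Centered moving average with a `window`-day span (offsets -4..+5 around
#' each day for the default 10-day window), truncated at the grid
#' boundaries: each output point is the mean of the in-window points that
#' exist.  Output length equals input length.
#'
#' @param series gap-free numeric series.
#' @param window window width in days (>= 1).
#' @return smoothed series, same length.
#' @export
moving_average <- function(series, window = 10) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- length(series)
  lo_off <- -floor((window - 1) / 2)
  hi_off <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, series))
  idx <- seq_len(n)
  lo <- pmax(1L, idx + lo_off)
  hi <- pmin(n, idx + hi_off)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Z-score transformation of a curve
#'
#' Standardizes a series to mean 0, SD 1 using the population SD (divide by
#' N).  Z-normalization puts curves of different production levels on a
#' common scale so distances compare shape rather than volume.
#'
#' @param series numeric series with positive spread.
#' @return standardized series.
#' @export
znormalize <- function(series) {
  m <- mean(series)
  s <- sqrt(mean((series - m)^2))
  if (!is.finite(s) || s <= 0) {
    stop("degenerate (constant) curve cannot be Z-normalized", call. = FALSE)
  }
  (series - m) / s
}

#' Build the aligned curve matrix from filter-passing records
#'
#' Runs the preprocessing pipeline per lactation — interpolate gaps, smooth
#' with the moving average, Z-normalize — and stacks the results.  Model
#' fitting consumes the original-unit curves (`raw`/`smoothed`); clustering
#' consumes the Z-normalized ones.  Degenerate (constant) curves cannot be
#' Z-normalized and are dropped with a warning.
#'
#' @param records filter-passing lactation records.
#' @param window smoothing window in days.
#' @return an object of class `"curve_matrix"`: list with `grid` (10:280),
#'   `raw`, `smoothed`, `znorm` (each n x 271), `ids`, `parities`.
#' @export
build_curve_matrix <- function(records, window = 10) {
  if (length(records) == 0) stop("no records to build a curve matrix from",
                                 call. = FALSE)
  grid <- dim_grid()
  raw <- t(vapply(records, interpolate_gaps, numeric(length(grid))))
  smoothed <- t(apply(raw, 1, moving_average, window = window))
  sds <- apply(smoothed, 1, function(x) sqrt(mean((x - mean(x))^2)))
  ok <- sds > 0
  if (!all(ok)) {
    warning(sprintf("dropping %d degenerate (constant) curve(s)", sum(!ok)))
  }
  if (!any(ok)) stop("all curves are degenerate; empty curve matrix",
                     call. = FALSE)
  raw <- raw[ok, , drop = FALSE]
  smoothed <- smoothed[ok, , drop = FALSE]
  znorm <- t(apply(smoothed, 1, znormalize))
  ids <- vapply(records, `[[`, character(1), "animal_id")[ok]
  parities <- vapply(records, function(r) as.integer(r$parity),
                     integer(1))[ok]
  structure(
    list(grid = grid, raw = raw, smoothed = smoothed, znorm = znorm,
         ids = ids, parities = parities),
    class = "curve_matrix"
  )
}

#' @export
print.curve_matrix <- function(x, ...) {
  cat(sprintf("curve_matrix: %d lactations on DIM %d..%d (%d points)\n",
              nrow(x$raw), min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}
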