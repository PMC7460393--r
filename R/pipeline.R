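#' Pipeline configuration
#'
#' Bundles every option of the end-to-end analysis so a run can be
#' reproduced from its manifest alone.
#'
#' @param out_dir output directory (created if needed).
#' @param input_csv optional existing records CSV; when `NULL` the
#'   synthetic herd defined by `herd`/`missing` is simulated first.
#' @param herd a [herd_spec()] used by [pipeline_simulate()].
#' @param missing a [missingness_spec()].
#' @param window smoothing window (days).
#' @param k fixed number of clusters, or `NULL` to select by
#'   [elbow_select_k()] over `k_range`.
#' @param k_range candidate cluster numbers for the elbow (used when `k`
#'   is `NULL`).
#' @param restarts,max_iter k-medoids settings.
#' @param models model families to fit to each representative curve.
#' @param tf lactation length (days) for the persistency midpoint.
#' @param alpha significance level for the summary letters.
#' @param seed master integer seed for the whole run.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, input_csv = NULL, herd = herd_spec(),
                            missing = default_missingness(), window = 10,
                            k = NULL, k_range = 2:10, restarts = 10,
                            max_iter = 100, models = LC_MODELS, tf = 280,
                            alpha = 0.05, seed = 1L) {
  if (!is.null(k) && k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.null(k) && length(k_range) < 3) {
    stop("either fix k or give a k_range of at least 3 values",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  models <- match.arg(models, LC_MODELS, several.ok = TRUE)
  structure(
    list(out_dir = out_dir, input_csv = input_csv, herd = herd,
         missing = missing, window = window, k = k, k_range = k_range,
         restarts = restarts, max_iter = max_iter, models = models,
         tf = tf, alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

out_path <- function(config, ...) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  file.path(config$out_dir, ...)
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's CSV artefacts from
#' `config$out_dir` and writes its own, so stages can be re-run and
#' inspected independently:
#'
#' * `pipeline_simulate()` — `records.csv`, `truth.csv` (synthetic herd;
#'   skipped when `config$input_csv` points at real data).
#' * `pipeline_preprocess()` — `filter_report.csv`, `curves_raw.csv`,
#'   `curves_smoothed.csv`, `curves_znorm.csv`.
#' * `pipeline_cluster()` — `labels.csv`, `medoids.csv`, and
#'   `elbow_profile.csv` when k is selected automatically.
#' * `pipeline_characterize()` — `model_fits.csv` (parameters, SEs,
#'   convergence, epsilon_f, epsilon_c), `features.csv` (closed-form peak
#'   and persistency per cluster and for the whole dataset),
#'   `cluster_summary.csv`.
#' * `pipeline_run_all()` — all of the above plus `manifest.json` (seed
#'   and options), returning the collected in-memory results invisibly.
#'
#' @param config a [pipeline_config()].
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config) {
  herd <- generate_herd(config$herd, config$missing)
  write_records_csv(herd$records, out_path(config, "records.csv"))
  utils::write.csv(herd$truth, out_path(config, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(herd)
}

#' @rdname pipeline
#' @export
pipeline_preprocess <- function(config) {
  src <- if (is.null(config$input_csv)) {
    out_path(config, "records.csv")
  } else config$input_csv
  if (!file.exists(src)) {
    stop(sprintf("missing input file: %s (run pipeline_simulate() first?)",
                 src), call. = FALSE)
  }
  records <- read_records_csv(src)
  report <- filter_lactations(records)
  utils::write.csv(filter_report_df(report),
                   out_path(config, "filter_report.csv"),
                   row.names = FALSE, quote = FALSE)
  cm <- build_curve_matrix(report$kept, window = config$window)
  for (layer in c("raw", "smoothed", "znorm")) {
    df <- as.data.frame(cm[[layer]])
    names(df) <- paste0("dim_", cm$grid)
    df <- cbind(data.frame(animal_id = cm$ids, parity = cm$parities), df)
    utils::write.csv(df, out_path(config, paste0("curves_", layer, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(report = report, curves = cm))
}

read_curve_layer <- function(config, layer) {
  path <- out_path(config, paste0("curves_", layer, ".csv"))
  if (!file.exists(path)) {
    stop(sprintf("missing input file: %s (run pipeline_preprocess() first?)",
                 path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(ids = df$animal_id, parities = df$parity,
       mat = as.matrix(df[, grep("^dim_", names(df)), drop = FALSE]))
}

#' @rdname pipeline
#' @export
pipeline_cluster <- function(config) {
  zn <- read_curve_layer(config, "znorm")
  D <- pairwise_distances(zn$mat)
  k <- config$k
  if (is.null(k)) {
    prof <- elbow_select_k(D, k_range = config$k_range, seed = config$seed,
                           max_iter = config$max_iter,
                           restarts = config$restarts)
    utils::write.csv(data.frame(k = prof$k, objective = prof$objective,
                                chord_distance = prof$distance),
                     out_path(config, "elbow_profile.csv"),
                     row.names = FALSE, quote = FALSE)
    k <- prof$chosen_k
  }
  res <- kmedoids(D, k, seed = config$seed, max_iter = config$max_iter,
                  restarts = config$restarts)
  utils::write.csv(data.frame(animal_id = zn$ids, parity = zn$parities,
                              cluster = res$labels),
                   out_path(config, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(cluster = seq_len(res$k),
                              medoid_row = res$medoid_indices,
                              medoid_animal_id = zn$ids[res$medoid_indices]),
                   out_path(config, "medoids.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(res)
}

#' @rdname pipeline
#' @export
pipeline_characterize <- function(config) {
  sm <- read_curve_layer(config, "smoothed")
  raw <- read_curve_layer(config, "raw")
  lab_path <- out_path(config, "labels.csv")
  if (!file.exists(lab_path)) {
    stop(sprintf("missing input file: %s (run pipeline_cluster() first?)",
                 lab_path), call. = FALSE)
  }
  labels <- utils::read.csv(lab_path, stringsAsFactors = FALSE)$cluster
  grid <- dim_grid()
  ks <- sort(unique(labels))
  groups <- c(stats::setNames(as.list(ks), paste0("cluster_", ks)),
              list(total = NULL))

  fit_rows <- list(); feat_rows <- list()
  for (gname in names(groups)) {
    members <- if (is.null(groups[[gname]])) sm$mat else
      sm$mat[labels == groups[[gname]], , drop = FALSE]
    rep_curve <- representative_curve(members)
    for (model in config$models) {
      fit <- fit_lc(model, grid, rep_curve)
      ef <- epsilon_f(fit, rep_curve, grid)
      ec <- epsilon_c(fit, members, grid)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        group = gname, model = model,
        param = names(fit$params), estimate = unname(fit$params),
        se = unname(fit$se), at_bound = unname(fit$boundary),
        converged = fit$converged, residual_rmse = fit$residual_rmse,
        eps_f = ef, eps_c = ec, stringsAsFactors = FALSE)
      if (model %in% c("wood", "dijkstra")) {
        ft <- lc_features(model, fit$params, tf = config$tf)
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          group = gname, model = model,
          peak_yield_l = ft$peak_yield, peak_dim_days = ft$peak_dim,
          persistency = ft$persistency, computable = ft$computable,
          stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, fit_rows),
                   out_path(config, "model_fits.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, feat_rows),
                   out_path(config, "features.csv"),
                   row.names = FALSE, quote = FALSE)

  cm <- structure(list(grid = grid, raw = raw$mat, smoothed = sm$mat,
                       znorm = NULL, ids = sm$ids, parities = sm$parities),
                  class = "curve_matrix")
  summ <- cluster_summary(cm, labels, alpha = config$alpha)
  utils::write.csv(summ, out_path(config, "cluster_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(fits = do.call(rbind, fit_rows),
                 features = do.call(rbind, feat_rows), summary = summ))
}

#' @rdname pipeline
#' @export
pipeline_run_all <- function(config) {
  t0 <- Sys.time()
  if (is.null(config$input_csv)) pipeline_simulate(config)
  pre <- pipeline_preprocess(config)
  clus <- pipeline_cluster(config)
  char <- pipeline_characterize(config)
  manifest <- list(
    seed = config$seed,
    k = clus$k,
    window = config$window,
    tf = config$tf,
    alpha = config$alpha,
    restarts = config$restarts,
    n_kept = as.integer(pre$report$counts["kept"]),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("lactoclust")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(preprocess = pre, clustering = clus,
                 characterization = char, manifest = manifest))
}
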