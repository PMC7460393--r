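#' Root-mean-square Euclidean distance between two curves
#'
#' `d(A,B) = sqrt( (1/N) * sum_i (m_Ai - m_Bi)^2 )` over the N aligned
#' days.  The 1/N factor makes distances comparable across grids of
#' different lengths; on Z-normalized curves the units are Z-score units
#' per day.
#'
#' @param a,b numeric curves of equal length N >= 1.
#' @return non-negative scalar.
#' @examples
#' distance_rms(c(1, 1, 1, 1), c(3, 3, 3, 3)) # 2
#' @export
distance_rms <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop("curves must have equal positive length", call. = FALSE)
  }
  sqrt(mean((a - b)^2))
}

#' All pairwise RMS-Euclidean distances
#'
#' @param x numeric matrix, one curve per row (typically
#'   `curve_matrix$znorm`).
#' @return n x n symmetric matrix with zero diagonal; entry (i, j) is
#'   [distance_rms()] of rows i and j.
#' @export
pairwise_distances <- function(x) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x, method = "euclidean")) / sqrt(ncol(x))
  dimnames(d) <- NULL
  d
}

#' Squared-distance-weighted medoid initialization
#'
#' k-means++-style seeding on a precomputed distance matrix: the first
#' medoid is uniform over all points; each subsequent medoid is drawn with
#' probability proportional to `D(x)^2`, where `D(x)` is the distance from
#' `x` to its nearest already-chosen medoid.  Points coinciding with a
#' chosen medoid have probability zero unless every remaining point does,
#' in which case the draw is uniform over the remainder.  This spreads the
#' initial medoids and speeds convergence.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param k number of medoids, `1 <= k <= n`.
#' @return integer vector of k distinct row indices.
#' @export
init_medoids <- function(D, k) {
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  chosen <- sample.int(n, 1)
  while (length(chosen) < k) {
    dmin <- apply(D[, chosen, drop = FALSE], 1, min)
    dmin[chosen] <- 0
    w <- dmin^2
    nxt <- if (sum(w) > 0) {
      sample.int(n, 1, prob = w)
    } else {
      rem <- setdiff(seq_len(n), chosen)
      rem[sample.int(length(rem), 1)]
    }
    chosen <- c(chosen, nxt)
  }
  chosen
}

#' k-medoids clustering of lactation-curve shapes
#'
#' Partitions n curves into k clusters by alternating (Voronoi-style)
#' k-medoids on a precomputed RMS-Euclidean distance matrix, minimising the
#' objective `sum_clusters sum_members d(X, medoid)`.  Medoids are actual
#' dataset members, which makes the centres robust to the outlier curves
#' common in raw milking data.
#'
#' Each iteration assigns every point to its nearest medoid (ties to the
#' lowest medoid index) and then replaces each cluster's medoid with the
#' member minimising the sum of within-cluster distances (ties to the
#' lowest index).  The objective never increases; iteration stops when the
#' medoid set is stable or after `max_iter` sweeps.  The best of `restarts`
#' squared-distance-weighted initializations ([init_medoids()]) is
#' returned, ties to the earliest restart.  If a cluster empties after
#' assignment its medoid is re-seeded with the point farthest from its own
#' medoid.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed optional integer seed fixed before the restarts for full
#'   reproducibility.
#' @param max_iter maximum assignment/update sweeps per restart.
#' @param restarts number of random initializations (ignored when `init`
#'   is supplied).
#' @param init optional explicit initial medoid indices (length k); runs a
#'   single deterministic restart from them.
#' @return an object of class `"kmedoids_result"`: list with `k`, `labels`
#'   (cluster index per curve, clusters numbered by medoid order),
#'   `medoid_indices`, `objective`, `n_iter`, `restarts`, `seed`.
#' @export
kmedoids <- function(D, k, seed = NULL, max_iter = 100, restarts = 10,
                     init = NULL) {
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  n_restarts <- if (is.null(init)) restarts else 1L
  for (r in seq_len(n_restarts)) {
    med0 <- if (is.null(init)) init_medoids(D, k) else as.integer(init)
    run <- kmedoids_single(D, med0, max_iter)
    if (is.null(best) || run$objective < best$objective - 1e-15) {
      best <- run
    }
  }
  structure(
    list(k = k, labels = best$labels, medoid_indices = best$medoids,
         objective = best$objective, n_iter = best$n_iter,
         restarts = n_restarts, seed = seed),
    class = "kmedoids_result"
  )
}

# One restart of the alternating assign/update scheme.
kmedoids_single <- function(D, medoids, max_iter) {
  n <- nrow(D)
  k <- length(medoids)
  prev_obj <- Inf
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    # assignment: nearest medoid, ties to the lowest medoid index
    dm <- D[, medoids, drop = FALSE]
    labels <- max.col(-dm, ties.method = "first")
    # re-seed any empty cluster with the farthest-from-its-medoid point not
    # already serving as a medoid; with fewer distinct points than clusters
    # (duplicate data) the cluster stays empty and contributes nothing
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        dmin <- apply(dm, 1, min)
        cand <- setdiff(order(dmin, decreasing = TRUE), medoids)
        if (length(cand) == 0) next
        far <- cand[1]
        medoids[j] <- far
        labels[far] <- j
        dm[, j] <- D[, far]
        message("k-medoids: empty cluster re-seeded")
      }
    }
    obj <- sum(dm[cbind(seq_len(n), labels)])
    if (obj > prev_obj + 1e-12) {
      stop("internal error: k-medoids objective increased", call. = FALSE)
    }
    prev_obj <- obj
    # update: member minimising the sum of within-cluster distances
    new_medoids <- medoids
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members) == 0) next
      sums <- colSums(D[members, members, drop = FALSE])
      new_medoids[j] <- members[which.min(sums)]
    }
    if (identical(sort(new_medoids), sort(medoids))) {
      medoids <- new_medoids
      break
    }
    medoids <- new_medoids
  }
  dm <- D[, medoids, drop = FALSE]
  labels <- max.col(-dm, ties.method = "first")
  objective <- sum(dm[cbind(seq_len(n), labels)])
  list(labels = labels, medoids = medoids, objective = objective,
       n_iter = iter)
}

#' Recompute a clustering objective from labels and medoids
#' @param D distance matrix; @param result a `"kmedoids_result"`.
#' @return the objective value `sum_i D[i, medoid(label_i)]`.
#' @export
kmedoids_objective <- function(D, result) {
  sum(D[cbind(seq_len(nrow(D)), result$medoid_indices[result$labels])])
}

#' @export
print.kmedoids_result <- function(x, ...) {
  cat(sprintf("k-medoids: k = %d, objective = %.6g, %d iteration(s), %d restart(s)\n",
              x$k, x$objective, x$n_iter, x$restarts))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Elbow-method selection of the number of clusters
#'
#' Runs [kmedoids()] for each k in `k_range`, records the best objective
#' J(k), and picks the elbow automatically by the chord rule: after
#' min-max scaling both axes to `[0, 1]`, the chosen k maximises the
#' perpendicular distance of (k, J(k)) from the straight line joining the
#' first and last profile points.  For a profile with no curvature
#' (J linear in k) every distance is ~0 and the smallest k is returned.
#' The full profile is returned so the choice can be overridden by eye,
#' which is how the elbow is used in practice.
#'
#' @param x curve matrix (rows = curves; typically `curve_matrix$znorm`) or
#'   a precomputed square distance matrix.
#' @param k_range candidate cluster counts (at least 3 values).
#' @param seed optional integer seed; each k is run with seed `seed + k` so
#'   profiles are reproducible.
#' @inheritParams kmedoids
#' @return an object of class `"elbow_profile"`: list with `k`, `objective`
#'   (J(k)), `chosen_k`, `distance` (scaled chord distances), `restarts`,
#'   `seed`.
#' @export
elbow_select_k <- function(x, k_range = 2:10, seed = NULL, max_iter = 100,
                           restarts = 10) {
  if (length(k_range) < 3) {
    stop("k_range must contain at least 3 values", call. = FALSE)
  }
  x <- as.matrix(x)
  D <- if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-12 &&
           all(abs(diag(x)) < 1e-12)) x else pairwise_distances(x)
  if (max(k_range) > nrow(D)) {
    stop("max(k_range) exceeds the number of curves", call. = FALSE)
  }
  k_range <- sort(as.integer(k_range))
  J <- vapply(k_range, function(k) {
    kmedoids(D, k, seed = if (is.null(seed)) NULL else seed + k,
             max_iter = max_iter, restarts = restarts)$objective
  }, numeric(1))
  # chord rule on min-max scaled axes
  kx <- (k_range - min(k_range)) / max(diff(range(k_range)), 1)
  jy <- if (diff(range(J)) > 0) (J - min(J)) / diff(range(J)) else J * 0
  p1 <- c(kx[1], jy[1])
  p2 <- c(kx[length(kx)], jy[length(jy)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  dist <- if (nv == 0) rep(0, length(kx)) else {
    abs(v[2] * (kx - p1[1]) - v[1] * (jy - p1[2])) / nv
  }
  chosen <- k_range[which.max(dist > max(dist) - 1e-12)]
  structure(
    list(k = k_range, objective = J, chosen_k = chosen, distance = dist,
         restarts = restarts, seed = seed),
    class = "elbow_profile"
  )
}

#' @export
print.elbow_profile <- function(x, ...) {
  cat("Elbow profile (chosen k =", x$chosen_k, ")\n")
  print(data.frame(k = x$k, objective = round(x$objective, 4),
                   chord_distance = round(x$distance, 4)))
  invisible(x)
}
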