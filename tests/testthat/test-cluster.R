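test_that("RMS distance matches its definition and a brute-force oracle", {
  expect_equal(distance_rms(c(1, 1, 1, 1), c(3, 3, 3, 3)), 2)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(271); b <- rnorm(271)
    expect_equal(distance_rms(a, b), brute_rms(a, b), tolerance = 1e-12)
    expect_equal(distance_rms(a, a), 0)
  }
  expect_error(distance_rms(1:3, 1:4), "equal")
})

test_that("pairwise distance matrix is a metric and matches the loop oracle", {
  set.seed(12)
  x <- matrix(rnorm(10 * 40), 10)
  x[7, ] <- x[2, ]  # planted duplicate row
  D <- pairwise_distances(x)
  expect_equal(dim(D), c(10, 10))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 10))
  expect_equal(D[2, 7], 0)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D[i, j], brute_rms(x[i, ], x[j, ]), tolerance = 1e-12)
  }
  # triangle inequality (RMS-Euclidean is a metric)
  for (i in 1:10) for (j in 1:10) for (l in 1:10) {
    expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-9)
  }
  expect_equal(pairwise_distances(matrix(1:5, 1)), matrix(0, 1, 1))
})

test_that("weighted initialization: uniform first draw, zero mass on chosen points", {
  set.seed(13)
  x <- matrix(rnorm(10 * 5), 10)
  D <- pairwise_distances(x)
  # k = 1 is a uniform draw over the n points
  draws <- replicate(10000, init_medoids(D, 1))
  freq <- tabulate(draws, 10) / 10000
  expect_true(all(abs(freq - 0.1) < 3 * sqrt(0.1 * 0.9 / 10000)))

  # a duplicate of a chosen center has squared-distance weight zero
  x2 <- rbind(x[1, ], x[1, ], x[1, ] + 100)
  D2 <- pairwise_distances(x2)
  for (i in 1:50) {
    m <- init_medoids(D2, 2)
    expect_false(all(m %in% 1:2))  # second pick is never the duplicate
  }

  # unless every remaining point is a duplicate: then uniform over the rest
  x3 <- rbind(x[1, ], x[1, ], x[1, ])
  m3 <- init_medoids(pairwise_distances(x3), 3)
  expect_equal(sort(m3), 1:3)
  expect_error(init_medoids(D, 11), "k must")
})

test_that("second initial center lands in the opposite of two far blobs", {
  set.seed(14)
  blob1 <- matrix(rnorm(6 * 4, 0, 0.1), 6)
  blob2 <- matrix(rnorm(6 * 4, 100, 0.1), 6)
  D <- pairwise_distances(rbind(blob1, blob2))
  opposite <- replicate(200, {
    m <- init_medoids(D, 2)
    (m[1] <= 6) != (m[2] <= 6)
  })
  expect_true(all(opposite))
})

test_that("k-medoids separates planted blobs and handles degenerate k", {
  set.seed(15)
  blobs <- rbind(matrix(rnorm(6 * 8, 0, 0.3), 6),
                 matrix(rnorm(6 * 8, 10, 0.3), 6))
  D <- pairwise_distances(blobs)
  res <- kmedoids(D, 2, seed = 1)
  expect_equal(length(unique(res$labels[1:6])), 1)
  expect_equal(length(unique(res$labels[7:12])), 1)
  expect_true(res$labels[1] != res$labels[7])
  # medoids are members of their own clusters
  expect_equal(res$labels[res$medoid_indices], 1:2)
  # objective equals recomputation from labels and medoids
  expect_equal(res$objective, kmedoids_objective(D, res), tolerance = 1e-12)

  # k = n: every point its own medoid, objective 0
  rn <- kmedoids(D, nrow(D), seed = 2)
  expect_equal(sort(rn$medoid_indices), 1:12)
  expect_equal(rn$objective, 0)
  expect_error(kmedoids(D, 0), "k must")
  expect_error(kmedoids(D, 13), "k must")
})

test_that("alternating k-medoids attains the exhaustive optimum from the best init", {
  set.seed(16)
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 6), n)
    D <- pairwise_distances(x)
    expect_equal(all_init_kmedoids_objective(D, k),
                 brute_kmedoids_objective(D, k), tolerance = 1e-12)
  }
})

test_that("k-medoids agrees with an independent PAM implementation on easy data", {
  skip_if_not_installed("cluster")
  set.seed(18)
  g <- generate_herd(fixture_recovery_herd(n = 45, seed = 18),
                     missingness_spec())
  cm <- build_curve_matrix(filter_lactations(g$records)$kept)
  D <- pairwise_distances(cm$znorm)
  ours <- kmedoids(D, 3, seed = 1, restarts = 10)
  pam <- cluster::pam(stats::as.dist(D), k = 3)
  # identical partitions up to label permutation
  expect_equal(length(unique(paste(ours$labels, pam$clustering))), 3)
})

test_that("clustering is reproducible and permutation-equivariant", {
  set.seed(19)
  x <- matrix(rnorm(20 * 15), 20)
  D <- pairwise_distances(x)
  r1 <- kmedoids(D, 4, seed = 77)
  r2 <- kmedoids(D, 4, seed = 77)
  expect_identical(r1[c("labels", "medoid_indices", "objective")],
                   r2[c("labels", "medoid_indices", "objective")])

  # equivariance holds whenever medoid choices are unique (tie-breaks are
  # index-based, so exact ties -- e.g. two-member clusters -- are excluded
  # by using clearly separated blobs with >= 3 members each)
  y <- rbind(matrix(rnorm(7 * 15, 0, 0.5), 7),
             matrix(rnorm(6 * 15, 8, 0.5), 6),
             matrix(rnorm(7 * 15, -8, 0.5), 7))
  Dy <- pairwise_distances(y)
  perm <- sample(20)
  Dp <- Dy[perm, perm]
  init <- c(2, 9, 16)
  rp <- kmedoids(Dp, 3, init = match(init, perm))
  ro <- kmedoids(Dy, 3, init = init)
  expect_equal(ro$labels[perm], rp$labels)
  expect_equal(sort(perm[rp$medoid_indices]), sort(ro$medoid_indices))
  expect_equal(ro$objective, rp$objective, tolerance = 1e-12)
})

test_that("three planted archetypes are recovered with ARI >= 0.9", {
  skip_if_not_installed("mclust")
  g <- generate_herd(fixture_recovery_herd(n = 90, noise_cv = 0.02,
                                           seed = 7),
                     missingness_spec())
  rep <- filter_lactations(g$records)
  cm <- build_curve_matrix(rep$kept)
  D <- pairwise_distances(cm$znorm)
  res <- kmedoids(D, 3, seed = 11)
  truth <- g$truth$archetype[match(cm$ids, g$truth$animal_id)]
  expect_gte(mclust::adjustedRandIndex(res$labels, truth), 0.9)
})

test_that("elbow profile is non-increasing and finds the planted k", {
  g <- generate_herd(fixture_recovery_herd(n = 60, noise_cv = 0.02,
                                           seed = 23),
                     missingness_spec())
  cm <- build_curve_matrix(filter_lactations(g$records)$kept)
  prof <- elbow_select_k(cm$znorm, k_range = 2:8, seed = 5, restarts = 5)
  expect_equal(prof$chosen_k, 3)
  expect_true(all(diff(prof$objective) <= 1e-9))

  expect_error(elbow_select_k(cm$znorm, k_range = 2:3), "at least 3")
})

test_that("a flat (elbow-free) profile falls back to the smallest k", {
  # identical curves: J(k) = 0 for every k, every chord distance is 0 and
  # the documented tie rule picks the smallest candidate k
  x <- matrix(rep(c(1, 2, 3, 4), each = 8), 8)
  prof <- elbow_select_k(x, k_range = 2:6, seed = 1, restarts = 3)
  expect_true(all(prof$objective == 0))
  expect_true(all(prof$distance == 0))
  expect_equal(prof$chosen_k, 2L)
})
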