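test_that("z-score scaling centers, scales and inverts exactly", {
  df <- data.frame(ptt_s = c(1, 3), pir_ratio = c(2, 2.5), hr_bpm = c(60, 80))
  sc <- fit_scaler(df)
  # population SD convention: column [1, 3] -> center 2, scale 1
  expect_equal(unname(sc$center["ptt_s"]), 2)
  expect_equal(unname(sc$scale["ptt_s"]), 1)
  expect_equal(unname(apply_scaler(sc, df)[, "ptt_s"]), c(-1, 1))

  ft <- toy_feature_table(50L)
  sc2 <- fit_scaler(ft)
  x <- apply_scaler(sc2, ft)
  expect_equal(unname(colMeans(x)), rep(0, 3), tolerance = 1e-12)
  back <- invert_scaler(sc2, x)
  expect_equal(unname(back[, 1]), ft$ptt_s, tolerance = 1e-12)
  expect_equal(unname(back[, 3]), ft$hr_bpm, tolerance = 1e-12)
})

test_that("constant features scale to zero with a warning", {
  df <- data.frame(ptt_s = c(5, 5, 5), pir_ratio = c(1, 2, 3),
                   hr_bpm = c(60, 70, 80))
  expect_warning(sc <- fit_scaler(df), "constant feature")
  expect_equal(unname(apply_scaler(sc, df)[, "ptt_s"]), c(0, 0, 0))
  expect_error(fit_scaler(df[0, ]), "empty")
})

test_that("k-means recovers two well-separated blobs and is deterministic", {
  x <- rbind(matrix(rnorm(30, 0, 0.05), 10, 3),
             matrix(rnorm(30, 10, 0.05), 10, 3))
  fit <- kmeans_fit(x, 2, seed = 7)
  expect_setequal(fit$labels[1:10], fit$labels[1])
  expect_setequal(fit$labels[11:20], fit$labels[11])
  expect_false(fit$labels[1] == fit$labels[11])
  centers <- fit$centroids[order(fit$centroids[, 1]), ]
  expect_equal(unname(centers[1, ]), colMeans(x[1:10, ]), tolerance = 1e-8)
  expect_equal(unname(centers[2, ]), colMeans(x[11:20, ]), tolerance = 1e-8)
  # inertia equals the within-blob scatter at the optimum
  expect_equal(fit$inertia,
               sum(sweep(x[1:10, ], 2, colMeans(x[1:10, ]))^2) +
                 sum(sweep(x[11:20, ], 2, colMeans(x[11:20, ]))^2),
               tolerance = 1e-8)
  refit <- kmeans_fit(x, 2, seed = 7)
  expect_identical(fit$labels, refit$labels)
  expect_identical(fit$centroids, refit$centroids)
})

test_that("k-means enforces its preconditions and monotone inertia", {
  x <- matrix(rnorm(60), 20, 3)
  expect_error(kmeans_fit(x, 1, seed = 1), "k must be >= 2")
  expect_error(kmeans_fit(x[c(1, 1, 1), ], 3, seed = 1), "distinct")
  fit <- kmeans_fit(x, 4, seed = 3)
  expect_true(all(diff(fit$inertia_trace) <= 1e-9))
  # agreement with the reference implementation on an easy instance
  blobs <- rbind(matrix(rnorm(60, 0, 0.1), 20, 3),
                 matrix(rnorm(60, 5, 0.1), 20, 3))
  ours <- kmeans_fit(blobs, 2, seed = 5)
  ref <- stats::kmeans(blobs, 2, nstart = 10)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("silhouette equals a brute-force oracle on random labelings", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(3 * n), n, 3)
    labels <- sample(rep(seq_len(k), length.out = n))
    expect_equal(mean_silhouette(x, labels), oracle_silhouette(x, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette honors its boundary conventions", {
  # two tight blobs >= 100x their spread apart -> score near 1
  set.seed(1)
  x <- rbind(matrix(rnorm(45, 0, 0.005), 15, 3),
             matrix(rnorm(45, 2, 0.005), 15, 3))
  labels <- rep(1:2, each = 15)
  expect_gte(mean_silhouette(x, labels), 0.99)
  # identical points split arbitrarily -> 0 by the a=b=0 convention
  same <- matrix(1, 10, 3)
  expect_equal(mean_silhouette(same, rep(1:2, 5)), 0)
  expect_error(mean_silhouette(x, rep(1L, 30)), "2 clusters")
})

test_that("select_k picks the constructed cluster count with smallest-k ties", {
  x <- rbind(matrix(rnorm(60, 0, 0.05), 20, 3),
             matrix(rnorm(60, 4, 0.05), 20, 3))
  m <- select_k(x, 2, 6, seed = 13)
  expect_identical(m$k, 2L)
  expect_length(m$silhouette_by_k, 5L)
  expect_identical(unname(which.max(m$silhouette_by_k)), 1L)
  # explicit tie -> smaller k (which.max takes the first maximum)
  sil <- c(`3` = 0.7, `4` = 0.7)
  expect_identical(names(sil)[which.max(sil)], "3")

  pop <- generate_population(default_regimes(n_beats = 120L), seed = 5,
                             waveforms = FALSE)
  xs <- apply_scaler(fit_scaler(pop$truth), pop$truth)
  m5 <- select_k(xs, 2, 10, seed = 6)
  expect_identical(m5$k, 5L)
  # labels match regimes up to permutation
  tab <- table(m5$labels, pop$truth$regime_id)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
})

test_that("single-regime feature clouds score low and flat across k", {
  pop <- generate_population(default_regimes(n_beats = 150L)[1], seed = 3,
                             waveforms = FALSE)
  x <- apply_scaler(fit_scaler(pop$truth), pop$truth)
  m <- select_k(x, 2, 8, seed = 4)
  expect_lt(max(m$silhouette_by_k), 0.6)
  expect_lt(diff(range(m$silhouette_by_k)), 0.25)
})

test_that("cluster assignment routes by nearest centroid with low-index ties", {
  ft <- toy_feature_table(30L)
  sc <- fit_scaler(ft)
  x <- apply_scaler(sc, ft)
  m <- cluster_fixed_k(x, 3L, seed = 9)
  # a point equal to a centroid maps to it
  for (j in 1:3) {
    expect_identical(assign_cluster(m, sc, m$centroids[j, , drop = FALSE],
                                    scaled = TRUE), j)
  }
  # the exact midpoint of two centroids takes the lower index
  sym <- structure(list(k = 2L, centroids = rbind(c(0, 0, 0), c(2, 0, 0)),
                        labels = integer(0), silhouette_by_k = numeric(0),
                        inertia = 0, seed = 1L),
                   class = "cluster_model")
  expect_identical(assign_cluster(sym, sc, rbind(c(1, 0, 0)), scaled = TRUE),
                   1L)
  # every training row routes to its own training label
  expect_identical(assign_cluster(m, sc, ft), m$labels)
})

test_that("cluster models round-trip through JSON", {
  ft <- toy_feature_table(40L)
  sc <- fit_scaler(ft)
  m <- cluster_fixed_k(apply_scaler(sc, ft), 3L, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(m, sc, path)
  back <- read_cluster_model(path)
  expect_identical(back$model$k, m$k)
  expect_equal(back$model$centroids, unname(m$centroids))
  expect_identical(back$model$labels, m$labels)
  expect_equal(unname(back$scaler$center), unname(sc$center))
  expect_identical(assign_cluster(back$model, back$scaler, ft), m$labels)
})
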