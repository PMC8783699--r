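# a feature table with a smooth recoverable BP response + tiny noise
linear_bp_table <- function(n = 300L, seed = 5L, noise = 0) {
  set.seed(seed)
  ptt <- runif(n, 0.15, 0.35)
  pir <- runif(n, 1.2, 2.6)
  hr <- runif(n, 55, 110)
  data.frame(record_id = "lin", cycle_index = seq_len(n) - 1L,
             ptt_s = ptt, pir_ratio = pir, hr_bpm = hr,
             sbp_mmHg = 160 - 150 * ptt + 8 * pir + 0.2 * hr +
               rnorm(n, 0, noise),
             dbp_mmHg = 100 - 90 * ptt + 4 * pir + 0.1 * hr +
               rnorm(n, 0, noise))
}

test_that("gradient boosting recovers a noise-free smooth target", {
  train <- linear_bp_table(400L, seed = 5L)
  test <- linear_bp_table(150L, seed = 6L)
  fit <- fit_global(train, learner_spec("gradient_boosting", seed = 2L))
  pred <- predict(fit, test)
  expect_lte(mae(pred$sbp_hat, test$sbp_mmHg), 1)
  expect_lte(mae(pred$dbp_hat, test$dbp_mmHg), 1)
})

test_that("trees reproduce a constant target exactly and fits are deterministic", {
  tab <- linear_bp_table(60L)
  tab$sbp_mmHg <- 123; tab$dbp_mmHg <- 81
  for (fam in c("gradient_boosting", "random_forest")) {
    fit <- fit_global(tab, learner_spec(fam, seed = 3L))
    pred <- predict(fit, tab)
    expect_equal(pred$sbp_hat, rep(123, 60L), tolerance = 1e-6)
    expect_equal(mae(pred$dbp_hat, tab$dbp_mmHg), 0, tolerance = 1e-6)
  }
  tab2 <- linear_bp_table(120L, noise = 2)
  for (fam in c("gradient_boosting", "random_forest", "mlp")) {
    f1 <- fit_global(tab2, learner_spec(fam, seed = 9L))
    f2 <- fit_global(tab2, learner_spec(fam, seed = 9L))
    expect_identical(predict(f1, tab2), predict(f2, tab2))
  }
  expect_error(fit_global(tab[1:5, ], learner_spec("gbr")), "at least 10")
})

test_that("boosting training loss is non-increasing in the number of stages", {
  tab <- linear_bp_table(200L, noise = 3)
  fit <- fit_global(tab, learner_spec("gradient_boosting", seed = 4L))
  trace <- fit$sbp$train_rmse
  expect_length(trace, 300L)
  expect_true(all(diff(trace) <= 1e-8))
})

test_that("learner specs validate their family and hyperparameters", {
  expect_identical(learner_spec("gbr")$family, "gradient_boosting")
  expect_identical(learner_spec("rfr")$family, "random_forest")
  expect_error(learner_spec("gbr", list(bogus = 1)), "unknown hyperparameter")
  expect_error(learner_spec("gbr", list(eta = 0)), "invalid")
  expect_error(learner_spec("mlp", list(hidden = 0)), "invalid")
})

test_that("per-cluster ensembles keep one model pair and count per cluster", {
  pop <- generate_population(default_regimes(n_beats = 60L), seed = 14,
                             waveforms = FALSE)
  feats <- pop$truth
  sc <- fit_scaler(feats)
  m <- cluster_fixed_k(apply_scaler(sc, feats), 5L, seed = 2)
  spec <- learner_spec("gradient_boosting", seed = 8L)
  ens <- fit_per_cluster(feats, m, sc, spec)
  expect_length(ens$models, 5L)
  expect_identical(sum(ens$counts), nrow(feats))
  expect_equal(sort(unname(ens$counts)),
               sort(unname(tabulate(m$labels, 5L))))
  expect_false(any(ens$fallback))
})

test_that("sparse clusters fall back to the global model with a warning", {
  ft <- toy_feature_table(63L)
  sc <- fit_scaler(ft)
  x <- apply_scaler(sc, ft)
  m <- cluster_fixed_k(x, 3L, seed = 4)
  # force one tiny cluster by relabeling
  labels <- m$labels
  labels[labels == 3L] <- 1L
  labels[1:3] <- 3L
  m$labels <- labels
  spec <- learner_spec("random_forest", seed = 5L)
  expect_warning(ens <- fit_per_cluster(ft, m, sc, spec), "global model")
  expect_true(ens$fallback[3])
  expect_false(any(ens$fallback[1:2]))
  # rows routed to the sparse cluster predict through the same global pair
  glob <- fit_global(ft, spec, sc)
  preds <- predict(ens, ft)
  routed <- preds$cluster == 3L
  if (any(routed)) {
    expect_equal(preds$sbp_hat[routed],
                 predict(glob, ft[routed, ])$sbp_hat)
  }
  # and a point exactly on centroid 3 certainly routes there
  c3 <- as.data.frame(invert_scaler(sc, m$centroids[3, , drop = FALSE]))
  names(c3) <- c("ptt_s", "pir_ratio", "hr_bpm")
  expect_equal(predict(ens, c3)$sbp_hat, predict(glob, c3)$sbp_hat)
})

test_that("prediction routes rows to their training clusters", {
  pop <- generate_population(default_regimes(n_beats = 50L), seed = 18,
                             waveforms = FALSE)
  feats <- pop$truth
  sc <- fit_scaler(feats)
  m <- cluster_fixed_k(apply_scaler(sc, feats), 5L, seed = 3)
  ens <- fit_per_cluster(feats, m, sc, learner_spec("gbr", seed = 1L))
  preds <- predict(ens, feats)
  expect_identical(preds$cluster, m$labels)
  expect_true(all(is.finite(preds$sbp_hat)))
  expect_true(all(c("record_id", "cycle_index") %in% names(preds)))
  # a row sitting exactly on a centroid is predicted by that cluster's model
  centroid_row <- as.data.frame(invert_scaler(sc, m$centroids[2, , drop = FALSE]))
  names(centroid_row) <- c("ptt_s", "pir_ratio", "hr_bpm")
  expect_identical(predict(ens, centroid_row)$cluster, 2L)
})

test_that("per-cluster ensembles beat the global fit on multitrend data", {
  pop <- generate_population(default_regimes(n_beats = 250L), seed = 77,
                             waveforms = FALSE)
  feats <- pop$truth
  sc <- fit_scaler(feats)
  m <- cluster_fixed_k(apply_scaler(sc, feats), 5L, seed = 2)
  spec <- learner_spec("gradient_boosting", seed = 6L)
  ens <- fit_per_cluster(feats, m, sc, spec)
  glob <- fit_global(feats, spec, sc)
  hold <- generate_population(default_regimes(n_beats = 120L), seed = 78,
                              waveforms = FALSE)$truth
  pe <- predict(ens, hold); pg <- predict(glob, hold)
  expect_lt(mae(pe$sbp_hat, hold$sbp_mmHg), mae(pg$sbp_hat, hold$sbp_mmHg))
  expect_lt(mae(pe$dbp_hat, hold$dbp_mmHg), mae(pg$dbp_hat, hold$dbp_mmHg))
})
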