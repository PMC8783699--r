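test_that("MAE/RMSE/r reproduce worked examples and equal brute-force oracles", {
  expect_equal(mae(c(120, 80), c(120, 80)), 0)
  expect_equal(mae(c(124, 78), c(120, 80)), 3.0)
  expect_equal(rmse(c(120, 80), c(120, 80)), 0)
  expect_equal(rmse(c(124, 78), c(120, 80)), sqrt((16 + 4) / 2))
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(pearson_r(-y + 7, y), -1)
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    est <- rnorm(n, 100, 15); ref <- rnorm(n, 100, 15)
    expect_equal(mae(est, ref), oracle_mae(est, ref), tolerance = 1e-12)
    expect_equal(rmse(est, ref), oracle_rmse(est, ref), tolerance = 1e-12)
    if (n >= 3) {
      expect_equal(pearson_r(est, ref), oracle_pearson(est, ref),
                   tolerance = 1e-12)
    }
  }
  expect_error(mae(1:3, 1:4), "equal non-zero length")
  expect_error(pearson_r(c(1, 1), c(1, 2)), "constant")
})

test_that("rmse dominates mae on random pairs", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    est <- rnorm(n); ref <- rnorm(n)
    expect_gte(rmse(est, ref) + 1e-12, mae(est, ref))
  }
})

test_that("weighted totals follow the per-cluster aggregation rule", {
  # published per-cluster GBR SBP MAEs reproduce the printed total
  expect_equal(weighted_total(c(2.644, 2.781, 2.533, 2.610, 1.643),
                              c(6282, 6276, 3355, 8300, 2390)),
               2.561, tolerance = 5e-4)
  expect_equal(weighted_total(c(3, 5), c(2, 2)), 4)      # equal counts: mean
  expect_equal(weighted_total(7.5, 123), 7.5)            # single cluster
  expect_error(weighted_total(1:2, c(1, 0)), "positive")
})

test_that("BHS grading applies the cumulative-percentage thresholds", {
  perfect <- bhs_grade(rep(120, 10), rep(120, 10))
  expect_equal(perfect$pct_le_5, 100)
  expect_identical(perfect$grade, "A")
  # published DBP percentages grade A
  expect_identical(bhs_grade(percentages = c(73.05, 90.12, 97.34))$grade, "A")
  # constructed boundary case: exactly at the A thresholds
  err <- c(rep(4, 6), rep(9, 3), 14)
  g <- bhs_grade(100 + err, rep(100, 10))
  expect_equal(c(g$pct_le_5, g$pct_le_10, g$pct_le_15), c(60, 90, 100))
  expect_identical(g$grade, "A")
  # one threshold short of A drops the grade to B
  expect_identical(bhs_grade(percentages = c(59.9, 90, 99))$grade, "B")
  expect_identical(bhs_grade(percentages = c(30, 50, 70))$grade, "D")
  # monotone percentages by construction
  set.seed(3)
  g2 <- bhs_grade(rnorm(500, 0, 8) + 100, rep(100, 500))
  expect_true(g2$pct_le_5 <= g2$pct_le_10 && g2$pct_le_10 <= g2$pct_le_15)
})

test_that("AAMI compliance combines error bounds with the subject count", {
  ok <- aami_check(mean_error = 2.811, sd_error = 5.596, n_subjects = 942)
  expect_true(ok$pass)
  expect_false(aami_check(mean_error = 6, sd_error = 4, n_subjects = 942)$pass)
  expect_false(aami_check(mean_error = 0, sd_error = 0, n_subjects = 84)$pass)
  set.seed(5)
  ref <- rnorm(200, 100, 10)
  res <- aami_check(ref + rnorm(200, 2, 4), ref, n_subjects = 100)
  expect_equal(res$mean_error, 2, tolerance = 1)
  expect_true(res$pass)
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  y <- c(100, 110, 120)
  expect_equal(unlist(bland_altman(y, y)[1:3]),
               c(bias = 0, lower_limit = 0, upper_limit = 0))
  ba <- bland_altman(y + 2, y)
  expect_equal(c(ba$bias, ba$lower_limit, ba$upper_limit), c(2, 2, 2))
  set.seed(8)
  d <- rnorm(1e5)
  ba2 <- bland_altman(100 + d, rep(100, 1e5))
  se <- sqrt(3 / 1e5)  # approx SE of the limit estimate
  expect_lt(abs(ba2$upper_limit - 1.96), 3 * se + 0.01)
  expect_lt(abs(ba2$lower_limit + 1.96), 3 * se + 0.01)
})

test_that("reports satisfy the weighted-total identities", {
  set.seed(21)
  n <- 120L
  refs <- toy_feature_table(n)
  preds <- data.frame(cluster = sample(1:4, n, replace = TRUE),
                      sbp_hat = refs$sbp_mmHg + rnorm(n, 0, 4),
                      dbp_hat = refs$dbp_mmHg + rnorm(n, 0, 3))
  rep1 <- build_report(preds, refs, n_subjects = 100)
  for (tgt in c("sbp", "dbp")) {
    t <- rep1[[tgt]]
    expect_equal(t$totals$mae, weighted_total(t$per_cluster$mae,
                                              t$per_cluster$n))
    expect_equal(t$totals$rmse, weighted_total(t$per_cluster$rmse,
                                               t$per_cluster$n))
    # per-cluster-weighted MAE equals pooled MAE (a mean of means)
    expect_equal(t$totals$mae,
                 mae(preds[[paste0(tgt, "_hat")]], refs[[paste0(tgt, "_mmHg")]]))
  }
  # permuting cluster labels leaves totals unchanged
  perm <- c(3L, 1L, 4L, 2L)
  preds2 <- preds; preds2$cluster <- perm[preds$cluster]
  rep2 <- build_report(preds2, refs, n_subjects = 100)
  expect_equal(rep2$sbp$totals$mae, rep1$sbp$totals$mae)
  expect_equal(rep2$dbp$totals$r, rep1$dbp$totals$r)
  # a single cluster collapses totals onto that cluster's row
  preds3 <- preds; preds3$cluster <- 1L
  rep3 <- build_report(preds3, refs, n_subjects = 100)
  expect_equal(rep3$sbp$totals$mae, rep3$sbp$per_cluster$mae[1])
  expect_equal(rep3$sbp$totals$rmse, rep3$sbp$per_cluster$rmse[1])
  # flattened table carries one total row per target
  tab <- as_metrics_table(rep1)
  expect_identical(sum(tab$cluster == "total"), 2L)
  expect_equal(tab$mae[tab$target == "SBP" & tab$cluster == "total"],
               rep1$sbp$totals$mae)
})

test_that("reports serialize to JSON", {
  refs <- toy_feature_table(30L)
  preds <- data.frame(cluster = rep(1:2, 15), sbp_hat = refs$sbp_mmHg,
                      dbp_hat = refs$dbp_mmHg)
  r <- build_report(preds, refs, n_subjects = 90)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sbp$totals$mae, 0)
  expect_identical(back$sbp$bhs$grade, "A")
  expect_true(back$sbp$aami$pass)
})
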