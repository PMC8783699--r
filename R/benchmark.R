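#' Published per-cluster benchmark of a clustered cuff-less BP estimator
#'
#' Per-cluster error metrics published for a five-cluster k-means +
#' regression blood-pressure estimator evaluated on a MIMIC-II-derived
#' ECG/PPG/ABP data set (26,603 cardiac cycles): MAE, RMSE and, for
#' gradient boosting, the correlation coefficient, per cluster and per
#' target, together with the printed weighted totals. The table is
#' shipped so the weighted-arithmetic-mean aggregation rule can be
#' validated against an independent published computation: applying
#' [weighted_total()] to the per-cluster cells must reproduce each
#' printed total to its printed rounding.
#'
#' @return list with elements `per_cluster` (data.frame: learner,
#'   cluster, n, sbp_mae, sbp_rmse, sbp_r, dbp_mae, dbp_rmse, dbp_r),
#'   `totals` (data.frame: learner, target, metric, value),
#'   `bhs` (data.frame: target, pct_le_5, pct_le_10, pct_le_15, grade),
#'   and `aami` (data.frame: target, mean_error, sd_error, n_subjects).
#' @export
published_cluster_benchmark <- function() {
  n <- c(6282L, 6276L, 3355L, 8300L, 2390L)
  per_cluster <- rbind(
    data.frame(learner = "random_forest", cluster = 1:5, n = n,
               sbp_mae = c(3.407, 3.468, 3.521, 3.396, 2.434),
               sbp_rmse = c(5.830, 5.724, 5.586, 5.500, 4.567),
               sbp_r = NA_real_,
               dbp_mae = c(3.250, 3.038, 2.813, 2.870, 2.677),
               dbp_rmse = c(5.698, 5.136, 5.408, 4.852, 4.879),
               dbp_r = NA_real_),
    data.frame(learner = "gradient_boosting", cluster = 1:5, n = n,
               sbp_mae = c(2.644, 2.781, 2.533, 2.610, 1.643),
               sbp_rmse = c(5.841, 5.694, 6.123, 5.522, 4.709),
               sbp_r = c(0.96, 0.93, 0.76, 0.85, 0.85),
               dbp_mae = c(2.486, 2.468, 2.003, 2.161, 1.504),
               dbp_rmse = c(5.648, 5.232, 5.491, 4.675, 4.467),
               dbp_r = c(0.98, 0.96, 0.80, 0.95, 0.95)),
    data.frame(learner = "mlp", cluster = 1:5, n = n,
               sbp_mae = c(5.230, 5.340, 6.235, 7.261, 4.326),
               sbp_rmse = c(8.244, 8.754, 9.523, 11.920, 8.156),
               sbp_r = NA_real_,
               dbp_mae = c(4.896, 5.263, 6.094, 6.288, 4.160),
               dbp_rmse = c(7.262, 8.956, 8.852, 9.003, 6.875),
               dbp_r = NA_real_))
  totals <- rbind(
    data.frame(learner = "random_forest", target = c("sbp", "dbp"),
               metric = "mae", value = c(3.344, 2.974)),
    data.frame(learner = "gradient_boosting", target = c("sbp", "dbp"),
               metric = "mae", value = c(2.561, 2.231)),
    data.frame(learner = "mlp", target = c("sbp", "dbp"),
               metric = "mae", value = c(5.937, 5.501)),
    data.frame(learner = "gradient_boosting", target = c("sbp", "dbp"),
               metric = "r", value = c(0.88, 0.94)))
  bhs <- data.frame(target = c("dbp", "sbp"),
                    pct_le_5 = c(73.05, 65.59),
                    pct_le_10 = c(90.12, 86.54),
                    pct_le_15 = c(97.34, 96.32),
                    grade = c("A", "A"))
  aami <- data.frame(target = c("dbp", "sbp"),
                     mean_error = c(2.811, 3.987),
                     sd_error = c(5.596, 5.715),
                     n_subjects = c(942L, 942L))
  list(per_cluster = per_cluster, totals = totals, bhs = bhs, aami = aami)
}

#' Published global (unclustered) baseline of the same benchmark
#'
#' MAE/RMSE/r of the same three learner families fitted on the whole
#' feature set without clustering, for comparison against the clustered
#' totals of [published_cluster_benchmark()].
#'
#' @return data.frame: learner, target, mae, rmse, r.
#' @export
published_global_benchmark <- function() {
  rbind(
    data.frame(learner = "random_forest", target = c("sbp", "dbp"),
               mae = c(7.426, 7.410), rmse = c(12.250, 12.110),
               r = c(0.65, 0.68)),
    data.frame(learner = "gradient_boosting", target = c("sbp", "dbp"),
               mae = c(6.367, 6.276), rmse = c(10.395, 10.221),
               r = c(0.67, 0.71)),
    data.frame(learner = "mlp", target = c("sbp", "dbp"),
               mae = c(9.422, 9.323), rmse = c(14.120, 14.099),
               r = c(0.59, 0.64)))
}
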