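#' Configuration of the end-to-end estimation pipeline
#'
#' Bundles every stage parameter of the signals-to-report flow:
#' waveform input (paths or synthetic regimes), extraction settings,
#' cluster count (or sweep range), learner family, the train/test split
#' and the master seed.
#'
#' @param regimes list of [regime_spec()]s to simulate from (used when
#'   no `record_paths` are given); default [default_regimes()].
#' @param record_paths optional character vector of waveform CSV paths
#'   to read instead of simulating.
#' @param layout a [waveform_layout()] for reading `record_paths`.
#' @param sampling_rate_hz sampling rate for simulation (default 125).
#' @param extraction an [extraction_config()].
#' @param k `"auto"` (silhouette sweep) or a fixed integer.
#' @param k_range length-2 integer vector, the sweep range for
#'   `k = "auto"` (default `c(2, 10)`).
#' @param learner a [learner_spec()] or family name.
#' @param train_fraction training fraction of the cluster-stratified
#'   split (default 0.8).
#' @param min_cluster_rows small-cluster fallback threshold (default 10).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory for stage artifacts (created if
#'   needed); `NULL` writes nothing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(regimes = default_regimes(),
                            record_paths = NULL,
                            layout = waveform_layout(),
                            sampling_rate_hz = 125,
                            extraction = extraction_config(),
                            k = "auto", k_range = c(2L, 10L),
                            learner = "gradient_boosting",
                            train_fraction = 0.8,
                            min_cluster_rows = 10L,
                            seed = 1L, out_dir = NULL) {
  if (!inherits(learner, "learner_spec")) {
    learner <- learner_spec(learner, seed = derive_seed(seed, 17L))
  }
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!identical(k, "auto")) stopifnot(is.numeric(k), k >= 2)
  structure(list(regimes = regimes, record_paths = record_paths,
                 layout = layout, sampling_rate_hz = sampling_rate_hz,
                 extraction = extraction, k = k, k_range = k_range,
                 learner = learner, train_fraction = train_fraction,
                 min_cluster_rows = min_cluster_rows,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Cluster-stratified train/test split
#'
#' Draws a random training subset of the requested fraction within each
#' cluster, so every cluster is represented in both splits.
#'
#' @param labels integer cluster labels.
#' @param train_fraction fraction of each cluster assigned to training.
#' @param seed integer seed.
#' @return logical vector, `TRUE` for training rows.
#' @export
stratified_split <- function(labels, train_fraction, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (j in unique(labels)) {
      rows <- which(labels == j)
      n_train <- max(1L, round(train_fraction * length(rows)))
      train[sample(rows, n_train)] <- TRUE
    }
    train
  })
}

#' Run the full estimation pipeline
#'
#' Executes the complete flow: obtain waveforms (simulate or read),
#' extract per-cycle features, z-scale, cluster with silhouette-selected
#' (or fixed) k, fit per-cluster regressors and a same-family global
#' baseline on the cluster-stratified training split, predict the test
#' split with nearest-centroid routing, and evaluate both estimators.
#' Stage artifacts (features.csv, model.json, ensemble.rds, preds.csv,
#' report.json, comparison.csv) are written when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list with `report` (clustered, test split), `report_global`,
#'   `report_train`, `cluster_model`, `scaler`, `ensemble`, `features`,
#'   `comparison` (one-row-per-estimator summary data.frame).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  # --- signals ---------------------------------------------------------
  records <- if (!is.null(config$record_paths)) {
    lapply(config$record_paths, read_waveform_record, layout = config$layout)
  } else {
    generate_population(config$regimes, config$sampling_rate_hz,
                        seed = derive_seed(config$seed, 1L))$records
  }
  # --- features --------------------------------------------------------
  tables <- lapply(records, build_feature_table, config = config$extraction)
  dropped <- sum(vapply(tables, function(t) attr(t, "dropped_cycles"),
                        integer(1L)))
  features <- do.call(rbind, tables)
  if (!nrow(features)) stop("pipeline stage 'extract': no valid cycles",
                            call. = FALSE)
  message(sprintf("extract: %d cycles retained, %d dropped", nrow(features),
                  dropped))
  if (!is.null(out)) write_feature_table(features, file.path(out, "features.csv"))
  # --- scaling + clustering -------------------------------------------
  scaler <- fit_scaler(features)
  x <- apply_scaler(scaler, features)
  model <- if (identical(config$k, "auto")) {
    select_k(x, config$k_range[1L], config$k_range[2L],
             seed = derive_seed(config$seed, 2L))
  } else {
    cluster_fixed_k(x, config$k, seed = derive_seed(config$seed, 2L))
  }
  message(sprintf("cluster: k = %d (mean silhouette %.3f)", model$k,
                  model$silhouette_by_k[as.character(model$k)]))
  if (!is.null(out)) write_cluster_model(model, scaler,
                                         file.path(out, "model.json"))
  # --- split + models --------------------------------------------------
  train <- stratified_split(model$labels, config$train_fraction,
                            seed = derive_seed(config$seed, 3L))
  feat_train <- features[train, , drop = FALSE]
  feat_test <- features[!train, , drop = FALSE]
  ensemble <- fit_per_cluster(feat_train, model, scaler, config$learner,
                              min_cluster_rows = config$min_cluster_rows,
                              labels = model$labels[train])
  if (any(ensemble$fallback)) {
    message(sprintf("train: %d cluster(s) fell back to the global model",
                    sum(ensemble$fallback)))
  }
  global <- fit_global(feat_train, config$learner, scaler)
  if (!is.null(out)) saveRDS(ensemble, file.path(out, "ensemble.rds"))
  # --- predictions + evaluation ---------------------------------------
  preds_test <- predict(ensemble, feat_test)
  preds_train <- predict(ensemble, feat_train)
  preds_global <- predict(global, feat_test)
  preds_global$cluster <- preds_test$cluster
  report <- build_report(preds_test, feat_test, label = "clustered, test split")
  report_train <- build_report(preds_train, feat_train,
                               label = "clustered, training split")
  report_global <- build_report(preds_global, feat_test,
                                label = "global, test split")
  comparison <- comparison_row(config$learner$family, report_global, report)
  if (!is.null(out)) {
    utils::write.csv(preds_test, file.path(out, "preds.csv"),
                     row.names = FALSE)
    write_report_json(report, file.path(out, "report.json"))
    utils::write.csv(comparison, file.path(out, "comparison.csv"),
                     row.names = FALSE)
  }
  list(report = report, report_global = report_global,
       report_train = report_train, cluster_model = model, scaler = scaler,
       ensemble = ensemble, features = features, train = train,
       comparison = comparison)
}

comparison_row <- function(family, report_global, report_clustered) {
  rbind(
    data.frame(learner = family, estimator = "global",
               sbp_mae = report_global$sbp$totals$mae,
               sbp_rmse = report_global$sbp$totals$rmse_pooled,
               sbp_r = suppressWarnings(report_global$sbp$totals$r),
               dbp_mae = report_global$dbp$totals$mae,
               dbp_rmse = report_global$dbp$totals$rmse_pooled,
               dbp_r = suppressWarnings(report_global$dbp$totals$r)),
    data.frame(learner = family, estimator = "clustered",
               sbp_mae = report_clustered$sbp$totals$mae,
               sbp_rmse = report_clustered$sbp$totals$rmse,
               sbp_r = report_clustered$sbp$totals$r,
               dbp_mae = report_clustered$dbp$totals$mae,
               dbp_rmse = report_clustered$dbp$totals$rmse,
               dbp_r = report_clustered$dbp$totals$r))
}

#' Compare global and clustered estimators across learner families
#'
#' Runs [run_pipeline()] once per learner family on a shared feature
#' set/seed and collects the global-vs-clustered metric pairs in one
#' table.
#'
#' @param config a [pipeline_config()] (its `learner` field is
#'   overridden per family).
#' @param learners character vector of learner families (>= 1).
#' @return data.frame with one global and one clustered row per family.
#' @export
run_comparison <- function(config, learners = c("gradient_boosting",
                                                "random_forest", "mlp")) {
  if (!length(learners)) {
    stop("parameter error: need at least one learner", call. = FALSE)
  }
  rows <- lapply(learners, function(fam) {
    cfg <- config
    cfg$learner <- learner_spec(fam, seed = derive_seed(config$seed, 17L))
    cfg$out_dir <- NULL
    run_pipeline(cfg)$comparison
  })
  do.call(rbind, rows)
}
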