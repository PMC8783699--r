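#' Specify a regression learner family and its hyperparameters
#'
#' Three families map the scaled (PTT, PIR, HR) features to one blood
#' pressure target each (separate models for SBP and DBP):
#'
#' * `gradient_boosting` ("gbr") — boosted regression trees via
#'   \pkg{xgboost}; defaults: 300 stages, depth 3, learning rate 0.1.
#' * `random_forest` ("rfr") — \pkg{ranger}; defaults: 300 trees,
#'   unlimited depth, `min.node.size` 5.
#' * `mlp` — single-hidden-layer perceptron via \pkg{nnet} (8 logistic
#'   units, BFGS, up to 500 iterations, weight decay 0.01, best of 3
#'   random restarts by training loss); the target is z-scored internally
#'   for conditioning and mapped back at prediction. The strong decay and
#'   restarts guard against the init sensitivity of small-sample neural
#'   fits.
#'
#' @param family one of `"gradient_boosting"`/`"gbr"`,
#'   `"random_forest"`/`"rfr"`, `"mlp"`.
#' @param hyperparameters named list overriding the family defaults
#'   (`nrounds`, `max_depth`, `eta` for boosting; `num_trees`, `mtry`,
#'   `min_node_size` for the forest; `hidden`, `maxit`, `decay`,
#'   `restarts` for the MLP).
#' @param seed integer seed used for every stochastic element of the fit.
#' @return a `learner_spec` list.
#' @export
learner_spec <- function(family = c("gradient_boosting", "random_forest", "mlp",
                                    "gbr", "rfr"),
                         hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  family <- switch(family, gbr = "gradient_boosting", rfr = "random_forest",
                   family)
  defaults <- switch(family,
    gradient_boosting = list(nrounds = 300L, max_depth = 3L, eta = 0.1),
    random_forest = list(num_trees = 300L, mtry = NULL, min_node_size = 5L),
    mlp = list(hidden = 8L, maxit = 500L, decay = 0.01, restarts = 3L))
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  if (family == "gradient_boosting" &&
      (hp$nrounds < 1 || hp$max_depth < 1 || hp$eta <= 0 || hp$eta > 1)) {
    stop("invalid gradient-boosting hyperparameters", call. = FALSE)
  }
  if (family == "random_forest" && hp$num_trees < 1) {
    stop("invalid random-forest hyperparameters", call. = FALSE)
  }
  if (family == "mlp" &&
      (hp$hidden < 1 || hp$maxit < 1 || hp$decay < 0 || hp$restarts < 1)) {
    stop("invalid MLP hyperparameters", call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

# fit a single regressor: scaled feature matrix x -> numeric target y
fit_learner <- function(x, y, spec) {
  hp <- spec$hyperparameters
  switch(spec$family,
    gradient_boosting = {
      dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      fit <- with_seed(spec$seed, xgboost::xgb.train(
        params = list(max_depth = hp$max_depth, learning_rate = hp$eta,
                      objective = "reg:squarederror", nthread = 1L,
                      seed = spec$seed),
        data = dm, nrounds = hp$nrounds, evals = list(train = dm),
        verbose = 0))
      list(kind = "xgb", fit = fit,
           train_rmse = attributes(fit)$evaluation_log$train_rmse)
    },
    random_forest = {
      df <- as.data.frame(x)
      fit <- ranger::ranger(
        y = y, x = df, num.trees = hp$num_trees,
        mtry = hp$mtry, min.node.size = hp$min_node_size,
        num.threads = 1L, seed = spec$seed)
      list(kind = "ranger", fit = fit)
    },
    mlp = {
      mu <- mean(y); sdy <- stats::sd(y)
      if (!is.finite(sdy) || sdy == 0) sdy <- 1
      # best of `restarts` random initializations by final training loss
      fit <- with_seed(spec$seed, {
        best <- NULL
        for (r in seq_len(hp$restarts)) {
          cand <- nnet::nnet(
            x = x, y = (y - mu) / sdy, size = hp$hidden, linout = TRUE,
            maxit = hp$maxit, decay = hp$decay, trace = FALSE,
            MaxNWts = 100000L)
          if (is.null(best) || cand$value < best$value) best <- cand
        }
        best
      })
      list(kind = "nnet", fit = fit, y_center = mu, y_scale = sdy)
    })
}

predict_learner <- function(model, x) {
  switch(model$kind,
    xgb = stats::predict(model$fit, x),
    ranger = stats::predict(model$fit, data = as.data.frame(x),
                            num.threads = 1L)$predictions,
    nnet = as.numeric(stats::predict(model$fit, x)) * model$y_scale +
      model$y_center)
}

#' Fit a global (unclustered) SBP/DBP regressor pair
#'
#' One model per target, fitted on all rows — the baseline the
#' per-cluster ensemble is compared against.
#'
#' @param features feature table with >= 10 rows.
#' @param spec a [learner_spec()].
#' @param scaler optional `bp_scaler`; fitted on `features` when absent.
#' @return a `bp_regressor_pair` (scaler, per-target models, spec).
#' @export
fit_global <- function(features, spec, scaler = NULL) {
  stopifnot(inherits(spec, "learner_spec"))
  if (nrow(features) < 10L) {
    stop("fit_global: need at least 10 rows", call. = FALSE)
  }
  scaler <- scaler %||% fit_scaler(features)
  x <- apply_scaler(scaler, features)
  structure(list(
    scaler = scaler, spec = spec,
    sbp = fit_learner(x, features$sbp_mmHg, spec),
    dbp = fit_learner(x, features$dbp_mmHg, spec),
    n = nrow(features)),
    class = "bp_regressor_pair")
}

#' @export
print.bp_regressor_pair <- function(x, ...) {
  cat(sprintf("<bp_regressor_pair: %s, trained on %d cycles>\n",
              x$spec$family, x$n))
  invisible(x)
}

#' Predict SBP/DBP with a fitted regressor pair
#'
#' @param object a `bp_regressor_pair`.
#' @param features feature table rows.
#' @param ... unused.
#' @return data.frame with `sbp_hat`, `dbp_hat` (mmHg).
#' @export
predict.bp_regressor_pair <- function(object, features, ...) {
  x <- apply_scaler(object$scaler, features)
  data.frame(sbp_hat = predict_learner(object$sbp, x),
             dbp_hat = predict_learner(object$dbp, x))
}

#' Fit one regressor pair per cluster
#'
#' The core of the clustered estimator: every cluster of the fitted
#' cluster model gets its own SBP and DBP regressor, trained only on
#' that cluster's rows. Clusters smaller than `min_cluster_rows` fall
#' back to a global pair fitted on all rows (with a warning), so sparse
#' clusters never receive an under-determined model.
#'
#' @param features feature table whose rows align with
#'   `cluster_model$labels` (i.e. the table the cluster model was fitted
#'   on), or any table when `labels` is supplied explicitly.
#' @param cluster_model a `cluster_model`.
#' @param scaler the `bp_scaler` used for clustering (shared by the
#'   regressors).
#' @param spec a [learner_spec()].
#' @param min_cluster_rows minimum rows for a dedicated pair
#'   (default 10).
#' @param labels optional explicit cluster labels for `features`.
#' @return a `cluster_ensemble`.
#' @export
fit_per_cluster <- function(features, cluster_model, scaler, spec,
                            min_cluster_rows = 10L, labels = NULL) {
  stopifnot(inherits(cluster_model, "cluster_model"),
            inherits(scaler, "bp_scaler"), inherits(spec, "learner_spec"))
  labels <- labels %||% cluster_model$labels
  if (length(labels) != nrow(features)) {
    stop("fit_per_cluster: labels do not align with the feature rows",
         call. = FALSE)
  }
  k <- cluster_model$k
  counts <- tabulate(labels, nbins = k)
  x <- apply_scaler(scaler, features)
  global <- NULL
  models <- vector("list", k)
  fallback <- logical(k)
  for (j in seq_len(k)) {
    rows <- labels == j
    if (counts[j] >= min_cluster_rows) {
      sj <- learner_spec(spec$family, spec$hyperparameters,
                         seed = derive_seed(spec$seed, j))
      models[[j]] <- list(
        sbp = fit_learner(x[rows, , drop = FALSE], features$sbp_mmHg[rows], sj),
        dbp = fit_learner(x[rows, , drop = FALSE], features$dbp_mmHg[rows], sj))
    } else {
      if (is.null(global)) global <- fit_global(features, spec, scaler)
      warning(sprintf(
        "fit_per_cluster: cluster %d has %d row(s) (< %d); using the global model",
        j, counts[j], min_cluster_rows), call. = FALSE)
      models[[j]] <- list(sbp = global$sbp, dbp = global$dbp)
      fallback[j] <- TRUE
    }
  }
  structure(list(cluster_model = cluster_model, scaler = scaler, spec = spec,
                 models = models, counts = counts, fallback = fallback),
            class = "cluster_ensemble")
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  cat(sprintf("<cluster_ensemble: %s, k = %d, cluster sizes %s%s>\n",
              x$spec$family, x$cluster_model$k,
              paste(x$counts, collapse = "/"),
              if (any(x$fallback)) sprintf(" (%d fallback)", sum(x$fallback))
              else ""))
  invisible(x)
}

#' Predict SBP/DBP with a per-cluster ensemble
#'
#' Each row is routed to its Euclidean-nearest centroid
#' ([assign_cluster()]) and predicted by that cluster's regressor pair.
#'
#' @param object a `cluster_ensemble`.
#' @param features feature table rows.
#' @param ... unused.
#' @return data.frame with `record_id`, `cycle_index` (when present in
#'   `features`), `cluster`, `sbp_hat`, `dbp_hat`.
#' @export
predict.cluster_ensemble <- function(object, features, ...) {
  x <- apply_scaler(object$scaler, features)
  cl <- assign_cluster(object$cluster_model, object$scaler, x, scaled = TRUE)
  sbp <- dbp <- rep(NA_real_, nrow(x))
  for (j in unique(cl)) {
    rows <- cl == j
    sbp[rows] <- predict_learner(object$models[[j]]$sbp, x[rows, , drop = FALSE])
    dbp[rows] <- predict_learner(object$models[[j]]$dbp, x[rows, , drop = FALSE])
  }
  out <- data.frame(cluster = cl, sbp_hat = sbp, dbp_hat = dbp)
  for (col in c("cycle_index", "record_id")) {
    if (col %in% names(features)) out <- cbind(features[col], out)
  }
  out
}
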