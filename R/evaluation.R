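#' Error metrics for blood-pressure estimates
#'
#' `mae()` is the mean absolute difference between estimates and
#' references, `rmse()` the root of the mean squared difference and
#' `pearson_r()` the product-moment correlation — the three per-cluster
#' performance measures of the estimator.
#'
#' @param estimates,references numeric vectors of equal non-zero length
#'   (mmHg).
#' @return a single number.
#' @export
mae <- function(estimates, references) {
  check_paired(estimates, references)
  mean(abs(estimates - references))
}

#' @rdname mae
#' @export
rmse <- function(estimates, references) {
  check_paired(estimates, references)
  sqrt(mean((estimates - references)^2))
}

#' @rdname mae
#' @export
pearson_r <- function(estimates, references) {
  check_paired(estimates, references)
  if (length(estimates) < 2L) {
    stop("pearson_r: need at least 2 pairs", call. = FALSE)
  }
  if (stats::sd(estimates) == 0 || stats::sd(references) == 0) {
    stop("pearson_r: constant input vector", call. = FALSE)
  }
  stats::cor(estimates, references)
}

check_paired <- function(estimates, references) {
  if (length(estimates) != length(references) || !length(estimates)) {
    stop("estimates and references must have equal non-zero length",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Weighted arithmetic mean of per-cluster values
#'
#' The totals of the clustered estimator are aggregated as
#' \eqn{\sum_i n_i v_i / \sum_i n_i} over clusters, with `counts` the
#' per-cluster sample counts — the convention used for total MAE, RMSE
#' and correlation alike.
#'
#' @param values per-cluster metric values.
#' @param counts per-cluster sample counts (positive, same length).
#' @return the weighted mean.
#' @export
weighted_total <- function(values, counts) {
  if (length(values) != length(counts) || !length(values)) {
    stop("values and counts must have equal non-zero length", call. = FALSE)
  }
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  sum(values * counts) / sum(counts)
}

#' Grade estimates against the BHS protocol
#'
#' The British Hypertension Society protocol grades a device by the
#' cumulative percentages of absolute errors within 5, 10 and 15 mmHg:
#' Grade A requires at least 60/85/95 percent, B 50/75/90, C 40/65/85;
#' anything weaker is D. All three thresholds of a grade must hold.
#'
#' @param estimates,references paired vectors (mmHg), or `NULL` when
#'   `percentages` is given.
#' @param percentages optional length-3 vector of cumulative percentages
#'   at 5/10/15 mmHg, graded directly.
#' @return list with `pct_le_5`, `pct_le_10`, `pct_le_15`, `grade`
#'   (one of "A","B","C","D").
#' @export
bhs_grade <- function(estimates = NULL, references = NULL, percentages = NULL) {
  if (is.null(percentages)) {
    check_paired(estimates, references)
    err <- abs(estimates - references)
    percentages <- 100 * c(mean(err <= 5), mean(err <= 10), mean(err <= 15))
  }
  stopifnot(length(percentages) == 3L)
  bounds <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "D"
  for (g in c("C", "B", "A")) {
    if (all(percentages >= bounds[[g]])) grade <- g
  }
  list(pct_le_5 = percentages[1L], pct_le_10 = percentages[2L],
       pct_le_15 = percentages[3L], grade = grade)
}

#' Check estimates against the AAMI standard
#'
#' The AAMI criterion passes a method whose signed mean error is within
#' 5 mmHg and error SD within 8 mmHg, validated on at least 85 subjects.
#' The subject count is a user input: readings-per-subject is a property
#' of the study design, not of the error vector.
#'
#' @param estimates,references paired vectors (mmHg), or `NULL` when
#'   `mean_error` and `sd_error` are given directly.
#' @param n_subjects number of subjects behind the readings.
#' @param mean_error,sd_error optional precomputed summary inputs.
#' @return list with `mean_error`, `sd_error`, `n_subjects`, `pass`.
#' @export
aami_check <- function(estimates = NULL, references = NULL, n_subjects,
                       mean_error = NULL, sd_error = NULL) {
  if (is.null(mean_error) || is.null(sd_error)) {
    check_paired(estimates, references)
    err <- estimates - references
    mean_error <- mean(err)
    sd_error <- stats::sd(err)
  }
  pass <- is.finite(n_subjects) && abs(mean_error) <= 5 && sd_error <= 8 &&
    n_subjects >= 85
  list(mean_error = mean_error, sd_error = sd_error,
       n_subjects = n_subjects, pass = pass)
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean of estimate minus reference) and the 95% limits of
#' agreement, bias +/- 1.96 times the SD of the differences.
#'
#' @param estimates,references paired vectors (mmHg).
#' @return list with `bias`, `lower_limit`, `upper_limit`, `sd_diff`.
#' @export
bland_altman <- function(estimates, references) {
  check_paired(estimates, references)
  d <- estimates - references
  bias <- mean(d)
  s <- if (length(d) > 1L) stats::sd(d) else 0
  if (!is.finite(s)) s <- 0
  list(bias = bias, lower_limit = bias - 1.96 * s,
       upper_limit = bias + 1.96 * s, sd_diff = s)
}

per_cluster_metrics <- function(est, ref, cluster) {
  lev <- sort(unique(cluster))
  rows <- lapply(lev, function(j) {
    e <- est[cluster == j]; r <- ref[cluster == j]
    r_val <- if (length(e) >= 2L && stats::sd(e) > 0 && stats::sd(r) > 0) {
      stats::cor(e, r)
    } else {
      NA_real_
    }
    data.frame(cluster = j, n = length(e), mae = mae(e, r),
               rmse = rmse(e, r), r = r_val)
  })
  do.call(rbind, rows)
}

target_report <- function(est, ref, cluster) {
  pc <- per_cluster_metrics(est, ref, cluster)
  totals <- list(
    mae = weighted_total(pc$mae, pc$n),
    rmse = weighted_total(pc$rmse, pc$n),
    rmse_pooled = rmse(est, ref),
    r = if (all(is.finite(pc$r))) weighted_total(pc$r, pc$n) else NA_real_)
  list(per_cluster = pc, totals = totals,
       bhs = bhs_grade(est, ref),
       bland_altman = bland_altman(est, ref))
}

#' Build a full evaluation report
#'
#' Per-cluster MAE/RMSE/r for each target (SBP, DBP) with
#' weighted-arithmetic-mean totals, BHS grading, AAMI compliance and
#' Bland-Altman limits. Total RMSE is reported both as the weighted mean
#' of per-cluster RMSEs (the aggregation rule used for all totals) and
#' pooled over all samples (`rmse_pooled`), since the two conventions
#' differ.
#'
#' @param predictions data.frame with `sbp_hat`, `dbp_hat` and `cluster`
#'   columns (as returned by [predict.cluster_ensemble()]).
#' @param references feature table rows aligned with `predictions`
#'   (columns `sbp_mmHg`, `dbp_mmHg`).
#' @param n_subjects subject count for the AAMI check; defaults to the
#'   number of distinct `record_id`s in `references` when present, else
#'   `NA`.
#' @param label free-text label (e.g. "test split"), carried in the
#'   report.
#' @return a `bp_report` object.
#' @export
build_report <- function(predictions, references, n_subjects = NULL,
                         label = "") {
  stopifnot(nrow(predictions) == nrow(references))
  if (!"cluster" %in% names(predictions)) {
    predictions$cluster <- 1L
  }
  n_subjects <- n_subjects %||%
    if ("record_id" %in% names(references)) {
      length(unique(references$record_id))
    } else {
      NA_real_
    }
  rep_of <- function(est, ref) {
    tr <- target_report(est, ref, predictions$cluster)
    tr$aami <- aami_check(est, ref, n_subjects = n_subjects)
    tr
  }
  structure(list(
    sbp = rep_of(predictions$sbp_hat, references$sbp_mmHg),
    dbp = rep_of(predictions$dbp_hat, references$dbp_mmHg),
    n = nrow(predictions), n_subjects = n_subjects, label = label),
    class = "bp_report")
}

#' @export
print.bp_report <- function(x, ...) {
  cat(sprintf("Blood-pressure estimation report%s (n = %d cycles)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "", x$n))
  for (tgt in c("sbp", "dbp")) {
    t <- x[[tgt]]
    cat(sprintf("  %s: MAE %.3f  RMSE %.3f (pooled %.3f)  r %s mmHg\n",
                toupper(tgt), t$totals$mae, t$totals$rmse,
                t$totals$rmse_pooled,
                if (is.na(t$totals$r)) "NA" else sprintf("%.3f", t$totals$r)))
    cat(sprintf("       BHS %.1f/%.1f/%.1f%% -> grade %s;  AAMI ME %.2f SD %.2f -> %s\n",
                t$bhs$pct_le_5, t$bhs$pct_le_10, t$bhs$pct_le_15, t$bhs$grade,
                t$aami$mean_error, t$aami$sd_error,
                if (isTRUE(t$aami$pass)) "pass" else "fail"))
  }
  invisible(x)
}

#' Flatten a report into a per-cluster metrics table
#'
#' One row per (target, cluster) plus a `total` row per target, shaped
#' like the per-cluster comparison tables of clustered BP estimators.
#'
#' @param report a `bp_report`.
#' @return data.frame with columns `target`, `cluster`, `n`, `mae`,
#'   `rmse`, `r`.
#' @export
as_metrics_table <- function(report) {
  stopifnot(inherits(report, "bp_report"))
  out <- lapply(c("sbp", "dbp"), function(tgt) {
    t <- report[[tgt]]
    pc <- cbind(target = toupper(tgt), t$per_cluster)
    tot <- data.frame(target = toupper(tgt), cluster = "total",
                      n = sum(t$per_cluster$n), mae = t$totals$mae,
                      rmse = t$totals$rmse, r = t$totals$r)
    pc$cluster <- as.character(pc$cluster)
    rbind(pc, tot)
  })
  do.call(rbind, out)
}

#' Serialize a report to JSON
#'
#' @param report a `bp_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "bp_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
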