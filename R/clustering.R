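#' Fit a z-score scaler on the independent features
#'
#' Standardization of the (PTT, PIR, HR) columns to zero mean and unit
#' variance (population SD). k-means with Euclidean distance needs the
#' three features on comparable scales: raw PTT spans fractions of a
#' second while HR spans tens of beats per minute, so an unscaled
#' distance would be dominated by HR. A constant column gets scale 1
#' (with a warning) so scaling stays invertible.
#'
#' @param features a feature table (or any data.frame containing the
#'   columns in `columns`), >= 2 rows.
#' @param columns feature columns to scale; default
#'   `c("ptt_s", "pir_ratio", "hr_bpm")`.
#' @return a `bp_scaler` object with per-feature `center` and `scale`.
#' @export
fit_scaler <- function(features, columns = c("ptt_s", "pir_ratio", "hr_bpm")) {
  if (!nrow(features)) stop("fit_scaler: empty feature table", call. = FALSE)
  missing <- setdiff(columns, names(features))
  if (length(missing)) {
    stop("fit_scaler: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(features[columns])
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))  # population SD
  const <- scale <= 0
  if (any(const)) {
    warning("fit_scaler: constant feature(s) ",
            paste(columns[const], collapse = ", "), "; scale set to 1",
            call. = FALSE)
    scale[const] <- 1
  }
  structure(list(center = center, scale = scale, columns = columns),
            class = "bp_scaler")
}

#' Apply / invert a fitted scaler
#'
#' `apply_scaler()` maps feature rows into scaled space (a numeric
#' matrix); `invert_scaler()` maps scaled points back to the original
#' units. The two are exact inverses.
#'
#' @param scaler a `bp_scaler` from [fit_scaler()].
#' @param features data.frame containing the scaler's columns, or a
#'   numeric matrix in column order.
#' @return numeric matrix (rows = samples, columns = features).
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "bp_scaler"))
  x <- if (is.matrix(features)) features else as.matrix(features[scaler$columns])
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, `/`)
}

#' @rdname apply_scaler
#' @param scaled numeric matrix in scaled space.
#' @export
invert_scaler <- function(scaler, scaled) {
  stopifnot(inherits(scaler, "bp_scaler"))
  sweep(sweep(as.matrix(scaled), 2L, scaler$scale, `*`), 2L, scaler$center, `+`)
}

# squared Euclidean distances between rows of x and rows of centers
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  pmax(d2, 0)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  mind2 <- dist2_to_centers(x, centers[1L, , drop = FALSE])[, 1L]
  for (j in 2L:k) {
    p <- mind2 / sum(mind2)
    if (!all(is.finite(p)) || sum(mind2) <= 0) {
      pick <- sample.int(n, 1L)  # all residual distances zero: uniform
    } else {
      pick <- sample.int(n, 1L, prob = p)
    }
    centers[j, ] <- x[pick, ]
    mind2 <- pmin(mind2, dist2_to_centers(x, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

lloyd_once <- function(x, k, max_iter, tol) {
  centers <- kmeanspp_init(x, k)
  inertia_trace <- numeric(0)
  labels <- rep(1L, nrow(x))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    inertia_trace <- c(inertia_trace, inertia)
    # centroid update; empty cluster reseeds at the point farthest from
    # its current centroid
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        centers[j, ] <- x[far, ]
        labels[far] <- j
      }
    }
    if (is.finite(prev) && prev - inertia <= tol * max(prev, 1e-12)) break
    prev <- inertia
  }
  # final assignment consistent with the returned centroids
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(centers = centers, labels = labels, inertia = inertia,
       inertia_trace = inertia_trace)
}

#' k-means clustering (Lloyd's algorithm, k-means++ initialization)
#'
#' Fits k-means in scaled feature space with `n_init` independent
#' k-means++ restarts, keeping the lowest-inertia solution. Within-run
#' inertia is non-increasing over Lloyd iterations (the per-iteration
#' trace is returned in `inertia_trace`); empty clusters are reseeded at
#' the point farthest from its assigned centroid.
#'
#' @param x numeric matrix of points (rows) in scaled space.
#' @param k number of clusters, 2 <= k <= number of distinct points.
#' @param seed integer seed (fixes initialization).
#' @param n_init number of k-means++ restarts (default 10).
#' @param max_iter maximum Lloyd iterations per restart (default 300).
#' @param tol relative inertia-improvement convergence threshold
#'   (default 1e-4).
#' @return list with `centroids` (k x d), `labels` (1-based, length
#'   nrow(x)), `inertia`, `inertia_trace` of the winning restart.
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_init = 10L, max_iter = 300L,
                       tol = 1e-4) {
  x <- as.matrix(x)
  if (k < 2L) stop("parameter error: k must be >= 2", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("parameter error: k exceeds the number of distinct points",
         call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- lloyd_once(x, k, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  list(centroids = best$centers, labels = best$labels,
       inertia = best$inertia, inertia_trace = best$inertia_trace)
}

#' Mean silhouette score of a clustering
#'
#' For each point, `a` is its mean distance to the other members of its
#' own cluster and `b` the smallest mean distance to any other cluster;
#' the silhouette is `(b - a) / max(a, b)`, with singleton clusters (and
#' the degenerate `a = b = 0` case) contributing 0. The mean over points
#' is the model-selection criterion used by [select_k()].
#'
#' @param x numeric matrix of points, or `NULL` when `dist_matrix` is
#'   supplied.
#' @param labels integer cluster labels (>= 2 distinct, each non-empty).
#' @param dist_matrix optional precomputed full Euclidean distance
#'   matrix; avoids recomputation across a k sweep.
#' @return mean silhouette in [-1, 1].
#' @export
mean_silhouette <- function(x, labels, dist_matrix = NULL) {
  if (is.null(dist_matrix)) {
    dist_matrix <- as.matrix(stats::dist(as.matrix(x)))
  }
  n <- nrow(dist_matrix)
  stopifnot(length(labels) == n)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    stop("mean_silhouette: need at least 2 clusters", call. = FALSE)
  }
  z <- 1 * outer(labels, lev, `==`)   # n x k membership
  counts <- colSums(z)
  sums <- dist_matrix %*% z           # n x k: sum of distances to each cluster
  own <- max.col(z, ties.method = "first")
  a <- sums[cbind(seq_len(n), own)] / pmax(counts[own] - 1, 1)
  meand <- sweep(sums, 2L, counts, `/`)
  meand[cbind(seq_len(n), own)] <- Inf
  b <- apply(meand, 1L, min)
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[counts[own] == 1L] <- 0  # singleton convention
  mean(s)
}

#' Select the number of clusters by the silhouette criterion
#'
#' Fits k-means for each candidate k in `[k_min, k_max]`, scores each fit
#' by mean silhouette and returns the model at the maximizer (ties break
#' to the smallest k). The full score map is kept in `silhouette_by_k`.
#'
#' @param x numeric matrix of points in scaled space.
#' @param k_min,k_max candidate range (defaults 2 and 10).
#' @param seed integer seed.
#' @param ... passed to [kmeans_fit()] (`n_init`, `max_iter`, `tol`).
#' @return a `cluster_model` object: `k`, `centroids`, `labels`,
#'   `silhouette_by_k`, `inertia`, `seed`.
#' @export
select_k <- function(x, k_min = 2L, k_max = 10L, seed = 1L, ...) {
  x <- as.matrix(x)
  if (k_min < 2L || k_max < k_min) {
    stop("parameter error: need 2 <= k_min <= k_max", call. = FALSE)
  }
  k_max <- min(k_max, nrow(unique(x)))
  dm <- as.matrix(stats::dist(x))
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  sil <- numeric(length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- kmeans_fit(x, ks[i], seed = derive_seed(seed, ks[i]), ...)
    sil[i] <- mean_silhouette(NULL, fits[[i]]$labels, dist_matrix = dm)
  }
  names(sil) <- ks
  best <- which.max(sil)  # ties -> first, i.e. smallest k
  fit <- fits[[best]]
  structure(list(k = ks[best], centroids = fit$centroids,
                 labels = fit$labels, silhouette_by_k = sil,
                 inertia = fit$inertia, seed = seed),
            class = "cluster_model")
}

#' Build a cluster model at a fixed k
#'
#' Like [select_k()] but with k given; `silhouette_by_k` then holds the
#' single evaluated k.
#'
#' @inheritParams select_k
#' @param k number of clusters.
#' @return a `cluster_model`.
#' @export
cluster_fixed_k <- function(x, k, seed = 1L, ...) {
  x <- as.matrix(x)
  fit <- kmeans_fit(x, k, seed = derive_seed(seed, k), ...)
  sil <- mean_silhouette(x, fit$labels)
  names(sil) <- k
  structure(list(k = as.integer(k), centroids = fit$centroids,
                 labels = fit$labels, silhouette_by_k = sil,
                 inertia = fit$inertia, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: k = %d, mean silhouette %.3f, inertia %.3f>\n",
              x$k, x$silhouette_by_k[as.character(x$k)], x$inertia))
  if (length(x$silhouette_by_k) > 1L) {
    cat("  silhouette by k:",
        paste(sprintf("%s:%.3f", names(x$silhouette_by_k), x$silhouette_by_k),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Route feature rows to their nearest cluster
#'
#' Scales the rows with the training scaler and assigns each to the
#' Euclidean-nearest centroid (ties break to the lowest cluster index).
#' This is the prediction-time routing of the per-cluster ensemble.
#'
#' @param model a `cluster_model`.
#' @param scaler the `bp_scaler` the model was fitted under.
#' @param features feature table rows (or scaled matrix via
#'   `scaled = TRUE`).
#' @param scaled logical; `TRUE` means `features` is already in scaled
#'   space.
#' @return integer vector of 1-based cluster indices.
#' @export
assign_cluster <- function(model, scaler, features, scaled = FALSE) {
  stopifnot(inherits(model, "cluster_model"))
  x <- if (scaled) as.matrix(features) else apply_scaler(scaler, features)
  d2 <- dist2_to_centers(x, model$centroids)
  max.col(-d2, ties.method = "first")
}

#' Serialize / restore a cluster model with its scaler as JSON
#'
#' @param model a `cluster_model`.
#' @param scaler a `bp_scaler`.
#' @param path output path.
#' @return `path` (write) / list with `model` and `scaler` (read).
#' @export
write_cluster_model <- function(model, scaler, path) {
  obj <- list(
    k = model$k,
    centroids = unname(apply(model$centroids, 1L, as.numeric, simplify = FALSE)),
    silhouette_by_k = as.list(model$silhouette_by_k),
    inertia = model$inertia,
    seed = model$seed,
    labels = model$labels,
    scaler = list(center = as.list(scaler$center),
                  scale = as.list(scaler$scale),
                  columns = scaler$columns)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- if (is.list(obj$centroids)) {
    do.call(rbind, lapply(obj$centroids, as.numeric))
  } else {
    as.matrix(obj$centroids)
  }
  model <- structure(list(k = as.integer(obj$k), centroids = centroids,
                          labels = as.integer(obj$labels),
                          silhouette_by_k = unlist(obj$silhouette_by_k),
                          inertia = obj$inertia, seed = obj$seed),
                     class = "cluster_model")
  scaler <- structure(list(center = unlist(obj$scaler$center),
                           scale = unlist(obj$scaler$scale),
                           columns = unlist(obj$scaler$columns)),
                      class = "bp_scaler")
  list(model = model, scaler = scaler)
}
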