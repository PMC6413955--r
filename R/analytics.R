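#' Min-max normalize a feature matrix
#'
#' Remaps each feature (row: a flux or a transcript) into `[0, 1]`: the
#' cell with the lowest value gets 0, the highest gets 1. Constant rows
#' become all zeros. Normalization prevents features with typically large
#' values from dominating Euclidean distances, and is idempotent.
#'
#' @param values numeric feature x cell matrix with finite entries.
#' @param kind `"flux"` or `"transcript"` (metadata only).
#' @return a `feature_matrix`: the normalized matrix with attribute
#'   `feature_kind`.
#' @export
minmax_normalize <- function(values, kind = c("flux", "transcript")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), all(is.finite(values)))
  rmin <- apply(values, 1, min)
  rmax <- apply(values, 1, max)
  span <- rmax - rmin
  out <- (values - rmin) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0
  structure(out, feature_kind = kind, class = c("feature_matrix", "matrix", "array"))
}

feat_mat <- function(features) {
  m <- unclass(features)
  attr(m, "feature_kind") <- NULL
  m
}

#' Hierarchical clustering of cells
#'
#' Agglomerative clustering of cells (columns) with Euclidean distance on
#' the normalized features, as used for clustergram displays.
#'
#' @param features a [minmax_normalize()]d matrix (features x cells).
#' @param method linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return an `hclust` tree over cells.
#' @export
hierarchical_cluster <- function(features, method = "average") {
  m <- feat_mat(features)
  if (ncol(m) < 2L) stop("hierarchical clustering needs at least 2 cells")
  stats::hclust(stats::dist(t(m), method = "euclidean"), method = method)
}

#' Best-of-restarts k-means clustering
#'
#' Runs k-means `n_restarts` times from random centroid assignments
#' (centroids drawn uniformly among distinct cells) and keeps the run with
#' the maximum between-cluster sum of squares — equivalently the minimum
#' within-cluster SSE, since the total is fixed. Deterministic for a given
#' seed.
#'
#' @param features a [minmax_normalize()]d matrix (features x cells).
#' @param k number of clusters, `2 <= k <= N_cells` (with `k = N_cells`
#'   every cell is its own cluster and SSE is 0).
#' @param n_restarts number of random restarts (default 100).
#' @param seed integer seed.
#' @return integer vector of cluster labels named by cell, with attributes
#'   `sse` (within-cluster sum of squares) and `betweenss`.
#' @export
kmeans_bootstrap <- function(features, k, n_restarts = 100, seed = 1) {
  m <- feat_mat(features)
  n <- ncol(m)
  if (k > n) stop(sprintf("k = %d exceeds the number of cells (%d)", k, n))
  if (k < 1) stop("k must be >= 1")
  X <- t(m)
  if (k == n) {
    labels <- stats::setNames(seq_len(n), colnames(m))
    attr(labels, "sse") <- 0
    attr(labels, "betweenss") <- total_ss(X)
    return(labels)
  }
  if (k == 1L) {
    labels <- stats::setNames(rep(1L, n), colnames(m))
    attr(labels, "sse") <- total_ss(X)
    attr(labels, "betweenss") <- 0
    return(labels)
  }
  Xu <- unique(X)
  if (nrow(Xu) < k) stop(sprintf("only %d distinct cells for k = %d", nrow(Xu), k))
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- Xu[sample.int(nrow(Xu), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 50)),
        error = function(e) NULL)  # a restart can die on an empty cluster
      if (!is.null(fit) && (is.null(best) || fit$betweenss > best$betweenss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) stop("all k-means restarts failed")
  labels <- stats::setNames(best$cluster, colnames(m))
  attr(labels, "sse") <- best$tot.withinss
  attr(labels, "betweenss") <- best$betweenss
  labels
}

total_ss <- function(X) sum(scale(X, scale = FALSE)^2)

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Elbow and silhouette diagnostics over a range of cluster counts
#'
#' For each `k` in `k_range` runs [kmeans_bootstrap()] and records the
#' within-cluster SSE (elbow curve) and, for `k >= 2`, per-cell and
#' average silhouette coefficients (Euclidean distance on the normalized
#' features).
#'
#' @param features a [minmax_normalize()]d matrix (features x cells).
#' @param k_range integer vector of cluster counts (default `1:20`,
#'   truncated at the number of cells).
#' @param n_restarts restarts per `k`.
#' @param seed integer seed.
#' @return object of class `cluster_report`: list with `k`, `sse`,
#'   `silhouette_avg`, `silhouette` (per-cell, per-k list), `labels`
#'   (cells x k matrix).
#' @export
elbow_and_silhouette <- function(features, k_range = 1:20, n_restarts = 100,
                                 seed = 1) {
  m <- feat_mat(features)
  k_range <- k_range[k_range >= 1 & k_range <= ncol(m)]
  if (!length(k_range)) stop("empty k_range after truncation")
  d <- stats::dist(t(m), method = "euclidean")
  sse <- numeric(length(k_range))
  sil_avg <- rep(NA_real_, length(k_range))
  sil <- vector("list", length(k_range))
  labels <- matrix(NA_integer_, nrow = ncol(m), ncol = length(k_range),
                   dimnames = list(colnames(m), paste0("k", k_range)))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- kmeans_bootstrap(features, k, n_restarts = n_restarts,
                            seed = seed + i)
    labels[, i] <- lab
    sse[i] <- attr(lab, "sse")
    if (k >= 2 && length(unique(lab)) >= 2) {
      s <- cluster::silhouette(as.integer(lab), d)
      sil[[i]] <- s[, "sil_width"]
      sil_avg[i] <- mean(s[, "sil_width"])
    }
  }
  structure(list(k = k_range, sse = sse, silhouette_avg = sil_avg,
                 silhouette = sil, labels = labels),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report>\n")
  print(data.frame(k = x$k, sse = x$sse, silhouette_avg = x$silhouette_avg))
  invisible(x)
}

#' Two-sample z contrast between two cell clusters
#'
#' For each feature computes the unequal-variance two-sample z statistic
#' `z = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)` with a normal reference,
#' and flags features whose `|z|` exceeds the two-sided critical value at
#' the given confidence level (2.576 at 99%). No multiple-testing
#' correction is applied: the confidence level is per-feature.
#'
#' @param features a [minmax_normalize()]d matrix (features x cells).
#' @param labels two-group partition of the cells (any two-valued vector,
#'   or the output of [kmeans_bootstrap()] with `k = 2`).
#' @param confidence per-feature confidence level (default 0.99).
#' @return data.frame `feature`, `z`, `significant`; attribute
#'   `critical_value`.
#' @export
zscore_between_clusters <- function(features, labels, confidence = 0.99) {
  m <- feat_mat(features)
  groups <- unique(labels)
  if (length(groups) != 2L) stop("labels must define exactly two groups")
  i1 <- which(labels == groups[1]); i2 <- which(labels == groups[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("both groups need at least 2 cells (variance undefined otherwise)")
  }
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  se <- sqrt(v1 / length(i1) + v2 / length(i2))
  z <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  crit <- stats::qnorm(1 - (1 - confidence) / 2)
  out <- data.frame(feature = rownames(m), z = z,
                    significant = abs(z) > crit,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "critical_value") <- crit
  out
}
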