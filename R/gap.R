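## Gap-statistic cluster-number selection and profile clustering.
##
## The gap statistic compares log within-cluster dispersion on the data
## against its expectation under a uniform reference drawn per feature over
## the observed range: Gap(k) = mean_b log W*_kb - log W_k, with
## s_k = sd_b(log W*_kb) * sqrt(1 + 1/B).  K-means (best-of-restarts Lloyd
## with k-means++ seeding) evaluates the curve by default; the final gene
## assignment uses hierarchical complete-linkage Euclidean clustering.

#' Total within-cluster dispersion
#'
#' `W = sum_r sum_{i in C_r} ||x_i - centroid_r||^2`, equal to
#' `sum_r D_r / (2 n_r)` with `D_r` the sum of pairwise squared Euclidean
#' distances inside cluster r.
#'
#' @param X item x feature numeric matrix.
#' @param labels cluster label per item; a label level with no items is an
#'   error.
#' @return non-negative scalar.
#' @export
within_dispersion <- function(X, labels) {
  X <- as.matrix(X)
  if (length(labels) != nrow(X))
    stop("labels must cover all items", call. = FALSE)
  f <- if (is.factor(labels)) labels else factor(labels)
  if (any(table(f) == 0))
    stop("empty cluster label: ",
         paste(levels(f)[table(f) == 0], collapse = ", "), call. = FALSE)
  n_r <- as.numeric(table(f))
  cent <- rowsum(X, f) / n_r
  sum(X^2) - sum(n_r * rowSums(cent^2))
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (k == 1L) return(centers)
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (c in 2L:k) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[c, ] <- X[i, ]
    d2c <- rowSums((X - matrix(centers[c, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, d2c)
  }
  centers
}

#' K-means clustering of profiles
#'
#' Best-of-restarts Lloyd iterations with k-means++ seeding; deterministic
#' under `seed`.  Restarts that produce an empty cluster are redrawn.
#'
#' @param X item x feature matrix.
#' @param k number of clusters (`1 <= k <=` number of items).
#' @param restarts independent seedings; the solution with the smallest
#'   within-cluster dispersion wins.
#' @param seed RNG seed.
#' @return integer label vector (1..k).
#' @export
kmeans_cluster <- function(X, k, restarts = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " exceeds number of items (", n, ")", call. = FALSE)
  if (k == n) return(seq_len(n))
  if (k == 1L) return(rep(1L, n))
  best <- NULL
  best_w <- Inf
  with_seed(seed, {
    tries <- 0L
    done <- 0L
    while (done < restarts && tries < restarts * 5L) {
      tries <- tries + 1L
      centers <- kmeanspp_init(X, k)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < k) next
      done <- done + 1L
      if (km$tot.withinss < best_w) {
        best_w <- km$tot.withinss
        best <- km$cluster
      }
    }
  })
  if (is.null(best))
    stop("k-means failed to find ", k, " non-empty clusters", call. = FALSE)
  as.integer(best)
}

#' Hierarchical clustering of profiles
#'
#' Complete-linkage agglomeration on Euclidean distances, cut to exactly
#' `k` clusters.  Labels are contiguous 1..k in order of first appearance.
#'
#' @inheritParams kmeans_cluster
#' @return integer label vector (1..k).
#' @export
hierarchical_cluster <- function(X, k) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k = ", k, " exceeds number of items (", nrow(X), ")",
                        call. = FALSE)
  hc <- stats::hclust(stats::dist(X, method = "euclidean"), method = "complete")
  as.integer(stats::cutree(hc, k = k))
}

#' Gap-statistic configuration
#'
#' @param kmax largest cluster number evaluated (default 100; clipped to
#'   n_items - 1 with a warning).
#' @param B number of uniform reference datasets (default 50).
#' @param clusterer `"kmeans"` (default) or `"hierarchical"` for evaluating
#'   the curve.
#' @param restarts k-means restarts per evaluation.
#' @param rule selection rule for [select_k()].
#' @param seed RNG seed driving references and k-means seeding.
#' @return list of class `gap_config`.
#' @export
gap_config <- function(kmax = 100, B = 50, clusterer = c("kmeans", "hierarchical"),
                       restarts = 10, rule = c("tibshirani_1se", "global_max"),
                       seed = 1) {
  stopifnot(kmax >= 1, B >= 1, restarts >= 1)
  structure(list(kmax = kmax, B = B, clusterer = match.arg(clusterer),
                 restarts = restarts, rule = match.arg(rule), seed = seed),
            class = "gap_config")
}

logW_curve <- function(X, kmax, clusterer, restarts, seed) {
  if (clusterer == "hierarchical") {
    hc <- stats::hclust(stats::dist(X, method = "euclidean"), method = "complete")
    vapply(seq_len(kmax), function(k)
      log(within_dispersion(X, stats::cutree(hc, k = k))), 0)
  } else {
    vapply(seq_len(kmax), function(k)
      log(within_dispersion(X, kmeans_cluster(X, k, restarts = restarts,
                                              seed = seed + k))), 0)
  }
}

#' Compute the gap-statistic curve
#'
#' @param X item x feature matrix (>= 3 items).
#' @param config a [gap_config()].
#' @return data.frame of class `gap_curve` with columns `k`, `logW`,
#'   `logW_ref`, `gap`, `s_k`.
#' @export
gap_statistic <- function(X, config = gap_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 items for the gap statistic", call. = FALSE)
  kmax <- config$kmax
  if (kmax >= n) {
    warning("kmax clipped from ", kmax, " to ", n - 1L, " (log W undefined at k = n)")
    kmax <- n - 1L
  }
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  logW <- logW_curve(X, kmax, config$clusterer, config$restarts,
                     stream_seed(config$seed, "obs"))
  ref <- matrix(NA_real_, config$B, kmax)
  for (b in seq_len(config$B)) {
    sb <- stream_seed(config$seed, paste0("ref", b))
    Xb <- with_seed(sb, {
      m <- matrix(stats::runif(n * ncol(X)), n, ncol(X))
      sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
    })
    ref[b, ] <- logW_curve(Xb, kmax, config$clusterer, config$restarts, sb + 1L)
  }
  logW_ref <- colMeans(ref)
  s_k <- apply(ref, 2, stats::sd) * sqrt(1 + 1 / config$B)
  structure(data.frame(k = seq_len(kmax), logW = logW, logW_ref = logW_ref,
                       gap = logW_ref - logW, s_k = s_k),
            class = c("gap_curve", "data.frame"))
}

#' Select the cluster number from a gap curve
#'
#' `tibshirani_1se`: smallest k with `Gap(k) >= Gap(k+1) - s_{k+1}`;
#' `global_max`: argmax of Gap (smallest k on ties).
#'
#' @param curve a [gap_statistic()] result.
#' @param rule selection rule.
#' @return integer K.
#' @export
select_k <- function(curve, rule = c("tibshirani_1se", "global_max")) {
  rule <- match.arg(rule)
  gap <- curve$gap
  kmax <- max(curve$k)
  if (rule == "global_max") {
    k <- curve$k[which.max(gap)]
    if (k == kmax)
      warning("gap is maximal at kmax = ", kmax, "; consider raising kmax")
    return(as.integer(k))
  }
  for (i in seq_len(kmax - 1L)) {
    if (gap[i] >= gap[i + 1L] - curve$s_k[i + 1L]) return(as.integer(curve$k[i]))
  }
  warning("1-SE criterion never satisfied below kmax = ", kmax,
          "; consider raising kmax")
  as.integer(kmax)
}

#' Cluster profiles into K groups
#'
#' @param X item x feature matrix (genes x timepoints, typically z-scores
#'   with gene rownames).
#' @param K number of clusters (from [select_k()] or user-supplied).
#' @param method `"hierarchical"` (default: complete linkage, Euclidean) or
#'   `"kmeans"`.
#' @param restarts,seed k-means parameters (ignored for hierarchical).
#' @return list of class `cluster_assignment`: named integer `labels`, `K`,
#'   `method` and distance/linkage metadata.
#' @export
assign_clusters <- function(X, K, method = c("hierarchical", "kmeans"),
                            restarts = 10, seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  labels <- if (method == "hierarchical") hierarchical_cluster(X, K)
            else kmeans_cluster(X, K, restarts = restarts, seed = seed)
  names(labels) <- rownames(X)
  meta <- if (method == "hierarchical")
    list(distance = "euclidean", linkage = "complete")
  else list(restarts = restarts, seed = seed, init = "kmeans++")
  structure(list(labels = labels, K = as.integer(K), method = method,
                 metadata = meta),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: K =", x$K, "(", x$method, ");",
      length(x$labels), "items\n")
  print(table(x$labels))
  invisible(x)
}

#' Mean temporal profile per cluster
#'
#' @param assignment a [assign_clusters()] result.
#' @param X the profile matrix it was computed on.
#' @return cluster x timepoint matrix of mean profiles.
#' @export
cluster_profiles <- function(assignment, X) {
  X <- as.matrix(X)
  f <- factor(assignment$labels, levels = seq_len(assignment$K))
  out <- rowsum(X, f) / as.numeric(table(f))
  rownames(out) <- paste0("cluster_", seq_len(assignment$K))
  out
}
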