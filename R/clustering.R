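#' Supported dissimilarities for the clustering analysis
#'
#' Canberra follows the usual |x-y| / (|x| + |y|) convention with 0/0
#' terms contributing 0 (features are min-max normalized to \[0, 1\], so
#' this matches [stats::dist()] on its support).
#'
#' @format Character vector of the five dissimilarity names.
#' @export
cg_distances <- c("euclidean", "sq_euclidean", "manhattan", "chebyshev",
                  "canberra")

# Distance between one point (vector) and a matrix of points (rows).
point_dist <- function(x, m, distance) {
  d <- sweep(m, 2, x)
  switch(distance,
    euclidean = sqrt(rowSums(d^2)),
    sq_euclidean = rowSums(d^2),
    manhattan = rowSums(abs(d)),
    chebyshev = apply(abs(d), 1, max),
    canberra = {
      num <- abs(d)
      den <- abs(sweep(m, 2, x, "+"))
      rowSums(ifelse(den == 0, 0, num / den))
    },
    cg_abort("cg_error_unknown_distance", "unknown distance: %s", distance))
}

#' Pairwise dissimilarity matrix
#'
#' @param features Numeric matrix (rows = slices, columns = features).
#' @param distance One of `"euclidean"`, `"sq_euclidean"`, `"manhattan"`,
#'   `"chebyshev"`, `"canberra"`.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
pairwise_dist <- function(features, distance = cg_distances) {
  distance <- match.arg(distance)
  n <- nrow(features)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    out[i, ] <- point_dist(features[i, ], features, distance)
  }
  (out + t(out)) / 2
}

#' Min-max normalize feature columns to \[0, 1\]
#'
#' Constant columns map to 0 (they carry no clustering information).
#'
#' @param features Numeric matrix.
#' @return Matrix of the same shape with every column in \[0, 1\].
#' @export
normalize_features <- function(features) {
  apply(features, 2, function(col) {
    rng <- range(col)
    if (rng[2] > rng[1]) (col - rng[1]) / (rng[2] - rng[1]) else col * 0
  })
}

#' Clustering feature matrix from evaluations and contrasts
#'
#' Builds the per-slice feature vectors used by the clustering analysis —
#' detection, DSC, HD, RAAD (signed) and Fisher's ratio — min-max
#' normalized to \[0, 1\] per feature.
#'
#' @param evals data.frame from [evaluate_dataset()].
#' @param contrasts data.frame with `slice_id`, `fisher`.
#' @param include_detection Keep the binary detection feature.
#' @return List with `features` (matrix) and `slice_id`, `fisher`
#'   (vectors, row-parallel).
#' @export
cluster_feature_matrix <- function(evals, contrasts,
                                   include_detection = TRUE) {
  f <- contrasts$fisher[match(evals$slice_id, contrasts$slice_id)]
  cg_assert(all(is.finite(f)), "cg_error_unpaired",
            "missing contrast for some evaluated slices")
  m <- cbind(detection = evals$detection, dsc = evals$dsc, hd = evals$hd,
             raad = evals$raad, fisher = f)
  if (!include_detection) m <- m[, colnames(m) != "detection", drop = FALSE]
  list(features = normalize_features(m), slice_id = evals$slice_id,
       fisher = f)
}

#' Two-cluster partition of slices
#'
#' K-means (k = 2) or agglomerative hierarchical clustering under one of
#' five dissimilarities. K-means draws `restarts` seeded initializations
#' (two distinct points as initial centroids), assigns points to the
#' nearest centroid under the chosen distance, updates centroids as
#' component-wise means, and keeps the restart with the smallest
#' within-cluster distance sum. Hierarchical clustering merges the closest
#' clusters (average linkage) until two remain. The silhouette is computed
#' under the same dissimilarity. Labels are canonicalized so cluster 1 has
#' the higher mean feature sum, making output independent of restart
#' ordering.
#'
#' @param features Numeric feature matrix, rows = slices, already
#'   normalized to \[0, 1\] (see [cluster_feature_matrix()]).
#' @param algorithm `"kmeans"` or `"hierarchical"`.
#' @param distance One of [pairwise_dist()]'s dissimilarities.
#' @param restarts K-means restarts.
#' @param seed Integer seed; restart seeds are derived deterministically.
#' @return List of class `cg_cluster_result`: `algorithm`, `distance`,
#'   `labels` (0/1), `centroids` (2 x p), `silhouette`, `objective`,
#'   `seed`.
#' @export
cluster_slices <- function(features, algorithm = c("kmeans", "hierarchical"),
                           distance = cg_distances, restarts = 10,
                           seed = 1) {
  algorithm <- match.arg(algorithm)
  distance <- match.arg(distance)
  features <- as.matrix(features)
  n <- nrow(features)
  cg_assert(n >= 2, "cg_error_too_few_points", "need at least 2 slices")
  cg_assert(all(is.finite(features)), "cg_error_nonfinite_features",
            "features must be finite")
  cg_assert(nrow(unique(features)) >= 2, "cg_error_degenerate_clustering",
            "all points identical: no 2-cluster structure")
  if (algorithm == "kmeans") {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- kmeans2_once(features, distance,
                          seed = as.integer(seed) * 1000L + r)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    labels <- best$labels
    objective <- best$objective
  } else {
    d <- pairwise_dist(features, distance)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    labels <- unname(stats::cutree(hc, k = 2)) - 1L
    objective <- NA_real_
  }
  # canonical orientation: cluster 1 = higher mean feature sum
  means <- tapply(rowSums(features), labels, mean)
  if (means["0"] > means["1"]) labels <- 1L - labels
  centroids <- rbind(colMeans(features[labels == 0L, , drop = FALSE]),
                     colMeans(features[labels == 1L, , drop = FALSE]))
  sil <- silhouette_score(pairwise_dist(features, distance), labels)
  structure(list(algorithm = algorithm, distance = distance,
                 labels = labels, centroids = centroids,
                 silhouette = sil, objective = objective,
                 seed = as.integer(seed)),
            class = "cg_cluster_result")
}

# One seeded k-means run (k = 2): init on two distinct sampled points;
# assignment under `distance`, centroid update = component-wise mean; a
# cluster that empties is refilled with the point farthest from the other
# centroid. Converges to an assignment fixed point (objective never
# increases).
kmeans2_once <- function(features, distance, seed, max_iter = 100) {
  n <- nrow(features)
  centroids <- with_local_seed(seed, {
    repeat {
      idx <- sample(n, 2)
      if (!all(features[idx[1], ] == features[idx[2], ])) break
    }
    features[idx, , drop = FALSE]
  })
  labels <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d0 <- point_dist(centroids[1, ], features, distance)
    d1 <- point_dist(centroids[2, ], features, distance)
    new_labels <- as.integer(d1 < d0)
    if (all(new_labels == 0L)) {
      new_labels[which.max(d0)] <- 1L
    } else if (all(new_labels == 1L)) {
      new_labels[which.max(d1)] <- 0L
    }
    if (iter > 1 && all(new_labels == labels)) break
    labels <- new_labels
    centroids <- rbind(colMeans(features[labels == 0L, , drop = FALSE]),
                       colMeans(features[labels == 1L, , drop = FALSE]))
  }
  d0 <- point_dist(centroids[1, ], features, distance)
  d1 <- point_dist(centroids[2, ], features, distance)
  list(labels = labels, centroids = centroids,
       objective = sum(ifelse(labels == 0L, d0, d1)))
}

#' Mean silhouette score of a partition
#'
#' For each point, cohesion a(i) is the mean dissimilarity to its own
#' cluster (excluding itself) and separation b(i) the mean dissimilarity
#' to the other cluster; its silhouette is (b - a) / max(a, b), zero for
#' singletons. Returns the mean over all points, in \[-1, 1\].
#'
#' @param d Pairwise dissimilarity matrix.
#' @param labels Integer cluster labels (two clusters).
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(d, labels) {
  n <- nrow(d)
  cg_assert(length(labels) == n, "cg_error_dim_mismatch",
            "labels do not match the dissimilarity matrix")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_len(n) != i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Purity of a two-cluster partition against a contrast cutoff
#'
#' Reference labels split slices at a Fisher's-ratio cutoff (`F <
#' purity_threshold` vs `F >= purity_threshold`); purity is the accuracy
#' of the best of the two cluster-to-label assignments — equivalently the
#' majority-vote mapping for two clusters. Undefined (reported, not
#' raised) when one reference class is empty.
#'
#' @param result `cg_cluster_result` from [cluster_slices()].
#' @param fisher Per-slice Fisher's ratios, parallel to the clustered rows.
#' @param purity_threshold Fisher's-ratio cutoff defining the reference
#'   classes.
#' @return List with `purity` (in \[0, 1\] or `NA`), `silhouette`, and
#'   `reason` (`NA` or why purity is undefined).
#' @export
cluster_quality <- function(result, fisher, purity_threshold) {
  cg_assert(length(fisher) == length(result$labels), "cg_error_dim_mismatch",
            "fisher vector does not match cluster labels")
  ref <- as.integer(fisher >= purity_threshold)
  if (length(unique(ref)) < 2) {
    return(list(purity = NA_real_, silhouette = result$silhouette,
                reason = "one reference class is empty"))
  }
  acc <- mean(result$labels == ref)
  list(purity = max(acc, 1 - acc), silhouette = result$silhouette,
       reason = NA_character_)
}
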