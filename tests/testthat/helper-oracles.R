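# Independent brute-force oracles. Deliberately naive (per-pixel and
# all-pairs loops) so they share no code path with the implementation.

oracle_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == 1
      g <- gt[i, j] == 1
      if (p && g) tp <- tp + 1L
      else if (p && !g) fp <- fp + 1L
      else if (!p && g) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_hausdorff <- function(pred, gt) {
  a <- which(pred == 1, arr.ind = TRUE)
  b <- which(gt == 1, arr.ind = TRUE)
  directed <- function(x, y) {
    worst <- 0
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y))) {
        d <- sqrt(sum((x[i, ] - y[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(a, b), directed(b, a))
}

oracle_point_dist <- function(x, y, distance) {
  switch(distance,
    euclidean = sqrt(sum((x - y)^2)),
    sq_euclidean = sum((x - y)^2),
    manhattan = sum(abs(x - y)),
    chebyshev = max(abs(x - y)),
    canberra = {
      num <- abs(x - y)
      den <- abs(x) + abs(y)
      sum(ifelse(den == 0, 0, num / den))
    })
}

oracle_dist_matrix <- function(features, distance) {
  n <- nrow(features)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- oracle_point_dist(features[i, ], features[j, ], distance)
    }
  }
  d
}

oracle_silhouette <- function(features, labels, distance) {
  d <- oracle_dist_matrix(features, distance)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    other <- which(labels != labels[i])
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- mean(d[i, other])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Best 2-partition by exhaustive search (mean centroids, objective = sum
# of the chosen distance from each point to its centroid). Feasible for
# n <= 12.
oracle_best_partition <- function(features, distance) {
  n <- nrow(features)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    labels <- as.integer(intToBits(code))[seq_len(n)]
    if (sum(labels) == 0 || sum(labels) == n) next
    obj <- 0
    for (k in 0:1) {
      pts <- features[labels == k, , drop = FALSE]
      ctr <- colMeans(pts)
      for (i in seq_len(nrow(pts))) {
        obj <- obj + oracle_point_dist(pts[i, ], ctr, distance)
      }
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(labels = labels, objective = obj)
    }
  }
  best
}

# Exact one-sided signed-rank p-value by enumerating all 2^n sign
# assignments of |d| (zeros must be removed by the caller).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  count <- 0
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code))[seq_len(n)]
    if (sum(r[signs == 1]) >= w_obs) count <- count + 1
  }
  count / 2^n
}

# Small random 0/1 mask with at most `max_px` foreground pixels.
random_mask <- function(side, max_px, rng) {
  m <- matrix(0L, side, side)
  n_px <- rng(1L, max_px)
  idx <- sample(side * side, n_px)
  m[idx] <- 1L
  m
}
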