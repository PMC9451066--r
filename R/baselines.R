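#' K-means as binary-assignment archetypal analysis
#'
#' When the convexity constraint on the archetypes is dropped and each
#' ancestry-fraction row is restricted to a one-hot vector, the alternating
#' solver reduces to Lloyd's algorithm: hard assignment to the nearest
#' center, then unconstrained center update as the mean of assigned points.
#'
#' @param data numeric N x D matrix.
#' @param k number of clusters, k <= N.
#' @param seed integer seed; initial centers are k distinct data rows.
#' @param init_centers optional k x D matrix of starting centers (overrides
#'   the seeded choice; useful to share an init with a reference
#'   implementation).
#' @param max_iter iteration cap; default 100.
#' @return list of class `hard_clustering`: `labels` (N integers in 1..k),
#'   `centers` (k x D), `inertia` (total within-cluster sum of squares),
#'   `empty` (logical length-k flags for clusters that ended empty before
#'   re-seeding was possible).
#' @export
kmeans_binary_alpha <- function(data, k, seed = 1L, init_centers = NULL,
                                max_iter = 100L) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (k > n) stop(sprintf("k = %d exceeds N = %d", k, n))
  centers <- if (is.null(init_centers)) {
    data[random_init(data, k, mode = "sample", seed = seed), , drop = FALSE]
  } else {
    as.matrix(init_centers)
  }
  labels <- rep(0L, n)
  empty <- rep(FALSE, k)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(data, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    if (all(new_labels == labels)) break
    labels <- new_labels
    empty <- tabulate(labels, k) == 0L
    for (kk in seq_len(k)) {
      members <- labels == kk
      if (any(members)) {
        centers[kk, ] <- colMeans(data[members, , drop = FALSE])
      } else if (length(unique(labels)) < k && n > length(unique(labels))) {
        # re-seed an empty cluster at the farthest point from its center,
        # unless the data cannot support k distinct clusters
        resid <- rowSums((data - centers[labels, , drop = FALSE])^2)
        if (max(resid) > 0) {
          centers[kk, ] <- data[which.max(resid), ]
          empty[kk] <- FALSE
        }
      }
    }
  }
  inertia <- sum((data - centers[labels, , drop = FALSE])^2)
  structure(list(labels = labels, centers = centers, inertia = inertia,
                 empty = tabulate(labels, k) == 0L),
            class = "hard_clustering")
}

# squared Euclidean distances, N x K
sq_dist <- function(data, centers) {
  dn <- rowSums(data^2)
  cn <- rowSums(centers^2)
  outer(dn, cn, `+`) - 2 * tcrossprod(data, centers)
}

#' K-medoids as doubly-binary archetypal analysis
#'
#' Restricting both the ancestry fractions and the archetype weights to
#' one-hot vectors forces every center to be an observed sample (a medoid);
#' alternating descent then assigns each point to its nearest medoid and
#' moves each medoid to the member of its cluster minimizing the
#' within-cluster squared-Euclidean cost. Ties break toward the lower index.
#'
#' @inheritParams kmeans_binary_alpha
#' @return list of class `hard_clustering` with `medoid_idx` (k row
#'   indices) in addition to `labels`, `centers`, `inertia`.
#' @export
kmedoids_binary <- function(data, k, seed = 1L, max_iter = 100L) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (k > n) stop(sprintf("k = %d exceeds N = %d", k, n))
  med <- sort(random_init(data, k, mode = "sample", seed = seed))
  labels <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(data, data[med, , drop = FALSE])
    labels <- max.col(-d2, ties.method = "first")
    new_med <- med
    for (kk in seq_len(k)) {
      members <- which(labels == kk)
      if (length(members) == 0) next
      costs <- vapply(members, function(i) {
        sum(sq_dist(data[members, , drop = FALSE],
                    data[i, , drop = FALSE]))
      }, numeric(1))
      new_med[kk] <- members[which.min(costs)]
    }
    if (all(new_med == med)) break
    med <- new_med
  }
  d2 <- sq_dist(data, data[med, , drop = FALSE])
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  structure(list(labels = labels, centers = data[med, , drop = FALSE],
                 medoid_idx = med, inertia = inertia,
                 empty = tabulate(labels, k) == 0L),
            class = "hard_clustering")
}

#' @export
print.hard_clustering <- function(x, ...) {
  cat(sprintf("hard_clustering: k = %d, N = %d, inertia = %.6g\n",
              nrow(x$centers), length(x$labels), x$inertia))
  invisible(x)
}

#' Match columns of two assignment matrices
#'
#' Finds the column permutation of `b` maximizing the summed per-pair Pearson
#' correlations with the columns of `a`, by exhaustive search over the K!
#' permutations (exact optimal assignment; supported for K <= 8).
#' Zero-variance columns contribute correlation 0.
#'
#' @param a numeric N x K matrix (e.g. fitted alpha).
#' @param b numeric N x K matrix (e.g. the truth Q, or another method's
#'   output).
#' @return list with `perm` (integer permutation such that `b[, perm]` is
#'   aligned with `a`), `mean_correlation`, and `mae` (mean absolute
#'   difference between `a` and the aligned `b`).
#' @export
match_columns <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b must have identical shapes")
  k <- ncol(a)
  if (k > 8) stop("match_columns supports K <= 8 (exhaustive optimal matching)")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  cmat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cmat[i, j] <- safe_cor(a[, i], b[, j])
  }
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(cmat[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  aligned <- b[, best, drop = FALSE]
  list(perm = best,
       mean_correlation = max(scores) / k,
       mae = mean(abs(a - aligned)))
}

# all permutations of 1..k as a list
permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(p, k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
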