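#' Archetypal Analysis configuration
#'
#' Bundles the solver parameters. Defaults follow the reference settings for
#' genotype data: constraint coefficient `C = 0.001`, relative-change
#' stopping tolerance `tol = 0.001`, at most 50 alternating iterations, and
#' FurthestSum initialization.
#'
#' @param k number of archetypes (clusters).
#' @param C positive constraint coefficient of the augmented NNLS systems;
#'   smaller values enforce the sum-to-one constraints more strongly.
#' @param tol stopping tolerance on the relative RSS change between
#'   alternating iterations.
#' @param max_iter maximum number of alternating iterations.
#' @param init initialization: `"furthest_sum"`, `"random_uniform"`, or
#'   `"random_sample"`.
#' @param seed integer seed; all randomness in the fit flows from it.
#' @param restarts number of independently initialized fits; the best-RSS
#'   fit is returned.
#' @return a list of class `aa_config`.
#' @export
aa_config <- function(k, C = 0.001, tol = 0.001, max_iter = 50L,
                      init = c("furthest_sum", "random_uniform", "random_sample"),
                      seed = 1L, restarts = 1L) {
  init <- match.arg(init)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a positive integer")
  }
  if (C <= 0) stop("C must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (restarts < 1) stop("restarts must be >= 1")
  structure(list(k = as.integer(k), C = C, tol = tol,
                 max_iter = as.integer(max_iter), init = init,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "aa_config")
}

#' Fit Archetypal Analysis by alternating constrained NNLS
#'
#' Decomposes an N x D data matrix (SVD scores, or any numeric features) as
#' `data ~ alpha %*% Z`, where the rows of `alpha` (the per-sample ancestry
#' fractions) and the columns of `beta` (the per-archetype weights over
#' samples, with `Z = t(data) %*% beta` transposed to K x D) are
#' simplex-valued. The solver alternates exact simplex-constrained NNLS
#' updates of each `alpha` row and each `beta` column, recomputes the
#' residual sum of squares after every sweep, and stops when the relative
#' RSS change falls to `tol` or after `max_iter` sweeps. Each subproblem
#' update is only accepted when it does not increase its residual, so the
#' RSS trace is non-increasing.
#'
#' Archetypes that lose all alpha mass during alternation are re-seeded to
#' the sample with the largest current reconstruction residual.
#'
#' @param data numeric N x D matrix, samples in rows. Typically the scores
#'   of [fit_projection()]; centered dosages give the same RSS when all
#'   components are retained.
#' @param k number of archetypes; ignored when `config` is given.
#' @param ... passed to [aa_config()] (`C`, `tol`, `max_iter`, `init`,
#'   `seed`, `restarts`).
#' @param config an [aa_config()]; overrides `k` and `...`.
#' @param init_indices optional integer vector of K row indices used as the
#'   initial archetypes, bypassing the configured initializer (useful to
#'   compare fits on different representations of the same data from an
#'   identical start).
#' @return an object of class `aa_fit` with elements `alpha` (N x K,
#'   row-stochastic), `beta` (N x K, column-stochastic), `Z` (K x D
#'   archetypes in fit space), `rss_trace`, `rss`, `explained_variance`,
#'   `converged`, `n_iter`, `config`, and free-parameter metadata `df`
#'   (total `2NK - N - K`, split as `N(K-1)` for alpha and `K(N-1)` for
#'   beta).
#' @export
archetypal_analysis <- function(data, k, ..., config = NULL,
                                init_indices = NULL) {
  if (is.null(config)) config <- aa_config(k, ...)
  stopifnot(inherits(config, "aa_config"))
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("data must be finite")
  n <- nrow(data)
  if (config$k > n) stop(sprintf("k = %d exceeds the number of samples N = %d",
                                 config$k, n))
  best <- NULL
  for (r in seq_len(config$restarts)) {
    seed_r <- config$seed + (r - 1L) * 1009L
    fit <- aa_fit_once(data, config, seed_r,
                       if (r == 1L) init_indices else NULL)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  best
}

aa_fit_once <- function(data, config, seed, init_indices = NULL) {
  n <- nrow(data)
  d <- ncol(data)
  k <- config$k
  C <- config$C

  # --- initial archetypes ---
  beta <- matrix(0, n, k)
  if (!is.null(init_indices)) {
    idx <- as.integer(init_indices)
    if (length(idx) != k || anyDuplicated(idx) || any(idx < 1 | idx > n)) {
      stop("init_indices must be k distinct row indices")
    }
    z <- data[idx, , drop = FALSE]
    beta[cbind(idx, seq_len(k))] <- 1
  } else if (config$init == "furthest_sum") {
    idx <- furthest_sum_init(data, k, seed = seed)
    z <- data[idx, , drop = FALSE]
    beta[cbind(idx, seq_len(k))] <- 1
  } else if (config$init == "random_sample") {
    idx <- random_init(data, k, mode = "sample", seed = seed)
    z <- data[idx, , drop = FALSE]
    beta[cbind(idx, seq_len(k))] <- 1
  } else {
    z <- random_init(data, k, mode = "uniform", seed = seed)
    # beta becomes well-defined after the first beta sweep
  }
  z <- matrix(z, k, d)

  alpha <- NULL
  rss_trace <- numeric(0)
  rss_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  tdata <- t(data)                      # D x N design shared by beta updates

  for (iter in seq_len(config$max_iter)) {
    n_iter <- iter
    alpha <- update_alpha(data, z, alpha, C)
    up <- update_beta(data, tdata, alpha, beta, z, C)
    beta <- up$beta
    z <- up$z
    rss <- rss_of(data, alpha, z)
    rss_trace <- c(rss_trace, rss)
    if (is.finite(rss_prev) &&
        abs(rss - rss_prev) / max(rss_prev, .Machine$double.eps) <= config$tol) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }

  yhat <- alpha %*% z
  ev <- tryCatch(explained_variance(data, yhat), error = function(e) NA_real_)
  dimnames(alpha) <- list(rownames(data), paste0("A", seq_len(k)))
  dimnames(beta) <- list(rownames(data), paste0("A", seq_len(k)))
  structure(
    list(alpha = alpha, beta = beta, Z = z,
         rss_trace = rss_trace, rss = rss_trace[length(rss_trace)],
         explained_variance = ev, converged = converged, n_iter = n_iter,
         config = config,
         df = list(total = 2L * n * k - n - k,
                   alpha = n * (k - 1L),
                   beta = k * (n - 1L))),
    class = "aa_fit"
  )
}

# one sweep of simplex-NNLS alpha-row updates, accepting only improvements
update_alpha <- function(data, z, alpha_old, C) {
  n <- nrow(data)
  k <- nrow(z)
  tz <- t(z)                            # D x K design
  alpha <- matrix(0, n, k)
  for (i in seq_len(n)) {
    w <- constrained_simplex_nnls(tz, data[i, ], C)
    if (!is.null(alpha_old)) {
      old <- alpha_old[i, ]
      if (sum((data[i, ] - tz %*% old)^2) < sum((data[i, ] - tz %*% w)^2)) {
        w <- old
      }
    }
    alpha[i, ] <- w
  }
  alpha
}

# one sweep of simplex-NNLS beta-column updates (exact coordinate descent:
# for fixed alpha and the other columns, each column's objective is a
# least-squares problem in t(data) %*% beta_k)
update_beta <- function(data, tdata, alpha, beta, z, C) {
  n <- nrow(data)
  k <- ncol(alpha)
  for (kk in seq_len(k)) {
    a <- alpha[, kk]
    s2 <- sum(a^2)
    if (s2 < 1e-12) {
      # dead archetype: re-seed to the worst-reconstructed sample
      resid <- data - alpha %*% z
      worst <- which.max(rowSums(resid^2))
      beta[, kk] <- 0
      beta[worst, kk] <- 1
      z[kk, ] <- data[worst, ]
      next
    }
    resid_k <- data - alpha %*% z + tcrossprod(a, z[kk, ])
    target <- as.vector(crossprod(resid_k, a)) / s2
    w <- constrained_simplex_nnls(tdata, target, C)
    z_new <- as.vector(tdata %*% w)
    if (sum((z_new - target)^2) <= sum((z[kk, ] - target)^2)) {
      beta[, kk] <- w
      z[kk, ] <- z_new
    }
  }
  list(beta = beta, z = z)
}

#' Residual sum of squares of an archetypal decomposition
#'
#' Squared Frobenius norm of `data - alpha %*% z`.
#'
#' @param data N x D matrix.
#' @param alpha N x K fraction matrix.
#' @param z K x D archetype matrix.
#' @return non-negative scalar.
#' @export
rss_of <- function(data, alpha, z) {
  data <- as.matrix(data); alpha <- as.matrix(alpha); z <- as.matrix(z)
  if (ncol(alpha) != nrow(z) || nrow(alpha) != nrow(data) ||
      ncol(z) != ncol(data)) {
    stop("shape mismatch: need data (N x D), alpha (N x K), z (K x D)")
  }
  sum((data - alpha %*% z)^2)
}

#' Explained variance of a reconstruction
#'
#' `EV(y, yhat) = 1 - Var(y - yhat) / Var(y)`, with the variance pooled over
#' all matrix entries. The clustering-quality metric used to compare
#' decompositions across K.
#'
#' @param y observed matrix (or vector).
#' @param yhat reconstruction, same shape.
#' @return scalar; 1 for a perfect reconstruction, 0 for a constant
#'   reconstruction at the mean.
#' @export
explained_variance <- function(y, yhat) {
  y <- as.vector(as.matrix(y))
  yhat <- as.vector(as.matrix(yhat))
  if (length(y) != length(yhat)) stop("y and yhat must have the same shape")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) {
    stop("explained variance undefined: Var(y) is zero")
  }
  1 - stats::var(y - yhat) / vy
}

#' Express archetypes in SNP space
#'
#' Row k is the beta-weighted convex combination of the sample dosage rows,
#' i.e. the k-th archetype as a dosage-like M-vector; every entry therefore
#' lies within the observed per-variant dosage range.
#'
#' @param g a [genotype_matrix] (or plain dosage matrix).
#' @param beta N x K matrix with non-negative entries and columns summing
#'   to 1.
#' @return K x M matrix.
#' @export
archetypes_in_snp_space <- function(g, beta) {
  x <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(x)) stop("beta must have one row per sample")
  if (any(beta < -1e-9)) stop("beta entries must be non-negative")
  if (any(abs(colSums(beta) - 1) > 1e-4)) stop("beta columns must sum to 1")
  out <- crossprod(beta, x)
  rownames(out) <- paste0("A", seq_len(ncol(beta)))
  out
}

#' @export
print.aa_fit <- function(x, ...) {
  cat(sprintf("aa_fit: K = %d archetypes over N = %d samples (D = %d)\n",
              ncol(x$alpha), nrow(x$alpha), ncol(x$Z)))
  cat(sprintf("  RSS = %.6g, explained variance = %.4f\n",
              x$rss, x$explained_variance))
  cat(sprintf("  %s after %d iteration(s); init = %s, seed = %d\n",
              if (x$converged) "converged" else "stopped at max_iter",
              x$n_iter, x$config$init, x$config$seed))
  invisible(x)
}

#' Tidy an archetypal fit into long format
#'
#' @param x an `aa_fit`.
#' @param ... unused.
#' @return tibble with columns `sample`, `archetype`, `alpha`, `beta`.
#' @importFrom generics tidy
#' @export
tidy.aa_fit <- function(x, ...) {
  n <- nrow(x$alpha)
  k <- ncol(x$alpha)
  samples <- rownames(x$alpha) %||% paste0("ind_", seq_len(n))
  tibble::tibble(
    sample = rep(samples, times = k),
    archetype = rep(colnames(x$alpha), each = n),
    alpha = as.vector(x$alpha),
    beta = as.vector(x$beta)
  )
}

#' One-row fit summary
#'
#' @param x an `aa_fit`.
#' @param ... unused.
#' @return tibble with k, rss, explained_variance, n_iter, converged, and
#'   free-parameter counts.
#' @importFrom generics glance
#' @export
glance.aa_fit <- function(x, ...) {
  tibble::tibble(
    k = ncol(x$alpha),
    n = nrow(x$alpha),
    rss = x$rss,
    explained_variance = x$explained_variance,
    n_iter = x$n_iter,
    converged = x$converged,
    df_total = x$df$total,
    df_alpha = x$df$alpha,
    df_beta = x$df$beta
  )
}
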