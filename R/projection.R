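#' Center genotypes and compute SVD scores
#'
#' Centers each variant column by its mean and computes the thin singular
#' value decomposition X_c = U Sigma V'. Because centered genotype vectors of
#' N samples span at most N - 1 dimensions, at most N - 1 components are
#' retained and the scores X' = U Sigma carry all the information in the
#' data: the map is a rotation, so distances, and the archetypal-analysis
#' residual sum of squares, are preserved. Components with singular value
#' below `1e-12 * max(sigma)` are numerically null and dropped.
#'
#' Singular-vector signs are fixed deterministically: the largest-magnitude
#' element of each right-singular vector is made non-negative.
#'
#' @param g a [genotype_matrix] (impute missing values first), or a plain
#'   numeric matrix of dosages.
#' @return an object of class `aa_projection` with elements `mu` (column
#'   means, length M), `v` (M x d right singular vectors), `sigma` (length-d
#'   singular values, non-increasing), `scores` (N x d matrix U Sigma),
#'   `n_samples`, `n_variants`.
#' @export
fit_projection <- function(g) {
  x <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2) stop("at least 2 samples are required")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  d_max <- min(n - 1L, m)
  sv <- svd(xc, nu = d_max, nv = d_max)
  sigma <- sv$d[seq_len(d_max)]
  if (max(sigma) <= 0) {
    warning("rank-0 input: all samples identical; scores are all zero")
    keep <- 1L
  } else {
    keep <- which(sigma > 1e-12 * max(sigma))
    if (length(keep) == 0) keep <- 1L
  }
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  sigma <- sigma[keep]
  # deterministic sign: largest-|.| entry of each V column non-negative
  for (j in seq_along(sigma)) {
    piv <- which.max(abs(v[, j]))
    if (v[piv, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(sigma, nrow = length(sigma))
  rownames(scores) <- rownames(x)
  structure(
    list(mu = mu, v = v, sigma = sigma, scores = scores,
         n_samples = n, n_variants = m,
         variant_ids = if (inherits(g, "genotype_matrix")) g$variant_ids else colnames(x)),
    class = "aa_projection"
  )
}

#' @export
print.aa_projection <- function(x, ...) {
  cat(sprintf("aa_projection: %d samples x %d variants -> %d components\n",
              x$n_samples, x$n_variants, length(x$sigma)))
  cat(sprintf("  top singular values: %s\n",
              paste(signif(utils::head(x$sigma, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Project (possibly new) samples into score space
#'
#' Applies the fitted centering and rotation: scores = (dosages - mu) V.
#' Variants must match the fitted model in identity and order.
#'
#' @param pm an [fit_projection()] model.
#' @param g a [genotype_matrix] or numeric matrix with the model's M variants.
#' @return N' x d score matrix.
#' @export
project_samples <- function(pm, g) {
  stopifnot(inherits(pm, "aa_projection"))
  x <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (ncol(x) != pm$n_variants) {
    stop(sprintf("variant mismatch: model has %d variants, input has %d",
                 pm$n_variants, ncol(x)))
  }
  if (inherits(g, "genotype_matrix") && !is.null(pm$variant_ids)) {
    diff <- which(g$variant_ids != pm$variant_ids)
    if (length(diff) > 0) {
      stop(sprintf("variant mismatch at position %d: '%s' vs fitted '%s'",
                   diff[1], g$variant_ids[diff[1]], pm$variant_ids[diff[1]]))
    }
  }
  sweep(x, 2, pm$mu) %*% pm$v
}

#' Map fit-space vectors back to SNP space
#'
#' Inverts the projection for points expressed in score coordinates:
#' returns z V' + mu, so fit-space archetypes become dosage-like M-vectors.
#'
#' @param pm an [fit_projection()] model.
#' @param z K x d matrix in score space (d = retained components).
#' @return K x M matrix in SNP space.
#' @export
back_project <- function(pm, z) {
  stopifnot(inherits(pm, "aa_projection"))
  z <- as.matrix(z)
  if (ncol(z) != length(pm$sigma)) {
    stop(sprintf("dimension mismatch: z has %d columns, model retains %d components",
                 ncol(z), length(pm$sigma)))
  }
  sweep(z %*% t(pm$v), 2, pm$mu, `+`)
}

#' Truncate a projection to its top components
#'
#' @param pm an [fit_projection()] model.
#' @param d number of leading singular triplets to keep (1 <= d <= retained).
#' @return truncated `aa_projection`.
#' @export
truncate_projection <- function(pm, d) {
  stopifnot(inherits(pm, "aa_projection"))
  d_full <- length(pm$sigma)
  if (!is.numeric(d) || length(d) != 1 || d < 1 || d > d_full || d != round(d)) {
    stop(sprintf("d must be an integer in [1, %d]", d_full))
  }
  d <- as.integer(d)
  pm$v <- pm$v[, seq_len(d), drop = FALSE]
  pm$sigma <- pm$sigma[seq_len(d)]
  pm$scores <- pm$scores[, seq_len(d), drop = FALSE]
  pm
}
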