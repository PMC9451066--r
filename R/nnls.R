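#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||a %*% x - b||` subject to `x >= 0`. Standard active-set
#' iteration with an anti-cycling guard: on degenerate systems (e.g. exact
#' fits with near-dependent columns) the solver returns the best feasible
#' iterate instead of aborting.
#'
#' @param a numeric D x K matrix.
#' @param b numeric length-D vector.
#' @return list with `x` (length-K non-negative coefficients) and `resnorm`
#'   (squared residual norm).
#' @export
nnls_fit <- function(a, b) {
  a <- as.matrix(a)
  k <- ncol(a)
  d <- nrow(a)
  if (length(b) != d) stop("length(b) must equal nrow(a)")
  tol <- 10 * .Machine$double.eps * max(abs(a)) * (max(d, k) + 1)
  passive <- logical(k)
  x <- numeric(k)
  w <- crossprod(a, b - a %*% x)
  outer_max <- 10L * k + 50L
  inner_max <- 10L * k + 50L
  outer <- 0L

  ls_sub <- function(idx) {
    # least squares on the passive columns; pseudo-inverse on rank deficiency
    sub <- a[, idx, drop = FALSE]
    z <- tryCatch(qr.solve(sub, b), error = function(e) NULL)
    if (is.null(z) || anyNA(z)) {
      sv <- svd(sub)
      pos <- sv$d > max(sv$d) * 1e-12
      z <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
      z <- as.vector(z)
    }
    z
  }

  while (any(!passive) && any(w[!passive] > tol) && outer < outer_max) {
    outer <- outer + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    z <- numeric(k)
    z[passive] <- ls_sub(passive)
    inner <- 0L
    while (any(z[passive] <= 0) && inner < inner_max) {
      inner <- inner + 1L
      q <- passive & (z <= 0)
      ratios <- x[q] / (x[q] - z[q])
      ratios[!is.finite(ratios)] <- 0   # degenerate 0/0 step: drop directly
      alpha <- min(ratios)
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      z <- numeric(k)
      if (any(passive)) z[passive] <- ls_sub(passive)
    }
    if (inner >= inner_max) break   # anti-cycling: keep current feasible x
    x <- z
    w <- crossprod(a, b - a %*% x)
  }
  x[x < 0] <- 0
  list(x = as.vector(x), resnorm = sum((b - a %*% x)^2))
}

#' Simplex-constrained non-negative least squares
#'
#' Solves min ||A w - b|| subject to w >= 0 and sum(w) = 1, by augmenting the
#' system with a row of ones: non-negative least squares is run on
#' rbind(A, 1/C) against c(b, 1/C), so the sum-to-one row carries relative
#' weight 1/C and smaller C enforces the constraint more strongly. The
#' returned weights are renormalized to sum to exactly 1.
#'
#' This is the inner solver of the alternating archetypal-analysis updates:
#' each ancestry-fraction row and each archetype-weight column is one such
#' problem.
#'
#' @param a numeric D x K design matrix.
#' @param b numeric length-D target.
#' @param C positive constraint coefficient; default 0.001.
#' @return length-K non-negative weight vector summing to 1.
#' @export
constrained_simplex_nnls <- function(a, b, C = 0.001) {
  a <- as.matrix(a)
  if (length(b) != nrow(a)) stop("length(b) must equal nrow(a)")
  if (!is.numeric(C) || C <= 0) stop("C must be a positive real")
  k <- ncol(a)
  if (k == 1L) return(1)
  if (all(a == 0)) {
    warning("all-zero design matrix; returning uniform weights")
    return(rep(1 / k, k))
  }
  # scale data rows to O(1) so the 1/C constraint weight is relative
  s <- max(abs(a))
  a_aug <- rbind(a / s, rep(1 / C, k))
  b_aug <- c(b / s, 1 / C)
  w <- nnls_fit(a_aug, b_aug)$x
  tot <- sum(w)
  if (tot <= 0) {
    warning("degenerate NNLS solution; returning uniform weights")
    return(rep(1 / k, k))
  }
  w / tot
}
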