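#' FurthestSum archetype initialization
#'
#' Greedy spread-out selection of K samples to seed the archetypes: the first
#' index is drawn uniformly at random, and each subsequent index is the
#' sample with the largest aggregate Euclidean distance to all previously
#' selected samples. Ties break toward the lowest index. Optionally the
#' random first pick can be discarded and re-selected greedily once K picks
#' exist (`reselect_first`), a refinement of the original scheme that is off
#' by default.
#'
#' @param data numeric N x D matrix (samples in rows).
#' @param k number of archetypes, 1 <= k <= N.
#' @param seed integer seed for the random first pick.
#' @param first optional explicit first index (overrides the random pick).
#' @param reselect_first logical; drop and greedily re-select the initial
#'   random pick after the other K - 1 are chosen. Default `FALSE`.
#' @return integer vector of K distinct row indices.
#' @export
furthest_sum_init <- function(data, k, seed = 1L, first = NULL,
                              reselect_first = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (k < 1 || k > n) stop(sprintf("k must be in [1, %d]", n))
  if (is.null(first)) {
    first <- local_seed(seed, sample.int(n, 1L))
  }
  sel <- as.integer(first)
  agg <- dist_to(data, sel)          # running sum of distances to selected
  while (length(sel) < k) {
    agg_masked <- agg
    agg_masked[sel] <- -Inf
    nxt <- which.max(agg_masked)     # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    agg <- agg + dist_to(data, nxt)
  }
  if (reselect_first && k > 1L) {
    agg_wo <- agg - dist_to(data, sel[1])
    # aggregate distance from each candidate to the k-1 non-first picks
    cand <- agg_wo
    cand[sel[-1]] <- -Inf
    sel[1] <- which.max(cand)
  }
  sel
}

# Euclidean distances from every row of data to row idx
dist_to <- function(data, idx) {
  diffs <- sweep(data, 2, data[idx, ])
  sqrt(rowSums(diffs^2))
}

# run expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Random archetype initialization
#'
#' `mode = "uniform"` draws each archetype coordinate uniformly within the
#' per-dimension \[min, max\] range of the data; `mode = "sample"` picks K
#' distinct data rows.
#'
#' @param data numeric N x D matrix.
#' @param k number of archetypes.
#' @param mode `"uniform"` or `"sample"`.
#' @param seed integer seed.
#' @return for `"uniform"`, a K x D matrix of initial archetypes; for
#'   `"sample"`, an integer vector of K distinct row indices.
#' @export
random_init <- function(data, k, mode = c("uniform", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  n <- nrow(data)
  d <- ncol(data)
  if (k < 1) stop("k must be >= 1")
  if (mode == "sample") {
    if (k > n) stop(sprintf("k must be <= N = %d in sample mode", n))
    return(local_seed(seed, sample.int(n, k)))
  }
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  local_seed(seed, {
    z <- matrix(stats::runif(k * d), k, d)
    sweep(sweep(z, 2, hi - lo, `*`), 2, lo, `+`)
  })
}
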