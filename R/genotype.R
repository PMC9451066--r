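#' Genotype dosage matrix
#'
#' Container for diploid biallelic genotypes encoded as average
#' alternate-allele dosages: each entry is the number of alternate alleles in
#' the diploid genotype divided by two, so observed genotypes map to
#' \{0, 0.5, 1\} and mean-imputed entries lie in \[0, 1\]. Samples are rows,
#' variants are columns, throughout the package.
#'
#' @param dosages numeric N x M matrix with entries in \[0, 1\].
#' @param sample_ids character vector of N unique sample identifiers.
#'   Defaults to rownames of `dosages` or `ind_1..ind_N`.
#' @param variant_ids character vector of M unique variant identifiers.
#'   Defaults to colnames of `dosages` or `snp_1..snp_M`.
#' @param populations optional character vector of N population labels.
#' @param missing_mask logical N x M matrix, `TRUE` where the genotype was
#'   missing before imputation. Defaults to all `FALSE`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `variant_ids`, `populations`, `missing_mask`.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, variant_ids = NULL,
                            populations = NULL, missing_mask = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n < 2L) stop("genotype_matrix requires at least 2 samples (rows)")
  if (m < 1L) stop("genotype_matrix requires at least 1 variant (column)")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% paste0("ind_", seq_len(n))
  }
  if (is.null(variant_ids)) {
    variant_ids <- colnames(dosages) %||% paste0("snp_", seq_len(m))
  }
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(dosages)")
  if (length(variant_ids) != m) stop("variant_ids length must equal ncol(dosages)")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variant_ids)) {
    stop("duplicate variant IDs: ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "))
  }
  if (is.null(missing_mask)) {
    missing_mask <- matrix(FALSE, n, m)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!is.logical(missing_mask) || !all(dim(missing_mask) == c(n, m))) {
      stop("missing_mask must be a logical matrix with the same shape as dosages")
    }
  }
  vals <- dosages[!missing_mask]
  if (anyNA(vals)) stop("non-missing dosages must not contain NA")
  if (any(vals < 0 | vals > 1)) {
    bad <- which(!missing_mask & (dosages < 0 | dosages > 1), arr.ind = TRUE)[1, ]
    stop(sprintf("dosage out of [0, 1] at sample %d, variant %d", bad[1], bad[2]))
  }
  # masked entries: NA means "not yet imputed" (provisional 0); an imputed
  # value in [0, 1] is kept, the mask recording provenance
  dosages[missing_mask & is.na(dosages)] <- 0
  masked_vals <- dosages[missing_mask]
  if (length(masked_vals) && any(masked_vals < 0 | masked_vals > 1)) {
    stop("imputed dosages under the missing mask must lie in [0, 1]")
  }
  if (!is.null(populations)) {
    populations <- as.character(populations)
    if (length(populations) != n) stop("populations length must equal nrow(dosages)")
  }
  dimnames(dosages) <- list(sample_ids, variant_ids)
  structure(
    list(dosages = dosages, sample_ids = sample_ids, variant_ids = variant_ids,
         populations = populations, missing_mask = missing_mask),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  nmiss <- sum(x$missing_mask)
  if (nmiss > 0) cat(sprintf("  missing genotypes: %d\n", nmiss))
  if (!is.null(x$populations)) {
    cat("  populations:", paste(names(table(x$populations)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequency per variant
#'
#' The dosage encoding is already the per-haplotype average alternate-allele
#' count, so the column mean over non-missing entries is the alternate-allele
#' frequency p; MAF is min(p, 1 - p).
#'
#' @param g a [genotype_matrix].
#' @return numeric vector of length M in \[0, 0.5\]; `NA` for columns with no
#'   non-missing entry.
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  d[g$missing_mask] <- NA_real_
  p <- colMeans(d, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  names(maf) <- g$variant_ids
  maf
}

#' Remove rare variants
#'
#' Drops variants with minor allele frequency strictly below `threshold`
#' (a site at exactly the threshold is kept). Variants whose MAF is undefined
#' (entirely missing) are removed as well.
#'
#' @param g a [genotype_matrix].
#' @param threshold MAF cut-off in \[0, 0.5\]; default 0.1.
#' @return filtered [genotype_matrix].
#' @export
filter_rare_variants <- function(g, threshold = 0.1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  maf <- compute_maf(g)
  keep <- !is.na(maf) & maf >= threshold
  removed <- sum(!keep)
  if (!any(keep)) {
    stop(sprintf("all %d variants have MAF < %g; nothing left after filtering",
                 length(keep), threshold))
  }
  if (removed > 0) {
    message(sprintf("filter_rare_variants: removed %d of %d variants with MAF < %g",
                    removed, length(keep), threshold))
  }
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  sample_ids = g$sample_ids,
                  variant_ids = g$variant_ids[keep],
                  populations = g$populations,
                  missing_mask = g$missing_mask[, keep, drop = FALSE])
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing entry by the non-missing mean of its variant column,
#' so column means (and hence the centering used before the SVD) are
#' unaffected. Columns with no non-missing entry are dropped with a warning.
#' The missing mask is kept for provenance.
#'
#' @param g a [genotype_matrix].
#' @return imputed [genotype_matrix].
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!any(g$missing_mask)) return(g)
  d <- g$dosages
  d[g$missing_mask] <- NA_real_
  p <- colMeans(d, na.rm = TRUE)
  dead <- is.nan(p)
  if (any(dead)) {
    warning(sprintf("dropping %d fully missing variant column(s): %s",
                    sum(dead), paste(g$variant_ids[dead], collapse = ", ")))
    d <- d[, !dead, drop = FALSE]
    p <- p[!dead]
  }
  mask <- g$missing_mask[, !dead, drop = FALSE]
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx) > 0) d[idx] <- p[idx[, 2]]
  genotype_matrix(d,
                  sample_ids = g$sample_ids,
                  variant_ids = g$variant_ids[!dead],
                  populations = g$populations,
                  missing_mask = mask)
}
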