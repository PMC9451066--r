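#' Read diploid biallelic genotypes from a VCF
#'
#' Parses a VCF (plain or gzipped) into the dosage encoding used throughout
#' the package: entry (i, j) is the number of alternate alleles in sample i's
#' diploid genotype at site j, divided by two, so genotypes map to
#' 0/0 -> 0, 0/1 -> 0.5, 1/1 -> 1. Phased and unphased genotypes are treated
#' identically. Records that are not biallelic SNPs (multi-allelic sites,
#' indels, symbolic alleles) are skipped and the count reported. Missing
#' genotypes get dosage 0 and are flagged in the missing mask; call
#' [impute_missing()] before analysis.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) stop("empty input: no variant records in ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  skipped <- sum(!keep)
  if (skipped > 0) {
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", skipped))
  }
  if (!any(keep)) stop("empty input: no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  ids <- fix[keep, "ID"]
  fallback <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])
  ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")

  gt_vec <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  miss <- is.na(gt_vec) | gt_vec %in% c(".", "./.", ".|.")
  dos <- rep(NA_real_, length(gt_vec))
  ok <- !miss
  if (any(ok)) {
    parts <- strsplit(gt_vec[ok], "/", fixed = TRUE)
    nall <- lengths(parts)
    if (any(nall != 2L)) {
      stop("non-diploid GT field encountered (e.g. '",
           gt_vec[ok][which(nall != 2L)[1]],
           "'); this encoding assumes diploid genotypes")
    }
    al <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    half_miss <- al[, 1] == "." | al[, 2] == "."
    a1 <- suppressWarnings(as.integer(al[, 1]))
    a2 <- suppressWarnings(as.integer(al[, 2]))
    bad <- !half_miss & (is.na(a1) | is.na(a2) | a1 > 1 | a2 > 1 | a1 < 0 | a2 < 0)
    if (any(bad)) {
      stop("unparseable GT allele in '", gt_vec[ok][which(bad)[1]], "'")
    }
    dos[ok] <- (a1 + a2) / 2
    miss_ok <- rep(FALSE, length(gt_vec))
    miss_ok[ok][half_miss] <- TRUE
    miss <- miss | miss_ok
  }
  # gt is variants x samples; dosage matrix is samples x variants
  d <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  mask <- matrix(miss, nrow = nrow(gt), ncol = ncol(gt))
  d[mask] <- 0
  genotype_matrix(t(d), sample_ids = samples, variant_ids = ids,
                  missing_mask = t(mask))
}

#' Read a plain delimited dosage matrix
#'
#' Reads a rectangular numeric table of dosages in \[0, 1\], rows = samples.
#' A header row of variant IDs and a leading column of sample IDs are
#' auto-detected (any non-numeric first row / first column). `NA`/`NaN` cells
#' are flagged missing.
#'
#' @param path path to a text file.
#' @param delimiter field separator; default splits on any whitespace or comma.
#' @return a [genotype_matrix].
#' @export
read_dosage_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty input: ", path)
  split1 <- function(s) {
    if (is.null(delimiter)) strsplit(trimws(s), "[,[:space:]]+")[[1]]
    else strsplit(trimws(s), delimiter, fixed = TRUE)[[1]]
  }
  cells <- lapply(lines, split1)
  widths <- lengths(cells)

  is_num <- function(x) {
    suppressWarnings(!is.na(as.numeric(x))) | toupper(x) %in% c("NA", "NAN")
  }
  # a header row has non-numeric cells beyond the first (a data row may
  # still start with a non-numeric sample ID)
  r1 <- cells[[1]]
  has_header <- !all(is_num(if (length(r1) > 1) r1[-1] else r1))
  body <- if (has_header) cells[-1] else cells
  if (length(body) == 0) stop("no data rows in ", path)
  bw <- lengths(body)
  if (length(unique(bw)) != 1) {
    bad <- which(bw != bw[1])[1]
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 bad + has_header, bw[bad], bw[1]))
  }
  first_col <- vapply(body, `[[`, "", 1L)
  has_ids <- !all(is_num(first_col))
  sample_ids <- if (has_ids) first_col else NULL
  dat <- lapply(body, function(r) if (has_ids) r[-1] else r)
  m <- length(dat[[1]])
  if (m < 1) stop("no numeric columns in ", path)
  variant_ids <- NULL
  if (has_header) {
    hdr <- cells[[1]]
    # header may or may not carry a cell above the ID column
    if (length(hdr) == m) variant_ids <- hdr
    else if (length(hdr) == m + 1) variant_ids <- hdr[-1]
  }
  vals <- matrix(NA_real_, length(dat), m)
  for (i in seq_along(dat)) {
    row <- dat[[i]]
    v <- suppressWarnings(as.numeric(row))
    bad <- is.na(v) & !(toupper(row) %in% c("NA", "NAN"))
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                   row[j], i + has_header, j + has_ids))
    }
    vals[i, ] <- v
  }
  mask <- is.na(vals)
  out_of_range <- !mask & (vals < 0 | vals > 1)
  if (any(out_of_range)) {
    bad <- which(out_of_range, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage %g out of [0, 1] at row %d, column %d",
                 vals[bad[1], bad[2]], bad[1] + has_header, bad[2] + has_ids))
  }
  vals[mask] <- 0
  genotype_matrix(vals, sample_ids = sample_ids, variant_ids = variant_ids,
                  missing_mask = mask)
}

#' Read per-sample population labels
#'
#' Two-column whitespace/tab file: sample ID, population label.
#'
#' @param path label file path.
#' @return named character vector (names = sample IDs).
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  stats::setNames(as.character(tab$population), as.character(tab$sample))
}

#' Write ancestry fractions in .Q convention
#'
#' Writes the N x K ancestry-fraction matrix as whitespace-delimited text with
#' six fixed decimals, one row per sample, in sample order (the convention of
#' ADMIXTURE-style `.Q` files). A sibling `<path>.samples` file lists the
#' sample IDs, one per line.
#'
#' @param alpha numeric N x K matrix whose rows sum to 1 within 1e-6.
#' @param path output file path.
#' @param sample_ids optional character vector of N sample IDs for the
#'   sibling file; rownames of `alpha` used when absent.
#' @return `path`, invisibly.
#' @export
write_fractions <- function(alpha, path, sample_ids = NULL) {
  alpha <- as.matrix(alpha)
  rs <- rowSums(alpha)
  if (any(abs(rs - 1) > 1e-6) || any(alpha < -1e-12)) {
    stop("alpha rows must be non-negative and sum to 1 within 1e-6")
  }
  lines <- apply(alpha, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(lines, path)
  ids <- sample_ids %||% rownames(alpha)
  if (!is.null(ids)) writeLines(as.character(ids), paste0(path, ".samples"))
  invisible(path)
}

#' Read a .Q-style ancestry-fraction file
#'
#' @param path file written by [write_fractions()] (or any whitespace-
#'   delimited numeric table of per-sample fractions).
#' @return numeric N x K matrix.
#' @export
read_fractions <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write a K x M table of SNP-space archetypes
#'
#' Whitespace-delimited, six decimals, one row per archetype ("P-like" file).
#'
#' @param arch numeric K x M matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_archetypes <- function(arch, path) {
  arch <- as.matrix(arch)
  lines <- apply(arch, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
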