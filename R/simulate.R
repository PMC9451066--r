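#' Simulate an admixed genotype panel with known truth
#'
#' Generative model of admixture: each of K ancestral populations has
#' per-SNP alternate-allele frequencies `F` (K x M), each individual has
#' simplex-valued ancestry fractions `Q` (N x K) drawn from a symmetric
#' Dirichlet, and the allele count at SNP j for individual i is
#' `n_ij ~ Binomial(2, p_ij)` with success probability `p_ij = sum_k q_ik
#' f_kj`; dosages are `n_ij / 2`. Population frequencies are drawn
#' independently per SNP, uniform in `0.5 +/- freq_spread`.
#'
#' @param n number of individuals.
#' @param m number of SNPs.
#' @param k number of ancestral populations.
#' @param dirichlet_conc symmetric Dirichlet concentration of the ancestry
#'   rows; default 0.3 (mixtures with some near-pure individuals).
#' @param freq_spread half-width of the allele-frequency range around 0.5,
#'   in (0, 0.5]; default 0.4.
#' @param seed integer seed; panels are reproduced bit-identically.
#' @return list with `panel` (a [genotype_matrix], populations labelled by
#'   the majority ancestry) and `truth` (class `admixture_truth`: `Q`, `F`,
#'   `P = Q %*% F`, `seed`).
#' @export
simulate_panel <- function(n, m, k, dirichlet_conc = 0.3, freq_spread = 0.4,
                           seed = 1L) {
  if (n < k || k < 1 || m < 1) stop("need n >= k >= 1 and m >= 1")
  if (dirichlet_conc <= 0) stop("dirichlet_conc must be > 0")
  if (freq_spread <= 0 || freq_spread > 0.5) stop("freq_spread must be in (0, 0.5]")
  local_seed(seed, {
    f <- matrix(stats::runif(k * m, 0.5 - freq_spread, 0.5 + freq_spread), k, m)
    q <- rdirichlet(n, rep(dirichlet_conc, k))
    truth <- admixture_truth(q, f, seed)
    panel <- genotypes_from_truth(truth)
    list(panel = panel, truth = truth)
  })
}

# symmetric-ish Dirichlet via normalized gammas
rdirichlet <- function(n, conc) {
  k <- length(conc)
  g <- matrix(stats::rgamma(n * k, shape = rep(conc, each = n)), n, k)
  zero <- rowSums(g) == 0
  if (any(zero)) {
    # tiny-concentration underflow: fall back to a one-hot draw
    g[zero, ] <- 0
    g[cbind(which(zero), sample.int(k, sum(zero), replace = TRUE))] <- 1
  }
  g / rowSums(g)
}

#' Bundle simulation ground truth
#'
#' @param q N x K row-stochastic ancestry fractions.
#' @param f K x M allele frequencies in \[0, 1\].
#' @param seed the generating seed.
#' @return object of class `admixture_truth` with `Q`, `F`, `P = Q %*% F`.
#' @export
admixture_truth <- function(q, f, seed = NA_integer_) {
  q <- as.matrix(q); f <- as.matrix(f)
  if (ncol(q) != nrow(f)) stop("ncol(Q) must equal nrow(F)")
  if (any(abs(rowSums(q) - 1) > 1e-8) || any(q < 0)) {
    stop("Q rows must be non-negative and sum to 1")
  }
  if (any(f < 0 | f > 1)) stop("F entries must be in [0, 1]")
  structure(list(Q = q, F = f, P = q %*% f, seed = seed),
            class = "admixture_truth")
}

#' Draw genotypes from an admixture truth
#'
#' Allele counts are `Binomial(2, P)` entrywise; dosages are counts / 2.
#' Population labels are the majority-ancestry component of each row of Q.
#'
#' @param truth an [admixture_truth()].
#' @param sample_prefix prefix for generated sample IDs.
#' @return a [genotype_matrix].
#' @export
genotypes_from_truth <- function(truth, sample_prefix = "ind") {
  stopifnot(inherits(truth, "admixture_truth"))
  p <- truth$P
  n <- nrow(p); m <- ncol(p)
  counts <- matrix(stats::rbinom(n * m, size = 2, prob = p), n, m)
  pops <- paste0("pop", max.col(truth$Q, ties.method = "first"))
  genotype_matrix(counts / 2,
                  sample_ids = sprintf("%s_%0*d", sample_prefix,
                                       nchar(as.character(n)), seq_len(n)),
                  variant_ids = sprintf("snp_%0*d",
                                        nchar(as.character(m)), seq_len(m)),
                  populations = pops)
}

#' Append pure-ancestry "vertex" individuals to a simulated panel
#'
#' Adds `per_pop` individuals per ancestral population whose ancestry rows
#' are one-hot, with genotypes drawn from `Binomial(2, f_kj) / 2`. Such
#' individuals sit at the extremes of the admixture simplex and give the
#' archetypes attainable targets.
#'
#' @param panel a [genotype_matrix] from [simulate_panel()].
#' @param truth the matching [admixture_truth()].
#' @param per_pop number of pure individuals per population.
#' @param seed integer seed.
#' @return list with extended `panel` and `truth`.
#' @export
add_vertex_individuals <- function(panel, truth, per_pop = 1L, seed = 1L) {
  stopifnot(inherits(panel, "genotype_matrix"), inherits(truth, "admixture_truth"))
  if (per_pop < 1) stop("per_pop must be >= 1")
  k <- nrow(truth$F)
  m <- ncol(truth$F)
  q_new <- matrix(0, k * per_pop, k)
  q_new[cbind(seq_len(k * per_pop), rep(seq_len(k), each = per_pop))] <- 1
  local_seed(seed, {
    p_new <- q_new %*% truth$F
    counts <- matrix(stats::rbinom(nrow(p_new) * m, 2, p_new), nrow(p_new), m)
    new_ids <- sprintf("vertex_pop%d_%d", rep(seq_len(k), each = per_pop),
                       rep(seq_len(per_pop), times = k))
    dos <- rbind(panel$dosages, counts / 2)
    g <- genotype_matrix(
      dos,
      sample_ids = c(panel$sample_ids, new_ids),
      variant_ids = panel$variant_ids,
      populations = c(panel$populations %||% rep(NA_character_, nrow(panel$dosages)),
                      paste0("pop", rep(seq_len(k), each = per_pop))),
      missing_mask = rbind(panel$missing_mask,
                           matrix(FALSE, nrow(counts), m))
    )
    list(panel = g, truth = admixture_truth(rbind(truth$Q, q_new), truth$F,
                                            truth$seed))
  })
}

#' Write a panel as a minimal VCF 4.2 fixture
#'
#' Emits a valid plain-text VCF with synthetic CHROM/POS/REF/ALT and GT
#' fields encoding the dosages (0 -> 0/0, 0.5 -> 0/1, 1 -> 1/1). Only
#' genotypic dosages can be expressed; imputed fractional values raise an
#' error. Missing entries are written as `./.`.
#'
#' @param panel a [genotype_matrix] with dosages in \{0, 0.5, 1\}.
#' @param path output `.vcf` path.
#' @param seed seed for the synthetic REF/ALT alleles.
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(panel, path, seed = 1L) {
  stopifnot(inherits(panel, "genotype_matrix"))
  d <- panel$dosages
  obs <- !panel$missing_mask
  if (!all(d[obs] %in% c(0, 0.5, 1))) {
    bad <- which(obs & !(d %in% c(0, 0.5, 1)), arr.ind = TRUE)[1, ]
    stop(sprintf("dosage %g at sample %d, variant %d is not a diploid genotype",
                 d[bad[1], bad[2]], bad[1], bad[2]))
  }
  n <- nrow(d); m <- ncol(d)
  alleles <- local_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    list(ref = ref, alt = alt)
  })
  gt_code <- matrix("./.", n, m)
  gt_code[obs & d == 0] <- "0/0"
  gt_code[obs & d == 0.5] <- "0/1"
  gt_code[obs & d == 1] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=aamix_fixture",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", as.character(j * 100L), panel$variant_ids[j],
            alleles$ref[j], alleles$alt[j], ".", "PASS", ".", "GT",
            gt_code[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
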