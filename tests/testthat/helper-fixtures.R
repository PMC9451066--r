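# Shared fixture builders; everything is generated in code at test time.

# genotype_matrix from a plain dosage matrix
gm <- function(d, ...) genotype_matrix(as.matrix(d), ...)

# a small VCF as text lines, 3 samples x 4 records:
#   snp1 biallelic with 0/0, 0/1, 1|1
#   snp2 with a missing genotype
#   indel + multiallelic records that the reader must skip
small_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1|1"), collapse = "\t"),
    paste(c("1", "200", "snp2", "C", "T", ".", "PASS", ".", "GT",
            "./.", "0/1", "0/0"), collapse = "\t"),
    paste(c("1", "300", "indel1", "CT", "C", ".", "PASS", ".", "GT",
            "0/0", "0/0", "0/1"), collapse = "\t"),
    paste(c("1", "400", "multi1", "G", "A,T", ".", "PASS", ".", "GT",
            "0/1", "1/2", "0/0"), collapse = "\t"))
}

write_small_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(small_vcf_lines(), path)
  path
}

# 30 samples as convex combinations of 3 well-separated generator rows,
# generators included as samples 1..3 -> a zero-residual AA instance
planted_instance <- function(seed = 42, n_mix = 27, d = 6) {
  set.seed(seed)
  gens <- matrix(0, 3, d)
  gens[cbind(1:3, 1:3)] <- 10
  w <- matrix(rgamma(n_mix * 3, 1), n_mix, 3)
  w <- w / rowSums(w)
  list(data = rbind(gens, w %*% gens), generators = gens, weights = w)
}

# two separable 2-D blobs
two_blobs <- function(seed = 7, n_per = 20) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per, mean = 0, sd = 0.3), ncol = 2),
        matrix(rnorm(2 * n_per, mean = 6, sd = 0.3), ncol = 2))
}

# brute-force K-medoids optimum by exhaustive search over medoid sets
brute_force_kmedoids <- function(data, k) {
  n <- nrow(data)
  combs <- utils::combn(n, k)
  best_cost <- Inf
  best <- NULL
  for (i in seq_len(ncol(combs))) {
    med <- combs[, i]
    d2 <- as.matrix(dist(data))^2
    cost <- sum(apply(d2[, med, drop = FALSE], 1, min))
    if (cost < best_cost) {
      best_cost <- cost
      best <- med
    }
  }
  list(medoids = best, cost = best_cost)
}
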