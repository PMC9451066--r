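test_that("simulated dosages follow the binomial admixture model", {
  sim <- simulate_panel(500, 300, 3, seed = 81)
  expect_equal(dim(sim$panel$dosages), c(500L, 300L))
  expect_true(all(sim$panel$dosages %in% c(0, 0.5, 1)))
  expect_equal(rowSums(sim$truth$Q), rep(1, 500), tolerance = 1e-12)
  expect_true(all(sim$truth$F >= 0 & sim$truth$F <= 1))
  expect_equal(sim$truth$P, sim$truth$Q %*% sim$truth$F, tolerance = 1e-12)
  # binomial mean: dosage expectation is p_ij
  expect_lt(abs(mean(sim$panel$dosages - sim$truth$P)), 0.02)
  expect_error(simulate_panel(2, 10, 3), "n >= k")
  expect_error(simulate_panel(10, 10, 2, freq_spread = 0.6), "freq_spread")
})

test_that("degenerate frequency panels produce constant dosages", {
  q <- diag(3)[rep(1:3, each = 2), ]
  t0 <- admixture_truth(q, matrix(0, 3, 8))
  expect_true(all(genotypes_from_truth(t0)$dosages == 0))
  t1 <- admixture_truth(q, matrix(1, 3, 8))
  expect_true(all(genotypes_from_truth(t1)$dosages == 1))
})

test_that("column means converge to the model means with sample size", {
  err_for <- function(n) {
    sim <- simulate_panel(n, 150, 3, dirichlet_conc = 1, seed = 82)
    mean(abs(colMeans(sim$panel$dosages) - colMeans(sim$truth$P)))
  }
  expect_lt(err_for(800), err_for(40))
})

test_that("panels are reproduced bit-identically from the seed", {
  a <- simulate_panel(25, 40, 3, seed = 83)
  b <- simulate_panel(25, 40, 3, seed = 83)
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(a$truth$Q, b$truth$Q)
  c_ <- simulate_panel(25, 40, 3, seed = 84)
  expect_false(identical(a$panel$dosages, c_$panel$dosages))
})

test_that("vertex individuals are appended with one-hot ancestry", {
  sim <- simulate_panel(20, 50, 3, seed = 85)
  vx <- add_vertex_individuals(sim$panel, sim$truth, per_pop = 1, seed = 86)
  expect_equal(nrow(vx$panel$dosages), 23L)
  added_q <- vx$truth$Q[21:23, ]
  expect_equal(sort(as.vector(added_q)), c(rep(0, 6), rep(1, 3)))
  expect_equal(rowSums(added_q), rep(1, 3))
  # appended dosage means track the population frequencies
  vx2 <- add_vertex_individuals(sim$panel, sim$truth, per_pop = 40, seed = 87)
  pop1 <- vx2$panel$dosages[21:60, ]
  expect_lt(mean(abs(colMeans(pop1) - vx2$truth$F[1, ])), 0.08)
})

test_that("vertex enrichment improves ancestry recovery", {
  deltas <- sapply(1:5, function(s) {
    sim <- simulate_panel(120, 150, 3, dirichlet_conc = 0.5, seed = 100 + s)
    pm0 <- fit_projection(sim$panel)
    f0 <- archetypal_analysis(pm0$scores, k = 3, seed = s)
    mae0 <- match_columns(f0$alpha, sim$truth$Q)$mae
    vx <- add_vertex_individuals(sim$panel, sim$truth, per_pop = 2,
                                 seed = 200 + s)
    pm1 <- fit_projection(vx$panel)
    f1 <- archetypal_analysis(pm1$scores, k = 3, seed = s)
    mae1 <- match_columns(f1$alpha, vx$truth$Q)$mae
    mae0 - mae1
  })
  expect_gt(mean(deltas), 0)
})

test_that("fixture VCFs round-trip through the reader exactly", {
  sim <- simulate_panel(6, 12, 2, seed = 88)
  p <- tempfile(fileext = ".vcf")
  write_fixture_vcf(sim$panel, p, seed = 1)
  g <- read_vcf(p)
  expect_identical(unname(g$dosages), unname(sim$panel$dosages))
  expect_equal(g$sample_ids, sim$panel$sample_ids)
  # minimal shape: N = 2 samples, M = 2 sites -> 2 data lines, 2 GT columns
  g2 <- gm(matrix(c(0, 0.5, 1, 0), 2, 2), sample_ids = c("x", "y"))
  p2 <- tempfile(fileext = ".vcf")
  write_fixture_vcf(g2, p2)
  lines <- readLines(p2)
  expect_equal(sum(!startsWith(lines, "#")), 2)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_identical(unname(read_vcf(p2)$dosages), unname(g2$dosages))
  # missing genotypes survive the round trip
  mask <- matrix(FALSE, 2, 2); mask[1, 2] <- TRUE
  g3 <- genotype_matrix(matrix(c(0, 0.5, 0, 1), 2, 2), missing_mask = mask)
  p3 <- tempfile(fileext = ".vcf")
  write_fixture_vcf(g3, p3)
  expect_true(read_vcf(p3)$missing_mask[1, 2])
  # fractional (imputed) dosages cannot be written as GT
  g4 <- gm(matrix(c(0.3, 0.5, 1, 0), 2, 2))
  expect_error(write_fixture_vcf(g4, tempfile()), "not a diploid genotype")
})
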