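test_that("K = 1 recovers the mean archetype and total sum of squares", {
  set.seed(61)
  data <- matrix(rnorm(30 * 5, sd = 2), 30, 5)
  fit <- archetypal_analysis(data, k = 1, seed = 1)
  mu <- colMeans(data)
  tot_ss <- sum(sweep(data, 2, mu)^2)
  expect_equal(as.vector(fit$Z), mu, tolerance = 1e-6 * max(abs(mu)) + 1e-6)
  expect_equal(fit$rss, tot_ss, tolerance = 1e-6)
  expect_true(all(fit$alpha == 1))
})

test_that("a planted zero-residual instance is solved exactly", {
  pl <- planted_instance(seed = 42)
  tot_ss <- sum(sweep(pl$data, 2, colMeans(pl$data))^2)
  fit <- archetypal_analysis(pl$data, k = 3, seed = 4)
  expect_lt(fit$rss, 1e-6 * tot_ss)
  m <- match_columns(t(pl$generators), t(fit$Z))
  expect_lt(max(abs(pl$generators - fit$Z[m$perm, ])), 1e-3)
})

test_that("K = N reproduces every sample as its own archetype", {
  set.seed(62)
  data <- matrix(rnorm(6 * 4), 6, 4)
  fit <- archetypal_analysis(data, k = 6, seed = 2)
  tot_ss <- sum(sweep(data, 2, colMeans(data))^2)
  expect_lte(fit$rss, 1e-8 * tot_ss)
})

test_that("rss_of equals the element-wise double loop", {
  set.seed(63)
  data <- matrix(rnorm(8 * 5), 8, 5)
  alpha <- matrix(rgamma(8 * 3, 1), 8, 3)
  alpha <- alpha / rowSums(alpha)
  z <- matrix(rnorm(3 * 5), 3, 5)
  slow <- 0
  for (i in 1:8) {
    xi_hat <- rep(0, 5)
    for (k in 1:3) xi_hat <- xi_hat + alpha[i, k] * z[k, ]
    slow <- slow + sum((data[i, ] - xi_hat)^2)
  }
  expect_equal(rss_of(data, alpha, z), slow, tolerance = 1e-10)
  expect_equal(rss_of(data, diag(8), data), 0)     # perfect reconstruction
  e <- matrix(rnorm(8 * 5), 8, 5)
  e <- e / sqrt(sum(e^2))                          # unit Frobenius error
  expect_equal(rss_of(data + e, diag(8), data), 1, tolerance = 1e-10)
  expect_error(rss_of(data, alpha, z[, 1:3]), "shape mismatch")
})

test_that("explained variance matches its definition", {
  y <- matrix(rnorm(20), 4, 5)
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, matrix(mean(y), 4, 5)), 0)
  expect_equal(explained_variance(c(0, 1, 2, 3), c(0, 1, 2, 1)), 0.4)
  expect_error(explained_variance(rep(1, 4), rep(1, 4)), "undefined")
})

test_that("the RSS trace is non-increasing across random configurations", {
  set.seed(64)
  cases <- expand.grid(n = c(20, 40), k = c(2, 4),
                       init = c("furthest_sum", "random_uniform", "random_sample"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    data <- matrix(rnorm(cases$n[i] * 8), cases$n[i], 8)
    fit <- archetypal_analysis(data, k = cases$k[i], init = cases$init[i],
                               seed = i, max_iter = 30)
    expect_true(all(diff(fit$rss_trace) <= 1e-8 * fit$rss_trace[1] + 1e-12),
                info = sprintf("case %d (%s)", i, cases$init[i]))
  }
})

test_that("alpha rows and beta columns are simplex points", {
  sim <- simulate_panel(40, 100, 3, seed = 65)
  pm <- fit_projection(sim$panel)
  for (k in c(2, 3, 5)) {
    fit <- archetypal_analysis(pm$scores, k = k, seed = k)
    expect_true(all(fit$alpha >= 0))
    expect_true(all(fit$beta >= 0))
    expect_equal(rowSums(fit$alpha), rep(1, 40), tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(colSums(fit$beta), rep(1, k), tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(fit$Z, crossprod(fit$beta, pm$scores), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("SNP-space archetypes stay inside observed dosage ranges", {
  sim <- simulate_panel(30, 80, 3, seed = 66)
  pm <- fit_projection(sim$panel)
  fit <- archetypal_analysis(pm$scores, k = 3, seed = 1)
  arch <- archetypes_in_snp_space(sim$panel, fit$beta)
  lo <- apply(sim$panel$dosages, 2, min)
  hi <- apply(sim$panel$dosages, 2, max)
  expect_true(all(sweep(arch, 2, lo, `>=`) | abs(sweep(arch, 2, lo)) < 1e-9))
  expect_true(all(sweep(arch, 2, hi, `<=`) | abs(sweep(arch, 2, hi)) < 1e-9))
  # one-hot and uniform beta columns
  beta1 <- matrix(0, 30, 1); beta1[7, 1] <- 1
  expect_equal(as.vector(archetypes_in_snp_space(sim$panel, beta1)),
               unname(sim$panel$dosages[7, ]))
  betau <- matrix(1 / 30, 30, 1)
  expect_equal(as.vector(archetypes_in_snp_space(sim$panel, betau)),
               unname(colMeans(sim$panel$dosages)))
  expect_error(archetypes_in_snp_space(sim$panel, -beta1), "non-negative")
  # consistency with back-projection when all components are retained
  arch_fit_space <- back_project(pm, fit$Z)
  expect_equal(arch_fit_space, arch, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fits are deterministic in the seed and improve with restarts", {
  sim <- simulate_panel(30, 60, 3, seed = 67)
  pm <- fit_projection(sim$panel)
  f1 <- archetypal_analysis(pm$scores, k = 3, seed = 11)
  f2 <- archetypal_analysis(pm$scores, k = 3, seed = 11)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$rss_trace, f2$rss_trace)
  fr <- archetypal_analysis(pm$scores, k = 3, seed = 11, restarts = 4,
                            init = "random_sample")
  f_single <- archetypal_analysis(pm$scores, k = 3, seed = 11,
                                  init = "random_sample")
  expect_lte(fr$rss, f_single$rss + 1e-10)
})

test_that("free-parameter accounting matches 2NK - N - K", {
  set.seed(68)
  data <- matrix(rnorm(15 * 4), 15, 4)
  fit <- archetypal_analysis(data, k = 3, seed = 1)
  expect_equal(fit$df$total, 2 * 15 * 3 - 15 - 3)
  expect_equal(fit$df$alpha, 15 * (3 - 1))
  expect_equal(fit$df$beta, 3 * (15 - 1))
  expect_equal(fit$df$alpha + fit$df$beta, fit$df$total)
  g <- glance(fit)
  expect_equal(g$df_total, fit$df$total)
  td <- tidy(fit)
  expect_equal(nrow(td), 15 * 3)
  expect_equal(sum(td$alpha), 15)
})

test_that("invalid inputs are rejected", {
  data <- matrix(rnorm(10), 5, 2)
  expect_error(archetypal_analysis(data, k = 6), "exceeds")
  data[2, 1] <- NA
  expect_error(archetypal_analysis(data, k = 2), "finite")
  expect_error(aa_config(k = 0), "positive integer")
  expect_error(aa_config(k = 2, C = -1), "C must be")
  expect_error(aa_config(k = 2, tol = 0), "tol must be")
})
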