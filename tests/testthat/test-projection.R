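test_that("scores span at most N - 1 dimensions and reconstruct the data", {
  set.seed(21)
  g <- gm(matrix(sample(c(0, 0.5, 1), 3 * 40, TRUE), 3, 40))
  pm <- fit_projection(g)
  expect_equal(ncol(pm$scores), 2L)
  recon <- pm$scores %*% t(pm$v) + rep(1, 3) %o% pm$mu
  expect_equal(recon, g$dosages, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(pm$v), diag(ncol(pm$v)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(pm$sigma)))
  # a constant column centers to zero and its mean is stored
  g2 <- gm(cbind(c(0.5, 0.5, 0.5), c(0, 0.5, 1), c(1, 0, 0.5)))
  pm2 <- fit_projection(g2)
  expect_equal(pm2$mu[1], 0.5, ignore_attr = TRUE)
})

test_that("projection is a rotation: distances and total SS preserved", {
  set.seed(22)
  g <- gm(matrix(sample(c(0, 0.5, 1), 10 * 60, TRUE), 10, 60))
  pm <- fit_projection(g)
  expect_equal(as.matrix(dist(pm$scores)), as.matrix(dist(g$dosages)),
               tolerance = 1e-8, ignore_attr = TRUE)
  xc <- sweep(g$dosages, 2, colMeans(g$dosages))
  expect_equal(sum(pm$sigma^2), sum(xc^2), tolerance = 1e-8)
})

test_that("project_samples is linear and consistent with stored scores", {
  set.seed(23)
  g <- gm(matrix(sample(c(0, 0.5, 1), 8 * 50, TRUE), 8, 50))
  pm <- fit_projection(g)
  expect_equal(project_samples(pm, g), pm$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.vector(project_samples(pm, matrix(pm$mu, 1))),
               rep(0, ncol(pm$scores)), tolerance = 1e-10)
  held_out <- (g$dosages[1, ] + g$dosages[2, ]) / 2
  expect_equal(as.vector(project_samples(pm, matrix(held_out, 1))),
               as.vector((pm$scores[1, ] + pm$scores[2, ]) / 2),
               tolerance = 1e-8)
  g_wrong <- gm(g$dosages[, c(2, 1, 3:50)],
                variant_ids = g$variant_ids[c(2, 1, 3:50)])
  expect_error(project_samples(pm, g_wrong), "variant mismatch at position 1")
  expect_error(project_samples(pm, g$dosages[, 1:10]), "variant mismatch")
})

test_that("back_project inverts the projection and maps 0 to mu", {
  set.seed(24)
  g <- gm(matrix(sample(c(0, 0.5, 1), 9 * 40, TRUE), 9, 40))
  pm <- fit_projection(g)
  z <- project_samples(pm, g$dosages[4:5, ])
  expect_equal(back_project(pm, z), g$dosages[4:5, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.vector(back_project(pm, matrix(0, 1, length(pm$sigma)))),
               unname(pm$mu), tolerance = 1e-10)
  expect_error(back_project(pm, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("truncation keeps leading components; projection discards variance", {
  set.seed(25)
  g <- gm(matrix(sample(c(0, 0.5, 1), 12 * 80, TRUE), 12, 80))
  pm <- fit_projection(g)
  full_d <- length(pm$sigma)
  expect_equal(truncate_projection(pm, full_d)$scores, pm$scores)
  expect_equal(ncol(truncate_projection(pm, 1)$scores), 1L)
  expect_error(truncate_projection(pm, 0), "d must be")
  expect_error(truncate_projection(pm, full_d + 1), "d must be")
  # the truncated-space fit, evaluated on the full scores, cannot beat the
  # same-seed fit that optimized the full-space objective directly
  f_full <- archetypal_analysis(pm$scores, k = 3, seed = 5)
  f_trunc <- archetypal_analysis(truncate_projection(pm, 3)$scores,
                                 k = 3, seed = 5)
  z_trunc_full <- crossprod(f_trunc$beta, pm$scores)
  rss_trunc_in_full <- rss_of(pm$scores, f_trunc$alpha, z_trunc_full)
  expect_gte(rss_trunc_in_full, f_full$rss * (1 - 1e-8))
})

test_that("RSS is invariant to fitting in score space vs centered SNP space", {
  sim <- simulate_panel(25, 120, 3, seed = 31)
  g <- sim$panel
  pm <- fit_projection(g)
  xc <- sweep(g$dosages, 2, colMeans(g$dosages))
  idx <- furthest_sum_init(pm$scores, 3, seed = 9)
  f_scores <- archetypal_analysis(pm$scores, k = 3, seed = 9, init_indices = idx)
  f_snp <- archetypal_analysis(xc, k = 3, seed = 9, init_indices = idx)
  expect_equal(f_scores$rss, f_snp$rss, tolerance = 1e-6)
  expect_equal(f_scores$alpha, f_snp$alpha, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("identical samples give a rank-0 warning", {
  g <- gm(matrix(0.5, 4, 10) + 0)
  expect_warning(pm <- fit_projection(g), "rank-0")
  expect_true(all(pm$sigma <= 1e-12))
})
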