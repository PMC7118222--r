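test_that("voxel-wise GLM T equals a per-voxel regression oracle", {
  set.seed(31)
  n <- 24; V <- 40
  X <- cbind(intercept = 1, group = rep(0:1, each = n / 2),
             age = scale(rnorm(n), scale = FALSE))
  Y <- matrix(rnorm(n * V), n, V)
  st <- fit_voxelwise_glm(Y, X, c(0, 1, 0))
  oracle <- vapply(seq_len(V), function(v) {
    fit <- stats::lm(Y[, v] ~ X[, 2] + X[, 3])
    summary(fit)$coefficients[2, "t value"]
  }, 0)
  expect_lt(max(abs(st$values - oracle)), 1e-8)
  expect_equal(st$dof, n - 3)
})

test_that("identical groups give null T; confounding attenuates T", {
  set.seed(32)
  base <- matrix(rnorm(10 * 25), 10, 25)
  Y <- rbind(base, base)              # two identical groups
  X <- cbind(1, rep(0:1, each = 10))
  st <- fit_voxelwise_glm(Y, X, c(0, 1))
  expect_lt(max(abs(st$values)), 1e-8)
  # a covariate that fully explains the group difference absorbs the T
  n <- 40
  g <- rep(0:1, each = n / 2)
  cov_ <- g * 2 + rnorm(n, sd = 0.01)  # group difference rides on cov
  Yc <- matrix(rnorm(n * 30), n, 30) + outer(g, rep(1, 30))
  t_raw <- fit_voxelwise_glm(Yc, cbind(1, g), c(0, 1))$values
  t_adj <- fit_voxelwise_glm(Yc, cbind(1, g, cov_ - mean(cov_)),
                             c(0, 1, 0))$values
  expect_lt(mean(abs(t_adj)), mean(abs(t_raw)) / 2)
})

test_that("interaction F: null when arm effects match, F = T^2 identity", {
  set.seed(33)
  nb <- 16; V <- 30
  Yb <- matrix(rnorm(nb * V), nb, V)
  shift <- matrix(rep(rnorm(V), each = nb), nb, V)
  Yf <- Yb + shift                    # same change in both arms
  arm <- rep(c("DPP", "DT"), each = nb / 2)
  fi <- interaction_f(Yb, Yf, arm)
  expect_equal(fi$values, fi$t_values^2, tolerance = 1e-12)
  expect_lt(max(abs(fi$t_values)), 5)  # no systematic arm difference
  # planted DPP-only change produces a large F
  Yf2 <- Yf
  Yf2[arm == "DPP", 1:5] <- Yf2[arm == "DPP", 1:5] + 3
  fi2 <- interaction_f(Yb, Yf2, arm)
  expect_gt(min(fi2$values[1:5]), qt(1 - 0.001, fi2$dof[2])^2)
  expect_error(interaction_f(Yb[1:3, ], Yf, arm), "every subject")
})

test_that("smoothness estimator tracks known smoothness", {
  d <- c(20, 24, 20)
  mask <- array(TRUE, d)
  set.seed(34)
  # unsmoothed noise: FWHM about one voxel (within 20%)
  est_w <- replicate(20, {
    R <- t(sapply(1:12, function(i) as.vector(array(rnorm(prod(d)), d))))
    mean(estimate_smoothness(R, mask, 3)$fwhm_mm)
  })
  expect_lt(abs(mean(est_w) - 3) / 3, 0.2)
  # 6 mm smoothed noise recovered within 20%
  est_s <- replicate(10, {
    R <- t(sapply(1:12, function(i)
      as.vector(gaussian_smooth_3d(array(rnorm(prod(d)), d), 6, 3))))
    mean(estimate_smoothness(R, mask, 3)$fwhm_mm)
  })
  expect_lt(abs(mean(est_s) - 6) / 6, 0.2)
  # scale invariance
  R <- t(sapply(1:12, function(i) as.vector(array(rnorm(prod(d)), d))))
  expect_equal(estimate_smoothness(R, mask, 3)$fwhm_mm,
               estimate_smoothness(2 * R, mask, 3)$fwhm_mm,
               tolerance = 1e-12)
})

test_that("cluster labelling agrees with the label-propagation oracle", {
  set.seed(35)
  for (r in 1:8) {
    bin <- array(runif(6 * 6 * 5) < 0.25, c(6, 6, 5))
    for (conn in c(6, 26)) {
      got <- label_clusters(bin, conn)
      want <- label_oracle(bin, conn)
      expect_equal(max(got$labels), want$n)
      expect_equal(sort(got$sizes), want$sizes)
    }
  }
})

test_that("GRF cluster table is monotone in the voxel threshold", {
  set.seed(36)
  d <- c(12, 12, 10)
  mask <- array(TRUE, d)
  Y <- t(sapply(1:30, function(i)
    as.vector(gaussian_smooth_3d(array(rnorm(prod(d)), d), 6, 3))))
  Y[16:30, 1:60] <- Y[16:30, 1:60] + 1.2
  X <- cbind(1, rep(0:1, each = 15))
  st <- fit_voxelwise_glm(Y, X, c(0, 1))
  sm <- estimate_smoothness(st$residuals, mask, 3)
  counts <- vapply(c(0.01, 0.001, 1e-4), function(vp) {
    tab <- attr(grf_cluster_correct(st, mask, sm, voxel_p = vp),
                "all_clusters")
    nrow(tab)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  bad_sm <- sm; bad_sm$resels <- 0
  expect_error(grf_cluster_correct(st, mask, bad_sm), "resels")
})

test_that("permutation stream is seed-deterministic and detects signal", {
  set.seed(37)
  d <- c(10, 10, 6)
  mask <- array(TRUE, d)
  Y <- matrix(rnorm(20 * prod(d)), 20)
  Y[11:20, 1:25] <- Y[11:20, 1:25] + 2
  X <- cbind(1, rep(0:1, each = 10))
  a <- permutation_cluster_null(Y, X, c(0, 1), mask, n_perm = 120, seed = 9)
  b <- permutation_cluster_null(Y, X, c(0, 1), mask, n_perm = 120, seed = 9)
  expect_identical(a$max_sizes, b$max_sizes)
  expect_gt(a$observed, a$q95)
  expect_warning(
    permutation_cluster_null(Y, X, c(0, 1), mask, n_perm = 50, seed = 1),
    "coarse")
})

test_that("cluster-mean features follow their degenerate identities", {
  co <- tiny_cohort()
  mask <- co$ground_truth$true_network_mask
  nh <- compute_nh(co$runs[["ctrl01.baseline"]], mask)
  d <- dim(mask)
  single <- array(FALSE, d)
  vox <- which(mask)[5]
  single[vox] <- TRUE
  feat <- extract_cluster_means(list(nh), list(single))
  expect_equal(feat$mean_nh, nh$values[vox])
  # uniform map value c gives feature c for any cluster
  u <- nh; u$values[mask] <- 0.37
  feat2 <- extract_cluster_means(list(u),
                                 list(co$ground_truth$planted_cluster_masks[[1]]))
  expect_equal(feat2$mean_nh, 0.37)
  expect_error(extract_cluster_means(list(nh), list(array(FALSE, d))),
               "empty")
})

test_that("pearson_corr matches cor.test and calibrates at the null", {
  x <- rnorm(30)
  pc <- pearson_corr(x, 2 * x + 1)
  expect_equal(pc$r, 1, tolerance = 1e-12)
  set.seed(38)
  for (r in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    ct <- stats::cor.test(a, b)
    got <- pearson_corr(a, b)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
  # ~5% rejections under shuffling
  set.seed(39)
  a <- rnorm(40); b <- rnorm(40)
  rej <- mean(vapply(1:1000, function(i)
    pearson_corr(a, sample(b))$p < 0.05, TRUE))
  expect_lt(abs(rej - 0.05), 0.025)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "variance")
})

test_that("chi-square follows the O/E formula and the stats oracle", {
  expect_equal(chi_square_contingency(rbind(c(10, 0), c(0, 10)))$statistic,
               20)
  expect_equal(chi_square_contingency(rbind(c(10, 20), c(5, 10)))$statistic,
               0)
  tab <- rbind(c(12, 15, 14), c(7, 5, 6))
  got <- chi_square_contingency(tab)
  want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
  expect_equal(got$dof, unname(want$parameter))
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))), "marginal")
})
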