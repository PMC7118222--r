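test_that("identical configurations generate bit-identical cohorts", {
  cfg <- tiny_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$runs[["dpp01.baseline"]]$data,
                   b$runs[["dpp01.baseline"]]$data)
  expect_identical(a$motion[["dt02.week8"]]$params,
                   b$motion[["dt02.week8"]]$params)
  expect_identical(a$subjects, b$subjects)
  # a different seed changes the data
  c_ <- generate_cohort(tiny_config(seed = 8))
  expect_false(identical(a$runs[[1]]$data, c_$runs[[1]]$data))
})

test_that("noise-free unit-loading network drives NH to 1", {
  cfg <- sim_config(seed = 1, grid_dims = c(10, 10, 6), n_timepoints = 60,
                    n_per_group = c(control = 1, patient_dpp = 1,
                                    patient_dt = 1),
                    network_fraction = 0.2, base_loading = 1,
                    noise_sd = 1e-8, local_sd = 0,
                    planted_clusters = list(
                      planted_effect(1, 1, 1, 1, center = c(0.3, 0.3, 0.55),
                                     size = 10)))
  co <- generate_cohort(cfg, timepoints = "baseline")
  nh <- compute_nh(co$runs[["ctrl01.baseline"]],
                   co$ground_truth$true_network_mask)
  expect_true(all(abs(nh_values(nh) - 1) < 1e-6))
})

test_that("planted clusters sit inside the network and share the grid", {
  co <- tiny_cohort()
  gt <- co$ground_truth
  for (m in gt$planted_cluster_masks) {
    expect_identical(dim(m), dim(gt$true_network_mask))
    expect_true(all(gt$true_network_mask[m]))
  }
  expect_identical(dim(co$runs[[1]]$data)[1:3],
                   dim(gt$true_network_mask))
  expect_identical(co$runs[[1]]$affine, gt$affine)
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(grid_dims = c(5, 5, 5)), "500")
  expect_error(sim_config(grid_dims = c(0, 10, 10)), "positive")
  expect_error(sim_config(n_timepoints = 10), "50")
  expect_error(sim_config(network_fraction = 1.2), "network_fraction")
  # explicit cluster voxels outside the network are a configuration error
  cfg <- tiny_config()
  cfg_mask <- make_ground_truth(cfg)$true_network_mask
  out_vox <- which(!cfg_mask)[1:5]
  crd <- arrayInd(out_vox, dim(cfg_mask))
  cfg$planted_clusters[[1]]$cluster_voxels <- crd
  expect_error(make_ground_truth(cfg), "outside")
})

test_that("expected in-cluster NH is monotone in the loading", {
  cfg <- tiny_config(seed = 3)
  gt <- make_ground_truth(cfg)
  cl1 <- match(which(gt$planted_cluster_masks[[1]]), gt$network_index)
  mean_nh_at <- function(loading, rep) {
    lam <- rep(cfg$base_loading, length(gt$network_index))
    lam[cl1] <- loading
    sim <- nhfmri:::simulate_run_matrix(cfg, gt, lam,
                                        paste0("mono", loading, rep))
    nh <- compute_nh(sim$data[, gt$network_index], mask = NULL)
    mean(nh$values[cl1])
  }
  levels_ <- c(0.2, 0.5, 0.9)
  means <- vapply(levels_, function(l)
    mean(vapply(1:50, function(r) mean_nh_at(l, r), 0)), 0)
  expect_true(all(diff(means) > 0))
})

test_that("patients' cluster NH is depressed well beyond sampling spread", {
  # loading 0.3 vs 0.9 in a 30-voxel cluster, default grid, n = 20/group
  cfg <- sim_config(seed = 5,
                    n_per_group = c(control = 20, patient_dpp = 20,
                                    patient_dt = 1))
  res <- cohort_nh_maps(cfg, timepoints = "baseline", preprocess = FALSE,
                        standardize = FALSE, clinical = FALSE,
                        subset = c(sprintf("ctrl%02d", 1:20),
                                   sprintf("dpp%02d", 1:20)))
  m1 <- res$ground_truth$planted_cluster_masks[[1]]
  feat <- vapply(res$maps, function(nh) mean(nh$values[m1]), 0)
  grp <- res$subjects$group[match(sub("\\.baseline$", "", names(feat)),
                                  res$subjects$subject_id)]
  gap <- mean(feat[grp == "control"]) - mean(feat[grp == "patient"])
  spread <- max(sd(feat[grp == "control"]), sd(feat[grp == "patient"]))
  expect_gt(gap, 3 * spread)
})

test_that("motion generator honours its degenerate and forced regimes", {
  cfg0 <- tiny_config(motion_spike_prob = 0, motion_step_sd = 0)
  mo <- generate_motion(cfg0, "s1")
  expect_true(all(mo$params == 0))
  expect_true(all(mo$fd == 0))

  cfg1 <- tiny_config(motion_spike_prob = 1)
  mo1 <- generate_motion(cfg1, "s1")
  expect_true(all(mo1$fd[-1] > 0.2))

  # a single 3 mm translation spike trips the 2 mm exclusion rule
  mo$params[30, 3] <- 3
  expect_true(exclude_by_motion(mo))
})

test_that("clinical coupling reproduces the requested correlation regimes", {
  subj <- make_subject_table(tiny_config())
  pat <- subj$group == "patient"
  nh <- setNames(rnorm(nrow(subj)), subj$subject_id)

  # noiseless positive slope: exact linear relation
  cl0 <- clinical_coupling(slope = 0.1, intercept = 0.5, noise_sd = 0)
  out <- generate_clinical(subj, nh, cl0, seed = 1)
  keep <- pat & out$rr_total > 0 & out$rr_total < 1   # unclamped range
  expect_equal(cor(nh[keep], out$rr_total[keep]), 1, tolerance = 1e-12)
  expect_true(all(out$rr_total[pat] >= 0 & out$rr_total[pat] <= 1))
  expect_true(all(out$panss_total_1[pat] > 75))
  # week-8 totals back-compute the reduction ratio
  expect_equal(reduction_ratio(out$panss_total_1[pat],
                               out$panss_total_2[pat]),
               out$rr_total[pat], tolerance = 1e-12)

  # zero slope: observed correlation below the p<0.05 critical value in
  # >= 90% of replicates at n = 19
  cfg19 <- sim_config(seed = 1, n_per_group = c(control = 2,
                                                patient_dpp = 19,
                                                patient_dt = 2))
  s19 <- make_subject_table(cfg19)
  p19 <- s19$group == "patient" & s19$arm == "DPP"
  rcrit <- {
    tcrit <- qt(1 - 0.025, 19 - 2)
    tcrit / sqrt(tcrit^2 + 17)
  }
  hits <- vapply(1:100, function(s) {
    nh19 <- setNames(rnorm(nrow(s19)), s19$subject_id)
    out <- generate_clinical(
      s19, nh19, clinical_coupling(slope = 0, intercept = 0.55,
                                   noise_sd = 0.08), seed = s)
    abs(cor(nh19[p19], out$rr_total[p19])) < rcrit
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # missing baseline NH for a patient errors
  nh_bad <- nh; nh_bad[subj$subject_id[pat][1]] <- NA
  expect_error(generate_clinical(subj, nh_bad, cl0, seed = 1), "missing")
})

test_that("streamed per-subject analysis matches the full cohort", {
  cfg <- tiny_config(seed = 9)
  co <- generate_cohort(cfg)
  res <- cohort_nh_maps(cfg, timepoints = "baseline", preprocess = FALSE,
                        standardize = FALSE)
  key <- "dt03.baseline"
  direct <- compute_nh(co$runs[[key]], co$ground_truth$true_network_mask)
  expect_equal(nh_values(res$maps[[key]]), nh_values(direct),
               tolerance = 1e-12)
  # subjects and ground truth agree between the two construction paths
  expect_equal(res$subjects$rr_total, co$subjects$rr_total)
  expect_equal(res$ground_truth$baseline_region_nh,
               co$ground_truth$baseline_region_nh)
})
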