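#' Ground-truth network geometry for a synthetic cohort
#'
#' Builds the true network mask (the `network_fraction` of grid voxels
#' nearest to a fixed set of blob centres, giving a compact multi-focal
#' geometry) and resolves every planted cluster to an explicit voxel set
#' inside the network.  Explicit `cluster_voxels` outside the network are a
#' configuration error.
#'
#' @param cfg a [sim_config()].
#' @return list with `true_network_mask` (logical 3-D),
#'   `planted_cluster_masks` (list of logical 3-D), `affine` (4 x 4
#'   grid-to-mm map, MNI-style centred origin), plus per-voxel index caches.
#' @export
make_ground_truth <- function(cfg) {
  validate_sim_config(cfg)
  d <- cfg$grid_dims
  V <- prod(d)
  crd <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  rel <- sweep(sweep(crd, 2, c(1, 1, 1)), 2, pmax(d - 1, 1), "/")
  centers <- rbind(c(0.30, 0.30, 0.55), c(0.70, 0.65, 0.45),
                   c(0.50, 0.80, 0.50), c(0.45, 0.15, 0.40))
  dist2 <- sapply(seq_len(nrow(centers)), function(k)
    rowSums(sweep(rel, 2, centers[k, ])^2))
  mind <- do.call(pmin, as.data.frame(dist2))
  n_net <- max(2L, round(cfg$network_fraction * V))
  net_idx <- order(mind)[seq_len(n_net)]
  mask <- array(FALSE, d)
  mask[net_idx] <- TRUE

  taken <- integer(0)
  cl_masks <- lapply(cfg$planted_clusters, function(pe) {
    m <- array(FALSE, d)
    if (!is.null(pe$cluster_voxels)) {
      cv <- as.matrix(pe$cluster_voxels)
      idx <- cv[, 1] + (cv[, 2] - 1) * d[1] + (cv[, 3] - 1) * d[1] * d[2]
      if (!all(mask[idx]))
        stop("planted cluster lies outside the true network")
    } else {
      dd <- rowSums(sweep(rel[net_idx, , drop = FALSE], 2, pe$center)^2)
      avail <- setdiff(order(dd), match(taken, net_idx))
      if (length(avail) < pe$size)
        stop("not enough free network voxels for a planted cluster")
      idx <- net_idx[avail[seq_len(pe$size)]]
    }
    taken <<- c(taken, idx)
    m[idx] <- TRUE
    m
  })
  aff <- diag(c(rep(cfg$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -(d / 2) * cfg$voxel_size_mm
  list(true_network_mask = mask, planted_cluster_masks = cl_masks,
       affine = aff, network_index = net_idx, grid_dims = d)
}

#' Simulate one subject's rigid-body motion series
#'
#' Six columns (3 translations in mm, 3 rotations in rad) follow a slowly
#' mean-reverting bounded random walk.  With probability
#' `motion_spike_prob` per frame (after the first), a transient translation
#' spike of amplitude `>= motion_spike_mm` is injected on one axis with a
#' frame-parity alternating sign, which guarantees the resulting framewise
#' displacement exceeds the 0.2 mm scrubbing threshold even for adjacent
#' spikes.
#'
#' @param cfg a [sim_config()].
#' @param seed_offset integer stream label; different subjects/timepoints
#'   use different offsets.
#' @return a `motion_series`: `params` (t x 6), `fd`, `mean_fd`,
#'   `spike_frames`.
#' @export
generate_motion <- function(cfg, seed_offset = 0L) {
  t <- cfg$n_timepoints
  stopifnot(t >= 2)
  with_seed(derive_seed(cfg$seed, "motion", seed_offset), {
    step <- cfg$motion_step_sd
    p <- matrix(0, t, 6)
    sds <- c(rep(step, 3), rep(step / 50, 3))  # rot steps ~ equal FD weight
    for (i in 2:t) p[i, ] <- 0.995 * p[i - 1, ] + rnorm(6, sd = sds)
    # bound the walk at +/- 1 mm / 0.02 rad by reflection
    bound <- c(rep(1, 3), rep(0.02, 3))
    for (j in 1:6) {
      v <- p[, j]
      v <- pmin(pmax(v, -2 * bound[j] - v), v)  # reflect at lower bound
      p[, j] <- sign(v) * pmin(abs(v), bound[j])
    }
    spikes <- which(runif(t) < cfg$motion_spike_prob)
    spikes <- spikes[spikes > 1]
    if (length(spikes)) {
      axis <- sample.int(3, length(spikes), replace = TRUE)
      amp <- cfg$motion_spike_mm * (1 + 0.5 * runif(length(spikes))) *
        ifelse(spikes %% 2 == 0, 1, -1)
      p[cbind(spikes, axis)] <- p[cbind(spikes, axis)] + amp
    }
    fd <- compute_fd(p)
    structure(list(params = p, fd = fd, mean_fd = mean(fd),
                   spike_frames = spikes),
              class = "motion_series")
  })
}

#' Demographic subject table for a configuration
#'
#' Subject ids, group/arm assignment, and seeded age/sex draws; clinical
#' scores are appended later by [generate_clinical()].
#'
#' @param cfg a [sim_config()].
#' @return data.frame with subject_id, group, arm, age, sex.
#' @export
make_subject_table <- function(cfg) {
  npg <- cfg$n_per_group
  subj <- data.frame(
    subject_id = c(sprintf("ctrl%02d", seq_len(npg["control"])),
                   sprintf("dpp%02d", seq_len(npg["patient_dpp"])),
                   sprintf("dt%02d", seq_len(npg["patient_dt"]))),
    group = rep(c("control", "patient", "patient"), npg),
    arm = rep(c("none", "DPP", "DT"), npg),
    stringsAsFactors = FALSE)
  n <- nrow(subj)
  subj$age <- with_seed(derive_seed(cfg$seed, "age"),
                        pmin(pmax(round(rnorm(n, 25, 5)), 18), 50))
  subj$sex <- with_seed(derive_seed(cfg$seed, "sex"),
                        ifelse(runif(n) < 0.7, "male", "female"))
  subj
}

# Canonical baseline regional NH used by the clinical coupling: the
# standardised in-network NH (true network mask, unpreprocessed run) of
# the coupled planted cluster.
canonical_region_nh <- function(cfg, gt, sim_data) {
  region <- cfg$clinical_coupling$coupled_region_index
  reg_vox <- which(as.vector(gt$planted_cluster_masks[[region]]))
  nhm <- compute_nh(sim_data[, gt$network_index, drop = FALSE], mask = NULL)
  zval <- nh_values(standardize_map(nhm))
  mean(zval[match(reg_vox, gt$network_index)])
}

# Loading vector over network voxels for one subject cell.  Each planted
# cluster's group-level loading is shifted by a per-subject trait drawn
# once per subject and cluster (seeded by subject id, so identical at
# both timepoints and under cohort subsetting), then clamped to [0, 1].
cell_loadings <- function(cfg, gt, group, arm, timepoint,
                          subject_id = NULL) {
  lam <- rep(cfg$base_loading, length(gt$network_index))
  for (k in seq_along(cfg$planted_clusters)) {
    pe <- cfg$planted_clusters[[k]]
    lk <- if (group == "control") {
      pe$baseline_loading_control
    } else if (timepoint == "baseline") {
      pe$baseline_loading_patient
    } else if (arm == "DPP") pe$followup_loading_dpp else pe$followup_loading_dt
    if (!is.null(subject_id) && (cfg$loading_sd %||% 0) > 0)
      lk <- min(max(lk + with_seed(
        derive_seed(cfg$seed, "trait", subject_id, k),
        rnorm(1, 0, cfg$loading_sd)), 0), 1)
    lam[match(which(gt$planted_cluster_masks[[k]]), gt$network_index)] <- lk
  }
  lam
}

# One run's voxel data (t x V matrix): in-network series are
# loading * shared network signal + private local signal + AR(1) noise;
# out-of-network voxels carry AR(1) noise only.  A white-matter and a CSF
# nuisance series are mixed weakly into every voxel and returned so that
# confound regression has something real to remove.
simulate_run_matrix <- function(cfg, gt, lam, stream) {
  t <- cfg$n_timepoints
  V <- prod(cfg$grid_dims)
  with_seed(derive_seed(cfg$seed, "bold", stream), {
    x <- ar1_noise(t, V, cfg$ar1_coef, cfg$noise_sd)
    g <- ar1_noise(t, 1, cfg$ar1_coef, 1)[, 1]
    loc <- ar1_noise(t, length(gt$network_index), cfg$ar1_coef, cfg$local_sd)
    x[, gt$network_index] <- x[, gt$network_index] + outer(g, lam) + loc
    wm <- ar1_noise(t, 1, cfg$ar1_coef, 1)[, 1]
    csf <- ar1_noise(t, 1, cfg$ar1_coef, 1)[, 1]
    x <- x + outer(wm, rep(0.15, V)) + outer(csf, rep(0.15, V))
    list(data = x, wm = wm, csf = csf)
  })
}

#' Generate a synthetic two-timepoint BOLD cohort
#'
#' Produces one run per subject per timepoint (controls: baseline only,
#' mirroring a design in which healthy controls are scanned once), motion
#' series, a subject table with demographics, PANSS and cognitive scores and
#' derived reduction ratios, and the generating ground truth.  Identical
#' configurations produce bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param timepoints which scans to simulate for patients: both (default)
#'   or baseline only (halves memory when follow-up runs are not needed).
#' @param keep_bold keep the 4-D voxel data in the returned runs.  If
#'   `FALSE`, each run retains only its metadata and per-run baseline NH
#'   summaries, which keeps large cohorts cheap.
#' @return list with `runs` (named list of `bold_run`), `motion` (named
#'   list of `motion_series`), `subjects` (data.frame), `ground_truth`.
#'   Run/motion names are `<subject_id>.<timepoint>`.
#' @export
generate_cohort <- function(cfg, timepoints = c("baseline", "week8"),
                            keep_bold = TRUE) {
  validate_sim_config(cfg)
  timepoints <- match.arg(timepoints, c("baseline", "week8"),
                          several.ok = TRUE)
  gt <- make_ground_truth(cfg)
  subj <- make_subject_table(cfg)
  n <- nrow(subj)

  runs <- list(); motion <- list()
  subj$mean_fd_baseline <- NA_real_; subj$mean_fd_week8 <- NA_real_
  region <- cfg$clinical_coupling$coupled_region_index
  if (region > length(gt$planted_cluster_masks))
    stop("coupled_region_index exceeds the number of planted clusters")
  baseline_nh <- setNames(rep(NA_real_, n), subj$subject_id)

  loading_rows <- list()
  for (i in seq_len(n)) {
    tps <- if (subj$group[i] == "control") "baseline" else timepoints
    for (tp in tps) {
      key <- paste(subj$subject_id[i], tp, sep = ".")
      lam <- cell_loadings(cfg, gt, subj$group[i], subj$arm[i], tp,
                           subj$subject_id[i])
      loading_rows[[key]] <- data.frame(
        subject_id = subj$subject_id[i], timepoint = tp,
        cluster = seq_along(cfg$planted_clusters),
        loading = vapply(seq_along(cfg$planted_clusters), function(k)
          lam[match(which(gt$planted_cluster_masks[[k]])[1],
                    gt$network_index)], 0))
      sim <- simulate_run_matrix(cfg, gt, lam, key)
      mo <- generate_motion(cfg, seed_offset = key)
      mo$subject_id <- subj$subject_id[i]; mo$timepoint <- tp
      motion[[key]] <- mo
      if (tp == "baseline") subj$mean_fd_baseline[i] <- mo$mean_fd
      else subj$mean_fd_week8[i] <- mo$mean_fd
      if (tp == "baseline")
        baseline_nh[i] <- canonical_region_nh(cfg, gt, sim$data)
      run <- structure(list(
        data = if (keep_bold)
          array(t(sim$data), dim = c(cfg$grid_dims, cfg$n_timepoints))
        else NULL,
        tr_s = cfg$tr_s, subject_id = subj$subject_id[i], timepoint = tp,
        affine = gt$affine, wm = sim$wm, csf = sim$csf),
        class = "bold_run")
      runs[[key]] <- run
    }
  }

  clin <- generate_clinical(subj, baseline_nh, cfg$clinical_coupling,
                            seed = derive_seed(cfg$seed, "clinical"))
  ground_truth <- list(
    true_network_mask = gt$true_network_mask,
    planted_cluster_masks = gt$planted_cluster_masks,
    affine = gt$affine,
    per_subject_loadings = do.call(rbind, loading_rows),
    baseline_region_nh = baseline_nh,
    true_rr = clin$rr_total[clin$group == "patient"])
  list(runs = runs, motion = motion, subjects = clin,
       ground_truth = ground_truth, config = cfg)
}

#' Couple clinical scores to measured baseline regional NH
#'
#' Patients' PANSS total reduction ratios are
#' `clamp(intercept + slope * baseline_region_NH + noise, 0, 1)`; subscale
#' reduction ratios track the total with small independent perturbations,
#' and week-8 scores are back-computed from the ratios.  Baseline PANSS
#' subscale scores are drawn around the emulated study's scale and the
#' total (their sum) is enforced to exceed 75, the inclusion threshold.
#' When the coupling's `slope` is `NULL` it is calibrated so that the
#' population correlation between baseline regional NH and RR equals
#' `target_r` (default 0.9) given the observed NH spread.
#'
#' @param subjects subject data.frame with `subject_id`, `group`.
#' @param baseline_nh named numeric vector of baseline mean NH in the
#'   coupled region (standardised units), one entry per subject; patients
#'   must be non-missing.
#' @param coupling a [clinical_coupling()].
#' @param seed integer seed for the clinical draws.
#' @return `subjects` extended with PANSS, cognitive and RR columns.
#' @export
generate_clinical <- function(subjects, baseline_nh, coupling, seed = 1L) {
  pat <- subjects$group == "patient"
  x <- baseline_nh[subjects$subject_id]
  if (any(pat & !is.finite(x)))
    stop("baseline regional NH missing for one or more patients")
  with_seed(seed, {
    n <- nrow(subjects)
    rpos <- function(mu, s) rnorm(n, mu, s)
    pos1 <- pmax(rpos(24, 4), 8); neg1 <- pmax(rpos(27, 5), 8)
    gen1 <- pmax(rpos(53, 5), 17)
    tot1 <- pos1 + neg1 + gen1
    # enforce the >75 inclusion rule by resampling the rare failures
    while (any(pat & tot1 <= 75)) {
      i <- which(pat & tot1 <= 75)
      gen1[i] <- pmax(rnorm(length(i), 53, 5), 17)
      tot1 <- pos1 + neg1 + gen1
    }
    cal <- if (is.null(coupling$slope) || is.null(coupling$intercept) ||
               is.null(coupling$noise_sd))
      calibrate_clinical_coupling(x[pat], coupling)
    sl <- coupling$slope %||% cal$slope
    ic <- coupling$intercept %||% cal$intercept
    ns <- coupling$noise_sd %||% cal$noise_sd
    rr_tot <- pmin(pmax(ic + sl * x + rnorm(n, 0, ns), 0), 1)
    rr_sub <- function() pmin(pmax(rr_tot + rnorm(n, 0, 0.04), 0), 1)
    rr_pos <- rr_sub(); rr_neg <- rr_sub(); rr_gen <- rr_sub()
    cog <- list(tmt_a = c(52, 18), bacs_sc = c(38, 9), hvlt_r = c(16, 4),
                bvmt_r = c(17, 6), cpt_ip = c(1.1, 0.7), wms_ss = c(11.5, 2.4),
                nab_m = c(9, 5), msceit = c(78, 9), cf_anf = c(13.4, 3.3))
    for (nm in names(cog))
      subjects[[paste0(nm, "_1")]] <- rnorm(n, cog[[nm]][1], cog[[nm]][2])
    patify <- function(v) ifelse(pat, v, NA_real_)
    subjects$panss_total_1 <- patify(tot1)
    subjects$panss_positive_1 <- patify(pos1)
    subjects$panss_negative_1 <- patify(neg1)
    subjects$panss_general_1 <- patify(gen1)
    subjects$rr_total <- patify(rr_tot)
    subjects$rr_positive <- patify(rr_pos)
    subjects$rr_negative <- patify(rr_neg)
    subjects$rr_general <- patify(rr_gen)
    subjects$panss_total_2 <- patify(tot1 * (1 - rr_tot))
    subjects$panss_positive_2 <- patify(pos1 * (1 - rr_pos))
    subjects$panss_negative_2 <- patify(neg1 * (1 - rr_neg))
    subjects$panss_general_2 <- patify(gen1 * (1 - rr_gen))
    subjects
  })
}

#' Calibrate the NH-to-RR coupling to a target correlation
#'
#' Given the baseline regional NH values of the patients, returns the
#' slope/intercept/noise of a linear coupling whose population correlation
#' with the reduction ratio is `coupling$target_r` with RR mean
#' `coupling$rr_mean` and SD `coupling$rr_sd`.
#'
#' @param nh_values numeric vector of patients' baseline regional NH.
#' @param coupling a [clinical_coupling()] carrying the targets.
#' @return list with `slope`, `intercept`, `noise_sd`.
#' @export
calibrate_clinical_coupling <- function(nh_values, coupling) {
  r <- coupling$target_r; m <- coupling$rr_mean; s <- coupling$rr_sd
  sx <- sd(nh_values)
  if (!is.finite(sx) || sx <= 0) stop("NH values have zero spread")
  slope <- r * s / sx
  list(slope = slope, intercept = m - slope * mean(nh_values),
       noise_sd = s * sqrt(max(0, 1 - r^2)))
}
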