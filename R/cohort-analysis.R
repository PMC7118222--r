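#' Stream a cohort into NH maps
#'
#' Regenerates each run of a synthetic cohort on demand (the generator is
#' a pure function of the configuration, so no voxel data needs to be
#' held for the whole cohort), optionally applies the temporal
#' preprocessing chain, and computes the per-voxel NH map on the given
#' mask.  Peak memory stays at roughly one run.
#'
#' @param cfg a [sim_config()].
#' @param mask logical 3-D array or `network_mask`; defaults to the
#'   ground-truth network.
#' @param timepoints scans to analyse.
#' @param preprocess apply [preprocess_run()] before NH.
#' @param standardize return in-mask standardised maps.
#' @param drop_excluded drop runs failing the 2 mm / 2 degree motion QC.
#' @param subset optional character vector of subject ids to analyse;
#'   every retained subject's data are bit-identical to a full-cohort run
#'   (per-run seeds derive from subject ids, not positions).
#' @param clinical attach generated clinical scores to the subject table
#'   (requires baseline runs for every patient in `subset`).
#' @return list with `maps` (named list of `nh_map`), `qc` (data.frame:
#'   subject_id, timepoint, excluded, usable, mean_fd, kept_frames),
#'   `subjects`, `ground_truth`.
#' @export
cohort_nh_maps <- function(cfg, mask = NULL,
                           timepoints = c("baseline", "week8"),
                           preprocess = TRUE, standardize = TRUE,
                           drop_excluded = TRUE, subset = NULL,
                           clinical = TRUE) {
  validate_sim_config(cfg)
  timepoints <- match.arg(timepoints, c("baseline", "week8"),
                          several.ok = TRUE)
  gt <- make_ground_truth(cfg)
  if (is.null(mask)) mask <- gt$true_network_mask
  if (inherits(mask, "network_mask")) mask <- mask$mask
  mask_idx <- which(as.vector(mask))
  subj <- make_subject_table(cfg)
  if (!is.null(subset)) subj <- subj[subj$subject_id %in% subset, ]
  baseline_nh <- setNames(rep(NA_real_, nrow(subj)), subj$subject_id)
  loading_rows <- list()
  maps <- list(); qc <- list()
  for (i in seq_len(nrow(subj))) {
    tps <- if (subj$group[i] == "control") "baseline" else
      unique(c("baseline", timepoints))
    for (tp in tps) {
      key <- paste(subj$subject_id[i], tp, sep = ".")
      lam <- cell_loadings(cfg, gt, subj$group[i], subj$arm[i], tp,
                           subj$subject_id[i])
      sim <- simulate_run_matrix(cfg, gt, lam, key)
      if (tp == "baseline")
        baseline_nh[i] <- canonical_region_nh(cfg, gt, sim$data)
      if (!(tp %in% timepoints)) next
      mo <- generate_motion(cfg, seed_offset = key)
      excluded <- exclude_by_motion(mo)
      if (preprocess) {
        run <- structure(list(
          data = array(t(sim$data), dim = c(cfg$grid_dims, cfg$n_timepoints)),
          tr_s = cfg$tr_s, subject_id = subj$subject_id[i], timepoint = tp,
          affine = gt$affine, wm = sim$wm, csf = sim$csf),
          class = "bold_run")
        pp <- preprocess_run(run, mo)
        usable <- pp$usable
        kept <- sum(pp$kept_mask)
        nh <- compute_nh(pp$run, mask)
      } else {
        usable <- TRUE; kept <- cfg$n_timepoints
        nh <- compute_nh(sim$data[, mask_idx, drop = FALSE], mask = NULL)
        v <- array(NA_real_, cfg$grid_dims)
        v[mask_idx] <- nh$values
        nh$values <- v; nh$mask <- mask
      }
      nh$subject_id <- subj$subject_id[i]; nh$timepoint <- tp
      if (standardize) nh <- standardize_map(nh)
      qc[[key]] <- data.frame(subject_id = subj$subject_id[i],
                              timepoint = tp, excluded = excluded,
                              usable = usable, mean_fd = mo$mean_fd,
                              kept_frames = kept)
      if (!(drop_excluded && excluded) && usable) maps[[key]] <- nh
    }
  }
  if (clinical)
    subj <- generate_clinical(subj, baseline_nh, cfg$clinical_coupling,
                              seed = derive_seed(cfg$seed, "clinical"))
  subj$mean_fd_baseline <-
    qc_field(qc, subj$subject_id, "baseline", "mean_fd")
  subj$mean_fd_week8 <- qc_field(qc, subj$subject_id, "week8", "mean_fd")
  ground_truth <- list(
    true_network_mask = gt$true_network_mask,
    planted_cluster_masks = gt$planted_cluster_masks,
    affine = gt$affine,
    baseline_region_nh = baseline_nh,
    true_rr = subj$rr_total[subj$group == "patient"])
  list(maps = maps, qc = do.call(rbind, qc), subjects = subj,
       ground_truth = ground_truth)
}

qc_field <- function(qc, ids, tp, field) {
  qcd <- do.call(rbind, qc)
  sel <- qcd[qcd$timepoint == tp, ]
  sel[[field]][match(ids, sel$subject_id)]
}

#' Baseline patient-versus-control NH inference on a cohort
#'
#' Builds the baseline design (group indicator, centred age and mean FD),
#' fits the voxel-wise GLM for the requested arm versus controls,
#' estimates residual smoothness, and applies GRF cluster correction.
#'
#' @param maps named list of baseline `nh_map`s (`<subject>.baseline`).
#' @param subjects subject table with `subject_id`, `group`, `arm`, `age`,
#'   `mean_fd_baseline`.
#' @param mask analysis mask.
#' @param arm `"DPP"`, `"DT"`, or `"pooled"` for both patient arms.
#' @param voxel_p,cluster_p GRF thresholds.
#' @param voxel_size_mm voxel size for smoothness/coordinates.
#' @param affine optional affine for mm peaks.
#' @return list with `clusters` (a `cluster_table`), `stat` (`stat_map`),
#'   `smoothness`, `design_rows` (subject ids used).
#' @export
baseline_group_inference <- function(maps, subjects, mask,
                                     arm = c("DPP", "DT", "pooled"),
                                     voxel_p = 0.001, cluster_p = 0.05,
                                     voxel_size_mm = 3, affine = NULL) {
  arm <- match.arg(arm)
  keep <- subjects$group == "control" |
    (if (arm == "pooled") subjects$group == "patient"
     else subjects$arm == arm)
  ids <- subjects$subject_id[keep]
  keys <- paste0(ids, ".baseline")
  present <- keys %in% names(maps)
  ids <- ids[present]; keys <- keys[present]
  sub <- subjects[match(ids, subjects$subject_id), ]
  Y <- stack_nh_maps(maps[keys])
  X <- build_design(
    data.frame(group = factor(sub$group, c("control", "patient")),
               age = sub$age, mean_fd = sub$mean_fd_baseline),
    indicators = "group", covariates = c("age", "mean_fd"))
  stat <- fit_voxelwise_glm(Y, X, "group_patient")
  stat$mask <- if (inherits(mask, "network_mask")) mask$mask else mask
  sm <- estimate_smoothness(stat$residuals, stat$mask, voxel_size_mm)
  cl <- grf_cluster_correct(stat, stat$mask, sm, voxel_p, cluster_p,
                            voxel_size_mm, affine)
  list(clusters = cl, stat = stat, smoothness = sm, design_rows = ids)
}
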