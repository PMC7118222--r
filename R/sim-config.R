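#' Planted group/treatment effect on network loading
#'
#' Describes one compact cluster of in-network voxels whose coupling
#' ("loading") onto the shared network signal differs by group and, for
#' patients, changes between baseline and the week-8 follow-up.  Lower
#' loading implies lower expected network homogeneity in the cluster, so the
#' loadings encode both the case-control deficit and any treatment-arm
#' restoration.
#'
#' The cluster geometry may be given explicitly as a voxel coordinate matrix
#' or left to the generator, which carves the `size` in-network voxels
#' nearest to `center` (relative grid coordinates in `[0, 1]^3`).
#'
#' @param baseline_loading_patient,baseline_loading_control loading in
#'   `[0, 1]` at baseline for patients / controls.
#' @param followup_loading_dpp,followup_loading_dt loading at week 8 for the
#'   drug-plus-psychotherapy and drug-therapy arms.
#' @param center length-3 numeric in `[0, 1]`, relative cluster centre.
#' @param size number of voxels in the cluster.
#' @param cluster_voxels optional integer matrix (n x 3) of explicit voxel
#'   coordinates; overrides `center`/`size`.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(baseline_loading_patient,
                           baseline_loading_control,
                           followup_loading_dpp,
                           followup_loading_dt,
                           center = c(0.5, 0.5, 0.5),
                           size = 30L,
                           cluster_voxels = NULL) {
  loads <- c(baseline_loading_patient, baseline_loading_control,
             followup_loading_dpp, followup_loading_dt)
  if (any(loads < 0 | loads > 1)) stop("loadings must lie in [0, 1]")
  if (is.null(cluster_voxels)) {
    stopifnot(length(center) == 3, all(center >= 0 & center <= 1), size >= 1)
  }
  structure(list(
    baseline_loading_patient = baseline_loading_patient,
    baseline_loading_control = baseline_loading_control,
    followup_loading_dpp = followup_loading_dpp,
    followup_loading_dt = followup_loading_dt,
    center = center, size = as.integer(size),
    cluster_voxels = cluster_voxels
  ), class = "planted_effect")
}

#' Coupling between baseline regional NH and clinical reduction ratio
#'
#' Patients' PANSS reduction ratios are generated as a linear function of
#' their measured baseline mean NH in one planted cluster, plus Gaussian
#' noise, clamped to `[0, 1]`.
#'
#' When `slope` is `NULL` (the default) the coupling is calibrated at
#' generation time so that the population correlation between baseline
#' regional NH and RR equals `target_r` with RR mean `rr_mean` and SD
#' `rr_sd` (see [calibrate_clinical_coupling()]).
#'
#' @param slope,intercept linear map from baseline regional NH (standardised
#'   units) to reduction ratio; `NULL` to calibrate from `target_r`.
#' @param noise_sd standard deviation of the additive noise (`NULL` to
#'   calibrate).
#' @param target_r population correlation used when calibrating.
#' @param rr_mean,rr_sd targeted RR mean and SD used when calibrating.
#' @param coupled_region_index which planted cluster carries the coupling.
#' @return an object of class `clinical_coupling`.
#' @export
clinical_coupling <- function(slope = NULL, intercept = NULL,
                              noise_sd = NULL,
                              target_r = 0.9, rr_mean = 0.55, rr_sd = 0.08,
                              coupled_region_index = 1L) {
  stopifnot(is.null(noise_sd) || noise_sd >= 0, coupled_region_index >= 1,
            abs(target_r) <= 1, rr_sd > 0)
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 target_r = target_r, rr_mean = rr_mean, rr_sd = rr_sd,
                 coupled_region_index = as.integer(coupled_region_index)),
            class = "clinical_coupling")
}

#' Default planted effects
#'
#' Two 30-voxel clusters with a strong baseline case-control loading gap
#' (patients 0.3 vs controls 0.9).  The first cluster is restored to the
#' control loading at week 8 in the psychotherapy (DPP) arm only, emulating
#' a treatment-specific NH normalisation; the second stays deficient in both
#' arms.
#'
#' @return list of [planted_effect()] objects.
#' @export
default_planted_effects <- function() {
  list(
    planted_effect(0.3, 0.9, followup_loading_dpp = 0.9,
                   followup_loading_dt = 0.3,
                   center = c(0.30, 0.30, 0.55), size = 30L),
    planted_effect(0.3, 0.9, followup_loading_dpp = 0.3,
                   followup_loading_dt = 0.3,
                   center = c(0.70, 0.65, 0.45), size = 30L)
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic BOLD cohort generator.  Defaults
#' mirror the emulated study design: 240 volumes at TR = 2 s on a
#' 20 x 24 x 20 grid of 3 mm voxels, 20 controls scanned once at baseline,
#' 20 + 21 patients (DPP / DT arms) scanned at baseline and week 8, a shared
#' network covering ~12% of the grid, AR(1) noise, occasional motion spikes,
#' and clinical scores coupled to baseline NH in the first planted cluster.
#'
#' @param seed integer master seed; every downstream draw derives from it.
#' @param grid_dims 3 positive integers, voxels per axis.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param n_timepoints frames per run before volume dropping.
#' @param tr_s repetition time (s).
#' @param n_per_group named integer vector with entries `control`,
#'   `patient_dpp`, `patient_dt`.
#' @param network_fraction fraction of grid voxels inside the true network.
#' @param base_loading network-signal loading of in-network voxels outside
#'   planted clusters (all groups).
#' @param loading_sd SD of the per-subject loading trait added to each
#'   planted cluster's group loading (persistent across timepoints, so
#'   baseline regional NH is a stable subject characteristic).
#' @param planted_clusters list of [planted_effect()].
#' @param ar1_coef lag-1 coefficient of the voxel noise.
#' @param noise_sd stationary SD of the voxel noise.
#' @param local_sd SD of the per-voxel private (local) signal.
#' @param motion_spike_prob per-frame probability of a motion spike whose
#'   framewise displacement exceeds 0.2 mm.
#' @param motion_step_sd per-frame SD (mm) of the bounded motion random walk.
#' @param motion_spike_mm translation amplitude of an injected spike (mm).
#' @param clinical_coupling a [clinical_coupling()] object.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       grid_dims = c(20L, 24L, 20L),
                       voxel_size_mm = 3,
                       n_timepoints = 240L,
                       tr_s = 2,
                       n_per_group = c(control = 20L, patient_dpp = 20L,
                                       patient_dt = 21L),
                       network_fraction = 0.12,
                       base_loading = 0.6,
                       loading_sd = 0.1,
                       planted_clusters = default_planted_effects(),
                       ar1_coef = 0.3,
                       noise_sd = 1,
                       local_sd = 0.5,
                       motion_spike_prob = 0.05,
                       motion_step_sd = 0.01,
                       motion_spike_mm = 0.3,
                       clinical_coupling = nhfmri::clinical_coupling()) {
  cfg <- structure(list(
    seed = as.integer(seed),
    grid_dims = as.integer(grid_dims),
    voxel_size_mm = voxel_size_mm,
    n_timepoints = as.integer(n_timepoints),
    tr_s = tr_s,
    n_per_group = n_per_group,
    network_fraction = network_fraction,
    base_loading = base_loading,
    loading_sd = loading_sd,
    planted_clusters = planted_clusters,
    ar1_coef = ar1_coef,
    noise_sd = noise_sd,
    local_sd = local_sd,
    motion_spike_prob = motion_spike_prob,
    motion_step_sd = motion_step_sd,
    motion_spike_mm = motion_spike_mm,
    clinical_coupling = clinical_coupling
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly, or an error describing the violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$grid_dims) != 3 || any(cfg$grid_dims <= 0))
    stop("grid_dims must be 3 positive integers")
  if (prod(cfg$grid_dims) < 500)
    stop("grid volume must be at least 500 voxels")
  if (cfg$n_timepoints < 50) stop("n_timepoints must be >= 50")
  if (cfg$tr_s <= 0 || cfg$voxel_size_mm <= 0)
    stop("tr_s and voxel_size_mm must be positive")
  need <- c("control", "patient_dpp", "patient_dt")
  if (!all(need %in% names(cfg$n_per_group)) ||
      any(cfg$n_per_group[need] <= 0))
    stop("n_per_group must name positive control/patient_dpp/patient_dt")
  if (cfg$network_fraction <= 0 || cfg$network_fraction >= 1)
    stop("network_fraction must lie in (0, 1)")
  if (cfg$ar1_coef < 0 || cfg$ar1_coef >= 1) stop("ar1_coef must be in [0,1)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$motion_spike_prob < 0 || cfg$motion_spike_prob > 1)
    stop("motion_spike_prob must be in [0,1]")
  n_clusters <- sum(vapply(cfg$planted_clusters, function(p)
    p$size %||% nrow(p$cluster_voxels), 1L))
  if (n_clusters > cfg$network_fraction * prod(cfg$grid_dims))
    stop("planted clusters cannot exceed the network size")
  invisible(cfg)
}
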