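#' Default pipeline configuration
#'
#' All study constants are named configuration defaults: 10 dropped
#' volumes, 0.01-0.08 Hz band, FD > 0.2 mm scrubbing, 2 mm / 2 degree
#' exclusion, voxel p < 0.001 / cluster p < 0.05 GRF thresholds, and the
#' 0.05/16 Bonferroni family for the SVR correlations.
#'
#' @return nested list of per-stage settings.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(),               # overrides for sim_config()
    preprocess = list(drop_k = 10, low_hz = 0.01, high_hz = 0.08,
                      fd_threshold_mm = 0.2, max_trans_mm = 2,
                      max_rot_deg = 2, enabled = TRUE),
    mask = list(use_ica = TRUE, n_components = 10, z_threshold = 1.96),
    nh = list(standardize = TRUE),
    infer = list(voxel_p = 0.001, cluster_p = 0.05, per_arm = TRUE),
    ml = list(grid_by = 4, inner_k = 3, alpha = 0.05, m = 16)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  base <- default_pipeline_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    else base[[nm]] <- config[[nm]]
  }
  base
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

checksums_ok <- function(entry) {
  !is.null(entry) && length(entry$outputs) &&
    all(file.exists(names(entry$outputs))) &&
    identical(unname(tools::md5sum(names(entry$outputs))),
              unname(unlist(entry$outputs)))
}

#' Run the full synthetic NH analysis pipeline
#'
#' Orchestrates simulate, mask, nh, infer and ml stages from a single
#' configuration with one master seed, writing per-stage artifacts and a
#' run manifest (config hash, per-stage output checksums, seed registry)
#' to `outdir`.  Stages whose configuration and on-disk outputs are
#' unchanged since the previous run are skipped; corrupting or removing
#' an intermediate file reruns that stage and everything downstream.
#'
#' @param config path to a JSON configuration or a nested list; see
#'   [default_pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param seed optional master seed overriding the config's.
#' @param verbose log stage progress.
#' @param force rerun every stage regardless of checksums.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), outdir = "nh-pipeline-out",
                         seed = NULL, verbose = TRUE, force = FALSE) {
  cfgl <- read_pipeline_config(config)
  if (!is.null(seed)) cfgl$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- cfgl$simulate
  sim_args$seed <- cfgl$seed
  scfg <- do.call(sim_config, sim_args)

  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (!force && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else NULL
  manifest <- list(version = as.character(utils::packageVersion("nhfmri")),
                   config_hash = config_hash(cfgl),
                   seed = cfgl$seed, stages = list())
  state <- new.env(parent = emptyenv())
  dirty <- isTRUE(force) ||
    !identical(old_manifest$config_hash, manifest$config_hash)

  run_stage <- function(name, outputs, compute, reload = NULL) {
    old <- old_manifest$stages[[name]]
    if (!dirty && checksums_ok(old)) {
      stage_log(verbose, name, "up to date, skipped")
      if (!is.null(reload)) reload()
      manifest$stages[[name]] <<- old
      return(invisible(FALSE))
    }
    dirty <<- TRUE
    stage_log(verbose, name, "running")
    tryCatch(compute(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      outputs = as.list(tools::md5sum(outputs)))
    invisible(TRUE)
  }

  p <- function(...) file.path(outdir, ...)

  ## -- simulate ----------------------------------------------------------
  run_stage("simulate",
    outputs = c(p("subjects.csv"), p("true_network_mask.nii.gz"),
                p("sim_config.json")),
    compute = function() {
      co <- generate_cohort(scfg, keep_bold = FALSE)
      state$subjects <- co$subjects
      state$gt <- co$ground_truth
      write.csv(co$subjects, p("subjects.csv"), row.names = FALSE)
      write_volume_nifti(co$ground_truth$true_network_mask,
                         p("true_network_mask.nii.gz"),
                         co$ground_truth$affine)
      for (k in seq_along(co$ground_truth$planted_cluster_masks))
        write_volume_nifti(co$ground_truth$planted_cluster_masks[[k]],
                           p(sprintf("planted_cluster_%d.nii.gz", k)),
                           co$ground_truth$affine)
      for (key in names(co$motion))
        write_motion_tsv(co$motion[[key]],
                         p(sprintf("motion_%s.tsv", key)))
      jsonlite::write_json(
        scfg[setdiff(names(scfg), c("planted_clusters", "clinical_coupling"))],
        p("sim_config.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    },
    reload = function() {
      state$subjects <- read.csv(p("subjects.csv"))
      co <- generate_cohort(scfg, keep_bold = FALSE)
      state$gt <- co$ground_truth
    })

  ## -- mask --------------------------------------------------------------
  run_stage("mask",
    outputs = c(p("network_mask.nii.gz"), p("mask_selection.json")),
    compute = function() {
      template <- state$gt$true_network_mask
      if (isTRUE(cfgl$mask$use_ica)) {
        base_keys <- paste0(state$subjects$subject_id, ".baseline")
        gtg <- make_ground_truth(scfg)
        reduced <- lapply(seq_len(nrow(state$subjects)), function(i) {
          lam <- cell_loadings(scfg, gtg, state$subjects$group[i],
                               state$subjects$arm[i], "baseline",
                               state$subjects$subject_id[i])
          sim <- simulate_run_matrix(scfg, gtg, lam, base_keys[i])
          sim$data
        })
        nm <- derive_network_mask(reduced, template,
                                  n_components = cfgl$mask$n_components,
                                  seed = derive_seed(cfgl$seed, "ica"),
                                  z_threshold = cfgl$mask$z_threshold)
        m3 <- array(as.vector(nm$mask), dim(template))
        state$mask <- m3
        sel <- list(index = nm$selection$index, score = nm$selection$score,
                    scores = nm$selection$scores,
                    components = nm$components)
      } else {
        state$mask <- template
        sel <- list(index = NA, score = NA, scores = numeric())
      }
      write_volume_nifti(state$mask, p("network_mask.nii.gz"),
                         state$gt$affine)
      jsonlite::write_json(sel, p("mask_selection.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    },
    reload = function() {
      img <- RNifti::readNifti(p("network_mask.nii.gz"))
      state$mask <- array(as.numeric(img) > 0.5, dim(img))
    })

  ## -- nh ----------------------------------------------------------------
  run_stage("nh",
    outputs = c(p("nh_long.csv"), p("nh_qc.json")),
    compute = function() {
      res <- cohort_nh_maps(scfg, mask = state$mask,
                            preprocess = isTRUE(cfgl$preprocess$enabled),
                            standardize = isTRUE(cfgl$nh$standardize))
      state$maps <- res$maps
      long <- do.call(rbind, lapply(names(res$maps), function(k) {
        nh <- res$maps[[k]]
        data.frame(subject_id = nh$subject_id, timepoint = nh$timepoint,
                   voxel = which(as.vector(state$mask)),
                   nh = nh_values(nh))
      }))
      write.csv(long, p("nh_long.csv"), row.names = FALSE)
      jsonlite::write_json(res$qc, p("nh_qc.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
    },
    reload = function() {
      long <- read.csv(p("nh_long.csv"))
      keys <- unique(paste(long$subject_id, long$timepoint, sep = "."))
      state$maps <- setNames(lapply(keys, function(k) {
        sl <- long[paste(long$subject_id, long$timepoint, sep = ".") == k, ]
        v <- array(NA_real_, dim(state$mask))
        v[sl$voxel] <- sl$nh
        structure(list(values = v, mask = state$mask,
                       subject_id = sl$subject_id[1],
                       timepoint = sl$timepoint[1],
                       standardized = isTRUE(cfgl$nh$standardize),
                       zero_variance = integer()), class = "nh_map")
      }), keys)
    })

  ## -- infer -------------------------------------------------------------
  run_stage("infer",
    outputs = c(p("clusters.csv"), p("inference.json"),
                p("cluster_labels_baseline.nii.gz")),
    compute = function() {
      arms <- if (isTRUE(cfgl$infer$per_arm)) c("DPP", "DT") else "pooled"
      all_rows <- list(); info <- list()
      state$contrasts <- list()
      for (a in arms) {
        inf <- baseline_group_inference(
          state$maps, state$subjects, state$mask, arm = a,
          voxel_p = cfgl$infer$voxel_p, cluster_p = cfgl$infer$cluster_p,
          voxel_size_mm = scfg$voxel_size_mm, affine = state$gt$affine)
        state$contrasts[[paste0(a, "_vs_control")]] <- inf
        if (nrow(inf$clusters)) {
          r <- as.data.frame(inf$clusters)
          r$contrast <- paste0(a, "_vs_control")
          all_rows[[a]] <- r
        }
        info[[a]] <- list(fwhm_mm = inf$smoothness$fwhm_mm,
                          resels = inf$smoothness$resels,
                          dof = inf$stat$dof,
                          t_critical = attr(inf$clusters, "t_critical"))
      }
      # group x time interaction over patient arms
      pat <- state$subjects[state$subjects$group == "patient", ]
      kb <- paste0(pat$subject_id, ".baseline")
      kf <- paste0(pat$subject_id, ".week8")
      ok <- kb %in% names(state$maps) & kf %in% names(state$maps)
      if (sum(ok) >= 4) {
        fi <- interaction_f(state$maps[kb[ok]], state$maps[kf[ok]],
                            pat$arm[ok],
                            covariates = data.frame(age = pat$age[ok]))
        fi$mask <- state$mask
        smi <- estimate_smoothness(fi$residuals, state$mask,
                                   scfg$voxel_size_mm)
        cli <- grf_cluster_correct(fi, state$mask, smi,
                                   cfgl$infer$voxel_p, cfgl$infer$cluster_p,
                                   scfg$voxel_size_mm, state$gt$affine)
        state$contrasts$interaction <- list(clusters = cli, stat = fi,
                                            smoothness = smi)
        if (nrow(cli)) {
          r <- as.data.frame(cli)
          r$contrast <- "group_x_time"
          all_rows$interaction <- r
        }
        info$interaction <- list(fwhm_mm = smi$fwhm_mm, resels = smi$resels)
      }
      tab <- if (length(all_rows)) do.call(rbind, all_rows) else
        data.frame(cluster_id = integer(), sign = numeric(),
                   peak_x = integer(), peak_y = integer(),
                   peak_z = integer(), peak_mm_x = numeric(),
                   peak_mm_y = numeric(), peak_mm_z = numeric(),
                   size_voxels = integer(), peak_stat = numeric(),
                   corrected_p = numeric(), contrast = character())
      state$cluster_rows <- tab
      first <- state$contrasts[[paste0(arms[1], "_vs_control")]]
      write_volume_nifti(attr(first$clusters, "labels"),
                         p("cluster_labels_baseline.nii.gz"),
                         state$gt$affine)
      write.csv(tab, p("clusters.csv"), row.names = FALSE)
      jsonlite::write_json(info, p("inference.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
    })

  ## -- ml ----------------------------------------------------------------
  run_stage("ml",
    outputs = c(p("svm_report.csv"), p("svr_report.csv")),
    compute = function() {
      grid <- svm_grid(by = cfgl$ml$grid_by)
      subj <- state$subjects
      gtm <- state$gt$planted_cluster_masks
      # features: significant clusters from the DPP contrast, else the
      # planted masks as a labelled fallback
      use <- state$contrasts[["DPP_vs_control"]] %||%
        state$contrasts[["pooled_vs_control"]]
      cl_masks <- if (!is.null(use) && nrow(use$clusters)) {
        labs <- attr(use$clusters, "labels")
        lapply(use$clusters$cluster_id, function(i) labs == i)
      } else gtm
      base_keys <- paste0(subj$subject_id, ".baseline")
      ok <- base_keys %in% names(state$maps)
      feats <- extract_cluster_means(state$maps[base_keys[ok]], cl_masks)
      svm_rows <- list(); svr_rows <- list()
      for (a in c("DPP", "DT")) {
        sel <- subj$subject_id[ok][subj$group[ok] == "control" |
                                     subj$arm[ok] == a]
        for (ci in unique(feats$cluster_id)) {
          f <- feats[feats$cluster_id == ci &
                       feats$subject_id %in% sel, ]
          lab <- subj$group[match(f$subject_id, subj$subject_id)]
          rep_ <- loo_svm_classify(f$mean_nh, lab, grid = grid,
                                   seed = derive_seed(cfgl$seed, "svm", a, ci),
                                   positive = "patient",
                                   inner_k = cfgl$ml$inner_k)
          svm_rows[[paste(a, ci)]] <- data.frame(
            arm = a, cluster_id = ci, t(rep_$metrics),
            tp = rep_$counts["tp"], fn = rep_$counts["fn"],
            tn = rep_$counts["tn"], fp = rep_$counts["fp"])
        }
        # SVR: baseline NH of the coupled region vs each symptomatic
        # domain; the feature is the detected cluster overlapping the
        # coupled planted mask best (detected-cluster numbering carries
        # no anatomical meaning)
        pat_ids <- subj$subject_id[subj$arm == a &
                                     subj$subject_id %in% feats$subject_id]
        coupled <- gtm[[min(scfg$clinical_coupling$coupled_region_index,
                            length(gtm))]]
        overlaps <- vapply(seq_along(cl_masks), function(k)
          sum(cl_masks[[k]] & coupled), 0)
        ci <- if (max(overlaps) > 0) which.max(overlaps) else 1L
        f <- feats[feats$cluster_id == ci & feats$subject_id %in% pat_ids, ]
        for (dom in c("total", "positive", "negative", "general")) {
          rr <- subj[[paste0("rr_", dom)]][match(f$subject_id,
                                                 subj$subject_id)]
          rep_ <- loo_svr_predict(f$mean_nh, rr, grid = grid,
                                  seed = derive_seed(cfgl$seed, "svr", a, dom),
                                  inner_k = cfgl$ml$inner_k,
                                  alpha = cfgl$ml$alpha, m = cfgl$ml$m)
          svr_rows[[paste(a, dom)]] <- data.frame(
            arm = a, domain = dom, cluster_id = ci, r = rep_$r, p = rep_$p,
            threshold = rep_$threshold, significant = rep_$significant)
        }
      }
      state$svm <- do.call(rbind, svm_rows)
      state$svr <- do.call(rbind, svr_rows)
      write.csv(state$svm, p("svm_report.csv"), row.names = FALSE)
      write.csv(state$svr, p("svr_report.csv"), row.names = FALSE)
    })

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$state <- state
  invisible(manifest)
}

#' Render summary report files from a pipeline run
#'
#' Produces a cluster summary in the conventional layout (location label,
#' peak mm coordinate, cluster extent, peak T; "No cluster" rows for
#' contrasts with no surviving cluster), a classifier metrics table, an
#' SVR summary, and the ground-truth overlap (Dice per planted cluster).
#'
#' @param outdir the pipeline output directory (must contain the stage
#'   outputs of [run_pipeline()]).
#' @return list of the report data.frames, invisibly; files are written
#'   into `outdir`.
#' @export
make_report <- function(outdir) {
  need <- c("clusters.csv", "svm_report.csv", "svr_report.csv",
            "true_network_mask.nii.gz")
  miss <- need[!file.exists(file.path(outdir, need))]
  if (length(miss))
    stop("missing upstream outputs: ", paste(miss, collapse = ", "))
  cl <- tryCatch(read.csv(file.path(outdir, "clusters.csv")),
                 error = function(e) data.frame())
  contrasts <- c("DPP_vs_control", "DT_vs_control", "group_x_time")
  rows <- lapply(contrasts, function(cn) {
    sub <- if (nrow(cl)) cl[cl$contrast == cn, , drop = FALSE] else cl
    if (!NROW(sub))
      return(data.frame(contrast = cn, location = "No cluster",
                        peak_x_mm = NA, peak_y_mm = NA, peak_z_mm = NA,
                        cluster_voxels = NA, t_value = NA))
    data.frame(contrast = cn,
               location = sprintf("cluster %d", sub$cluster_id),
               peak_x_mm = sub$peak_mm_x, peak_y_mm = sub$peak_mm_y,
               peak_z_mm = sub$peak_mm_z, cluster_voxels = sub$size_voxels,
               t_value = sub$peak_stat)
  })
  cluster_report <- do.call(rbind, rows)
  write.csv(cluster_report, file.path(outdir, "report_clusters.csv"),
            row.names = FALSE)

  svm <- read.csv(file.path(outdir, "svm_report.csv"))
  write.csv(svm[, c("arm", "cluster_id", "accuracy", "sensitivity",
                    "specificity")],
            file.path(outdir, "report_classifier.csv"), row.names = FALSE)
  svr <- read.csv(file.path(outdir, "svr_report.csv"))
  write.csv(svr, file.path(outdir, "report_svr.csv"), row.names = FALSE)

  # ground-truth overlap for the synthetic run
  tm <- RNifti::readNifti(file.path(outdir, "true_network_mask.nii.gz"))
  planted <- list()
  k <- 1
  while (file.exists(file.path(outdir, sprintf("planted_cluster_%d.nii.gz",
                                               k)))) {
    planted[[k]] <- as.numeric(RNifti::readNifti(
      file.path(outdir, sprintf("planted_cluster_%d.nii.gz", k)))) > 0.5
    k <- k + 1
  }
  lab_file <- file.path(outdir, "cluster_labels_baseline.nii.gz")
  dice <- if (file.exists(lab_file) && length(planted)) {
    labs <- RNifti::readNifti(lab_file)
    labs <- array(round(as.numeric(labs)), dim(labs))
    vapply(seq_along(planted), function(k) {
      pk <- planted[[k]]
      ids <- setdiff(unique(labs[pk]), 0)
      if (!length(ids)) return(0)
      max(vapply(ids, function(i) dice_coefficient(labs == i, pk), 0))
    }, 0)
  } else rep(NA_real_, length(planted))
  overlap <- data.frame(planted_cluster = seq_along(planted),
                        dice = dice)
  write.csv(overlap, file.path(outdir, "report_overlap.csv"),
            row.names = FALSE)
  invisible(list(clusters = cluster_report, classifier = svm, svr = svr,
                 overlap = overlap))
}
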