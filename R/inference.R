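#' Stack NH maps into a subjects-by-voxels matrix
#'
#' @param maps list of `nh_map`s on the same mask.
#' @return numeric matrix, one row per map, one column per mask voxel.
#' @export
stack_nh_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  do.call(rbind, lapply(maps, nh_values))
}

#' Voxel-wise general linear model with a t contrast
#'
#' Ordinary least squares per voxel with a common design matrix;
#' `T = c'beta / se(c'beta)` with `dof = n - rank(X)`.  Covariate columns
#' should be centred (see [build_design()]).  Residual maps are returned
#' for smoothness estimation.  Within-subject (paired) contrasts are
#' handled upstream by fitting difference maps.
#'
#' @param maps list of `nh_map`s or an `n x V` matrix.
#' @param design `n x p` design matrix (including intercept).
#' @param contrast length-`p` numeric contrast vector, or the name of a
#'   design column.
#' @return a `stat_map` list: `values` (length-`V` T statistics), `dof`,
#'   `kind = "T"`, `residuals` (`n x V`), `beta`, `mask` (when the maps
#'   carried one).
#' @export
fit_voxelwise_glm <- function(maps, design, contrast) {
  mask <- NULL
  if (is.list(maps) && inherits(maps[[1]], "nh_map")) {
    mask <- maps[[1]]$mask
    Y <- stack_nh_maps(maps)
  } else Y <- as.matrix(maps)
  X <- as.matrix(design)
  if (nrow(X) != nrow(Y)) stop("design rows must align with maps")
  if (is.character(contrast)) {
    cvec <- rep(0, ncol(X))
    j <- match(contrast, colnames(X))
    if (is.na(j)) stop("unknown design column in contrast: ", contrast)
    cvec[j] <- 1
  } else cvec <- as.numeric(contrast)
  stopifnot(length(cvec) == ncol(X))
  qx <- qr(X)
  rk <- qx$rank
  if (rk < ncol(X))
    warning("rank-deficient design (rank ", rk, " of ", ncol(X),
            "); pseudoinverse used")
  beta <- qr.coef(qx, Y)
  beta[is.na(beta)] <- 0
  res <- Y - X %*% beta
  dof <- nrow(X) - rk
  if (dof < 1) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / dof
  XtXinv_c <- tryCatch(solve(crossprod(X), cvec),
                       error = function(e) qr.solve(crossprod(X), cvec))
  vc <- sum(cvec * XtXinv_c)
  se <- sqrt(pmax(sigma2 * vc, 0))
  tval <- as.vector(crossprod(beta, cvec)) / se
  tval[!is.finite(tval)] <- 0
  structure(list(values = tval, dof = dof, kind = "T",
                 residuals = res, beta = beta, mask = mask),
            class = "stat_map")
}

#' Design matrix helper with centred covariates
#'
#' Builds `[intercept | indicators | centred covariates]` from a subject
#' table.  Factor-like columns are expanded to 0/1 indicators against
#' their first level; numeric covariates are mean-centred.
#'
#' @param df data.frame of predictors (rows align with maps).
#' @param indicators character vector of indicator columns.
#' @param covariates character vector of numeric covariate columns.
#' @return numeric design matrix with named columns.
#' @export
build_design <- function(df, indicators = character(),
                         covariates = character()) {
  n <- nrow(df)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  for (v in indicators) {
    f <- factor(df[[v]])
    for (lv in levels(f)[-1]) {
      X <- cbind(X, as.numeric(f == lv))
      colnames(X)[ncol(X)] <- paste0(v, "_", lv)
    }
  }
  for (v in covariates) {
    x <- df[[v]]
    X <- cbind(X, x - mean(x))
    colnames(X)[ncol(X)] <- v
  }
  X
}

#' Group-by-time interaction on within-subject difference maps
#'
#' The repeated-measures group x time interaction is fitted as a
#' two-sample comparison of the per-subject (week8 - baseline) difference
#' maps between arms, with optional covariates; the interaction F equals
#' the squared two-sample T on a 2-level factor.
#'
#' @param baseline_maps,followup_maps lists of `nh_map`s, same subjects in
#'   the same order.
#' @param arm character vector of arm labels (2 levels), one per subject.
#' @param covariates optional data.frame of numeric covariates to centre.
#' @return a `stat_map` with `kind = "F"`, `dof = c(1, err_dof)`, plus
#'   `t_values` (the signed T) for direction.
#' @export
interaction_f <- function(baseline_maps, followup_maps, arm,
                          covariates = NULL) {
  if (length(baseline_maps) != length(followup_maps))
    stop("both timepoints must be present for every subject")
  Yb <- if (is.matrix(baseline_maps)) baseline_maps else
    stack_nh_maps(baseline_maps)
  Yf <- if (is.matrix(followup_maps)) followup_maps else
    stack_nh_maps(followup_maps)
  D <- Yf - Yb
  f <- factor(arm)
  if (nlevels(f) != 2) stop("arm must have exactly 2 levels")
  df <- data.frame(arm = f)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  X <- build_design(df, indicators = "arm",
                    covariates = setdiff(names(df), "arm"))
  cvec <- as.numeric(colnames(X) == paste0("arm_", levels(f)[2]))
  tm <- fit_voxelwise_glm(D, X, cvec)
  tm$t_values <- tm$values
  tm$values <- tm$values^2
  tm$kind <- "F"
  tm$dof <- c(1, tm$dof)
  tm
}

#' Residual-based smoothness (FWHM / resel) estimate
#'
#' Kiebel/Worsley-style estimator: residual maps are standardised per
#' voxel, the variance of their spatial first differences is pooled per
#' axis within the mask, and `FWHM_ax = sqrt(4 log 2 / lambda_ax)` in
#' voxel units.  Resels are `mask voxels / prod(FWHM in voxels)`.
#'
#' @param residuals `n x V` residual matrix over mask voxels (>= 10 maps),
#'   or a `stat_map` carrying residuals.
#' @param mask logical 3-D array with `V` `TRUE` voxels (>= 30).
#' @param voxel_size_mm isotropic voxel size.
#' @return list with `fwhm_mm` (3 values), `fwhm_vox`, `resels`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm = 3) {
  if (inherits(residuals, "stat_map")) residuals <- residuals$residuals
  if (inherits(mask, "network_mask")) mask <- mask$mask
  R <- as.matrix(residuals)
  if (nrow(R) < 10) stop("need at least 10 residual maps")
  nvox <- sum(mask)
  if (nvox < 30) stop("mask too small for smoothness estimation")
  stopifnot(ncol(R) == nvox)
  # standardise each voxel's residual series
  s <- sqrt(colSums(R^2) / nrow(R))
  s[s <= 0] <- 1
  U <- sweep(R, 2, s, "/")
  d <- dim(mask)
  idx <- array(NA_integer_, d)
  idx[mask] <- seq_len(nvox)
  lambda <- numeric(3)
  for (ax in 1:3) {
    sh <- idx
    if (ax == 1) sh <- idx[c(2:d[1], NA), , , drop = FALSE]
    if (ax == 2) sh <- idx[, c(2:d[2], NA), , drop = FALSE]
    if (ax == 3) sh <- idx[, , c(2:d[3], NA), drop = FALSE]
    a <- as.vector(idx); b <- as.vector(sh)
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 10) stop("mask has too few adjacent voxel pairs on axis ", ax)
    Dm <- U[, b[ok], drop = FALSE] - U[, a[ok], drop = FALSE]
    lambda[ax] <- mean(Dm^2)
  }
  fwhm_vox <- sqrt(4 * log(2) / lambda)
  list(fwhm_mm = fwhm_vox * voxel_size_mm, fwhm_vox = fwhm_vox,
       resels = nvox / prod(fwhm_vox))
}

#' Label connected clusters in a binary map
#'
#' Breadth-first connected-component labelling with 26-neighbour (vertex)
#' connectivity, the convention of the REST/DPABI ecosystem.
#'
#' @param bin logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per label).
#' @export
label_clusters <- function(bin, connectivity = 26) {
  stopifnot(length(dim(bin)) == 3)
  d <- dim(bin)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  labels <- array(0L, d)
  lab <- 0L
  todo <- which(bin)
  inmap <- array(FALSE, d); inmap[todo] <- TRUE
  sizes <- integer(0)
  for (v in todo) {
    if (labels[v] != 0L) next
    lab <- lab + 1L
    queue <- v
    labels[v] <- lab
    count <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      count <- count + 1L
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      ni <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
        (nb[ok, 3] - 1L) * d[1] * d[2]
      ni <- ni[inmap[ni] & labels[ni] == 0L]
      labels[ni] <- lab
      queue <- c(queue, ni)
    }
    sizes[lab] <- count
  }
  list(labels = labels, sizes = sizes)
}

# Expected-cluster GRF quantities at a (Gaussian-equivalent) threshold u:
# EC density rho3, expected cluster count Em over `resels`, expected
# suprathreshold voxel count En over `nvox`.
grf_expectations <- function(u, resels, nvox) {
  rho3 <- (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
  Em <- max(resels * rho3, .Machine$double.eps)
  En <- nvox * pnorm(-u)
  list(Em = Em, En = En)
}

# P(a cluster at threshold u has >= k voxels), stationary GRF form
# (exponential law for k^(2/3)).
grf_cluster_p_size <- function(k, Em, En) {
  beta <- (gamma(5 / 2) * Em / En)^(2 / 3)
  exp(-beta * k^(2 / 3))
}

#' GRF cluster-level correction of a statistic map
#'
#' Thresholds the map voxel-wise at `voxel_p` (two-sided inference as two
#' one-sided passes, each tail at `voxel_p`), labels 26-connected
#' clusters, and assigns each a family-wise corrected p-value from the
#' stationary Gaussian-random-field expected-cluster-count approximation
#' (`p_FWE = 1 - exp(-Em * P(size >= k))`) with the Gaussian-equivalent
#' height threshold and the estimated resel count.  Clusters with
#' `corrected_p < cluster_p` are reported.
#'
#' @param stat a `stat_map` (kind T with `dof`, or F with `dof = c(1, v)`
#'   which is converted to the signed T).
#' @param mask logical 3-D array of analysed voxels.
#' @param smoothness result of [estimate_smoothness()].
#' @param voxel_p cluster-defining (one-tail) voxel threshold.
#' @param cluster_p cluster-level significance level.
#' @param voxel_size_mm isotropic voxel size; with `affine`, used for mm
#'   peak coordinates.
#' @param affine optional 4 x 4 grid-to-mm map for peak coordinates.
#' @return a `cluster_table` data.frame (cluster_id, sign, peak grid/mm
#'   coordinates, size_voxels, peak_stat, corrected_p) with the label
#'   array and thresholds as attributes; zero rows when nothing survives.
#' @export
grf_cluster_correct <- function(stat, mask, smoothness,
                                voxel_p = 0.001, cluster_p = 0.05,
                                voxel_size_mm = 3, affine = NULL) {
  if (inherits(mask, "network_mask")) mask <- mask$mask
  if (smoothness$resels <= 0) stop("resels must be positive")
  vals <- stat$values
  if (stat$kind == "F") {
    if (is.null(stat$t_values)) stop("F map without stored signed T")
    vals <- stat$t_values
    dof <- stat$dof[2]
  } else dof <- stat$dof
  nvox <- sum(mask)
  stopifnot(length(vals) == nvox)
  tcrit <- qt(1 - voxel_p, dof)
  u <- qnorm(1 - voxel_p)  # Gaussian-equivalent height for GRF formulas
  ex <- grf_expectations(u, smoothness$resels, nvox)

  d <- dim(mask)
  labels_all <- array(0L, d)
  rows <- list()
  next_id <- 0L
  statv <- array(NA_real_, d); statv[mask] <- vals
  for (sgn in c(1, -1)) {
    bin <- array(FALSE, d)
    bin[mask] <- sgn * vals > tcrit
    if (!any(bin)) next
    lb <- label_clusters(bin, 26)
    for (k in seq_along(lb$sizes)) {
      sz <- lb$sizes[k]
      p_size <- grf_cluster_p_size(sz, ex$Em, ex$En)
      pc <- 1 - exp(-ex$Em * p_size)
      vox <- which(lb$labels == k)
      peak <- vox[which.max(sgn * statv[vox])]
      pk <- arrayInd(peak, d)
      mm <- if (!is.null(affine)) as.vector(affine %*% c(pk, 1))[1:3]
      else (pk - d / 2) * voxel_size_mm
      next_id <- next_id + 1L
      if (pc < cluster_p) labels_all[vox] <- next_id
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = next_id, sign = sgn,
        peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
        peak_mm_x = mm[1], peak_mm_y = mm[2], peak_mm_z = mm[3],
        size_voxels = sz, peak_stat = statv[peak], corrected_p = pc)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cluster_id = integer(), sign = numeric(), peak_x = integer(),
    peak_y = integer(), peak_z = integer(), peak_mm_x = numeric(),
    peak_mm_y = numeric(), peak_mm_z = numeric(), size_voxels = integer(),
    peak_stat = numeric(), corrected_p = numeric())
  keep <- tab$corrected_p < cluster_p
  out <- tab[keep, , drop = FALSE]
  attr(out, "all_clusters") <- tab
  attr(out, "labels") <- labels_all
  attr(out, "voxel_p") <- voxel_p
  attr(out, "cluster_p") <- cluster_p
  attr(out, "t_critical") <- tcrit
  attr(out, "critical_size") <- grf_critical_size(smoothness, nvox,
                                                  voxel_p, cluster_p)
  class(out) <- c("cluster_table", class(out))
  out
}

#' Smallest cluster extent significant under GRF correction
#'
#' @param smoothness result of [estimate_smoothness()].
#' @param nvox number of analysed voxels.
#' @param voxel_p,cluster_p thresholds as in [grf_cluster_correct()].
#' @return minimal cluster size (voxels) with corrected p below
#'   `cluster_p`.
#' @export
grf_critical_size <- function(smoothness, nvox, voxel_p = 0.001,
                              cluster_p = 0.05) {
  u <- qnorm(1 - voxel_p)
  ex <- grf_expectations(u, smoothness$resels, nvox)
  for (k in 1:100000) {
    pc <- 1 - exp(-ex$Em * grf_cluster_p_size(k, ex$Em, ex$En))
    if (pc < cluster_p) return(k)
  }
  Inf
}

#' Permutation null of the maximal suprathreshold cluster size
#'
#' Independent oracle for the GRF correction: permutes the rows of the
#' group-indicator column (relabelling exchangeable subjects), refits the
#' voxel-wise GLM, thresholds both tails at `voxel_p`, and records the
#' maximal 26-connected cluster size per permutation.
#'
#' @param Y `n x V` matrix of in-mask map values.
#' @param design design matrix.
#' @param contrast contrast vector or design column name.
#' @param mask logical 3-D array.
#' @param voxel_p one-tail voxel threshold.
#' @param n_perm number of permutations (values below 100 trigger a
#'   warning).
#' @param seed integer seed for the permutation stream.
#' @param perm_cols columns of the design whose rows are permuted
#'   (default: every non-intercept indicator implied by the contrast).
#' @return list with `max_sizes` (length `n_perm`), `q95` (95th
#'   percentile), `observed` (observed maximal cluster size).
#' @export
permutation_cluster_null <- function(Y, design, contrast, mask,
                                     voxel_p = 0.001, n_perm = 500L,
                                     seed = 1L, perm_cols = NULL) {
  if (n_perm < 100) warning("n_perm < 100: permutation null will be coarse")
  X <- as.matrix(design)
  if (is.character(contrast)) {
    cvec <- as.numeric(colnames(X) == contrast)
  } else cvec <- as.numeric(contrast)
  if (is.null(perm_cols)) perm_cols <- which(cvec != 0)
  d <- dim(mask)
  max_cluster <- function(tm) {
    tcrit <- qt(1 - voxel_p, tm$dof)
    mx <- 0L
    for (sgn in c(1, -1)) {
      bin <- array(FALSE, d)
      bin[mask] <- sgn * tm$values > tcrit
      if (any(bin)) mx <- max(mx, max(label_clusters(bin, 26)$sizes))
    }
    mx
  }
  obs <- max_cluster(fit_voxelwise_glm(Y, X, cvec))
  sizes <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(b) {
      Xp <- X
      pr <- sample.int(nrow(X))
      Xp[, perm_cols] <- X[pr, perm_cols, drop = FALSE]
      max_cluster(fit_voxelwise_glm(Y, Xp, cvec))
    }, 0L)
  })
  list(max_sizes = sizes, q95 = unname(quantile(sizes, 0.95, type = 1)),
       observed = obs)
}

#' Cluster-mean NH features
#'
#' Per map (subject/timepoint) and per cluster, the mean NH over the
#' cluster's voxels, in long format.
#'
#' @param maps list of `nh_map`s.
#' @param clusters a `cluster_table` from [grf_cluster_correct()] (its
#'   label array is used), or a list of logical cluster masks.
#' @return data.frame: subject_id, timepoint, cluster_id, mean_nh.
#' @export
extract_cluster_means <- function(maps, clusters) {
  masks <- if (inherits(clusters, "cluster_table")) {
    labs <- attr(clusters, "labels")
    ids <- clusters$cluster_id
    if (!length(ids)) stop("empty cluster table")
    lapply(ids, function(i) labs == i)
  } else if (is.list(clusters)) clusters else stop("unsupported clusters")
  if (!length(masks)) stop("empty cluster list")
  for (m in masks) if (!any(m)) stop("empty cluster")
  rows <- lapply(seq_along(maps), function(i) {
    nh <- maps[[i]]
    data.frame(subject_id = nh$subject_id %||% as.character(i),
               timepoint = nh$timepoint %||% "baseline",
               cluster_id = seq_along(masks),
               mean_nh = vapply(masks, function(m)
                 mean(nh$values[m]), 0))
  })
  do.call(rbind, rows)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors, `n >= 3`, finite, non-constant.
#' @return list with `r`, `p` (two-sided, from `t = r sqrt((n-2)/(1-r^2))`
#'   on `n - 2` dof), `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Pearson chi-square test on a contingency table
#'
#' `chi2 = sum (O - E)^2 / E` with `E` from the product of margins and
#' `dof = (r - 1)(c - 1)`; upper-tail p-value.  No continuity correction.
#'
#' @param table numeric matrix of counts (e.g. 2 x k sex-by-group).
#' @return list with `statistic`, `dof`, `p`, `expected`.
#' @export
chi_square_contingency <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0)) stop("counts must be non-negative")
  rs <- rowSums(O); cs <- colSums(O); n <- sum(O)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in table")
  E <- outer(rs, cs) / n
  if (any(E <= 0)) stop("expected cell counts must be positive")
  stat <- sum((O - E)^2 / E)
  dof <- as.integer((nrow(O) - 1) * (ncol(O) - 1))
  list(statistic = stat, dof = dof,
       p = pchisq(stat, dof, lower.tail = FALSE), expected = E)
}
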