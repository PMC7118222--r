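#' Group spatial ICA over concatenated runs
#'
#' Standard two-stage group ICA: each run's time series are centred and
#' reduced to a per-subject principal temporal subspace, the reduced data
#' are concatenated across runs, reduced again to a group subspace, and a
#' fixed-point (FastICA, symmetric decorrelation, tanh contrast)
#' unmixing is run over the spatial dimension.  Component maps are
#' z-scored over grid voxels; results are deterministic given `seed`.
#'
#' @param runs list of `bold_run`s (or `t x V` matrices) on a common grid.
#' @param n_components number of independent components to extract.
#' @param seed integer seed for the (orthonormalised) random unmixing
#'   initialisation.
#' @param n_subject_pcs per-run temporal principal components retained
#'   before concatenation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return list of `spatial_component` objects: `map` (3-D z-scored
#'   loadings, or a vector for matrix input), `timecourse` (concatenated
#'   back-projected group time course), `index`.
#' @export
group_ica <- function(runs, n_components = 20L, seed = 1L,
                      n_subject_pcs = 30L, max_iter = 500L, tol = 1e-7) {
  stopifnot(length(runs) >= 2, n_components >= 1)
  mats <- lapply(runs, function(r) as_run_matrix(r)$m)
  V <- ncol(mats[[1]])
  dims3 <- NULL
  r1 <- runs[[1]]
  if (inherits(r1, "bold_run")) dims3 <- dim(r1$data)[1:3]
  else if (is.array(r1) && length(dim(r1)) == 4) dims3 <- dim(r1)[1:3]
  if (any(vapply(mats, ncol, 0L) != V)) stop("runs differ in voxel count")

  reduce_rows <- function(m, k) {
    m <- m - rowMeans(m)          # centre each time point over voxels
    if (max(abs(m)) == 0) stop("degenerate (constant) data")
    k <- min(k, nrow(m) - 1L)
    e <- eigen(tcrossprod(m) / ncol(m), symmetric = TRUE)
    keep <- which(e$values > max(e$values) * 1e-10)[seq_len(k)]
    if (anyNA(keep)) keep <- which(e$values > max(e$values) * 1e-10)
    t(e$vectors[, keep, drop = FALSE]) %*% m
  }
  red <- lapply(mats, reduce_rows, k = n_subject_pcs)
  X <- do.call(rbind, red)
  if (n_components >= nrow(X))
    stop("n_components must be below the total reduced dimension")
  if (max(abs(X)) == 0) stop("degenerate (constant) data")
  # group-level reduction + whitening
  e <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)
  if (e$values[n_components] <= e$values[1] * 1e-12)
    stop("degenerate (constant) data: group subspace collapses")
  K <- diag(1 / sqrt(e$values[seq_len(n_components)])) %*%
    t(e$vectors[, seq_len(n_components), drop = FALSE])
  Z <- K %*% X                    # n_components x V, white over voxels

  W <- fastica_fixed_point(Z, seed, max_iter, tol)
  S <- W %*% Z                    # components x V spatial maps
  # back-projected concatenated time courses
  A <- t(e$vectors[, seq_len(n_components), drop = FALSE] %*%
           diag(sqrt(e$values[seq_len(n_components)])) %*% t(W))
  lapply(seq_len(n_components), function(i) {
    map <- as.vector(scale(S[i, ]))
    if (!is.null(dims3)) map <- array(map, dims3)
    structure(list(map = map, timecourse = A[i, ], index = i),
              class = "spatial_component")
  })
}

# Symmetric fixed-point ICA with tanh contrast on whitened data Z (k x V).
fastica_fixed_point <- function(Z, seed, max_iter, tol) {
  k <- nrow(Z); V <- ncol(Z)
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / V - diag(rowMeans(Gp)) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Select the component matching a network template
#'
#' Returns the component whose absolute z-map correlates best (Pearson)
#' with a binary template over the grid.
#'
#' @param components list of `spatial_component`s from [group_ica()].
#' @param template logical array/vector of the same grid.
#' @return list with `index`, `score` (the winning correlation), and
#'   `scores` for all components.
#' @export
select_network_component <- function(components, template) {
  if (!length(components)) stop("empty component list")
  tv <- as.numeric(as.logical(template))
  if (sum(tv) == 0) stop("template is empty")
  if (var(tv) == 0) stop("template covers the whole grid")
  scores <- vapply(components, function(cmp) {
    m <- abs(as.vector(cmp$map))
    if (length(m) != length(tv)) stop("template dims mismatch")
    cor(m, tv)
  }, 0)
  i <- which.max(scores)
  list(index = i, score = scores[i], scores = scores)
}

#' Threshold a component map into a network mask
#'
#' Keeps voxels whose z-scored loading exceeds `z_threshold` on the
#' positively loading side; the map's sign is first aligned so that the
#' template (when given) or the suprathreshold mass is positive.
#'
#' @param component a `spatial_component`.
#' @param z_threshold z threshold (default 1.96).
#' @param template optional binary template used to fix the sign.
#' @param min_voxels minimum surviving voxels (error below).
#' @return a `network_mask`: `mask` (logical, shape of the map),
#'   `source_component`, `z_threshold`, `n_voxels`, `n_components`
#'   (26-connected piece count).
#' @export
threshold_to_mask <- function(component, z_threshold = 1.96,
                              template = NULL, min_voxels = 30L) {
  m <- component$map
  v <- as.vector(m)
  sgn <- if (!is.null(template)) {
    s <- cor(v, as.numeric(as.logical(template)))
    if (is.na(s) || s == 0) 1 else sign(s)
  } else if (abs(min(v)) > max(v)) -1 else 1
  v <- v * sgn
  keep <- v >= z_threshold
  if (sum(keep) < min_voxels)
    stop("only ", sum(keep), " voxels survive z >= ", z_threshold)
  mask <- if (is.array(m)) array(keep, dim(m)) else keep
  ncomp <- if (is.array(m)) max(label_clusters(mask)$labels, 0) else NA_integer_
  structure(list(mask = mask, source_component = component$index,
                 z_threshold = z_threshold, n_voxels = sum(keep),
                 n_components = ncomp),
            class = "network_mask")
}

#' Derive a network mask from a cohort by group ICA
#'
#' Runs [group_ica()] on the supplied runs, selects the component best
#' matching `template`, and thresholds it into a mask.  Because a
#' network commonly decomposes into several independent components
#' (e.g. subnetworks, or regions whose coupling differs across
#' subjects), secondary components are merged into the mask when their
#' suprathreshold voxels fall predominantly inside the template:
#' a component joins the union if at least `min_precision` of its
#' `z >= z_threshold` voxels lie in the template and it has at least
#' `secondary_min_voxels` of them.
#'
#' @param runs list of `bold_run`s or `t x V` matrices (typically all
#'   baseline runs).
#' @param template binary template of the network of interest.
#' @param n_components,seed,z_threshold passed through.
#' @param min_precision in-template fraction required of a secondary
#'   component's suprathreshold voxels.
#' @param secondary_min_voxels minimal suprathreshold voxel count for a
#'   secondary component to be considered.
#' @return a `network_mask` with a `selection` report (per-component
#'   template correlation, suprathreshold precision, inclusion flag).
#' @export
derive_network_mask <- function(runs, template, n_components = 20L,
                                seed = 1L, z_threshold = 1.96,
                                min_precision = 0.5,
                                secondary_min_voxels = 10L) {
  comps <- group_ica(runs, n_components = n_components, seed = seed)
  sel <- select_network_component(comps, template)
  tv <- as.logical(template)
  report <- lapply(seq_along(comps), function(i) {
    m <- tryCatch(threshold_to_mask(comps[[i]], z_threshold = z_threshold,
                                    template = template, min_voxels = 1L),
                  error = function(e) NULL)
    n_supra <- if (is.null(m)) 0L else m$n_voxels
    prec <- if (n_supra) sum(as.vector(m$mask) & tv) / n_supra else 0
    list(index = i, score = sel$scores[i], n_suprathreshold = n_supra,
         precision = prec,
         included = i == sel$index ||
           (n_supra >= secondary_min_voxels && prec >= min_precision),
         mask = if (is.null(m)) NULL else m$mask)
  })
  keep <- vapply(report, `[[`, TRUE, "included")
  union_mask <- Reduce(`|`, lapply(report[keep], `[[`, "mask"))
  if (sum(union_mask) < 30)
    stop("only ", sum(union_mask), " voxels in the derived network mask")
  out <- threshold_to_mask(comps[[sel$index]], z_threshold = z_threshold,
                           template = template)
  out$mask <- if (is.array(out$mask)) array(union_mask, dim(out$mask))
  else union_mask
  out$n_voxels <- sum(union_mask)
  out$selection <- sel
  out$components <- lapply(report, function(r)
    r[c("index", "score", "n_suprathreshold", "precision", "included")])
  out
}
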