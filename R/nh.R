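#' Per-voxel network homogeneity
#'
#' For every voxel inside the network mask, network homogeneity (NH) is the
#' mean Pearson correlation between that voxel's time series and the series
#' of all other in-network voxels (self-correlation excluded):
#' `NH(i) = (1/(N-1)) * sum_{j != i} cor(x_i, x_j)`.
#'
#' The default `method = "fast"` uses an algebraic reformulation: with
#' column-standardised series `z_i`, the row sums of the correlation matrix
#' are `t(Z) %*% rowSums(Z) / (t - 1)`, so NH is computed in `O(N * t)`
#' without forming the `N x N` correlation matrix.  `method = "pairwise"`
#' is the literal pairwise definition, retained as the reference path; the
#' two agree to near machine precision.
#'
#' Zero-variance voxel series are handled by convention: all their pairwise
#' correlations are treated as 0 (the event is recorded in the returned
#' object's `zero_variance` field), so no `NaN` ever propagates.
#'
#' @param run a `bold_run` (see [generate_cohort()]), or a 4-D array, or a
#'   `t x N` matrix of in-mask series (in which case `mask` may be `NULL`).
#' @param mask logical 3-D array (or a `network_mask` object) selecting the
#'   in-network voxels; at least 2 voxels.
#' @param method `"fast"` (production) or `"pairwise"` (reference).
#' @param fisher_z average Fisher-z-transformed correlations instead of raw
#'   correlations (back-transformed at the end).  Default `FALSE`: the NH
#'   definition averages raw correlations.
#' @return an `nh_map` object: `values` (3-D array, `NA` off mask, or a
#'   vector when the input was a matrix), `mask`, `subject_id`, `timepoint`,
#'   `standardized = FALSE`, `zero_variance` (indices of degenerate voxels).
#' @seealso [standardize_map()]
#' @export
compute_nh <- function(run, mask = NULL, method = c("fast", "pairwise"),
                       fisher_z = FALSE) {
  method <- match.arg(method)
  if (inherits(mask, "network_mask")) mask <- mask$mask
  info <- list(subject_id = NULL, timepoint = NULL)
  if (inherits(run, "bold_run")) {
    info <- run[c("subject_id", "timepoint")]
    run <- run$data
  }
  if (is.array(run) && length(dim(run)) == 4) {
    stopifnot(!is.null(mask), all(dim(mask) == dim(run)[1:3]))
    d <- dim(run)
    m <- matrix(run, prod(d[1:3]), d[4])
    x <- t(m[as.vector(mask), , drop = FALSE])
  } else if (is.matrix(run)) {
    x <- run
  } else stop("run must be a bold_run, 4-D array, or t x N matrix")
  tN <- nrow(x); N <- ncol(x)
  if (N < 2) stop("mask must contain at least 2 voxels")
  if (tN < 3) stop("need at least 3 retained frames")

  z <- zscore_cols(x)
  zv <- attr(z, "zero_var")
  if (method == "fast") {
    s <- rowSums(z)
    rsum <- as.vector(crossprod(z, s)) / (tN - 1)  # row sums of cor matrix
    selfr <- ifelse(zv, 0, 1)
    r <- (rsum - selfr) / (N - 1)
    if (fisher_z) {
      # fast path unavailable for fisher-z averaging; fall through
      r <- nh_pairwise(z, zv, fisher_z = TRUE)
    }
  } else {
    r <- nh_pairwise(z, zv, fisher_z = fisher_z)
  }

  r <- unname(r)
  if (!is.null(mask)) {
    vals <- array(NA_real_, dim(mask))
    vals[as.vector(mask)] <- r
  } else vals <- r
  structure(list(values = vals, mask = mask,
                 subject_id = info$subject_id, timepoint = info$timepoint,
                 standardized = FALSE,
                 zero_variance = which(zv)),
            class = "nh_map")
}

# Literal pairwise-mean reference path on pre-standardised columns.
nh_pairwise <- function(z, zv, fisher_z = FALSE) {
  tN <- nrow(z); N <- ncol(z)
  R <- crossprod(z) / (tN - 1)
  R[zv, ] <- 0; R[, zv] <- 0
  diag(R) <- 0
  if (fisher_z) {
    Rc <- pmin(pmax(R, -1 + 1e-12), 1 - 1e-12)
    Z <- atanh(Rc); diag(Z) <- 0
    Z[zv, ] <- 0; Z[, zv] <- 0
    return(tanh(rowSums(Z) / (N - 1)))
  }
  rowSums(R) / (N - 1)
}

#' Standardise an NH map within its mask
#'
#' Subtracts the in-mask mean and divides by the in-mask standard deviation,
#' the conventional within-subject normalisation before voxel-wise group
#' analysis of NH maps.
#'
#' @param nh an `nh_map` from [compute_nh()].
#' @return the map with `standardized = TRUE`; error if the in-mask SD is 0.
#' @export
standardize_map <- function(nh) {
  stopifnot(inherits(nh, "nh_map"))
  v <- nh$values
  inm <- if (is.null(nh$mask)) rep(TRUE, length(v)) else as.vector(nh$mask)
  x <- v[inm]
  s <- sd(x)
  if (!is.finite(s) || s <= 0) stop("in-mask SD is zero; cannot standardise")
  v[inm] <- (x - mean(x)) / s
  nh$values <- v
  nh$standardized <- TRUE
  nh
}

#' In-mask values of an NH map as a vector
#'
#' @param nh an `nh_map`.
#' @return numeric vector of in-mask NH values, in mask voxel order.
#' @export
nh_values <- function(nh) {
  stopifnot(inherits(nh, "nh_map"))
  if (is.null(nh$mask)) return(as.vector(nh$values))
  nh$values[as.vector(nh$mask)]
}

#' @export
print.nh_map <- function(x, ...) {
  v <- nh_values(x)
  cat(sprintf(
    "<nh_map> %s/%s: %d mask voxels, mean %.4f, sd %.4f%s%s\n",
    x$subject_id %||% "?", x$timepoint %||% "?", length(v),
    mean(v), sd(v),
    if (isTRUE(x$standardized)) ", standardized" else "",
    if (length(x$zero_variance)) sprintf(", %d zero-variance voxel(s)",
                                         length(x$zero_variance)) else ""))
  invisible(x)
}
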