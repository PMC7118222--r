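#' @importFrom stats rnorm runif sd var cor pt pf pnorm qnorm qt quantile
#'   model.matrix pchisq rbinom complete.cases setNames
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stationary AR(1) noise matrix
#'
#' Draws a `t x n` matrix whose columns are independent AR(1) series with
#' stationary standard deviation `sd` and lag-1 coefficient `coef`.
#' Innovations are scaled by `sqrt(1 - coef^2)` and the first row is drawn
#' from the stationary distribution, so the marginal variance is constant
#' over time.
#'
#' @param t number of time points.
#' @param n number of series.
#' @param coef lag-1 autocorrelation, in `[0, 1)`.
#' @param sd stationary standard deviation.
#' @return numeric matrix, `t` rows by `n` columns.
#' @keywords internal
ar1_noise <- function(t, n, coef, sd = 1) {
  stopifnot(t >= 1, n >= 1, coef >= 0, coef < 1, sd >= 0)
  if (sd == 0) return(matrix(0, t, n))
  # series laid out as rows internally: column-contiguous updates over time
  x <- matrix(0, n, t)
  x[, 1] <- rnorm(n, sd = sd)
  if (t > 1) {
    e <- matrix(rnorm((t - 1) * n, sd = sd * sqrt(1 - coef^2)), n, t - 1)
    for (i in 2:t) x[, i] <- coef * x[, i - 1] + e[, i - 1]
  }
  t(x)
}

# Column-wise z-scoring with a guard for zero-variance columns: those are
# returned as all-zero and flagged in the "zero_var" attribute.
zscore_cols <- function(m) {
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  s <- sqrt(colSums(xc^2) / (nrow(m) - 1))
  zv <- s <= 0 | !is.finite(s)
  s[zv] <- 1
  z <- sweep(xc, 2, s, "/")
  z[, zv] <- 0
  attr(z, "zero_var") <- zv
  z
}

#' Separable 3-D Gaussian smoothing
#'
#' Smooths a 3-D array with an isotropic Gaussian kernel of the given full
#' width at half maximum, applied separably along each axis with renormalised
#' (zero-padded) boundaries.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_mm kernel FWHM in millimetres.
#' @param voxel_mm isotropic voxel size in millimetres.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_mm = 1) {
  stopifnot(length(dim(arr)) == 3, fwhm_mm >= 0, voxel_mm > 0)
  if (fwhm_mm == 0) return(arr)
  sigma <- fwhm_mm / voxel_mm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), d[axis])
    L <- d[axis]
    # banded convolution matrix with edge renormalisation
    K <- matrix(0, L, L)
    for (off in -half:half) {
      idx <- seq_len(L)
      j <- idx + off
      ok <- j >= 1 & j <= L
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[off + half + 1]
    }
    K <- K / rowSums(K)
    out <- K %*% m
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

# Deterministic child seed derived from a base seed and a stream label;
# stays below 2^31 - 1.
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(lab)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays (or vectors) of equal length.
#' @return Dice coefficient `2|A & B| / (|A| + |B|)`; `NA` if both are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
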