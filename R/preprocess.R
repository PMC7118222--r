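#' Drop the initial volumes of a run
#'
#' Removes the first `k` frames of a BOLD run (signal-equilibration /
#' adaptation period; `k = 10` by convention for 240-volume runs).
#'
#' @param run a `bold_run` or 4-D array or `t x V` matrix.
#' @param k number of leading frames to drop.
#' @param motion optional `motion_series` to trim in step with the run.
#' @return the trimmed run (same class as the input); if `motion` was
#'   given, a list with `run` and `motion`.
#' @export
drop_initial_volumes <- function(run, k = 10L, motion = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 0)
  nt <- run_length(run)
  if (nt <= k) stop("run has ", nt, " frames; cannot drop ", k)
  out <- subset_frames(run, (k + 1L):nt)
  if (is.null(motion)) return(out)
  m <- motion
  m$params <- m$params[(k + 1L):nt, , drop = FALSE]
  m$fd <- compute_fd(m$params)
  m$mean_fd <- mean(m$fd)
  list(run = out, motion = m)
}

run_length <- function(run) {
  if (inherits(run, "bold_run")) dim(run$data)[4]
  else if (is.matrix(run)) nrow(run)
  else dim(run)[length(dim(run))]
}

subset_frames <- function(run, idx) {
  if (inherits(run, "bold_run")) {
    run$data <- run$data[, , , idx, drop = FALSE]
    run
  } else if (is.matrix(run)) {
    run[idx, , drop = FALSE]
  } else {
    run[, , , idx, drop = FALSE]
  }
}

# t x V matrix view of a run, plus a closure to put it back.
as_run_matrix <- function(run) {
  if (inherits(run, "bold_run")) {
    d <- dim(run$data)
    m <- t(matrix(run$data, prod(d[1:3]), d[4]))
    list(m = m, restore = function(mm) {
      run$data <- array(t(mm), dim = c(d[1:3], nrow(mm)))
      run
    })
  } else if (is.matrix(run)) {
    list(m = run, restore = function(mm) mm)
  } else {
    d <- dim(run)
    m <- t(matrix(run, prod(d[1:3]), d[4]))
    list(m = m, restore = function(mm) array(t(mm), dim = c(d[1:3], nrow(mm))))
  }
}

#' Power-style framewise displacement
#'
#' `fd[i] = sum(|delta translations|) + head_radius * sum(|delta rotations|)`
#' with `fd[1] = 0`; rotations (radians) are converted to arc length on a
#' sphere of `head_radius_mm` (default 50 mm).
#'
#' @param params `t x 6` matrix: 3 translations (mm), 3 rotations (rad).
#' @param head_radius_mm sphere radius used for the rotation terms.
#' @return length-`t` non-negative vector (mm).
#' @export
compute_fd <- function(params, head_radius_mm = 50) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, nrow(params) >= 1)
  if (any(!is.finite(params))) stop("non-finite motion parameters")
  if (nrow(params) == 1) return(0)
  d <- abs(diff(params))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Motion-based subject exclusion
#'
#' A run is excluded when any frame exceeds 2 mm absolute translation on
#' any axis or 2 degrees absolute rotation on any axis.
#'
#' @param motion a `motion_series` or `t x 6` parameter matrix.
#' @param max_trans_mm,max_rot_deg exclusion thresholds.
#' @return `TRUE` if the run should be excluded.
#' @export
exclude_by_motion <- function(motion, max_trans_mm = 2, max_rot_deg = 2) {
  p <- if (inherits(motion, "motion_series")) motion$params else as.matrix(motion)
  stopifnot(nrow(p) >= 1, ncol(p) == 6)
  any(abs(p[, 1:3]) > max_trans_mm) ||
    any(abs(p[, 4:6]) * 180 / pi > max_rot_deg)
}

#' Remove a linear trend
#'
#' Least-squares removal of intercept and linear time trend; the result is
#' orthogonal to both regressors.
#'
#' @param series numeric vector (length >= 3) or `t x V` matrix (columns
#'   detrended independently).
#' @return detrended series of the same shape.
#' @export
detrend_linear <- function(series) {
  m <- if (is.matrix(series)) series else matrix(series)
  if (nrow(m) < 3) stop("need at least 3 frames to detrend")
  x <- cbind(1, seq_len(nrow(m)))
  res <- m - x %*% qr.coef(qr(x), m)
  if (is.matrix(series)) res else as.vector(res)
}

#' Temporal band-pass filter
#'
#' Frequency-domain filter with an ideal pass band and a 10% raised-cosine
#' roll-off on each edge (taper width = 10% of the pass-band width).  With
#' the default band 0.01-0.08 Hz the DC component is removed.
#'
#' @param series numeric vector or `t x V` matrix.
#' @param tr_s repetition time in seconds.
#' @param low_hz,high_hz pass-band edges; `high_hz` must be below the
#'   Nyquist frequency `1/(2 tr_s)`.
#' @return filtered series, same shape; the mean is removed when
#'   `low_hz > 0`.
#' @export
bandpass <- function(series, tr_s, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(tr_s > 0, low_hz >= 0, high_hz > low_hz)
  nyq <- 1 / (2 * tr_s)
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency ", nyq)
  m <- if (is.matrix(series)) series else matrix(series)
  nt <- nrow(m)
  f <- (seq_len(nt) - 1) / (nt * tr_s)
  f <- pmin(f, 1 / tr_s - f)  # two-sided spectrum folded to [0, nyq]
  w <- 0.1 * (high_hz - low_hz)
  H <- as.numeric(f >= low_hz & f <= high_hz)
  lo_ramp <- f > low_hz - w & f < low_hz
  H[lo_ramp] <- 0.5 * (1 + cos(pi * (low_hz - f[lo_ramp]) / w))
  hi_ramp <- f > high_hz & f < high_hz + w
  H[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - high_hz) / w))
  out <- Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / nt
  if (is.matrix(series)) out else as.vector(out)
}

#' Friston-24 motion regressor expansion
#'
#' The 6 rigid-body parameters, their one-frame lags, and the squares of
#' both: columns ordered `[p, p^2, lag(p), lag(p)^2]` per parameter.  The
#' undefined lag at the first frame is filled with 0 (any constant offset
#' is absorbed by the regression intercept).
#'
#' @param params `t x 6` motion parameter matrix.
#' @return `t x 24` matrix.
#' @export
build_friston24 <- function(params) {
  p <- as.matrix(params)
  stopifnot(ncol(p) == 6, nrow(p) >= 2)
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- matrix(0, nrow(p), 24)
  for (j in 1:6)
    out[, (j - 1) * 4 + 1:4] <- cbind(p[, j], p[, j]^2, lag[, j], lag[, j]^2)
  colnames(out) <- paste0(rep(paste0("p", 1:6), each = 4),
                          c("", "_sq", "_lag", "_lag_sq"))
  out
}

#' Assemble the default confound matrix
#'
#' Friston-24 motion expansion plus white-matter and CSF nuisance series
#' (26 columns).
#'
#' @param params `t x 6` motion parameters.
#' @param wm,csf length-`t` nuisance series.
#' @return `t x 26` labelled matrix.
#' @export
build_confounds <- function(params, wm, csf) {
  f24 <- build_friston24(params)
  stopifnot(length(wm) == nrow(f24), length(csf) == nrow(f24))
  cbind(f24, wm = wm, csf = csf)
}

#' Regress confounds out of a run
#'
#' Per voxel, returns the residual of the least-squares projection onto
#' `[intercept | confounds]`.  Rank-deficient designs are handled through
#' the QR pseudo-inverse (`NA` coefficients treated as 0), never by
#' propagating `NaN`; residuals are orthogonal to every confound column on
#' full-rank designs.
#'
#' @param run a `bold_run`, 4-D array, or `t x V` matrix.
#' @param confounds `t x k` confound matrix (no intercept column needed).
#' @return the residual run, same class as input.
#' @export
regress_confounds <- function(run, confounds) {
  rm_ <- as_run_matrix(run)
  m <- rm_$m
  X <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(X) != nrow(m)) stop("confound rows must match run frames")
  qx <- qr(X)
  beta <- qr.coef(qx, m)
  beta[is.na(beta)] <- 0
  rm_$restore(m - X %*% beta)
}

#' Scrub high-motion frames
#'
#' Removes frames whose framewise displacement exceeds `threshold_mm`
#' (default 0.2 mm).  If fewer than `min_frames` frames survive the run is
#' flagged unusable.
#'
#' @param run a `bold_run`, 4-D array, or `t x V` matrix.
#' @param fd length-`t` framewise displacement vector.
#' @param threshold_mm scrubbing threshold.
#' @param min_frames minimum retained frames for a usable run.
#' @return list with `run` (censored), `kept_mask` (logical length-`t`),
#'   `usable` (logical).
#' @export
scrub <- function(run, fd, threshold_mm = 0.2, min_frames = 20L) {
  nt <- run_length(run)
  stopifnot(length(fd) == nt)
  kept <- fd <= threshold_mm
  out <- subset_frames(run, which(kept))
  list(run = out, kept_mask = kept, usable = sum(kept) >= min_frames)
}

#' Full temporal preprocessing of one run
#'
#' Applies the fixed pipeline: drop initial volumes, (optional) motion QC
#' exclusion, linear detrend, band-pass filter, nuisance regression
#' (Friston-24 + WM + CSF; the global signal is never removed), and FD
#' scrubbing (censor-after-filter).  Re-running on identical inputs gives
#' identical output.
#'
#' @param run a `bold_run`.
#' @param motion the matching `motion_series`.
#' @param drop_k initial volumes to drop.
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param fd_threshold_mm scrubbing threshold.
#' @param max_trans_mm,max_rot_deg motion QC exclusion thresholds.
#' @param scrub_frames apply scrubbing (the censor-after-filter switch).
#' @return list with `run` (preprocessed, censored), `kept_mask`,
#'   `excluded` (motion QC verdict), `usable`, `mean_fd`.
#' @export
preprocess_run <- function(run, motion, drop_k = 10L,
                           low_hz = 0.01, high_hz = 0.08,
                           fd_threshold_mm = 0.2,
                           max_trans_mm = 2, max_rot_deg = 2,
                           scrub_frames = TRUE) {
  stopifnot(inherits(run, "bold_run"), inherits(motion, "motion_series"))
  excluded <- exclude_by_motion(motion, max_trans_mm, max_rot_deg)
  nt0 <- run_length(run)
  dr <- drop_initial_volumes(run, drop_k, motion)
  run <- dr$run; motion <- dr$motion
  keep0 <- (drop_k + 1L):nt0
  run$wm <- (run$wm %||% rep(0, nt0))[keep0]
  run$csf <- (run$csf %||% rep(0, nt0))[keep0]
  rm_ <- as_run_matrix(run)
  m <- detrend_linear(rm_$m)
  m <- bandpass(m, run$tr_s, low_hz, high_hz)
  conf <- build_confounds(motion$params, run$wm, run$csf)
  conf <- cbind(detrend_linear(conf[, 1:24, drop = FALSE]),
                wm = bandpass(detrend_linear(conf[, "wm"]), run$tr_s,
                              low_hz, high_hz),
                csf = bandpass(detrend_linear(conf[, "csf"]), run$tr_s,
                               low_hz, high_hz))
  run <- regress_confounds(rm_$restore(m), conf)
  if (scrub_frames) {
    sc <- scrub(run, motion$fd, fd_threshold_mm)
    list(run = sc$run, kept_mask = sc$kept_mask, usable = sc$usable,
         excluded = excluded, mean_fd = motion$mean_fd)
  } else {
    list(run = run, kept_mask = rep(TRUE, run_length(run)), usable = TRUE,
         excluded = excluded, mean_fd = motion$mean_fd)
  }
}
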