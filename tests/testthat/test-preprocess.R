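test_that("initial-volume dropping respects its boundary contract", {
  m <- matrix(rnorm(240 * 5), 240, 5)
  expect_equal(nrow(drop_initial_volumes(m, 10)), 230)
  expect_identical(drop_initial_volumes(m, 0), m)
  expect_equal(nrow(drop_initial_volumes(m[1:11, ], 10)), 1)
  expect_error(drop_initial_volumes(m[1:10, ], 10), "cannot drop")
})

test_that("framewise displacement matches its arithmetic definition", {
  # one-frame step of +0.1 mm on each translation axis
  p <- matrix(0, 5, 6)
  p[3, 1:3] <- 0.1
  fd <- compute_fd(p)
  expect_equal(fd[3], 0.3)
  expect_equal(fd[4], 0.3)  # stepping back down
  expect_equal(fd[1], 0)
  # 0.002 rad rotation at 50 mm radius contributes 0.1 mm
  p2 <- matrix(0, 4, 6)
  p2[2, 5] <- 0.002
  expect_equal(compute_fd(p2)[2], 0.1)
  # constant parameters give zero FD
  expect_true(all(compute_fd(matrix(1, 7, 6)) == 0))
  # brute-force frame-by-frame oracle on random inputs
  set.seed(1)
  for (r in 1:10) {
    p <- matrix(rnorm(20 * 6, sd = 0.1), 20, 6)
    expect_equal(compute_fd(p), fd_oracle(p), tolerance = 1e-12)
  }
  expect_error(compute_fd(matrix(c(NA, rnorm(11)), 2, 6)), "finite")
})

test_that("motion exclusion applies the 2 mm / 2 degree rule", {
  p <- matrix(0, 10, 6)
  expect_false(exclude_by_motion(p))
  p[4, 3] <- 2.5                      # tz = 2.5 mm
  expect_true(exclude_by_motion(p))
  p2 <- matrix(0, 10, 6)
  p2[7, 4] <- 2.5 * pi / 180          # 2.5 degrees
  expect_true(exclude_by_motion(p2))
  p2[7, 4] <- 1.5 * pi / 180
  expect_false(exclude_by_motion(p2))
})

test_that("a cohort with two spiked subjects reproduces the 41 -> 39 flow", {
  cfg <- sim_config(seed = 13, n_per_group = c(control = 20,
                                               patient_dpp = 20,
                                               patient_dt = 21))
  subj <- make_subject_table(cfg)
  pats <- subj$subject_id[subj$group == "patient"]
  expect_length(pats, 41)
  motions <- lapply(pats, function(id)
    generate_motion(cfg, paste0(id, ".baseline")))
  spiked <- c(1L, 25L)                  # one per arm
  for (k in spiked) motions[[k]]$params[100, 1] <-
      motions[[k]]$params[100, 1] + 3
  excl <- vapply(motions, exclude_by_motion, TRUE)
  expect_equal(sum(excl), 2)
  expect_equal(sum(!excl), 39)
  expect_identical(which(excl), spiked)
})

test_that("linear detrending removes exactly the linear part", {
  t_ <- 1:100
  expect_true(all(abs(detrend_linear(2 + 3 * t_)) < 1e-9))
  set.seed(2)
  noise <- rnorm(100)
  out <- detrend_linear(noise)
  expect_lt(abs(cor(out, t_)), 1e-10)
  # trend + sinusoid: residual equals the least-squares oracle
  sinus <- sin(2 * pi * t_ / 25)
  y <- 5 - 0.3 * t_ + sinus
  oracle <- stats::residuals(stats::lm(y ~ t_))
  expect_equal(detrend_linear(y), unname(oracle), tolerance = 1e-10)
  expect_error(detrend_linear(c(1, 2)), "3 frames")
})

test_that("band-pass filter keeps the band and kills the stop band", {
  tr <- 2; n <- 230
  tt <- (0:(n - 1)) * tr
  amp_ratio <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    y <- bandpass(x, tr)
    sqrt(sum(y^2) / sum(x^2))
  }
  expect_gt(amp_ratio(0.04), 0.9)     # mid-band
  expect_gt(amp_ratio(0.02), 0.9)
  expect_lt(amp_ratio(0.2), 0.1)      # >= 2x the upper edge
  expect_lt(amp_ratio(0.16), 0.1)
  expect_lt(max(abs(bandpass(rep(5, n), tr))), 1e-10)  # DC removed
  expect_error(bandpass(rnorm(n), tr, high_hz = 0.25), "Nyquist")
})

test_that("Friston-24 expansion matches a hand-built construction", {
  p0 <- matrix(0, 10, 6)
  expect_true(all(build_friston24(p0) == 0))
  pc <- matrix(rep(c(1, -2, 0.5, 0.1, -0.3, 2), each = 10), 10, 6)
  f <- build_friston24(pc)
  expect_equal(dim(f), c(10L, 24L))
  expect_equal(unname(f[2, 2]), 1)            # p1^2
  expect_equal(unname(f[1, 3]), 0)            # lag at frame 0 filled with 0
  expect_equal(unname(f[2, 3]), 1)            # lag picks up frame 1
  set.seed(3)
  p <- matrix(rnorm(15 * 6), 15, 6)
  f <- build_friston24(p)
  # explicit column-by-column oracle
  for (j in 1:6) {
    lag <- c(0, p[-15, j])
    expect_equal(f[, (j - 1) * 4 + 1], p[, j])
    expect_equal(f[, (j - 1) * 4 + 2], p[, j]^2)
    expect_equal(f[, (j - 1) * 4 + 3], lag)
    expect_equal(f[, (j - 1) * 4 + 4], lag^2)
  }
  expect_lte(qr(f)$rank, 24)
})

test_that("confound regression projects cleanly and never yields NaN", {
  set.seed(4)
  n <- 80
  conf <- matrix(rnorm(n * 3), n, 3)
  # voxel equal to a confound column vanishes
  y <- cbind(conf[, 2], rnorm(n))
  res <- regress_confounds(y, conf)
  expect_lt(max(abs(res[, 1])), 1e-10)
  # orthogonal confounds leave a series unchanged up to mean removal
  x <- rnorm(n)
  x_orth <- stats::residuals(stats::lm(x ~ conf))
  res2 <- regress_confounds(cbind(x_orth), conf)
  expect_equal(as.vector(res2), unname(x_orth), tolerance = 1e-10)
  # known mixing: signal recovered at r > 0.99
  wm <- rnorm(n)
  signal <- rnorm(n)
  y3 <- cbind(signal + 2 * wm)
  res3 <- regress_confounds(y3, cbind(wm))
  expect_gt(cor(as.vector(res3), signal), 0.99)
  # residual orthogonality to every confound column
  Y <- matrix(rnorm(n * 20), n, 20)
  R <- regress_confounds(Y, conf)
  expect_lt(max(abs(cor(R, conf))), 1e-8)
  # rank-deficient designs are handled, not NaN-propagated
  conf_dup <- cbind(conf, conf[, 1])
  Rd <- suppressWarnings(regress_confounds(Y, conf_dup))
  expect_false(any(is.na(Rd)))
})

test_that("scrubbing censors exactly the high-FD frames", {
  m <- matrix(rnorm(100 * 4), 100, 4)
  fd <- rep(0.05, 100)
  s <- scrub(m, fd)
  expect_identical(s$run, m)
  expect_true(s$usable)
  fd[c(10, 20, 30, 40, 50)] <- 0.3
  s2 <- scrub(m, fd)
  expect_equal(nrow(s2$run), 95)
  expect_equal(sum(!s2$kept_mask), 5)
  # threshold 0 keeps only frame 1 (fd = 0) and flags the run unusable
  s3 <- scrub(m, compute_fd(matrix(rnorm(600, sd = 1), 100, 6)),
              threshold_mm = 0)
  expect_equal(sum(s3$kept_mask), 1)
  expect_false(s3$usable)
})

test_that("the full temporal pipeline is idempotent in its inputs", {
  co <- tiny_cohort()
  run <- co$runs[["dpp01.baseline"]]
  mo <- co$motion[["dpp01.baseline"]]
  a <- preprocess_run(run, mo)
  b <- preprocess_run(run, mo)
  expect_identical(a$run$data, b$run$data)
  expect_equal(dim(a$run$data)[4], sum(a$kept_mask))
  expect_false(a$excluded)
})
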