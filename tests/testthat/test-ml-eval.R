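test_that("reduction ratio follows its defining arithmetic", {
  expect_equal(reduction_ratio(100, 100), 0)
  expect_equal(reduction_ratio(100, 0), 1)
  expect_equal(reduction_ratio(104.84, 46.64), 0.55513, tolerance = 1e-5)
  expect_equal(reduction_ratio(c(80, 90), c(40, 90)), c(0.5, 0))
  expect_error(reduction_ratio(0, 10), "positive")
  expect_error(reduction_ratio(-5, 1), "positive")
})

test_that("confusion metric identities hold for arbitrary counts", {
  expect_equal(unname(confusion_metrics(20, 0, 20, 0)),
               c(100, 100, 100))
  set.seed(41)
  for (r in 1:25) {
    k <- sample(0:30, 4, replace = TRUE) + c(1, 0, 1, 0)
    m <- confusion_metrics(k[1], k[2], k[3], k[4])
    expect_equal(unname(m["accuracy"]),
                 round(100 * (k[1] + k[3]) / sum(k), 2))
    expect_equal(unname(m["sensitivity"]),
                 round(100 * k[1] / (k[1] + k[2]), 2))
    expect_equal(unname(m["specificity"]),
                 round(100 * k[3] / (k[3] + k[4]), 2))
  }
  expect_error(confusion_metrics(0, 0, 3, 1), "class")
  expect_error(confusion_metrics(1.5, 1, 1, 1), "integer")
})

test_that("bonferroni threshold arithmetic", {
  expect_identical(bonferroni_threshold(0.05, 16), 0.003125)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.10, 4), 0.025)
  expect_error(bonferroni_threshold(0, 4))
})

test_that("reference linear SVM solves its analytic cases", {
  # 1-D separable {-1: 0, +1: 2}: boundary at 1, w = 1, b = -1
  m <- train_svm_primal(matrix(c(0, 2)), c(-1, 1), C = 1e6)
  expect_equal(m$w, 1, tolerance = 1e-6)
  expect_equal(m$b, -1, tolerance = 1e-6)
  expect_lt(m$kkt_gap, 1e-6)
  # KKT margin conditions at the optimum
  f <- c(0, 2) * m$w + m$b
  expect_true(all(c(-1, 1) * f >= 1 - m$slack - 1e-6))
  # scaling C by 1e6 on separable data reproduces the hard margin
  m2 <- train_svm_primal(matrix(c(0, 2)), c(-1, 1), C = 1)
  expect_equal(m2$w, m$w, tolerance = 1e-6)
  # conflicting duplicated points force slack; objective matches an
  # exhaustive 2-parameter grid minimisation
  x <- matrix(c(1, 1))
  y <- c(-1, 1)
  mc <- train_svm_primal(x, y, C = 0.5)
  grid_obj <- function(w, b)
    0.5 * w^2 + 0.5 * sum(pmax(0, 1 - y * (c(1, 1) * w + b)))
  ws <- seq(-2, 2, by = 0.01); bs <- seq(-3, 3, by = 0.01)
  best <- min(outer(ws, bs, Vectorize(grid_obj)))
  expect_equal(mc$objective, best, tolerance = 1e-3)
  expect_gt(sum(mc$slack), 0)
})

test_that("reference SVM matches a generic convex-QP oracle", {
  skip_if_not_installed("kernlab")
  set.seed(42)
  for (r in 1:20) {
    n <- sample(6:14, 1); d <- sample(1:3, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.1, 1, 10), 1)
    m <- train_svm_primal(x, y, C = C)
    # dual QP: min 1/2 a' Q a - 1' a, 0 <= a <= C, y'a = 0
    Q <- (y %*% t(y)) * tcrossprod(x)
    sol <- kernlab::ipop(c = matrix(-1, n), H = Q + diag(1e-10, n),
                         A = matrix(y, 1), b = 0, l = matrix(0, n),
                         u = matrix(C, n), r = 0)
    a <- kernlab::primal(sol)
    w <- as.vector(crossprod(x, a * y))
    f <- as.vector(x %*% w)
    bcand <- y - f
    obj <- min(vapply(bcand, function(bb)
      0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (f + bb))), 0))
    expect_lt(abs(m$objective - obj), 1e-6 * (1 + abs(obj)))
  }
})

test_that("LOO SVM separates well-separated classes and reports folds", {
  set.seed(43)
  x <- c(rnorm(20, 0, 0.5), rnorm(20, 6, 0.5))
  y <- rep(c("control", "patient"), each = 20)
  rep_ <- loo_svm_classify(x, y, grid = fast_grid(), seed = 1,
                           positive = "patient", inner_k = 3)
  expect_equal(unname(rep_$metrics), c(100, 100, 100))
  expect_equal(length(rep_$predictions), 40)
  expect_false(any(is.na(rep_$predictions)))
  expect_equal(sum(rep_$counts), 40)
  expect_error(loo_svm_classify(x, rep("a", 40)), "two classes")
})

test_that("LOO protocol is invariant to subject ordering", {
  set.seed(44)
  x <- c(rnorm(10, 0, 1), rnorm(10, 2, 1))
  y <- rep(c("control", "patient"), each = 10)
  r1 <- loo_svm_classify(x, y, grid = point_grid(), seed = 5,
                         positive = "patient")
  perm <- sample(20)
  r2 <- loo_svm_classify(x[perm], y[perm], grid = point_grid(), seed = 5,
                         positive = "patient")
  expect_identical(as.character(r1$predictions)[perm],
                   as.character(r2$predictions))
  expect_identical(r1$counts, r2$counts)
  # and seed-deterministic end to end
  r3 <- loo_svm_classify(x, y, grid = point_grid(), seed = 5,
                         positive = "patient")
  expect_identical(r1$predictions, r3$predictions)
})

test_that("label-permuted features never classify above chance", {
  # under the null, LOO accuracy is biased *downward* (a degenerate fit
  # predicts the training-fold majority, which with balanced classes is
  # always the opposite of the held-out label), so the distribution is
  # left-skewed; the property that matters is the absence of optimism
  set.seed(45)
  accs <- vapply(1:50, function(s) {
    x <- rnorm(40)
    y <- sample(rep(c("control", "patient"), each = 20))
    loo_svm_classify(x, y, grid = point_grid(), seed = s,
                     positive = "patient")$metrics[["accuracy"]]
  }, 0)
  expect_gte(mean(accs <= 65), 0.9)   # no replicate run is optimistic
  expect_lte(mean(accs), 55)          # and the average sits at/below chance
})

test_that("LOO SVR recovers a noiseless linear mapping", {
  set.seed(46)
  f <- rnorm(20)
  rr <- 0.5 + 0.1 * f
  rep_ <- loo_svr_predict(f, rr, grid = fast_grid(), seed = 1, inner_k = 3)
  expect_gt(rep_$r, 0.97)
  expect_lt(rep_$p, 1e-6)
  expect_true(rep_$significant)
  expect_identical(rep_$threshold, 0.003125)
  expect_error(loo_svr_predict(f, rep(0.5, 20)), "constant")
  # seed determinism
  rep2 <- loo_svr_predict(f, rr, grid = fast_grid(), seed = 1, inner_k = 3)
  expect_identical(rep_$predictions, rep2$predictions)
})
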