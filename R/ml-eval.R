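#' Symptomatic reduction ratio
#'
#' `RR = (baseline - week8) / baseline`, the treatment-response outcome;
#' the same formula applies to the PANSS total and to each subscale.
#'
#' @param score_baseline baseline score(s), strictly positive.
#' @param score_week8 week-8 score(s).
#' @return reduction ratio(s); 0 means no change, 1 full remission.
#' @export
reduction_ratio <- function(score_baseline, score_week8) {
  if (any(score_baseline <= 0)) stop("baseline score must be positive")
  (score_baseline - score_week8) / score_baseline
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' @param tp,fn,tn,fp non-negative integer counts; each class must be
#'   represented (`tp + fn >= 1`, `tn + fp >= 1`).
#' @return named numeric vector of percentages, rounded to 2 decimals:
#'   `accuracy = (tp+tn)/n`, `sensitivity = tp/(tp+fn)`,
#'   `specificity = tn/(tn+fp)`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (tp + fn < 1 || tn + fp < 1) stop("each class needs at least one case")
  c(accuracy = round(100 * (tp + tn) / sum(counts), 2),
    sensitivity = round(100 * tp / (tp + fn), 2),
    specificity = round(100 * tn / (tn + fp), 2))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m number of comparisons (e.g. 16 = 4 regions x 4 PANSS domains).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 16L) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Default hyperparameter grid for SVM/SVR searches
#'
#' Powers of two, the LIBSVM convention: `C` in `2^(-5..15)`, `gamma` in
#' `2^(-15..3)`.  `by` controls the exponent stride; simulation suites use
#' coarser strides for speed.
#'
#' @param c_exp,gamma_exp exponent ranges.
#' @param by exponent step.
#' @return list with `C` and `gamma` vectors.
#' @export
svm_grid <- function(c_exp = c(-5, 15), gamma_exp = c(-15, 3), by = 2) {
  list(C = 2^seq(c_exp[1], c_exp[2], by = by),
       gamma = 2^seq(gamma_exp[1], gamma_exp[2], by = by))
}

# Deterministic inner-fold assignment from a seed (stratified when labels
# are given).
make_folds <- function(n, k, seed, labels = NULL) {
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(labels)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (lv in unique(labels)) {
        i <- which(labels == lv)
        fold[i] <- sample(rep_len(seq_len(k), length(i)))
      }
    }
    fold
  })
}

# Content hash of a numeric row, so per-fold seeds depend on the held-out
# subject's data rather than its position: LOO results are then invariant
# to subject ordering.
row_key <- function(v) paste(format(v, digits = 12), collapse = ",")

# Inner grid search: mean CV error of e1071::svm over the grid, on the
# training fold only.  type: "C-classification" or "eps-regression".
# Rows are put in a canonical order before fold assignment so that the
# inner splits do not depend on the caller's subject ordering.
inner_grid_search <- function(x, y, grid, type, k = 5L, seed = 1L,
                              kernel = "radial") {
  ord <- do.call(order, c(as.list(as.data.frame(x)), list(as.numeric(y))))
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  n <- nrow(x)
  k <- min(k, n)
  labels <- if (type == "C-classification") y else NULL
  fold <- make_folds(n, k, seed, labels)
  best <- NULL; best_err <- Inf
  surface <- expand.grid(C = grid$C, gamma = grid$gamma)
  surface$cv_error <- NA_real_
  for (gi in seq_len(nrow(surface))) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f; te <- !tr
      if (type == "C-classification" &&
          length(unique(y[tr])) < 2) return(NA_real_)
      tryCatch({
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = type,
                          kernel = kernel, cost = surface$C[gi],
                          gamma = surface$gamma[gi], scale = FALSE)
        pred <- stats::predict(fit, x[te, , drop = FALSE])
        if (type == "C-classification") mean(pred != y[te])
        else mean((as.numeric(pred) - y[te])^2)
      }, error = function(e) NA_real_)  # unfittable cell (e.g. empty model)
    }, 0)
    err <- if (all(is.na(errs))) NA_real_ else mean(errs, na.rm = TRUE)
    surface$cv_error[gi] <- err
    if (is.finite(err) && err < best_err - 1e-12) {
      best_err <- err
      best <- surface[gi, c("C", "gamma")]
    }
  }
  if (is.null(best))
    best <- data.frame(C = 1, gamma = stats::median(grid$gamma))
  list(C = best$C, gamma = best$gamma, surface = surface)
}

# Fit-and-predict with a graceful fallback: if LIBSVM cannot produce a
# model (degenerate fold), predict the training majority / mean.
safe_svm_predict <- function(xtr, ytr, xte, type, C, gamma) {
  tryCatch({
    fit <- e1071::svm(xtr, ytr, type = type, kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    stats::predict(fit, xte)
  }, error = function(e) {
    if (type == "C-classification") {
      tab <- table(ytr)
      factor(rep(names(tab)[which.max(tab)], nrow(xte)),
             levels = levels(ytr))
    } else rep(mean(ytr), nrow(xte))
  })
}

#' Leave-one-out SVM classification of cluster-mean NH features
#'
#' For each fold, one subject is held out and an SVM (RBF kernel by
#' default) is trained on the rest; hyperparameters are chosen by a grid
#' search cross-validated *within the training fold only* (no leakage),
#' and features are standardised with training-fold statistics.  Pooled
#' fold predictions give the confusion counts and the accuracy /
#' sensitivity / specificity percentages; the last fold's grid surface is
#' kept for the conventional "3D view" of the parameter search.
#'
#' @param features `n x d` numeric matrix (a single cluster-mean NH
#'   column in the emulated analyses) or a vector.
#' @param labels length-`n` vector with exactly two levels; the *positive*
#'   (patient) class is taken as the first level encountered unless
#'   `positive` is given.
#' @param grid hyperparameter grid from [svm_grid()].
#' @param seed integer seed (inner-fold assignment).
#' @param positive label value treated as the positive class.
#' @param inner_k inner cross-validation folds for the grid search.
#' @return a `classifier_report`: `predictions` (per-subject), `counts`
#'   (tp/fn/tn/fp), `metrics` (percentages), `grid_surface`.
#' @export
loo_svm_classify <- function(features, labels, grid = svm_grid(),
                             seed = 1L, positive = NULL, inner_k = 5L) {
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(n >= 4, length(labels) == n)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two classes")
  positive <- positive %||% lv[1]
  y <- factor(labels, levels = c(setdiff(lv, positive), positive))
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  surface <- NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2)
      stop("a training fold lacks one of the classes")
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    sdv[sdv <= 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    gs <- inner_grid_search(xs[tr, , drop = FALSE], y[tr], grid,
                            "C-classification", k = inner_k,
                            seed = derive_seed(seed, "svm", row_key(x[i, ])))
    pred[i] <- safe_svm_predict(xs[tr, , drop = FALSE], y[tr],
                                xs[i, , drop = FALSE],
                                "C-classification", gs$C, gs$gamma)
    surface <- gs$surface
  }
  pos <- levels(y)[2]
  tp <- sum(pred == pos & y == pos); fn <- sum(pred != pos & y == pos)
  tn <- sum(pred != pos & y != pos); fp <- sum(pred == pos & y != pos)
  structure(list(predictions = pred, truth = y, positive = pos,
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 metrics = confusion_metrics(tp, fn, tn, fp),
                 grid_surface = surface),
            class = "classifier_report")
}

#' Leave-one-out SVR prediction of reduction ratios
#'
#' Epsilon-insensitive support vector regression per LOO fold with the
#' same nested grid search and training-fold standardisation as
#' [loo_svm_classify()].  The report carries the Pearson correlation
#' between pooled LOO predictions and the actual reduction ratios, with
#' its t-transform p-value and the Bonferroni threshold it is compared
#' against.  The significance test is one-sided for a positive
#' correlation: only a positive predicted-vs-actual association is
#' evidence that the features predict treatment response (under the null,
#' LOO predictions tend to be *negatively* correlated with the target,
#' which a two-sided test would spuriously reward); the two-sided p is
#' also reported.
#'
#' @param features `n x d` matrix or vector of baseline cluster-mean NH.
#' @param target_rr length-`n` reduction ratios (non-constant).
#' @param grid hyperparameter grid from [svm_grid()].
#' @param seed integer seed.
#' @param inner_k inner cross-validation folds.
#' @param alpha,m Bonferroni family parameters (defaults 0.05 / 16).
#' @return an `svr_report`: `predictions`, `r`, `p`, `significant`,
#'   `threshold`, `grid_surface`.
#' @export
loo_svr_predict <- function(features, target_rr, grid = svm_grid(),
                            seed = 1L, inner_k = 5L, alpha = 0.05, m = 16L) {
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(n >= 6, length(target_rr) == n)
  if (var(target_rr) == 0) stop("constant target")
  pred <- numeric(n)
  surface <- NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    sdv[sdv <= 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    # standardise the target with training-fold statistics too, so the
    # epsilon tube is scale-free; predictions are mapped back afterwards
    ymu <- mean(target_rr[tr]); ysd <- sd(target_rr[tr])
    if (!is.finite(ysd) || ysd <= 0) ysd <- 1
    ys <- (target_rr - ymu) / ysd
    gs <- inner_grid_search(xs[tr, , drop = FALSE], ys[tr], grid,
                            "eps-regression", k = inner_k,
                            seed = derive_seed(seed, "svr", row_key(x[i, ])))
    pred[i] <- as.numeric(safe_svm_predict(xs[tr, , drop = FALSE], ys[tr],
                                           xs[i, , drop = FALSE],
                                           "eps-regression",
                                           gs$C, gs$gamma)) * ysd + ymu
    surface <- gs$surface
  }
  ct <- pearson_corr(pred, target_rr)
  # prediction succeeds only through a *positive* predicted-vs-actual
  # correlation, so significance is one-sided: under the null, LOO
  # predictions are typically anti-correlated with the target and a
  # two-sided test would flag that artifact as success
  tstat <- ct$r * sqrt((n - 2) / max(1 - ct$r^2, .Machine$double.eps))
  p_pos <- pt(tstat, n - 2, lower.tail = FALSE)
  thr <- bonferroni_threshold(alpha, m)
  structure(list(predictions = pred, actual = target_rr,
                 r = ct$r, p = p_pos, p_two_sided = ct$p, threshold = thr,
                 significant = p_pos < thr, grid_surface = surface),
            class = "svr_report")
}

#' Linear soft-margin SVM by dual coordinate optimisation (reference)
#'
#' Solves `min_(w,b) 0.5 ||w||^2 + C sum_i xi_i` subject to
#' `y_i (x_i . w + b) >= 1 - xi_i`, `xi_i >= 0` -- equivalently hinge loss
#' with an l2 penalty (`lambda' <-> 1/C` scaling) -- via SMO-style
#' two-variable updates on the dual.  Intended as the transparent
#' reference implementation for small problems; the production LOO paths
#' use LIBSVM through e1071 and are checked against this and against a
#' generic convex-QP solution in the tests.
#'
#' @param features `n x d` matrix or vector.
#' @param labels length-`n` vector coercible to -1/+1 (two classes).
#' @param C soft-margin penalty.
#' @param max_passes,tol optimisation controls; KKT conditions are
#'   enforced to `tol` at the reported optimum.
#' @return an `svm_model`: `w`, `b`, `alpha`, `slack`, `objective`
#'   (primal value), `dual_objective`, `converged`.
#' @export
train_svm_primal <- function(features, labels, C = 1,
                             max_passes = 200000L, tol = 1e-9) {
  x <- as.matrix(features)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("need exactly two classes")
  y <- ifelse(labels == lv[2], 1, -1)
  n <- nrow(x)
  K <- tcrossprod(x)
  a <- numeric(n)
  grad <- rep(-1, n)                  # gradient of dual objective wrt alpha
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    yg <- -y * grad                   # KKT scores
    up <- (y > 0 & a < C - 0) | (y < 0 & a > 0)
    lo <- (y > 0 & a > 0) | (y < 0 & a < C)
    if (!any(up) || !any(lo)) { converged <- TRUE; break }
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol) { converged <- TRUE; break }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    step <- (yg[i] - yg[j]) / eta
    step <- min(step,
                if (y[i] > 0) C - a[i] else a[i],
                if (y[j] > 0) a[j] else C - a[j])
    a[i] <- a[i] + y[i] * step
    a[j] <- a[j] - y[j] * step
    grad <- grad + step * y * (K[, i] - K[, j])
  }
  if (!converged)
    stop("SMO did not converge within the iteration budget (final KKT gap ",
         format(max(0, diff(range(-y * grad)))), ")")
  w <- as.vector(crossprod(x, a * y))
  # exact bias: the primal objective is convex piecewise-linear in b, so
  # its minimum over b sits at one of the hinge kinks y_i - x_i.w
  f <- as.vector(x %*% w)
  cand <- y - f
  obj_b <- vapply(cand, function(bb)
    C * sum(pmax(0, 1 - y * (f + bb))), 0)
  b <- cand[which.min(obj_b)]
  slack <- pmax(0, 1 - y * (f + b))
  objective <- 0.5 * sum(w^2) + C * sum(slack)
  dual <- sum(a) - 0.5 * sum((a * y) * (K %*% (a * y)))
  structure(list(w = w, b = b, alpha = a, slack = slack,
                 objective = objective, dual_objective = dual,
                 converged = converged, kkt_gap = objective - dual,
                 C = C, levels = lv),
            class = "svm_model")
}

#' Predict with a reference linear SVM model
#'
#' @param object an `svm_model` from [train_svm_primal()].
#' @param newdata matrix or vector of features.
#' @param ... unused.
#' @return factor of predicted labels (original level values).
#' @export
predict.svm_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  f <- as.vector(x %*% object$w + object$b)
  ifelse(f >= 0, object$levels[2], object$levels[1])
}
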