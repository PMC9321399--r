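#' Solver and path settings for the elastic-net learner
#'
#' The penalty follows the glmnet convention: per-observation averaged
#' logistic log-likelihood plus `lambda * sum((1 - alpha)/2 * beta^2 +
#' alpha * |beta|)`, with an unpenalised intercept, so `alpha = 0.9` means
#' 90% lasso / 10% ridge. Features are expected to be standardised upstream;
#' the learner's internal standardisation is disabled to avoid double
#' scaling.
#'
#' @param thresh coordinate-descent convergence threshold (default 1e-7).
#' @param maxit maximum number of passes (default 1e5).
#' @param nlambda number of points on the log-spaced lambda path (default 100).
#' @param lambda_min_ratio smallest path lambda as a fraction of `lambda_max`
#'   (default 1e-4).
#' @return a list of settings.
#' @export
enet_control <- function(thresh = 1e-7, maxit = 1e5, nlambda = 100L,
                         lambda_min_ratio = 1e-4) {
  list(thresh = thresh, maxit = maxit, nlambda = as.integer(nlambda),
       lambda_min_ratio = lambda_min_ratio)
}

#' Smallest lambda with an all-zero elastic-net solution
#'
#' @param X standardised feature matrix.
#' @param y binary 0/1 labels.
#' @param alpha elastic-net mixing parameter.
#' @return `lambda_max = max |X'(y - mean(y))| / (n * max(alpha, 1e-3))`.
#' @export
lambda_max <- function(X, y, alpha = 0.9) {
  n <- nrow(X)
  max(abs(crossprod(X, y - mean(y)))) / (n * max(alpha, 1e-3))
}

# glmnet requires >= 2 columns; pad single-feature designs with an all-zero
# dummy whose coefficient is exactly zero under any penalty.
pad_design <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `..pad` = 0)
}

check_design <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) stopf("'X' must be a numeric matrix")
  if (any(!is.finite(X))) stopf("'X' contains non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  assert_binary_labels(y)
  if (nrow(X) != length(y)) stopf("nrow(X) != length(y)")
  X
}

#' Fit a penalized logistic regression at a fixed penalty
#'
#' Elastic-net logistic regression solved by cyclic coordinate descent
#' (via glmnet) along a warm-started path that terminates exactly at the
#' requested `lambda`, so the returned coefficients carry the solver's exact
#' zeros.
#'
#' @param X column-standardised numeric matrix (no internal re-scaling).
#' @param y binary 0/1 labels with both classes present.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.9).
#' @param lambda penalty weight, `>= 0`.
#' @param control an [enet_control()].
#' @return object of class `enet_fit`: `intercept`, named `beta`, `alpha`,
#'   `lambda`, `features`, `converged`.
#' @export
fit_enet_logistic <- function(X, y, alpha = 0.9, lambda,
                              control = enet_control()) {
  X <- check_design(X, y)
  y <- as.numeric(y)
  if (lambda < 0) stopf("'lambda' must be >= 0")
  lmax <- lambda_max(X, y, alpha)
  if (alpha > 0 && lambda >= lmax * (1 - 1e-12)) {
    # full shrinkage has a closed form; at the exact lambda_max boundary the
    # solver's soft threshold sits on an equality and leaves float dust
    return(structure(list(intercept = stats::qlogis(mean(y)),
                          beta = stats::setNames(rep(0, ncol(X)), colnames(X)),
                          alpha = alpha, lambda = lambda,
                          features = colnames(X), converged = TRUE),
                     class = "enet_fit"))
  }
  lo <- max(lmax * control$lambda_min_ratio, .Machine$double.eps)
  path <- exp(seq(log(lmax), log(lo), length.out = control$nlambda))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  path <- path[path >= lambda]           # stop the path at the target
  if (lambda == 0) path <- c(path, 0)
  fit <- glmnet::glmnet(pad_design(X), y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = control$thresh, maxit = control$maxit)
  i <- which(abs(fit$lambda - lambda) < 1e-12)[1L]
  if (is.na(i)) i <- which.min(abs(fit$lambda - lambda))
  beta <- as.numeric(fit$beta[, i])
  names(beta) <- rownames(fit$beta)
  beta <- beta[colnames(X)]
  structure(list(intercept = as.numeric(fit$a0[i]), beta = beta,
                 alpha = alpha, lambda = lambda, features = colnames(X),
                 converged = fit$jerr == 0),
            class = "enet_fit")
}

#' Linear predictor of an elastic-net fit
#' @param fit an `enet_fit` (or any object with `beta` and `intercept`).
#' @param X matrix with the fit's features as columns.
#' @return numeric vector of scores `X beta + b`.
#' @export
enet_score <- function(fit, X) {
  drop(X[, names(fit$beta), drop = FALSE] %*% fit$beta) + fit$intercept
}

#' Features with exactly nonzero coefficients
#' @param fit an `enet_fit`.
#' @return character vector of feature ids with `beta != 0`.
#' @export
nonzero_features <- function(fit) {
  names(fit$beta)[fit$beta != 0]
}

#' Stratified cross-validation fold assignment
#'
#' Assigns fold ids 1..k so that each class is spread as evenly as possible
#' across folds. Uses the current RNG stream.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @return integer vector of fold ids.
#' @export
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

# Mean per-fold AUC at every lambda from a prevalidated prediction matrix.
# Falls back to pooled AUC when folds are too small to carry both classes.
fold_mean_auc <- function(preval, y, foldid) {
  folds <- sort(unique(foldid))
  ok <- vapply(folds, function(f) {
    yy <- y[foldid == f]
    sum(yy == 1) >= 1 && sum(yy == 0) >= 1
  }, logical(1))
  if (!all(ok)) {
    return(apply(preval, 2L, function(p) roc_auc(p, y)))
  }
  per_fold <- vapply(folds, function(f) {
    sel <- foldid == f
    apply(preval[sel, , drop = FALSE], 2L, function(p) roc_auc(p, y[sel]))
  }, numeric(ncol(preval)))
  if (is.null(dim(per_fold))) per_fold <- matrix(per_fold, nrow = 1L)
  rowMeans(per_fold)
}

#' Tune the elastic-net penalty by stratified k-fold cross-validation
#'
#' Fits the lambda path on each training fold, collects out-of-fold linear
#' predictors, and picks the lambda maximising the mean per-fold AUC
#' (`criterion = "auc"`, the default) or minimising the cross-validated
#' binomial deviance. With `lambda_rule = "1se"` the most regularised lambda
#' within one standard error of the optimum is taken instead. The model is
#' then refit on all of `(X, y)` at the selected lambda.
#'
#' Folds are stratified by class; every training set must contain both
#' classes. When folds are too small for a within-fold AUC (e.g.
#' leave-one-out), the AUC is pooled across folds instead of averaged.
#'
#' @inheritParams fit_enet_logistic
#' @param n_folds number of folds (default 10).
#' @param criterion `"auc"` (default) or `"deviance"`.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param foldid optional integer fold assignment; when `NULL`, stratified
#'   folds are drawn from the current RNG stream.
#' @return object of class `enet_cv`: `lambda`, `fit` (the refit
#'   [fit_enet_logistic()] at `lambda`), `cv` (data.frame of `lambda` and the
#'   criterion curve), `criterion`, `foldid`.
#' @export
tune_lambda_cv <- function(X, y, alpha = 0.9, n_folds = 10L,
                           criterion = c("auc", "deviance"),
                           lambda_rule = c("min", "1se"),
                           control = enet_control(), foldid = NULL) {
  criterion <- match.arg(criterion)
  lambda_rule <- match.arg(lambda_rule)
  X <- check_design(X, y)
  y <- as.numeric(y)
  n <- length(y)
  if (n < n_folds) stopf("n_folds (%d) exceeds sample size (%d)", n_folds, n)
  if (is.null(foldid)) foldid <- stratified_folds(y, n_folds)
  for (f in sort(unique(foldid))) {
    if (length(unique(y[foldid != f])) < 2L) {
      stopf("training set of fold %d contains a single class", f)
    }
  }
  cvfit <- suppressWarnings(glmnet::cv.glmnet(
    pad_design(X), y, family = "binomial", alpha = alpha, foldid = foldid,
    type.measure = "deviance", keep = TRUE, standardize = FALSE,
    thresh = control$thresh, maxit = control$maxit,
    nlambda = control$nlambda, lambda.min.ratio = control$lambda_min_ratio))
  lam <- cvfit$lambda
  preval <- cvfit$fit.preval[, seq_along(lam), drop = FALSE]
  if (criterion == "auc") {
    curve <- fold_mean_auc(preval, y, foldid)
    best <- which(curve == max(curve))[1L]  # lambdas decreasing: tie -> larger
    if (lambda_rule == "1se") {
      folds <- sort(unique(foldid))
      per_fold <- try(vapply(folds, function(f) {
        sel <- foldid == f
        roc_auc(preval[sel, best], y[sel])
      }, numeric(1)), silent = TRUE)
      se <- if (inherits(per_fold, "try-error")) 0 else
        stats::sd(per_fold) / sqrt(length(folds))
      best <- which(curve >= max(curve) - se)[1L]
    }
  } else {
    curve <- cvfit$cvm
    best <- if (lambda_rule == "1se") which(lam == cvfit$lambda.1se)[1L]
            else which(lam == cvfit$lambda.min)[1L]
  }
  lambda_star <- lam[best]
  refit <- fit_enet_logistic(X, y, alpha = alpha, lambda = lambda_star,
                             control = control)
  structure(list(lambda = lambda_star, fit = refit,
                 cv = data.frame(lambda = lam, criterion = curve),
                 criterion = criterion, foldid = foldid),
            class = "enet_cv")
}
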