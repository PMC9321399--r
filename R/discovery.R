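#' Resampling-based feature importance
#'
#' Runs `n_sim` simulations. In each, the cohort is split into stratified
#' train/test parts (`train_frac` to train), an elastic-net logistic model
#' (alpha = 0.9 by default) is tuned by inner k-fold lambda cross-validation
#' and fit on the training part, and its AUC is measured on the held-out
#' part. When that test AUC is strictly above 0.5 (better than random), the
#' model's nonzero features are appended to a feature list. A feature's
#' importance is its frequency in that list, i.e. occurrence count divided by
#' `n_sim`.
#'
#' @param X standardised feature matrix (clinical covariates included if they
#'   should compete for selection).
#' @param y binary 0/1 response labels.
#' @param n_sim number of simulations (default 500).
#' @param train_frac training fraction per split (default 0.8).
#' @param seed RNG seed (default 200). Determinism holds within one build of
#'   the package; the seed does not reproduce other implementations' draws.
#' @param alpha elastic-net mixing parameter (default 0.9).
#' @param n_folds inner lambda-CV folds (default 10).
#' @param control an [enet_control()].
#' @return object of class `feature_importance`: data.frame `importance`
#'   (feature, frequency, mean_coef — the mean coefficient across gated
#'   models, used only for tie-breaking), plus `n_sim`, `n_gated`, `seed`.
#' @export
feature_importance <- function(X, y, n_sim = 500L, train_frac = 0.8,
                               seed = 200L, alpha = 0.9, n_folds = 10L,
                               control = enet_control()) {
  X <- check_design(X, y)
  y <- as.numeric(y)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  coef_sum <- counts
  n_gated <- 0L
  with_preserved_seed(seed, {
    for (s in seq_len(n_sim)) {
      idx1 <- which(y == 1)
      idx0 <- which(y == 0)
      # stratified split; clamp so both classes appear on both sides
      n_tr1 <- min(max(round(train_frac * length(idx1)), 1L), length(idx1) - 1L)
      n_tr0 <- min(max(round(train_frac * length(idx0)), 1L), length(idx0) - 1L)
      tr <- c(sample(idx1, n_tr1), sample(idx0, n_tr0))
      te <- setdiff(seq_along(y), tr)
      cv <- tune_lambda_cv(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                           n_folds = n_folds, control = control)
      auc <- roc_auc(enet_score(cv$fit, X[te, , drop = FALSE]), y[te])
      if (auc > 0.5) {
        n_gated <- n_gated + 1L
        nz <- nonzero_features(cv$fit)
        counts[nz] <- counts[nz] + 1
        coef_sum[nz] <- coef_sum[nz] + cv$fit$beta[nz]
      }
    }
  })
  imp <- data.frame(feature = names(counts),
                    frequency = unname(counts) / n_sim,
                    mean_coef = ifelse(counts > 0, unname(coef_sum / pmax(counts, 1)), 0),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$frequency, -abs(imp$mean_coef), imp$feature), ]
  rownames(imp) <- NULL
  structure(list(importance = imp, n_sim = as.integer(n_sim),
                 n_gated = n_gated, seed = seed),
            class = "feature_importance")
}

#' @export
print.feature_importance <- function(x, ...) {
  cat(sprintf("<feature_importance> %d simulations, %d passed the AUC gate\n",
              x$n_sim, x$n_gated))
  print(utils::head(x$importance, 10L))
  invisible(x)
}

# Proteins ordered by decreasing selection frequency; ties broken by
# decreasing |mean coefficient across gated models|, then feature id.
ranked_proteins <- function(fi, protein_ids) {
  imp <- fi$importance[fi$importance$feature %in% protein_ids, ]
  imp$feature[order(-imp$frequency, -abs(imp$mean_coef), imp$feature)]
}

#' Stepwise model-size evaluation under nested cross-validation
#'
#' Evaluates models of growing size under 5-fold (by default) outer
#' cross-validation: the base model holds the clinical covariates only
#' (gender and baseline DAS), then proteins are added one by one in
#' decreasing feature-importance order. For each size k and each outer fold,
#' the penalty is tuned by inner k-fold lambda CV on the outer-training set
#' alone, the model is refit there, and AUC is recorded on both the
#' outer-training and the held-out outer-test set.
#'
#' @param X_clinical standardised clinical covariate matrix (always included).
#' @param X_proteins standardised protein matrix (candidates).
#' @param y binary 0/1 labels.
#' @param fi a [feature_importance()] computed on the same feature universe.
#' @param k_max largest number of proteins to include (default 30; clamped to
#'   the number of available proteins with a warning).
#' @param outer_folds number of outer folds (default 5).
#' @param inner_folds number of inner lambda-CV folds (default 10).
#' @param alpha elastic-net mixing parameter (default 0.9).
#' @param seed RNG seed for the fold draws.
#' @param control an [enet_control()].
#' @return object of class `nested_cv_curve`: data.frame `curve` (`k`,
#'   `mean_train_auc`, `mean_test_auc`), `protein_order`, `foldid`,
#'   `fold_detail` (per-(k, fold) AUCs), `seed`.
#' @export
stepwise_nested_cv <- function(X_clinical, X_proteins, y, fi, k_max = 30L,
                               outer_folds = 5L, inner_folds = 10L,
                               alpha = 0.9, seed = NULL,
                               control = enet_control()) {
  stopifnot(inherits(fi, "feature_importance"))
  X_clinical <- check_design(X_clinical, y)
  X_proteins <- check_design(X_proteins, y)
  y <- as.numeric(y)
  order_all <- ranked_proteins(fi, colnames(X_proteins))
  if (k_max > length(order_all)) {
    warnf("k_max = %d exceeds available proteins (%d); clamping",
          k_max, length(order_all))
    k_max <- length(order_all)
  }
  with_preserved_seed(seed, {
    foldid <- stratified_folds(y, outer_folds)
    detail <- vector("list", (k_max + 1L) * outer_folds)
    row <- 0L
    for (k in 0:k_max) {
      feats <- order_all[seq_len(k)]
      Xk <- cbind(X_clinical, X_proteins[, feats, drop = FALSE])
      for (f in seq_len(outer_folds)) {
        tr <- foldid != f
        inner_foldid <- stratified_folds(y[tr], inner_folds)
        cv <- tune_lambda_cv(Xk[tr, , drop = FALSE], y[tr], alpha = alpha,
                             n_folds = inner_folds, control = control,
                             foldid = inner_foldid)
        s_tr <- enet_score(cv$fit, Xk[tr, , drop = FALSE])
        s_te <- enet_score(cv$fit, Xk[!tr, , drop = FALSE])
        row <- row + 1L
        detail[[row]] <- data.frame(
          k = k, fold = f, lambda = cv$lambda,
          train_auc = roc_auc(s_tr, y[tr]),
          test_auc = roc_auc(s_te, y[!tr]))
      }
    }
    detail <- do.call(rbind, detail)
    curve <- do.call(rbind, lapply(split(detail, detail$k), function(d) {
      data.frame(k = d$k[1L], mean_train_auc = mean(d$train_auc),
                 mean_test_auc = mean(d$test_auc))
    }))
    curve <- curve[order(curve$k), ]
    rownames(curve) <- NULL
    structure(list(curve = curve, protein_order = order_all, foldid = foldid,
                   fold_detail = detail, seed = seed),
              class = "nested_cv_curve")
  })
}

#' @export
print.nested_cv_curve <- function(x, ...) {
  cat(sprintf("<nested_cv_curve> k = 0..%d, %d outer folds\n",
              max(x$curve$k), length(unique(x$fold_detail$fold))))
  print(x$curve)
  invisible(x)
}

#' Select the model size from a nested-CV curve
#'
#' Default rule: among sizes k whose mean training AUC did not decrease
#' relative to size k - 1, pick the smallest k maximising the mean test AUC
#' ("highest test-set AUC without a decrease in training-set AUC").
#' `rule = "argmax"` ignores the training constraint.
#'
#' @param curve a [stepwise_nested_cv()] result.
#' @param rule `"no_train_decrease"` (default) or `"argmax"`.
#' @return the selected number of proteins `k*`.
#' @export
select_k <- function(curve, rule = c("no_train_decrease", "argmax")) {
  rule <- match.arg(rule)
  cv <- curve$curve
  if (nrow(cv) == 0L) stopf("empty curve")
  eligible <- if (rule == "argmax") rep(TRUE, nrow(cv)) else
    c(TRUE, diff(cv$mean_train_auc) >= 0)
  cand <- cv[eligible, ]
  cand$k[which.max(cand$mean_test_auc)]  # which.max takes the smallest tie
}

#' Fit the final full-cohort model
#'
#' Refits the elastic net on the whole cohort at a lambda tuned by k-fold CV,
#' using the selected features, and sets the decision threshold at the Youden
#' best point of the full-cohort score ROC.
#'
#' @param X standardised feature matrix containing every selected feature.
#' @param y binary 0/1 labels.
#' @param features character vector of selected feature ids.
#' @param alpha elastic-net mixing parameter (default 0.9).
#' @param n_folds lambda-CV folds (default 10).
#' @param ref a [reference_stats()] for the features (carried along so new
#'   patients can be standardised identically); optional.
#' @param seed RNG seed for the CV fold draw.
#' @param control an [enet_control()].
#' @return object of class `final_model`: `features`, `beta`, `intercept`,
#'   `threshold`, `alpha`, `lambda`, `ref`, `seed`.
#' @export
fit_final <- function(X, y, features, alpha = 0.9, n_folds = 10L,
                      ref = NULL, seed = NULL, control = enet_control()) {
  X <- check_design(X, y)
  missing <- setdiff(features, colnames(X))
  if (length(missing)) {
    stopf("selected feature(s) not in X: %s", paste(missing, collapse = ", "))
  }
  Xs <- X[, features, drop = FALSE]
  with_preserved_seed(seed, {
    cv <- tune_lambda_cv(Xs, y, alpha = alpha, n_folds = n_folds,
                         control = control)
    if (!cv$fit$converged) stopf("elastic-net solver did not converge")
    scores <- enet_score(cv$fit, Xs)
    best <- youden_best_point(roc_curve(scores, y))
    structure(list(features = features, beta = cv$fit$beta,
                   intercept = cv$fit$intercept, threshold = best$threshold,
                   alpha = alpha, lambda = cv$lambda, ref = ref, seed = seed),
              class = "final_model")
  })
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("<final_model> %d features, intercept %.4f, threshold %.4f\n",
              length(x$features), x$intercept, x$threshold))
  invisible(x)
}

#' Serialise / load a final model as JSON
#'
#' The JSON file stores feature ids, coefficients, intercept, mixing
#' parameter, penalty, decision threshold and (when present) the reference
#' standardisation statistics, and round-trips losslessly.
#'
#' @param model a `final_model`.
#' @param path file path.
#' @return `read_model` returns a `final_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "final_model"))
  obj <- list(features = model$features,
              beta = as.list(model$beta),
              intercept = model$intercept,
              threshold = model$threshold,
              alpha = model$alpha, lambda = model$lambda,
              seed = model$seed)
  if (!is.null(model$ref)) {
    obj$reference <- list(feature = model$ref$feature, mean = model$ref$mean,
                          sd = model$ref$sd, n = attr(model$ref, "n"))
  }
  # digits = I(17): significant digits, enough for a lossless double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- NULL
  if (!is.null(obj$reference)) {
    ref <- reference_stats(obj$reference$feature, obj$reference$mean,
                           obj$reference$sd, n = obj$reference$n %||% NA_integer_)
  }
  structure(list(features = obj$features,
                 beta = stats::setNames(as.numeric(obj$beta), names(obj$beta)),
                 intercept = obj$intercept, threshold = obj$threshold,
                 alpha = obj$alpha, lambda = obj$lambda, ref = ref,
                 seed = obj$seed),
            class = "final_model")
}
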