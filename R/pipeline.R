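#' Run the full discovery pipeline on a cohort
#'
#' Preprocesses the NPX matrix (QC, below-LoD masking, k-NN imputation,
#' standardisation), builds the feature universe (standardised proteins plus
#' raw gender and standardised baseline DAS), computes resampling feature
#' importance, evaluates stepwise model sizes under nested cross-validation,
#' selects the model size, and fits the final full-cohort model with a
#' Youden-index decision threshold.
#'
#' @param ds an [npx_dataset()].
#' @param clinical a `clinical_table`; `patient_id` must match the dataset's
#'   sample ids.
#' @param n_sim number of feature-importance simulations (default 500).
#' @param k_max largest model size to evaluate (default 30).
#' @param alpha elastic-net mixing parameter (default 0.9).
#' @param seed base RNG seed (default 200); the stepwise and final stages use
#'   `seed + 1` and `seed + 2`.
#' @param outer_folds,inner_folds nested-CV fold counts (defaults 5 and 10).
#' @param impute_k neighbours for k-NN imputation (default 5).
#' @param control an [enet_control()].
#' @return list with `fi` ([feature_importance()]), `curve`
#'   ([stepwise_nested_cv()]), `k` (selected size), `model` (`final_model`),
#'   `ref` (cohort [reference_stats()] incl. `baseline_das`).
#' @export
run_discovery <- function(ds, clinical, n_sim = 500L, k_max = 30L,
                          alpha = 0.9, seed = 200L, outer_folds = 5L,
                          inner_folds = 10L, impute_k = 5L,
                          control = enet_control()) {
  stopifnot(inherits(ds, "npx_dataset"))
  ids <- npx_samples(ds)
  idx <- match(ids, clinical$patient_id)
  if (anyNA(idx)) stopf("sample id(s) missing from the clinical table")
  clinical <- clinical[idx, , drop = FALSE]
  y <- as.numeric(clinical$response)

  prep <- preprocess_npx(ds, k = impute_k)
  X_prot <- prep$z
  das <- as.numeric(clinical$baseline_das)
  das_mu <- mean(das); das_sd <- stats::sd(das)
  if (das_sd == 0) stopf("baseline DAS has zero variance")
  X_clin <- cbind(gender = as.numeric(clinical$gender),
                  baseline_das = (das - das_mu) / das_sd)
  rownames(X_clin) <- ids
  ref <- reference_stats(c(prep$ref$feature, "baseline_das"),
                         c(prep$ref$mean, das_mu), c(prep$ref$sd, das_sd),
                         n = length(ids))

  fi <- feature_importance(cbind(X_clin, X_prot), y, n_sim = n_sim,
                           seed = seed, alpha = alpha,
                           n_folds = inner_folds, control = control)
  curve <- stepwise_nested_cv(X_clin, X_prot, y, fi, k_max = k_max,
                              outer_folds = outer_folds,
                              inner_folds = inner_folds, alpha = alpha,
                              seed = seed + 1L, control = control)
  k <- select_k(curve)
  features <- c("gender", "baseline_das",
                curve$protein_order[seq_len(k)])
  model <- fit_final(cbind(X_clin, X_prot), y, features, alpha = alpha,
                     n_folds = inner_folds,
                     ref = ref[ref$feature %in% setdiff(features, "gender"), ],
                     seed = seed + 2L, control = control)
  list(fi = fi, curve = curve, k = k, model = model, ref = ref)
}

#' Score a new patient with a discovered model
#'
#' Standardises the patient's raw continuous features with the model's
#' reference statistics (gender stays raw 0/1), evaluates the linear score
#' and maps it through the logistic at the model's threshold.
#'
#' @param input patient file path (template `feature_id,value`) or named
#'   numeric vector of raw values.
#' @param model a `final_model` from [run_discovery()]/[fit_final()] with
#'   reference statistics attached.
#' @return a `prediction_result`.
#' @export
predict_with_model <- function(input, model) {
  stopifnot(inherits(model, "final_model"))
  if (is.null(model$ref)) stopf("model carries no reference statistics")
  raw <- if (is.character(input) && length(input) == 1L) read_patient_file(input)
         else input
  cont_feats <- intersect(model$features, model$ref$feature)
  ref <- model$ref[model$ref$feature %in% cont_feats, ]
  class(ref) <- class(model$ref)
  z <- standardize_new(raw[intersect(names(raw), ref$feature)], ref)
  feats <- z
  if ("gender" %in% model$features) {
    if (!"gender" %in% names(raw)) stopf("missing model feature(s): gender")
    feats <- c(feats, gender = as.numeric(raw[["gender"]]))
  }
  S <- score(feats, list(beta = model$beta, intercept = model$intercept))
  p <- predict_probability(S, model$threshold)
  structure(list(score = S, probability = p, label = classify(p),
                 contributions = model$beta * feats[names(model$beta)],
                 features = feats[names(model$beta)]),
            class = "prediction_result")
}
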