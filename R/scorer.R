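#' The packaged published anti-TNF response model
#'
#' Loads the published 17-protein plasma signature with its gender and
#' baseline-DAS coefficients, intercept b = 3.800 and decision threshold
#' t = 0.7136, from the coefficient file shipped with the package. Protein
#' features and baseline DAS enter the score as z-scores against a reference
#' cohort; gender enters raw (male = 1, female = 0).
#'
#' The original reference cohort's per-feature means and SDs are not public,
#' so the package ships a clearly labelled *synthetic* stand-in
#' (`synthetic_reference_stats.csv`); predictions for real patients require a
#' user-supplied reference file with the true cohort statistics. The scorer
#' itself is exact on the published coefficients and threshold.
#'
#' @param reference a [reference_stats()] covering the 17 proteins and
#'   `baseline_das`, or a path to such a CSV. Defaults to the packaged
#'   synthetic stand-in.
#' @return object of class `published_model`: `coefficients` (data.frame with
#'   feature metadata, FI and beta), `beta` (named vector over the 19 model
#'   features), `intercept`, `threshold`, `ref`.
#' @export
published_model <- function(reference = NULL) {
  path <- system.file("extdata", "published_coefficients.csv",
                      package = "tnfresponse", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  intercept <- tab$beta[tab$feature == "intercept"]
  coefs <- tab[tab$feature != "intercept", ]
  beta <- stats::setNames(coefs$beta, coefs$feature)
  if (is.null(reference)) {
    reference <- system.file("extdata", "synthetic_reference_stats.csv",
                             package = "tnfresponse", mustWork = TRUE)
  }
  ref <- if (inherits(reference, "reference_stats")) reference
         else read_reference_stats(reference)
  z_feats <- setdiff(names(beta), "gender")
  missing <- setdiff(z_feats, ref$feature)
  if (length(missing)) {
    stopf("reference stats missing feature(s): %s",
          paste(missing, collapse = ", "))
  }
  structure(list(coefficients = coefs, beta = beta, intercept = intercept,
                 threshold = 0.7136, ref = ref),
            class = "published_model")
}

#' @export
print.published_model <- function(x, ...) {
  n_prot <- sum(!x$coefficients$feature %in% c("gender", "baseline_das"))
  cat(sprintf("<published_model> %d proteins + gender + baseline DAS; b = %.3f, t = %.4f\n",
              n_prot, x$intercept, x$threshold))
  invisible(x)
}

#' Linear model score of a standardised feature vector
#'
#' `S = sum(beta_i * x_i) + b` over the model's features. Every model feature
#' must be present exactly once; nothing is silently zero-filled.
#'
#' @param features named numeric vector of standardised feature values
#'   (gender raw 0/1).
#' @param model a [published_model()] or `final_model`.
#' @return the score S.
#' @export
score <- function(features, model) {
  beta <- model$beta
  b <- model$intercept
  if (is.null(names(features))) stopf("'features' must be named")
  missing <- setdiff(names(beta), names(features))
  if (length(missing)) {
    stopf("missing model feature(s): %s", paste(missing, collapse = ", "))
  }
  x <- as.numeric(features[names(beta)])
  if (anyNA(x)) stopf("non-numeric or NA feature values")
  sum(beta * x) + b
}

#' Map a model score to a response probability
#'
#' `p = 1 / (1 + exp(-(S - t)))`, the logistic mapping centred at the
#' decision threshold, strictly increasing in S.
#'
#' @param S model score.
#' @param t decision threshold (default: the published 0.7136).
#' @return probability in \[0, 1\].
#' @export
predict_probability <- function(S, t = 0.7136) {
  if (!is.finite(S) || !is.finite(t)) stopf("'S' and 't' must be finite")
  stats::plogis(S - t)
}

#' Binarise a response probability
#'
#' Responder iff `p > 0.5` (equivalently S > t). The boundary `p = 0.5` is
#' classified non-responder: at exact indifference the tool does not promise
#' benefit.
#'
#' @param p probability in \[0, 1\].
#' @return `"responder"` or `"non-responder"`.
#' @export
classify <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stopf("'p' must lie in [0, 1]")
  if (p > 0.5) "responder" else "non-responder"
}

#' Read a patient input file
#'
#' Template: a two-column CSV/TSV with header `feature_id,value`, one row per
#' model feature: `gender` (M/F or 1/0), `baseline_das` (raw DAS28-ESR) and
#' raw NPX values for the 17 signature proteins (gene symbols). A protein
#' assayed on two panels may be supplied as two rows with `:PANEL` suffixes;
#' their z-scores are averaged.
#'
#' @param path file path.
#' @return named numeric vector of raw feature values.
#' @export
read_patient_file <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("feature_id", "value") %in% names(df))) {
    stopf("patient file must have columns 'feature_id' and 'value'")
  }
  ids <- trimws(as.character(df$feature_id))
  if (anyDuplicated(ids)) {
    stopf("duplicate feature_id: %s", ids[duplicated(ids)][1L])
  }
  val <- df$value
  g <- ids == "gender"
  if (any(g) && is.character(val)) {
    val[g] <- ifelse(toupper(trimws(val[g])) %in% c("M", "1"), "1", "0")
  }
  stats::setNames(as.numeric(val), ids)
}

#' Score a new patient with the published model
#'
#' Standardises the patient's raw continuous features (baseline DAS and the
#' 17 protein NPX values) against the model's reference cohort statistics,
#' evaluates the linear score, maps it to a response probability and a
#' responder / non-responder call, and reports per-feature contributions
#' `beta_i * x_i` for interpretability.
#'
#' @param input a patient file path or a named numeric vector of raw values.
#' @param model a [published_model()] (default: the packaged one).
#' @return object of class `prediction_result`: `score`, `probability`,
#'   `label`, `contributions` (named vector summing to `score - intercept`).
#' @export
predict_patient <- function(input, model = published_model()) {
  raw <- if (is.character(input) && length(input) == 1L) read_patient_file(input)
         else input
  if (is.null(names(raw))) stopf("'input' must be a file path or named vector")
  beta <- model$beta
  if (!"gender" %in% names(raw)) stopf("missing model feature(s): gender")
  gender <- raw[["gender"]]
  if (is.na(gender) || !gender %in% c(0, 1)) stopf("gender must be 0/1")
  cont_feats <- setdiff(names(beta), "gender")
  cont <- raw[setdiff(names(raw), "gender")]

  # merge duplicate-panel assays: entries "NAME:PANEL" are standardised with
  # NAME's reference stats, then averaged into a single z per protein name
  base_name <- sub(":[^:]*$", "", names(cont))
  z_each <- vapply(seq_along(cont), function(i) {
    nm <- base_name[i]
    r <- model$ref[model$ref$feature == nm, ]
    if (nrow(r) == 0L) return(NA_real_)
    (as.numeric(cont[i]) - r$mean) / r$sd
  }, numeric(1))
  known <- !is.na(z_each)
  if (any(!known)) {
    warnf("ignoring feature(s) not in the reference: %s",
          paste(names(cont)[!known], collapse = ", "))
  }
  z <- tapply(z_each[known], base_name[known], mean)
  missing <- setdiff(cont_feats, names(z))
  if (length(missing)) {
    stopf("missing model feature(s): %s", paste(missing, collapse = ", "))
  }
  feats <- c(stats::setNames(as.numeric(z[cont_feats]), cont_feats),
             gender = as.numeric(gender))
  S <- score(feats, model)
  p <- predict_probability(S, model$threshold)
  contributions <- beta * feats[names(beta)]
  structure(list(score = S, probability = p, label = classify(p),
                 contributions = contributions,
                 features = feats[names(beta)]),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("score S = %.4f  probability p = %.4f  ->  %s\n",
              x$score, x$probability, x$label))
  invisible(x)
}

#' Write a prediction result as JSON
#' @param result a `prediction_result`.
#' @param path file path.
#' @export
write_prediction <- function(result, path) {
  jsonlite::write_json(
    list(score = result$score, probability = result$probability,
         label = result$label, contributions = as.list(result$contributions)),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
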