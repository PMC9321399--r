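#' Discard measurements with a QC warning
#'
#' Every cell belonging to a flagged (sample, panel) pair is set missing;
#' all other cells are untouched. Idempotent.
#'
#' @param ds an [npx_dataset()] with QC flags populated.
#' @return the dataset with flagged cells set to `NA`.
#' @export
apply_qc <- function(ds) {
  stopifnot(inherits(ds, "npx_dataset"))
  if (!any(ds$qc)) return(ds)
  for (p in colnames(ds$qc)) {
    flagged <- rownames(ds$qc)[ds$qc[, p]]
    if (length(flagged)) {
      cols <- names(ds$panel)[ds$panel == p]
      ds$values[flagged, cols] <- NA_real_
    }
  }
  ds
}

#' Mask NPX values below the limit of detection
#'
#' Cells strictly below their protein's LoD become missing; values exactly
#' equal to the LoD are retained. The resulting missing fraction is attached
#' as attribute `missing_fraction`.
#'
#' @param ds an [npx_dataset()] with an LoD for every protein.
#' @return the dataset with below-LoD cells set to `NA`.
#' @export
mask_below_lod <- function(ds) {
  stopifnot(inherits(ds, "npx_dataset"))
  below <- sweep(ds$values, 2L, ds$lod, "<")  # NA cells stay NA
  ds$values[which(below)] <- NA_real_
  attr(ds, "missing_fraction") <- mean(is.na(ds$values))
  ds
}

#' k-nearest-neighbour imputation of missing NPX values
#'
#' For each missing cell, the imputed value is the unweighted mean of that
#' protein's values in the `k` nearest samples among those where the protein
#' was observed. Distance between two samples is the Euclidean distance over
#' their mutually observed proteins, scaled by the number of shared proteins
#' (so samples with different missingness patterns remain comparable).
#' Observed cells are never altered.
#'
#' @param ds an [npx_dataset()].
#' @param k number of neighbours (default 5); must satisfy `1 <= k < n`.
#' @param max_missing refuse imputation when the missing fraction exceeds
#'   this ceiling (default 0.10).
#' @return the dataset with no missing cells.
#' @export
impute_knn <- function(ds, k = 5L, max_missing = 0.10) {
  stopifnot(inherits(ds, "npx_dataset"))
  x <- ds$values
  n <- nrow(x)
  if (k < 1L || k >= n) stopf("'k' must satisfy 1 <= k < number of samples (%d)", n)
  miss <- is.na(x)
  frac <- mean(miss)
  if (frac == 0) return(ds)
  if (frac > max_missing) {
    stopf("missing fraction %.3f exceeds ceiling %.3f; refusing to impute",
          frac, max_missing)
  }
  all_missing <- rowSums(!miss) == 0L
  if (any(all_missing)) {
    stopf("sample(s) with all proteins missing: %s",
          paste(rownames(x)[all_missing], collapse = ", "))
  }
  need <- which(rowSums(miss) > 0L)
  for (i in need) {
    xi <- x[i, ]
    # normalised Euclidean distance over mutually observed proteins
    d <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      shared <- !miss[i, ] & !miss[j, ]
      ns <- sum(shared)
      if (ns == 0L) return(Inf)
      sqrt(sum((xi[shared] - x[j, shared])^2) / ns)
    }, numeric(1))
    ord <- order(d)
    for (p in which(miss[i, ])) {
      donors <- ord[!miss[ord, p] & is.finite(d[ord])]
      if (length(donors) == 0L) {
        stopf("no donor sample observes protein '%s'", colnames(x)[p])
      }
      use <- donors[seq_len(min(k, length(donors)))]
      x[i, p] <- mean(x[use, p])
    }
  }
  ds$values <- x
  ds
}

#' Reference standardisation statistics
#'
#' Per-feature mean and standard deviation of a reference cohort, used to
#' place new measurements on the cohort's z-score scale.
#'
#' @param feature character vector of unique feature ids.
#' @param mean,sd numeric vectors of per-feature statistics; every `sd` must
#'   be strictly positive.
#' @param n reference cohort size.
#' @return a `data.frame` of class `reference_stats` with attribute `n`.
#' @export
reference_stats <- function(feature, mean, sd, n = NA_integer_) {
  feature <- as.character(feature)
  if (anyDuplicated(feature)) stopf("duplicate feature id in reference stats")
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stopf("all reference SDs must be finite and > 0")
  }
  out <- data.frame(feature = feature, mean = as.numeric(mean),
                    sd = as.numeric(sd), stringsAsFactors = FALSE)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("reference_stats", "data.frame")
  out
}

#' Standardise each protein to zero mean and unit variance
#'
#' Scales every column of a complete NPX matrix to a standard normal scale
#' (z-scores), the preprocessing the relative NPX unit requires before
#' proteins can be compared or combined in one model. Returns both the
#' z-matrix and the pre-scaling per-feature statistics.
#'
#' @param x a complete numeric matrix (samples x features) or a complete
#'   [npx_dataset()].
#' @return list with `z` (matrix of z-scores) and `ref` ([reference_stats()]).
#' @export
standardize <- function(x) {
  if (inherits(x, "npx_dataset")) x <- x$values
  if (anyNA(x)) stopf("matrix contains missing values; impute first")
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    stopf("zero-variance feature(s): %s",
          paste(utils::head(colnames(x)[zero], 5L), collapse = ", "))
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")
  list(z = z, ref = reference_stats(colnames(x), mu, sdev, n = nrow(x)))
}

#' Standardise a new record against reference statistics
#'
#' Computes `z_i = (x_i - mean_i) / sd_i` for every feature named in `ref`.
#' Features in the record but absent from `ref` are dropped with a warning;
#' a feature required by `ref` but absent from the record is an error.
#'
#' @param record named numeric vector of raw feature values.
#' @param ref a [reference_stats()] object.
#' @return named numeric z-vector in the order of `ref$feature`.
#' @export
standardize_new <- function(record, ref) {
  stopifnot(inherits(ref, "reference_stats"))
  if (is.null(names(record))) stopf("'record' must be a named vector")
  missing <- setdiff(ref$feature, names(record))
  if (length(missing)) {
    stopf("record is missing feature(s): %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(record), ref$feature)
  if (length(extra)) {
    warnf("ignoring feature(s) not in the reference: %s",
          paste(extra, collapse = ", "))
  }
  x <- as.numeric(record[ref$feature])
  stats::setNames((x - ref$mean) / ref$sd, ref$feature)
}

#' Full NPX preprocessing pipeline
#'
#' QC masking, below-LoD masking, k-NN imputation and per-protein
#' standardisation, in that order.
#'
#' @inheritParams impute_knn
#' @return list with `z`, `ref` and the imputed `dataset`.
#' @export
preprocess_npx <- function(ds, k = 5L, max_missing = 0.10) {
  ds <- apply_qc(ds)
  ds <- mask_below_lod(ds)
  ds <- impute_knn(ds, k = k, max_missing = max_missing)
  c(standardize(ds), list(dataset = ds))
}

#' Write / read reference statistics as CSV
#' @param ref a [reference_stats()] object.
#' @param path file path.
#' @return `read_reference_stats` returns a [reference_stats()] object.
#' @export
write_reference_stats <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("feature", "mean", "sd") %in% names(df))) {
    stopf("reference stats file must have columns feature, mean, sd")
  }
  reference_stats(df$feature, df$mean, df$sd,
                  n = if ("n" %in% names(df)) df$n[1L] else NA_integer_)
}
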