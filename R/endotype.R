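#' Principal component analysis of a standardised NPX matrix
#'
#' Thin wrapper around the SVD of the column-centered matrix: scores are
#' `U D`, loadings the right singular vectors, explained-variance fractions
#' the normalised squared singular values.
#'
#' @param x complete numeric matrix (samples x proteins), typically the
#'   z-matrix from [standardize()].
#' @param n_components number of components to keep; clamped to
#'   `min(n - 1, p)` with a warning when larger.
#' @return object of class `npx_pca`: `scores` (samples x q), `loadings`
#'   (proteins x q), `explained` (fraction per component), `center`.
#' @export
npx_pca <- function(x, n_components = NULL) {
  if (inherits(x, "npx_dataset")) x <- x$values
  if (anyNA(x)) stopf("matrix contains missing values")
  n <- nrow(x); p <- ncol(x)
  q_max <- min(n - 1L, p)
  q <- n_components %||% q_max
  if (q > q_max) {
    warnf("requested %d components but only %d available; clamping", q, q_max)
    q <- q_max
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = q, nv = q)
  d2 <- sv$d^2
  scores <- sv$u %*% diag(sv$d[seq_len(q)], q, q)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(q)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(q)))
  structure(list(scores = scores, loadings = loadings,
                 explained = d2[seq_len(q)] / sum(d2), center = mu),
            class = "npx_pca")
}

#' @export
print.npx_pca <- function(x, ...) {
  cat(sprintf("<npx_pca> %d components; explained variance: %s...\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5L)),
                    collapse = ", ")))
  invisible(x)
}

# Least-squares PCA scores for a row with coordinate j excluded, for all j at
# once, via a rank-one Sherman-Morrison downdate of the (orthonormal)
# loading Gram matrix. V: p x q loadings, xc: centered row.
scores_excluding_each <- function(V, xc) {
  q <- ncol(V)
  P <- drop(crossprod(V, xc))                      # full projection, q
  vnorm2 <- rowSums(V^2)                           # |v_j|^2, p
  # s_j = (I - v_j v_j')^{-1} (P - v_j x_j)
  #     = w_j + v_j (v_j' w_j) / (1 - |v_j|^2),  w_j = P - v_j x_j
  W <- -V * xc + matrix(P, nrow(V), q, byrow = TRUE)  # rows are w_j
  corr <- rowSums(V * W) / pmax(1 - vnorm2, 1e-12)
  W + V * corr                                      # rows are s_j
}

#' Leave-one-out PRESS for choosing the number of principal components
#'
#' For each left-out sample a PCA is fitted on the remaining samples and the
#' held-out row is reconstructed with `q` components; `PRESS(q)` is the total
#' squared reconstruction error over held-out cells, for `q = 0..max_pcs`.
#' Two reconstructions are available: `"naive"` projects the full held-out
#' row onto the training loadings (each cell thereby participates in its own
#' prediction, biasing PRESS downward as q grows), and `"pseudoinverse"`
#' predicts each cell from the row's *other* coordinates via least-squares
#' scores on the loadings with that coordinate removed, avoiding
#' self-prediction.
#'
#' @param x complete numeric matrix (samples x proteins).
#' @param max_pcs largest number of components to evaluate (default 20,
#'   clamped to `min(n - 2, p)`).
#' @param method `"pseudoinverse"` (default) or `"naive"`.
#' @return data.frame of class `press_curve` with columns `q` (0..max_pcs)
#'   and `press`; attribute `best_q` holds the argmin.
#' @export
loocv_press <- function(x, max_pcs = 20L, method = c("pseudoinverse", "naive")) {
  method <- match.arg(method)
  if (inherits(x, "npx_dataset")) x <- x$values
  if (anyNA(x)) stopf("matrix contains missing values")
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stopf("need at least 3 samples for leave-one-out PRESS")
  max_pcs <- min(max_pcs, n - 2L, p)
  press <- numeric(max_pcs + 1L)
  for (i in seq_len(n)) {
    train <- x[-i, , drop = FALSE]
    mu <- colMeans(train)
    V <- svd(sweep(train, 2L, mu), nu = 0, nv = max_pcs)$v
    xc <- x[i, ] - mu
    press[1L] <- press[1L] + sum(xc^2)             # q = 0: predict the mean
    if (method == "naive") {
      proj <- numeric(p)
      for (q in seq_len(max_pcs)) {
        vq <- V[, q]
        proj <- proj + vq * sum(vq * xc)
        press[q + 1L] <- press[q + 1L] + sum((xc - proj)^2)
      }
    } else {
      for (q in seq_len(max_pcs)) {
        Vq <- V[, seq_len(q), drop = FALSE]
        S <- scores_excluding_each(Vq, xc)          # p x q
        xhat <- rowSums(S * Vq)
        press[q + 1L] <- press[q + 1L] + sum((xc - xhat)^2)
      }
    }
  }
  out <- data.frame(q = 0:max_pcs, press = press)
  attr(out, "best_q") <- out$q[which.min(out$press)]
  attr(out, "method") <- method
  class(out) <- c("press_curve", "data.frame")
  out
}

#' Assign molecular endotypes by the sign of a principal component
#'
#' Patients with a positive oriented score on the chosen component form
#' endotype 1, those with a negative score endotype 2 (a score of exactly 0
#' is assigned endotype 2). The sign indeterminacy of the SVD is resolved by
#' orienting the component so that the endotype-1 group has the higher mean
#' baseline DAS when clinical data are supplied, and otherwise so that the
#' largest-|loading| protein loads positively.
#'
#' @param pca an [npx_pca()] result.
#' @param component component index (default 3).
#' @param clinical optional `clinical_table` with `patient_id` matching the
#'   PCA's sample ids, used for orientation.
#' @return object of class `endotype_assignment`: data.frame `assignment`
#'   (`sample_id`, `score`, `endotype`), plus `component` and `flipped`.
#' @export
assign_endotypes <- function(pca, component = 3L, clinical = NULL) {
  stopifnot(inherits(pca, "npx_pca"))
  if (component > ncol(pca$scores)) {
    stopf("component %d not available (%d computed)", component, ncol(pca$scores))
  }
  s <- pca$scores[, component]
  flipped <- FALSE
  if (!is.null(clinical)) {
    das <- clinical$baseline_das[match(rownames(pca$scores), clinical$patient_id)]
    m_pos <- mean(das[s > 0], na.rm = TRUE)
    m_neg <- mean(das[s < 0], na.rm = TRUE)
    if (is.finite(m_pos) && is.finite(m_neg) && m_pos < m_neg) flipped <- TRUE
  } else {
    j <- which.max(abs(pca$loadings[, component]))
    if (pca$loadings[j, component] < 0) flipped <- TRUE
  }
  if (flipped) s <- -s
  endotype <- ifelse(s > 0, 1L, 2L)
  structure(list(assignment = data.frame(sample_id = rownames(pca$scores),
                                         score = unname(s),
                                         endotype = endotype,
                                         stringsAsFactors = FALSE),
                 component = component, flipped = flipped),
            class = "endotype_assignment")
}

#' @export
print.endotype_assignment <- function(x, ...) {
  tab <- table(x$assignment$endotype)
  cat(sprintf("<endotype_assignment> PC%d sign split: endotype 1 n = %d, endotype 2 n = %d\n",
              x$component, tab["1"], tab["2"]))
  invisible(x)
}

#' Compare clinical features between endotypes
#'
#' Joins the endotype assignment to the clinical table and tests each
#' demographic / clinical variable between the two endotypes (t-test for
#' continuous, chi-square for binary), in the usual cohort-table layout.
#'
#' @param assignment an [assign_endotypes()] result.
#' @param clinical a `clinical_table`.
#' @param ... passed to [two_group_tests()].
#' @return data.frame with per-variable group summaries and p-values.
#' @export
compare_endotypes <- function(assignment, clinical, ...) {
  stopifnot(inherits(assignment, "endotype_assignment"))
  a <- assignment$assignment
  idx <- match(a$sample_id, clinical$patient_id)
  if (anyNA(idx)) stopf("sample id(s) missing from the clinical table")
  clin <- clinical[idx, , drop = FALSE]
  grouping <- as.numeric(a$endotype == 1L)
  if (all(grouping == 1) || all(grouping == 0)) stopf("one endotype is empty")
  vars <- intersect(c("gender", "age", "disease_duration", "baseline_das",
                      "delta_das", "response"), names(clin))
  out <- two_group_tests(clin, grouping, variables = vars, ...)
  names(out)[names(out) == "group1"] <- "endotype1"
  names(out)[names(out) == "group0"] <- "endotype2"
  out
}
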