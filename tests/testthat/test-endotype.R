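# A low-rank matrix with known structure plus jitter, for PCA / PRESS tests.
make_rank2_matrix <- function(n = 30, p = 12, noise = 0.05, seed = 51) {
  set.seed(seed)
  u <- matrix(rnorm(n * 2), n, 2)
  v <- matrix(rnorm(p * 2), 2, p)
  x <- u %*% diag(c(6, 3)) %*% v + noise * matrix(rnorm(n * p), n, p)
  dimnames(x) <- list(sprintf("s%02d", 1:n), sprintf("p%02d", 1:p))
  x
}

# Explicit least-squares oracle for the pseudoinverse PRESS reconstruction.
press_pinv_oracle <- function(x, q) {
  n <- nrow(x); p <- ncol(x)
  total <- 0
  for (i in seq_len(n)) {
    train <- x[-i, , drop = FALSE]
    mu <- colMeans(train)
    V <- svd(sweep(train, 2, mu))$v[, seq_len(q), drop = FALSE]
    xc <- x[i, ] - mu
    for (j in seq_len(p)) {
      s <- qr.solve(V[-j, , drop = FALSE], xc[-j])
      total <- total + unname((xc[j] - sum(V[j, ] * s))^2)
    }
  }
  total
}

test_that("npx_pca satisfies the SVD identities", {
  x <- make_rank2_matrix(noise = 0)
  pca <- npx_pca(x)
  expect_gt(sum(pca$explained[1:2]), 0.999999)

  x2 <- make_rank2_matrix(noise = 0.3, seed = 52)
  pca2 <- npx_pca(x2)
  # loadings orthonormal
  gram <- crossprod(pca2$loadings)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # full reconstruction
  rec <- pca2$scores %*% t(pca2$loadings)
  expect_lt(max(abs(sweep(rec, 2, pca2$center, "+") - x2)), 1e-8)
  # score covariance is diagonal with eigenvalue entries
  cv <- crossprod(pca2$scores) / (nrow(x2) - 1)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  # explained-variance fractions non-increasing
  expect_true(all(diff(pca2$explained) <= 1e-12))
  expect_warning(npx_pca(x2, n_components = 100), "clamping")
})

test_that("PCA scores are invariant to row permutation up to column sign", {
  x <- make_rank2_matrix(noise = 0.4, seed = 53)
  pca <- npx_pca(x, n_components = 4)
  perm <- sample(nrow(x))
  pca_p <- npx_pca(x[perm, ], n_components = 4)
  for (j in 1:4) {
    a <- pca$scores[perm, j][order(perm)]
    a <- pca$scores[, j]
    b <- pca_p$scores[match(rownames(x), rownames(x)[perm]), j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("loocv_press: q = 0 equals the centered total sum of squares", {
  x <- make_rank2_matrix()
  pr <- loocv_press(x, max_pcs = 3)
  oracle_q0 <- sum(sapply(seq_len(nrow(x)), function(i) {
    sum((x[i, ] - colMeans(x[-i, , drop = FALSE]))^2)
  }))
  expect_equal(pr$press[pr$q == 0], oracle_q0)
})

test_that("pseudoinverse PRESS matches the explicit least-squares oracle", {
  x <- make_rank2_matrix(n = 12, p = 6, noise = 0.2, seed = 54)
  pr <- loocv_press(x, max_pcs = 3, method = "pseudoinverse")
  for (q in 1:3) {
    expect_equal(pr$press[pr$q == q], press_pinv_oracle(x, q), tolerance = 1e-8)
  }
})

test_that("PRESS recovers the true rank and exposes the naive bias", {
  x <- make_rank2_matrix(n = 30, p = 12, noise = 0.05)
  pr <- loocv_press(x, max_pcs = 6, method = "pseudoinverse")
  expect_identical(attr(pr, "best_q"), 2L)

  # naive self-prediction: strictly smaller error at q >= rank
  nv <- loocv_press(x, max_pcs = 6, method = "naive")
  expect_true(all(pr$press[pr$q >= 2] > nv$press[nv$q >= 2]))

  # pure noise: no structure, the argmin stays small
  for (seed in 1:3) {
    set.seed(seed)
    xn <- matrix(rnorm(25 * 10), 25, 10,
                 dimnames = list(sprintf("s%02d", 1:25), sprintf("p%02d", 1:10)))
    prn <- loocv_press(xn, max_pcs = 8, method = "pseudoinverse")
    expect_lte(attr(prn, "best_q"), 2L)
  }
})

test_that("endotype assignment recovers a planted bimodal factor", {
  co <- generate_cohort(synth_config(n_patients = 89, n_proteins = 80,
                                     n_informative = 5, n_blocks = 4,
                                     endotype_strength = 1.2, n_panels = 2),
                        seed = 55)
  prep <- preprocess_npx(co$npx)
  pca <- npx_pca(prep$z)
  # find the component that separates the planted groups best
  g <- co$truth$endotype$group
  seps <- sapply(1:4, function(j) abs(mean(pca$scores[g == 1, j]) -
                                      mean(pca$scores[g == 2, j])))
  comp <- which.max(seps)
  a <- assign_endotypes(pca, component = comp, clinical = co$clinical)
  agree <- mean(a$assignment$endotype == g)
  expect_gte(max(agree, 1 - agree), 0.95)

  # orientation makes the assignment invariant to a component sign flip
  pca_f <- pca
  pca_f$scores[, comp] <- -pca_f$scores[, comp]
  pca_f$loadings[, comp] <- -pca_f$loadings[, comp]
  a_f <- assign_endotypes(pca_f, component = comp, clinical = co$clinical)
  expect_identical(a$assignment$endotype, a_f$assignment$endotype)
  a_nf <- assign_endotypes(pca_f, component = comp)  # loading-based fallback
  a_n <- assign_endotypes(pca, component = comp)
  expect_identical(a_n$assignment$endotype, a_nf$assignment$endotype)

  # all-positive scores put everyone in endotype 1
  pca_pos <- pca
  pca_pos$scores[, comp] <- abs(pca_pos$scores[, comp])
  a_pos <- assign_endotypes(pca_pos, component = comp,
                            clinical = co$clinical)
  expect_true(all(a_pos$assignment$endotype == 1L))
})

test_that("endotype 1 carries the higher baseline DAS by construction", {
  co <- generate_cohort(synth_config(n_patients = 60, n_proteins = 40,
                                     n_informative = 3, n_blocks = 4,
                                     endotype_strength = 1.0, n_panels = 2),
                        seed = 56)
  prep <- preprocess_npx(co$npx)
  a <- assign_endotypes(npx_pca(prep$z), component = 3,
                        clinical = co$clinical)
  das <- co$clinical$baseline_das[match(a$assignment$sample_id,
                                        co$clinical$patient_id)]
  expect_gte(mean(das[a$assignment$endotype == 1]),
             mean(das[a$assignment$endotype == 2]))
})

test_that("compare_endotypes is calibrated under the null and powered under a shift", {
  # null: clinical variables independent of the split -> ~5% of p < 0.05
  set.seed(57)
  n_sig <- 0; n_tests <- 0
  for (r in 1:50) {
    n <- 89
    clin <- validate_clinical(data.frame(
      patient_id = sprintf("P%03d", 1:n), gender = rbinom(n, 1, 0.3),
      age = rnorm(n, 60, 11), disease_duration = runif(n, 0, 30),
      baseline_das = pmin(pmax(rnorm(n, 5.4, 1.3), 0), 10),
      delta_das = rnorm(n, -2, 1.5), response = rbinom(n, 1, 0.6)))
    fake <- structure(list(assignment = data.frame(
      sample_id = clin$patient_id, score = rnorm(n),
      endotype = sample(c(1L, 2L), n, TRUE, prob = c(0.6, 0.4))),
      component = 3L, flipped = FALSE), class = "endotype_assignment")
    cmp <- compare_endotypes(fake, clin)
    p <- cmp$p_value[cmp$variable %in% c("age", "disease_duration",
                                         "baseline_das", "delta_das")]
    n_sig <- n_sig + sum(p < 0.05, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(p))
  }
  expect_lt(n_sig / n_tests, 0.12)

  # power: a planted 1.0 DAS shift at n = 89 is detected most of the time
  set.seed(58)
  hits <- 0
  for (r in 1:30) {
    n <- 89
    endo <- c(rep(1L, 55), rep(2L, 34))
    clin <- validate_clinical(data.frame(
      patient_id = sprintf("P%03d", 1:n), gender = rbinom(n, 1, 0.3),
      age = rnorm(n, 60, 11), disease_duration = runif(n, 0, 30),
      baseline_das = pmin(pmax(rnorm(n, 5.0 + (endo == 1) * 1.0, 1.3), 0), 10),
      delta_das = rnorm(n, -2, 1.5), response = rbinom(n, 1, 0.6)))
    fake <- structure(list(assignment = data.frame(
      sample_id = clin$patient_id, score = rnorm(n), endotype = endo),
      component = 3L, flipped = FALSE), class = "endotype_assignment")
    cmp <- compare_endotypes(fake, clin)
    if (cmp$p_value[cmp$variable == "baseline_das"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 24)  # >= 80% of 30 simulations

  # identical groups duplicated -> continuous p ~ 1
  clin1 <- validate_clinical(data.frame(
    patient_id = sprintf("P%03d", 1:40),
    gender = rep(rbinom(20, 1, 0.5), 2), age = rep(rnorm(20, 60, 10), 2),
    disease_duration = rep(runif(20, 1, 20), 2),
    baseline_das = rep(rnorm(20, 5, 1), 2),
    delta_das = rep(rnorm(20, -2, 1), 2), response = rep(rbinom(20, 1, .5), 2)))
  fake1 <- structure(list(assignment = data.frame(
    sample_id = clin1$patient_id, score = rnorm(40),
    endotype = rep(c(1L, 2L), each = 20)),
    component = 3L, flipped = FALSE), class = "endotype_assignment")
  cmp1 <- compare_endotypes(fake1, clin1)
  expect_true(all(cmp1$p_value[cmp1$type == "continuous"] > 0.999))
})
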