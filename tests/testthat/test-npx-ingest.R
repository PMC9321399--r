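test_that("wide and long layouts of the same data read to identical matrices", {
  dir <- withr::local_tempdir()
  wide <- file.path(dir, "wide.csv")
  writeLines(c("sample_id,p1,p2",
               "s1,1.5,2.5",
               "s2,3.0,4.0",
               "s3,5.0,6.0"), wide)
  lodf <- file.path(dir, "lod.csv")
  writeLines(c("protein,lod,panel", "p1,0.1,A", "p2,0.2,A"), lodf)
  ds_wide <- read_npx(wide, layout = "wide", lod_path = lodf)
  expect_identical(dim(ds_wide), c(3L, 2L))

  long <- file.path(dir, "long.tsv")
  rows <- c("sample_id\tprotein\tpanel\tnpx\tlod\tqc_warning")
  for (s in c("s1", "s2", "s3")) for (p in c("p1", "p2")) {
    v <- ds_wide$values[s, p]
    rows <- c(rows, sprintf("%s\t%s\tA\t%g\t%g\tFALSE", s, p, v,
                            ds_wide$lod[p]))
  }
  writeLines(rows, long)
  ds_long <- read_npx(long, layout = "long")
  expect_equal(ds_long$values, ds_wide$values)
  expect_equal(ds_long$lod, ds_wide$lod)
})

test_that("readers reject malformed input", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.csv")
  writeLines(c("sample_id,p1", "s1,1", "s1,2"), dup)
  lodf <- file.path(dir, "lod.csv")
  writeLines(c("protein,lod", "p1,0"), lodf)
  expect_error(read_npx(dup, "wide", lod_path = lodf), "duplicate sample id")

  ragged <- file.path(dir, "ragged.csv")
  writeLines(c("sample_id,p1,p2", "s1,1,2", "s2,1"), ragged)
  expect_error(read_npx(ragged, "wide", lod_path = lodf), "line 3")

  longdup <- file.path(dir, "longdup.csv")
  writeLines(c("sample_id,protein,panel,npx,lod,qc_warning",
               "s1,p1,A,1,0,FALSE", "s1,p1,A,2,0,FALSE"), longdup)
  expect_error(read_npx(longdup, "long"), "duplicate \\(sample, protein\\)")
})

test_that("proteins assayed on two panels become distinct suffixed features", {
  dir <- withr::local_tempdir()
  long <- file.path(dir, "long.csv")
  writeLines(c("sample_id,protein,panel,npx,lod,qc_warning",
               "s1,CXCL1,CVDII,1,0,FALSE",
               "s1,CXCL1,INFLAM,2,0,FALSE",
               "s1,IL13,INFLAM,3,0,FALSE",
               "s2,CXCL1,CVDII,4,0,FALSE",
               "s2,CXCL1,INFLAM,5,0,FALSE",
               "s2,IL13,INFLAM,6,0,FALSE"), long)
  ds <- read_npx(long, "long")
  expect_setequal(npx_proteins(ds), c("CXCL1:CVDII", "CXCL1:INFLAM", "IL13"))
})

test_that("apply_qc masks exactly the flagged (sample, panel) cells", {
  ds <- make_toy_npx(qc_flag_s1_a = FALSE)
  expect_identical(apply_qc(ds)$values, ds$values)

  ds2 <- make_toy_npx(qc_flag_s1_a = TRUE)
  out <- apply_qc(ds2)
  expect_true(all(is.na(out$values["s1", c("p1", "p2")])))
  expect_identical(sum(is.na(out$values)), 2L)

  ds3 <- ds2
  ds3$qc[] <- TRUE
  expect_true(all(is.na(apply_qc(ds3)$values)))
})

test_that("mask_below_lod is strict and reports the missing fraction", {
  ds <- make_toy_npx()
  out <- mask_below_lod(ds)
  expect_true(is.na(out$values["s2", "p2"]))  # 1.0 < LoD 2.0
  expect_identical(sum(is.na(out$values)), 1L)
  expect_equal(attr(out, "missing_fraction"), 1 / 9)

  # value exactly at LoD is retained
  ds$values["s2", "p2"] <- ds$lod["p2"]
  expect_false(anyNA(mask_below_lod(ds)$values))

  # a 20 x 10 fixture with exactly 3 of 200 cells below LoD -> 1.5% missing
  set.seed(3)
  v <- matrix(rnorm(200, 10, 1), 20, 10,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("p%02d", 1:10)))
  v[cbind(c(1, 7, 15), c(2, 5, 9))] <- 0.5
  ds200 <- npx_dataset(v, lod = setNames(rep(1, 10), colnames(v)))
  out200 <- mask_below_lod(ds200)
  expect_equal(attr(out200, "missing_fraction"), 0.015)
})

test_that("qc and lod masking are idempotent and commute", {
  ds <- make_toy_npx(qc_flag_s1_a = TRUE)
  a <- mask_below_lod(apply_qc(ds))
  b <- apply_qc(mask_below_lod(ds))
  expect_equal(a$values, b$values)
  expect_equal(apply_qc(apply_qc(ds))$values, apply_qc(ds)$values)
  expect_equal(mask_below_lod(mask_below_lod(ds))$values,
               mask_below_lod(ds)$values)
})

test_that("impute_knn fills every gap, never touches observed cells", {
  # constant column: imputed value equals the constant for any k
  v <- matrix(1.7, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  v[, "b"] <- c(1, 2, 3, 4)
  v[2, "a"] <- NA
  ds <- npx_dataset(v, lod = c(a = -10, b = -10))
  for (k in 1:3) {
    expect_equal(impute_knn(ds, k = k, max_missing = 0.2)$values[2, "a"], 1.7)
  }

  # 4-sample toy, k = 2: verified against hand-computed nearest neighbours
  v2 <- matrix(c(1.0, 1.1, 5.0, 9.0,
                 2.0, 2.2, 6.0, 8.0,
                 NA,  3.0, 7.0, 4.0), nrow = 4,
               dimnames = list(paste0("s", 1:4), c("x", "y", "z")))
  ds2 <- npx_dataset(v2, lod = c(x = -10, y = -10, z = -10))
  # (s1, z) is missing; distances from s1 over shared proteins (x, y)
  d <- sapply(2:4, function(j) sqrt(sum((v2[1, 1:2] - v2[j, 1:2])^2) / 2))
  nearest2 <- (2:4)[order(d)][1:2]
  expect_equal(impute_knn(ds2, k = 2)$values[1, "z"],
               mean(v2[nearest2, "z"]))
  # observed cells unchanged
  out <- impute_knn(ds2, k = 2)$values
  expect_identical(out[-1, ], v2[-1, ])

  # complete matrix is returned unchanged
  ds3 <- make_toy_npx()
  expect_identical(impute_knn(ds3, k = 2), ds3)

  # imputed values stay within the observed range of the protein
  set.seed(5)
  v4 <- matrix(rnorm(300), 30, 10,
               dimnames = list(sprintf("s%02d", 1:30), sprintf("p%02d", 1:10)))
  v4[sample(300, 15)] <- NA
  ds4 <- npx_dataset(v4, lod = setNames(rep(-10, 10), colnames(v4)))
  out4 <- impute_knn(ds4, k = 5)$values
  for (j in which(colSums(is.na(v4)) > 0)) {
    obs <- v4[!is.na(v4[, j]), j]
    imp <- out4[is.na(v4[, j]), j]
    expect_true(all(imp >= min(obs) & imp <= max(obs)))
  }
})

test_that("impute_knn enforces its preconditions", {
  v <- matrix(c(NA, NA, 1, 2), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  v2 <- v; v2[1, ] <- NA
  ds <- npx_dataset(v2, lod = c(a = -10, b = -10))
  expect_error(impute_knn(ds, k = 1, max_missing = 0.9), "all proteins missing")
  ds_ok <- npx_dataset(matrix(c(NA, 1, 2, 3), 2, 2,
                              dimnames = list(c("s1", "s2"), c("a", "b"))),
                       lod = c(a = -10, b = -10))
  expect_error(impute_knn(ds_ok, k = 1, max_missing = 0.1), "ceiling")
  expect_error(impute_knn(ds_ok, k = 5), "'k' must satisfy")
})

test_that("standardize yields exact z-scores and is its own fixed point", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  out <- standardize(x)
  expect_equal(unname(out$z[, 1]), c(-1, 0, 1))

  set.seed(9)
  x2 <- matrix(rnorm(100, 5, 3), 20, 5,
               dimnames = list(NULL, paste0("p", 1:5)))
  out2 <- standardize(x2)
  expect_lt(max(abs(colMeans(out2$z))), 1e-10)
  expect_lt(max(abs(apply(out2$z, 2, sd) - 1)), 1e-10)
  # round trip z * sd + mean reproduces the input
  back <- sweep(sweep(out2$z, 2, out2$ref$sd, "*"), 2, out2$ref$mean, "+")
  expect_lt(max(abs(back - x2)), 1e-12)
  # re-standardising a z-matrix is the identity
  expect_lt(max(abs(standardize(out2$z)$z - out2$z)), 1e-10)

  x2[, 2] <- 7
  expect_error(standardize(x2), "zero-variance.*p2")
})

test_that("standardize_new matches the closed form and validates features", {
  ref <- reference_stats(c("a", "b"), mean = c(2, 10), sd = c(0.5, 4), n = 10)
  expect_equal(unname(standardize_new(c(a = 2, b = 10), ref)), c(0, 0))
  expect_equal(unname(standardize_new(c(a = 2.5, b = 14), ref)), c(1, 1))
  rec <- c(a = 3.1, b = 7.7)
  expect_equal(unname(standardize_new(rec, ref)),
               (as.numeric(rec) - c(2, 10)) / c(0.5, 4))
  expect_error(standardize_new(c(a = 1), ref), "missing feature\\(s\\): b")
  expect_warning(standardize_new(c(a = 1, b = 2, c = 3), ref), "ignoring")
})

test_that("the preprocessing pipeline preserves dimensions on synthetic data", {
  co <- generate_cohort(synth_config(n_patients = 40, n_proteins = 24,
                                     n_informative = 4, n_blocks = 4,
                                     n_panels = 2), seed = 77)
  prep <- preprocess_npx(co$npx)
  expect_identical(dim(prep$z), dim(co$npx$values))
  expect_false(anyNA(prep$z))
  expect_lt(max(abs(colMeans(prep$z))), 1e-10)
})

test_that("clinical readers recode and validate", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "clin.csv")
  writeLines(c("patient_id,gender,age,disease_duration,baseline_das,delta_das,response",
               "P1,F,60,5,5.5,-2.5,R",
               "P2,M,55,8,4.2,-0.1,NR"), f)
  cl <- read_clinical(f)
  expect_identical(cl$gender, c(0, 1))
  expect_identical(cl$response, c(1, 0))
  writeLines(c("patient_id,gender,age,disease_duration,baseline_das,delta_das,response",
               "P1,F,60,5,12.5,-2.5,R"), f)
  expect_error(read_clinical(f), "baseline_das")
})
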