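# Small in-code fixtures shared across test files.

# Hand-built 3-sample x 3-protein dataset on two panels: p1, p2 on PANELA,
# p3 on PANELB. Values chosen so one cell (s2, p2) sits below its LoD.
make_toy_npx <- function(qc_flag_s1_a = FALSE) {
  values <- matrix(c(5.0, 6.0, 7.0,
                     4.0, 1.0, 4.5,
                     8.0, 8.2, 7.9), nrow = 3, byrow = FALSE,
                   dimnames = list(c("s1", "s2", "s3"), c("p1", "p2", "p3")))
  lod <- c(p1 = 2.0, p2 = 2.0, p3 = 3.0)
  panel <- c(p1 = "PANELA", p2 = "PANELA", p3 = "PANELB")
  qc <- matrix(FALSE, 3, 2, dimnames = list(c("s1", "s2", "s3"),
                                            c("PANELA", "PANELB")))
  qc["s1", "PANELA"] <- qc_flag_s1_a
  npx_dataset(values, lod = lod, panel = panel, qc = qc)
}

# Standardised small cohort with planted signal in the first column.
make_signal_matrix <- function(n = 80, p = 6, effect = 2, seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rbinom(n, 1, plogis(effect * X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = scale(X), y = y)
}

# Write a cohort's wide NPX + companions into a temp dir, return the paths.
write_temp_cohort <- function(cohort,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_cohort(cohort, dir)
  list(npx = file.path(dir, "npx.csv"), lod = file.path(dir, "lod.csv"),
       qc = file.path(dir, "qc.csv"), clinical = file.path(dir, "clinical.csv"),
       dir = dir)
}
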