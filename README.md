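# tnfresponse

Predicting response to anti-TNF therapy in rheumatoid arthritis from
targeted plasma proteomics.

About a third of rheumatoid arthritis patients do not benefit from anti-TNF
biologics, at high cost and at the price of months of uncontrolled disease.
`tnfresponse` implements, in R, the full discovery-and-deployment pipeline
behind a plasma-protein response predictor:

* **NPX preprocessing** — QC-warning masking, strict below-LoD masking,
  k-nearest-neighbour imputation, per-protein standardisation of Olink-style
  NPX (log2-scale relative quantification) matrices, with reference
  statistics retained so new patients can be placed on the cohort z-scale.
* **Discovery** — resampling feature importance (500 stratified 80:20
  splits; elastic-net logistic regression, α = 0.9, inner 10-fold λ tuning
  by mean out-of-fold AUC; an AUC > 0.5 gate; importance = selection
  frequency) followed by stepwise model-size evaluation under 5-fold nested
  cross-validation and a final full-cohort fit with a Youden-index decision
  threshold.
* **A packaged published scorer** — the 17-protein signature with gender and
  baseline DAS28-ESR:

  `S = Σ βᵢ·xᵢ + b` with b = 3.800, and `p = 1 / (1 + exp(−(S − t)))` with
  t = 0.7136; responder iff p > 0.5.
* **Endotype discovery** — PCA of the standardised proteome,
  leave-one-out PRESS (naive and pseudoinverse reconstructions) for choosing
  the number of components, sign-of-PC3 endotype assignment, and
  endotype-vs-clinical comparison tables.
* **A synthetic cohort generator** — block-correlated Gaussian NPX cohorts
  with planted logistic effects, latent endotype factors, below-LoD
  missingness and QC flags, plus a preset emulating an 89-patient,
  352-protein cohort with 60 responders; every pipeline stage is testable
  offline with known ground truth.

The scorer ships with a clearly labelled **synthetic** stand-in for the
original reference cohort's standardisation statistics
(`inst/extdata/synthetic_reference_stats.csv`): coefficient arithmetic is
exact, but clinically meaningful probabilities require supplying the real
cohort statistics.

## Worked example

```r
library(tnfresponse)

# a synthetic cohort shaped like the real one: 89 patients, 352 proteins
co <- make_paper_like_cohort(seed = 8)
co$npx
#> <npx_dataset> 89 samples x 352 proteins, 4 panel(s), 0.00% missing

table(co$clinical$response)
#>  0  1
#> 29 60

# discovery, scaled down for a quick run (500 simulations by default)
res <- run_discovery(co$npx, co$clinical, n_sim = 60, k_max = 30, seed = 200)
res$k
#> [1] 28
head(res$fi$importance, 3)
#>   feature frequency  mean_coef
#> 1 PROT007 0.8833333 -0.4828656
#> 2 PROT003 0.8166667 -0.6441645
#> 3 PROT155 0.8166667  0.5423879
res$model
#> <final_model> 30 features, intercept 3.6994, threshold -0.0497
```

The FI table ranks features by the share of gated resampled models selecting
them; `res$k` is the number of proteins whose
stepwise addition maximised mean outer-test AUC without degrading training
AUC; the final model carries coefficients, intercept and the Youden
threshold on the full-cohort score scale.

Scoring a new patient with the packaged published model:

```r
pm <- published_model()
pm
#> <published_model> 17 proteins + gender + baseline DAS; b = 3.800, t = 0.7136

pred <- predict_patient(
  system.file("extdata", "example_responder_synthetic.csv",
              package = "tnfresponse"), pm)
pred
#> score S = 60.8020  probability p = 1.0000  ->  responder
```

A patient sitting at the reference means (all z = 0, female) scores exactly
the intercept: `S = 3.800`, `p = 1/(1+e^(−(3.800−0.7136))) ≈ 0.956`.

Endotypes:

```r
prep <- preprocess_npx(co$npx)
pca  <- npx_pca(prep$z)
loocv_press(prep$z[, 1:40], max_pcs = 8)   # PRESS curve, argmin = best q
assignment <- assign_endotypes(pca, component = 3, clinical = co$clinical)
compare_endotypes(assignment, co$clinical)
```

## Command line

```sh
Rscript inst/cli/tnfresponse simulate --preset paper --seed 8 --out-dir cohort/
Rscript inst/cli/tnfresponse discover --npx cohort/npx.csv --lod cohort/lod.csv \
    --qc cohort/qc.csv --clinical cohort/clinical.csv --n-sim 60 --out-dir out/
Rscript inst/cli/tnfresponse predict --input patient.csv --model out/model.json
Rscript inst/cli/tnfresponse endotype --npx cohort/npx.csv --lod cohort/lod.csv \
    --clinical cohort/clinical.csv --component 3 --out-dir endo/
```

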