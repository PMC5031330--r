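# gldskit

Biomarker discovery in cell-line drug screens is confounded by a latent
axis we call the **general level of drug sensitivity (GLDS)**: some cell
lines are sensitive, and others resistant, to many drugs regardless of
mechanism — a pre-clinical echo of clinical multi-drug resistance. When a
mutation is more common in generally-resistant lines, a naive regression
of any drug's log(IC50) on that mutation produces a spurious "biomarker";
at the same time, the shared axis inflates residual variance and hides
genuine drug-specific effects.

gldskit is a toolkit for pharmacogenomics analysts that estimates GLDS and
conditions it out of mutation–drug association screens:

* **Iterative matrix completion** for missing IC50 values: each cell
  line's observed profile is regressed on the eigen-drugs (right singular
  vectors) of the remaining rows with a cross-validated lasso penalty,
  sweeping until the total update `A = Σ|X′ − X|` stabilizes.
* **GLDS summary** by SVD of the column-centered completed matrix (PC1 =
  dominant shared-resistance axis), plus the per-cell-line median IC50 as
  an interpretable alternative.
* **Negative-control covariates**: for each target drug, drugs with
  unrelated mechanism that are not among its most-correlated neighbors
  form a control set; the first 10 principal components of the control
  submatrix enter the association model as covariates, so GLDS is removed
  without absorbing drug-specific signal. For the model of a drug's
  response `y` on mutation `g`,

  `y = β₀ + β₁ g + Σₖ γₖ PCₖ(controls) + ε`,

  `β₁` (positive = mutation confers resistance) is tested by a two-sided
  t-test with Benjamini–Hochberg FDR across the screen.
* **Expression-proxy signature**: genes consistently top-correlated with
  every drug's GLDS PCs form a signature whose expression PCs serve as
  covariates when no large drug panel is available.
* **Synthetic screens with known truth** (`simulate_screen()`) and an
  **evaluation harness** (`run_evaluation()`) measuring type-I error on
  confounded-null mutations, power at matched realized FDR, and PPV.

See `vignettes/glds-correction.Rmd` for the model, the generator's
assumptions, and known limitations.

## Worked example

```r
library(gldskit)

cfg <- sim_config(m = 120, n_drugs = 40, missing_fraction = 0.15,
                  n_genes = 2000, n_glds_genes = 10, seed = 42)
screen <- simulate_screen(cfg)
screen
#> synthetic_screen: 120 cell lines x 40 drugs (15% missing), 20 genes mutated, 2000 expression genes

completed <- complete(screen$response, impute_config(max_iter = 4, seed = 1))
completed
#> completed_matrix: 120 x 40, 720 imputed entries, 3 iterations (converged)
hidden <- !screen$response$mask
round(cor(screen$response_full[hidden], completed$values[hidden])^2, 3)
#> [1] 0.596

glds <- glds_decompose(completed, k = 10)
glds
#> glds_components: 120 cell lines, 40 drugs, k = 10 (PC1 64.3% of variance)
round(cor(glds$scores, screen$glds_factor, method = "spearman")[1], 3)
#> [1] 0.982

covs <- covariates_for_all_drugs(screen$response, completed,
                                 screen$annotation, k_corr = 4,
                                 min_controls = 15, n_pcs = 10)
uncorr  <- run_screen(screen$response, screen$mutations, "uncorrected")
glds_scr <- run_screen(screen$response, screen$mutations, "glds",
                       covariates = covs)
conf <- screen$mutation_truth$gene[screen$mutation_truth$truth == "confounded_null"]
c(uncorrected_fp = sum(uncorr$q < 0.05 & uncorr$gene %in% conf, na.rm = TRUE),
  glds_fp        = sum(glds_scr$q < 0.05 & glds_scr$gene %in% conf, na.rm = TRUE))
#> uncorrected_fp        glds_fp
#>            153              0
```

Reading the numbers: the imputer explains ~60% of held-out variance on
this noisy screen (the column-mean baseline explains ~0%); PC1 tracks the
true latent factor at Spearman 0.98; and of the 160 (confounded gene ×
drug) tests, the uncorrected screen flags 153 spurious associations at
q < 0.05 while the GLDS-corrected screen flags none.

## Command-line use

A thin front end is installed at `exec/gldskit`:

```sh
gldskit simulate --config sim.yaml --out screen/
gldskit impute   --in screen/response.tsv --out screen/completed.tsv
gldskit glds     --in screen/completed.tsv --k 10 --out-prefix screen/glds
gldskit evaluate --config sim.yaml --replicates 10 --out report.json
```

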