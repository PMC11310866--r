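# emtsub — methylation-driven EMT subtyping of breast cancer

Breast tumours spread along the epithelial–mesenchymal transition (EMT), a
continuum from epithelial (E) through hybrid (H) to mesenchymal (M) states
that is tightly controlled by promoter DNA methylation. `emtsub` is an R
package plus a numbered analysis workflow for researchers who want to
discover EMT subtypes from gene-level methylation beta values, quantify each
sample's EMT state, distill the subtypes into a small, portable gene-panel
classifier, and nominate subtype-specific drugs from cell-line
pharmacogenomics — all reproducible at desk scale on seeded synthetic
cohorts with planted structure.

## What is in the box

* **Differential filter** — empirical-Bayes moderated t on M-values
  (method-of-moments prior; t = Δ/(s̃·√(1/n₁+1/n₂)) with
  s̃² = (d₀s₀² + d·s²)/(d₀+d)), BH adjustment, and the candidate gate
  |Δβ| > 0.1 ∧ q < 0.001 ∧ membership in an EMT-associated gene list.
* **Consensus NMF** — Brunet multiplicative updates minimizing the
  generalized KL divergence D(V‖WH), seeded multi-restart consensus,
  cophenetic ρ_k and dispersion η_k = mean 4(c−½)², rank chosen by the
  steepest forward drop of ρ_k·η_k, silhouette on 1−consensus, and
  deterministic C1..Ck ordering along the EMT axis.
* **EMT scores** — per-sample two-sample-KS score (D_M − D_E),
  correlation-weighted 76-gene-style score (higher = epithelial),
  mean(M)−mean(E), and a generic ssGSEA engine (rank^α running sum,
  α = 0.25).
* **Classifier cascade** — consensus differential analysis (moderated t ∩
  SAM ∩ Westfall–Young maxT, one-vs-rest), logistic quality control (1000
  subsample iterations), Pearson decollinearization, Boruta + linear SVM-RFE
  wrappers, multinomial sparse-group-lasso stability selection (FISTA solver
  in C++), 5×10-fold competition of five model families, and a deployable
  classifier with a per-cohort median/MAD standardization contract.
* **Drug transfer** — per-gene purity regression, per-drug ridge models
  (closed-form SVD, 10-fold CV penalty) trained on cell lines and applied to
  purified tumours, Kruskal–Wallis + BH nomination of subtype-specific
  agents with min-max normalized sensitivity scores (lower = more
  sensitive).
* **Synthetic cohorts** — a seeded generator planting subtype-specific
  promoter methylation shifts (logit-Gaussian, |Δβ| up to 0.3), inversely
  coupled expression, purity confounding, subtype-dependent exponential
  survival with tuned uniform censoring, and linear drug-response
  signatures; every knob is a `simulation_config()` field.

## Worked example

The workflow lives in `analysis/01_simulate.R` … `07_survival.R`; each stage
reads its predecessor's tables under `results/`. Running stages 1–3,

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_dm_filter.R
Rscript analysis/03_subtype.R
```

prints (seed 20260929):

```
cohort: 120 tumors (40/40/40), 40 normals, 300 genes (60 informative)
tested 300 genes; 60 pass |dB| > 0.1 & q < 0.001; 60 candidates after the annotation intersection
rank table:
  rank cophenetic dispersion combined forward_drop
1    2      0.999      0.409    0.409       -0.591
2    3      1.000      1.000    1.000        0.093
3    4      0.999      0.907    0.907        0.028
4    5      0.999      0.880    0.879        0.049
5    6      0.996      0.833    0.830           NA
chosen rank: 3 (low confidence: FALSE); mean silhouette 1.00; cluster sizes 40/40/40
```

The tumor-vs-normal filter recovers exactly the 60 planted driver genes; the
combined cophenetic×dispersion score is maximal and drops steepest after
rank 3, recovering the three planted subtypes with a perfect consensus
silhouette. Stage 4 orders the clusters along the EMT axis (C1 most
epithelial); stage 5 derives a 45-gene panel and the model competition puts
four families at balanced accuracy 1.000 on held-out splits (boosted trees
0.953), with an independently simulated validation cohort classified at ARI
1.0 and identical subtype fractions; stage 6 nominates each of the five
planted drugs for its target subtype (all q < 1e-10, gaps ≥ 1.3 pooled SD);
stage 7's log-rank test separates the subtypes (χ² = 7.02, 2 df, p = 0.03),
with the mesenchymal-most subtype C3 having the shortest median survival.

## Package layout

```
R/, src/        implementation (R + RcppArmadillo solvers)
analysis/       numbered workflow drivers (thin wrappers over the package)
results/        small summary tables written by the workflow
tests/testthat/ unit, property and end-to-end recovery tests
scripts/        acceptance.R (see above)
vignettes/      methods vignette: models, parameters, design decisions
```
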