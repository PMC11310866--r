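---
title: "Methylation-driven EMT subtyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-driven EMT subtyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Epithelial-mesenchymal transition (EMT) is a phenotypic continuum - epithelial
(E) through hybrid (H) to mesenchymal (M) states - that shapes metastasis,
recurrence and therapy resistance in breast cancer, and is under tight DNA
methylation control. `emtsub` implements a complete desk-scale pipeline for
discovering methylation-driven EMT subtypes and making them clinically
portable: differential-methylation filtering of EMT-associated genes,
consensus non-negative matrix factorization (NMF) with data-driven rank
selection, per-sample EMT state scoring, a multi-stage machine-learning
cascade that distills a small gene panel and a deployable subtype classifier,
and a ridge-regression transfer of cell-line drug response that nominates
subtype-specific agents.

Because real cohorts (450k methylation arrays, RNA-seq, pharmacogenomic
panels) cannot be bundled, the package ships a first-class synthetic-cohort
generator that plants the statistical structure every downstream stage
assumes. All tests and the reproduction script run against that generator.

# The synthetic cohort generator

`simulation_config()` fixes the study conditions; `simulate_cohort()` draws a
cohort. The generator emulates, per component:

* **Methylation.** Beta values are generated as Gaussians on the logit
  (M-value) scale around per-gene, per-cluster means and mapped back through
  the inverse logit, so values live strictly in (0,1) and M-value analyses of
  the planted effects are exact - the standard noise model for 450k-style
  data. Planted driver genes follow promoter biology: *hypermethylating*
  drivers start low (base beta U(0.10, 0.20)) and gain `delta_beta` (default
  0.25) in exactly one target cluster; *hypomethylating* drivers start high
  (U(0.55, 0.80)) and lose it. Nuisance genes share one mean across clusters,
  uniform over [0.1, 0.9]. This bimodal architecture matters: with mid-range
  baselines the argmax connectivity of KL-NMF becomes degenerate (equal-KL
  local optima with scrambled partitions), which is not how methylation
  subtype data behave; marker-like contrast is both the realistic choice and
  the regime the clustering method is designed for.
* **Adjacent normals.** Normal samples sit half an effect size beyond the
  tumor base, opposite the driver's direction, so the tumor-vs-normal filter
  has signal on exactly the informative genes, and the candidate gate's
  annotation intersection is exercised with an "EMT-associated gene" list
  containing all informative genes plus half the nuisance genes.
* **Expression.** Driver genes: expression = intercept − `expr_coupling` ×
  beta + Gaussian noise (`expr_noise_sd`, default 0.3 on the log scale) -
  the methylation-expression anticorrelation that makes methylation subtypes
  visible in transcriptome space. A per-gene random purity slope
  (sd `purity_effect`) injects the stromal confounding that the drug module's
  purity correction must remove. Tumor purity itself is Beta(5, 2).
* **Survival.** Exponential event times with per-subtype hazard multipliers
  (default 1 / 1.5 / 2.5 over baseline 0.08), censored by an independent
  uniform time whose horizon is tuned by bisection on the analytic censoring
  probability to hit `censor_rate` (default 30%) within 2%.
* **Pharmacogenomics.** Cell-line expression is Gaussian per gene; each
  drug's response is a unit-weight linear function of a disjoint gene
  signature plus noise. In the full cohort each drug's signature is drawn
  from the hypermethylated (hence expression-low) drivers of one subtype in
  rotation, so tumors of the target subtype are predicted most sensitive
  (lower response = more sensitive throughout).

Defaults (3 x 40 tumors, 40 normals, 300 genes, 60 informative, logit noise
sd 0.5) were chosen once as realistic desk-scale conditions and are not
revisited per analysis. What the generator does **not** emulate: genome
coordinates and probe design, co-methylation block structure, batch and
platform effects, non-exponential hazards, and cohort-specific noise spectra.
Passing tests therefore demonstrate internal correctness and planted-structure
recovery, not performance on any real cohort.

# Differential methylation

`moderated_t()` is a self-contained empirical-Bayes moderated t: per-gene
two-group contrasts with the posterior variance
s²_g = (d₀ s₀² + d s²_g) / (d₀ + d), where the prior (d₀, s₀²) is fitted by
the method of moments on log sample variances (digamma/trigamma matching,
with a Newton trigamma inverse). When the log-variance spread is no wider
than sampling noise the fit collapses to full shrinkage (d₀ = ∞, s₀² = mean
variance). Tests verify numerical agreement with limma as an independent
oracle; limma is never the implementation. Tests run on M-values (beta
clipped at 1e-6) while effect sizes are always reported on the beta scale -
the variance-stabilizing convention. The candidate gate uses strict
inequalities (|Δβ| > 0.1, q < 0.001, read literally) and an explicit
annotation intersection.

# Consensus NMF and rank selection

`nmf_brunet()` minimizes the generalized Kullback-Leibler divergence with
multiplicative updates (denominators floored at 1e-12; the KL trace is
recorded and asserted non-increasing). Factors are initialized i.i.d.
uniform(0, mean(V)) from seeds derived off one master seed, which makes the
sample connectivity equivariant to rescaling of the input. A run stops when
the argmax-of-H connectivity is unchanged for 40 consecutive checks (every 10
iterations) or at 2000 iterations. Beta values are factorized directly: they
are natively nonnegative.

`consensus_cluster()` averages binary connectivity over restarts; labels come
from average-linkage clustering of 1 − consensus. Rank selection combines
the cophenetic correlation ρ_k and the dispersion η_k = mean 4(c − ½)² as
their product, and the chosen rank is the one with the largest forward drop
combined_k − combined_{k+1} among ranks whose combined score exceeds the
grid median - an operationalization of "last rank before the steepest
decline". The combination rule and the dissimilarity for the silhouette
(1 − consensus) are conventions, exposed as arguments; a `low_confidence`
flag is raised when the chosen rank's combined score is below 0.8, the regime
we observe on unstructured data.

Cluster names are made biologic by `relabel_by_emt()`: clusters are renamed
C1..Ck by ascending mean mesenchymal score (ties by size, then lexical id),
so C1 is always the most epithelial cluster and Ck the most mesenchymal.

# EMT scores

The three signature scores are implemented as the three established
conventions, and this mapping is an explicit, swappable assumption:

* `score_ks()` - per-sample two-sample Kolmogorov-Smirnov comparison of
  E-set vs M-set expression, score = D_M − D_E ∈ [−1, 1], positive =
  mesenchymal; rank-based, hence invariant to per-sample monotone transforms.
* `score_76gs()` - signature genes weighted by cohort-wide Pearson
  correlation with a reference epithelial anchor (CDH1-style); higher =
  epithelial. Note the weights depend on the scoring cohort.
* `score_mlr()` - mean(M) − mean(E) per sample.

`ssgsea()` is the generic engine: genes ranked descending per sample, running
sum of rank^α-weighted in-set mass minus uniform out-of-set mass, ES = sum of
the running sum, α = 0.25, ties broken by stable gene order, optional global
min-max normalization (off by default). Gene sets ship as editable GMT files;
nothing is hard-coded.

# The classifier cascade

Stages, each returning a subset of its input (asserted in tests):

1. **Consensus differential analysis** - one-vs-rest per subtype, a gene
   must pass all three: moderated t (q < 0.05), SAM (permutation q < 0.05;
   fudge factor s₀ minimizes the coefficient of variation of windowed MADs of
   d), and Westfall-Young maxT (adjusted p < 0.05, single-step with enforced
   monotonicity). The union over subtypes feeds the next stage. SAM
   permutation p-values pool the null statistics across genes for resolution.
2. **Logistic quality control** - 1000 stratified 80% subsamples; per gene
   and subtype a univariate logistic Wald test; retention at frequency >=
   0.5. Perfect separation drives the Wald statistic to zero (Hauck-Donner),
   so clipped slopes (|b| = 15) are treated as decisive and flagged.
3. **Correlation filter** - greedy pass in decreasing-MAD order, dropping
   genes with |r| > 0.9 against anything retained.
4. **Wrappers** - Boruta (shadow features, binomial confirmation at α =
   0.01, tentative resolved by median importance) and linear SVM-RFE (10%
   eliminated per round, one-vs-rest squared-weight ranking, top half kept),
   combined by **union**: recall is preserved ahead of the aggressive sparse
   stage, which owns precision.
5. **Stability selection** - multinomial sparse group lasso (one group =
   one gene's coefficients across classes; penalty α·L1 + (1−α)·√K·group-L2,
   α = 0.95), solved by an accelerated proximal (FISTA) scheme with
   backtracking and momentum restart, convergence at 1e-6 within 1e4
   iterations (else an explicit convergence error). Per run: stratified 80%
   resample, penalty by 10-fold CV deviance over 15 log-spaced points
   spanning two decades below λ_max (the CV optimum sits in the sparse upper
   path at these sizes; a longer grid only adds runtime), selection =
   group norm > 1e-8; panel = frequency >= 0.5. The unpenalized limit is
   tested against `nnet::multinom`.

Thresholds 0.5/0.5, the union combiner, α = 0.95, and the identity of the
five competition families (linear SVM, random forest, k-NN, penalized
multinomial regression, gradient-boosted trees) are defaults filling gaps the
source architecture leaves open; all are arguments.

**Competition and deployment.** `model_competition()` evaluates the five
families over 5 × 10 seeded stratified shuffled 80/20 splits with balanced
accuracy, macro AUROC and macro AUPRC; within a split, standardization
parameters are fit on the training portion only. The deployable classifier
standardizes each *cohort* per gene by its own median/MAD - the
cross-platform contract that makes predictions invariant to per-gene affine
transforms of a cohort - and imputes up to 10% missing panel genes at
standardized zero (more is a coverage error).

# Drug-response transfer

Purity correction is per-gene linear regression on purity with the intercept
restored - a deliberate simplification of factor-model purification (no
factor parameters are available to reproduce), documented here and
idempotent by construction. Ridge models (closed-form SVD solution; the
λ → 0 limit is tested against the normal equations) are trained per drug on
cell-line expression with the penalty chosen by 10-fold CV MSE over a
25-point grid; tumors are mapped with the training standardization. A drug
is nominated for the subtype with the lowest mean predicted response if the
Kruskal-Wallis BH-adjusted q < 0.05 across subtypes and the best-vs-runner-up
gap is at least 0.5 pooled SDs (the gap threshold is a guard of our own;
none is stated upstream). Scores are min-max normalized per drug; the
"lower = more sensitive" convention is stored in the model objects.

# Numerical choices and degenerate inputs

* Beta values clipped at 1e-6 before logit; NMF denominators floored at
  1e-12; group-norm selection cut at 1e-8.
* Zero-variance genes: flagged, p = 1 when no shrinkage is available.
* Constant purity: correction skipped with a warning (unidentifiable slope).
* All-tied Kruskal-Wallis input: H = 0, p = 1 with a warning; zero-event
  log-rank: an error, not NaN.
* Zero-variance consensus: cophenetic coefficient is an error, not NaN.
* Ties: ssGSEA and correlation-filter orderings break ties by stable gene
  order; EMT relabeling by cluster size then lexical id.
* Every stochastic step draws its seed from one master seed through a
  splitmix-style integer hash (`derive_seed()`), so stages are reproducible
  independently of one another.

# Problem sizes used in tests and reproduction

The shipped analyses and the reproduction script use 3 × 40 tumors × 300
genes for subtype discovery (30 NMF restarts over ranks 2-6), 3 × 50 × 500
genes for panel derivation with 100 stability runs (the derivation procedure
itself defaults to 1000), 50 pooled seeds of 1000 null genes for calibration,
and 10 seeds for the panel and drug loops. These sizes give stable
Monte-Carlo estimates at desk scale; all counts are arguments, so larger
studies only cost time.

# Known limitations

* The three EMT score formulas are conventional mappings of ambiguous names;
  directions are asserted on planted data, not against published score
  values.
* The rank-selection combination rule is one reasonable operationalization;
  a different rule can change the chosen rank on marginal data.
* Per-cohort median/MAD standardization assumes the subtype mixture of an
  incoming cohort is not radically different from training; a cohort of one
  subtype would be mis-scaled.
* The purity correction is linear and gene-wise; shared stromal factors
  beyond purity are not modeled.
* Synthetic validation only: no claim about real-cohort accuracy, and no
  clinical claim about nominated drugs.
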