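---
title: "Explainable CNN prioritization of case-control GWAS variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable CNN prioritization of case-control GWAS variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-locus genome-wide association scans rank variants by marginal
p-values. For phenotype *prediction*, however, the most useful SNP panel is
often not the handful of genome-wide-significant hits: variants of
intermediate significance can carry complementary information. `gwasxplain`
implements a two-step explainable-AI workflow for case-control genotype
data that addresses exactly this gap:

1. **Association-guided screening.** A covariate-adjusted per-SNP logistic
   scan produces nested SNP subsets at a ladder of p-value thresholds
   (5e-2 down to 5e-8). A small one-dimensional convolutional network
   (CNN) is trained to classify case status from each subset under a
   stratified 50/25/25 train/validation/test split, and the subset whose
   model achieves the highest validation accuracy is selected.
2. **Attribution-based prioritization.** Deep SHAP attributions (DeepLIFT
   rescale multipliers averaged over a background sample) of the selected
   model are aggregated into a per-SNP *contribution score* — the mean
   absolute attribution over test-set cases the model classified
   correctly — which ranks variants by their influence on prediction.
   Prediction is then re-evaluated with only the top-k ranked SNPs.

Everything is testable end to end because the package ships a synthetic
genotype simulator with planted causal SNPs.

# The synthetic cohort generator

`sim_config()` / `simulate_dataset()` generate a case-control cohort with
the statistical structure the analysis assumes:

* **Genotypes.** Biallelic SNPs with ancestral minor-allele frequencies
  drawn uniformly from a configurable range. Population structure follows
  the Balding–Nichols model: subpopulation allele frequencies are drawn
  from `Beta(p(1-F)/F, (1-p)(1-F)/F)` for divergence `F` (Wright's Fst),
  and genotypes are `Binomial(2, p_s)` within subpopulations, i.e.
  Hardy–Weinberg equilibrium holds within each subpopulation and the
  empirical between-subpopulation Fst concentrates around `F`.
* **Phenotype.** Case status follows a logistic model
  `logit P(case) = b0 + sum_j beta_j g_j + gamma_age (age - mean) +
  gamma_sex sex`. The intercept `b0` is calibrated by bisection so the
  expected case fraction matches the target (default 17.6%, the case
  share of a post-surgical sepsis case-control design with 750 cases and
  3,500 population controls). A population logistic model with a
  calibrated intercept was chosen over case-quota sampling because it is
  simpler and yields an analytic null.
* **Covariate confounding.** Cases end up older and more often male
  through `gamma_age = 0.08` per year (age mean 50, sd 15, truncated at
  18) and `gamma_sex = 0.45` — confounding is produced through the
  disease model, not through separate per-class age distributions, which
  would be circular. These values emulate the strong age and moderate sex
  imbalance typical of surgical-cohort-versus-population-control designs.
* **Causal SNPs.** A configurable number of variants receive per-allele
  log odds ratios of uniform magnitude (default between ln 2 and ln 3)
  and random sign. Positions are uniform over the panel; no linkage
  disequilibrium is simulated by default.

What the generator deliberately does **not** emulate: real LD maps,
imputation artefacts, chip ascertainment, sex chromosomes, or clinical
covariates beyond age and sex. Tests passing on this generator therefore
demonstrate correctness of the machinery and recoverability of additive
signal under confounding and structure — not performance on real
genotyping data.

The default end-to-end demonstration size is n = 2,000 subjects and
m = 1,000 SNPs with 10 causal variants; these sizes keep a full pipeline
run in the tens of seconds on a single core while leaving enough power
that every stage's behaviour is measurable.

# Quality control

Filters run in a fixed order — sample call rate, SNP call rate, minor
allele frequency, Hardy–Weinberg equilibrium in controls — each against
the survivors of the previous step, with every removal recorded with its
reason. Defaults (`qc_config()`): call rates at least 0.95, MAF at least
0.01, HWE p at least 1e-6; conventional GWAS values, all overridable.

Two deliberate simplifications: HWE uses the 1-df chi-square test rather
than the exact test (adequate at desk-scale counts, and closed-form
testable), and residual missingness is mean-imputed per SNP rather than
mode-imputed, so dosage information is preserved for the standardization
the classifier applies anyway.

# The association scan

Each SNP is tested in an additive logistic model adjusted for centered
age, sex, and the top two genotype principal components, fitted by
iteratively reweighted least squares (`glm.fit`, at most 50 iterations).
P-values are two-sided Wald (the convention of standard GWAS software for
logistic scans; whether the original analyses used Wald or
likelihood-ratio p-values is not documented, so Wald is the declared
choice). Monomorphic SNPs, non-converged fits and quasi-complete
separation are flagged and excluded from threshold subsets rather than
Firth-corrected — at desk scale such SNPs are artefacts, and Firth
correction is listed as a non-goal.

PCs are computed on standardized dosages `(g - 2p)/sqrt(2p(1-p))` via the
eigendecomposition of the SNP covariance, with a deterministic sign
convention (largest-magnitude loading positive). No LD pruning is applied
before PCA because the simulator generates no LD; a pruning hook exists in
the configuration. Threshold subsets use strict inequality (`p < tau`) and
are nested by construction.

# The classifier

The CNN is implemented directly in base R matrix code (there is no deep
learning framework dependency): repeated blocks of 1-D convolution →
ReLU → average pooling over the SNP axis, then a dense ReLU layer with
dropout and a single logistic output. Default architecture: two blocks of
16 and 32 filters, kernel width 5, pool width 2, 32 dense units, dropout
0.3, Adam at learning rate 1e-3, batch size 32, at most 200 epochs with
early stopping after 10 epochs without validation-loss improvement and
restoration of the best-epoch weights. The SNP axis is ordered by genomic
position, so convolution locality is genomic locality — an interpretive
choice, documented rather than claimed optimal. For inputs shorter than
the kernel the effective kernel shrinks to the input length and pooling
is skipped below the pool width, so subsets down to a single SNP remain
trainable.

Two design choices deserve explanation:

* **Average pooling instead of max pooling.** Average pooling is linear,
  so every layer except ReLU is exactly linear. The DeepLIFT rescale rule
  is exact for single-input nonlinearities, which makes the Deep SHAP
  completeness identity hold to float precision (see below). Max pooling
  admits no exact single-input rescale rule and would turn a hard
  algebraic identity into an approximation.
* **Class weighting plus prior correction.** Class imbalance (about 17.6%
  cases) is handled by weighting the binary cross-entropy inversely to
  class frequency. A network trained this way estimates the posterior
  under a *balanced* prevalence, so its raw output is mis-calibrated for
  the natural cohort: at the usual 0.5 probability threshold, accuracy
  would fall below the trivial always-control classifier. Predictions are
  therefore prior-corrected — the logit is shifted by
  `log(n_case/n_control)` of the training split — which restores
  natural-prevalence probabilities, keeps the 0.5 decision threshold
  meaningful, and makes validation-accuracy-based model selection
  consistent with the metric definitions. The decision threshold remains
  configurable, since in screening applications one may prefer
  sensitivity over specificity.

Model selection trains one classifier per non-empty threshold subset with
identical splits and seed, picks the highest validation accuracy, and
breaks exact ties toward the smaller subset (parsimony). Test metrics
(sensitivity, specificity, accuracy, rank-based AUC with ties counted
0.5, and the diagnostic odds ratio with a +0.5 continuity correction when
a confusion cell is zero) are computed once, for the selected model only.

# Deep SHAP attributions and the contribution score

For each background reference `b` (default: 100 samples drawn uniformly
from the training split, both classes), DeepLIFT multipliers are
propagated from the model's pre-sigmoid output to the inputs — linear
rule for convolution, pooling and dense layers, rescale rule
(delta-activation over delta-preactivation) for ReLU — yielding
per-reference attributions `phi^(b)_ij = m_ij (x_ij - b_j)` that satisfy
`sum_j phi^(b)_ij = f(x_i) - f(b)` exactly. Averaging over the background
gives the Deep SHAP estimate, and completeness against
`baseline = mean_b f(b)` is asserted to 1e-4 for every subject at
construction — a violation signals an unsupported layer type rather than
being silently accepted.

Attribution operates on the logit (pre-sigmoid) output, where the final
layer is linear and the rescale rule is exact; the unit is recorded in
the result. For a purely linear model the construction reduces to the
closed form `phi_ij = w_j (x_ij - mean_b b_j)`, which the tests verify.

The contribution score of SNP j is the mean of `|phi_ij|` over the
aggregation set — test-set subjects whose true label is case and whose
predicted probability reaches the decision threshold (true positives).
Mean-of-absolute was chosen over absolute-of-mean because per-subject
attributions of a given SNP change sign with genotype, and the published
convention this score follows reports strictly positive values. Ranks
break ties by ascending association p-value, then SNP id, so ranking is
fully deterministic.

Top-k re-evaluation retrains the classifier from scratch on the top-k
ranked SNPs with the same splits and seed (the stricter, leakage-free
reading; an input-masking mode is available behind a flag for
comparison). Default k values are 3 and 20.

# Numerical choices and degenerate inputs

* IRLS convergence: deviance tolerance 1e-10, 50 iterations; separation
  flagged at `|beta| > 15` or `se > 100`.
* Intercept bisection: bracket [-30, 30], tolerance 1e-6, verified to
  reach the target case fraction within 1e-4; non-bracketing (extreme
  effect sizes) raises with a diagnostic.
* ReLU rescale fallback: where the preactivation delta is below 1e-9 the
  multiplier falls back to the activation derivative (completeness is
  unaffected because the corresponding output delta is zero).
* Zero-variance SNPs in the training split are dropped from the encoder
  with a warning; monomorphic SNPs are dropped from PCA input.
* Empty threshold subsets are skipped with a warning; an empty
  aggregation set (no true positives) skips attribution with a warning
  rather than failing the run.
* All randomness is seeded through a single master seed from which stage
  seeds are derived; identical configuration implies byte-identical
  results, including CNN weights.

# Known limitations

* The association scan runs on the full cohort before the
  train/validation/test split, mirroring the published workflow in which
  the genome-wide scan precedes classifier training. This means threshold
  subsets are selected with knowledge of all labels: under a pure null,
  SNPs passing a stringent threshold retain a positive expected
  association in every split (conditional on a small full-data p-value,
  the test-split z-statistic has expectation about
  `sqrt(n_test/n_total)` times the full-data one), so null models trained
  on such subsets score a few AUC points above chance. A training-only
  scan would remove this optimism but depart from the procedure the
  package implements; users wanting strict nested validation should scan
  inside the training split.
* Accuracy-based model selection is noisy at desk scale: with a few
  hundred validation samples and moderate genotype signal, the 7
  threshold models often differ by only one or two correctly classified
  subjects, so which subset wins can be effectively random (and exact
  ties resolve to the smallest subset). When a stringent subset wins, the
  contribution ranking covers only the SNPs that passed that threshold.
  On real cohort-scale data with strong signal, validation-accuracy
  margins between subsets dwarf this noise.
* The CNN sees genotypes only; heavily covariate-driven case status (as
  simulated here, where age carries substantial risk) bounds the
  achievable AUC well below 1 by design.
* The simulator's lack of LD means PCA needs no pruning and convolution
  locality carries no correlation structure; both would need revisiting
  for real data.
* HWE chi-square is anti-conservative for very rare variants; the MAF
  filter runs first, which bounds the distortion at default thresholds.
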