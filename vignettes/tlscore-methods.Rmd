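---
title: "Deriving and validating a TLS signature score"
author: "tlscore"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tertiary lymphoid structures (TLS) — ectopic aggregates of T and B cells that
form in tumor tissue — are associated with better prognosis and stronger
response to immune checkpoint blockade in head and neck squamous cell
carcinoma and other solid tumors. Histology detects them sample by sample;
`tlscore` instead quantifies TLS activity from bulk expression with a
per-patient score derived from a 23-gene TLS-related signature (6 chemokines,
2 chemokine receptors, 2 cytokines, 4 transcription factors,
4 co-stimulatory molecules, 2 inhibitory receptors, 2 cytokine receptors and
one ECM-associated molecule; `tls_signature()`).

# The derivation chain

`run_derivation()` executes the chain end to end; each stage is also exposed
on its own.

1. **Preprocessing.** FPKM input is converted to TPM
   (`TPM_gs = FPKM_gs / sum_g FPKM_gs * 1e6`), log2-transformed with a
   pseudocount of 1, and batch-corrected when cohorts are merged
   (`combat_correct()`): the parametric empirical-Bayes location/scale model —
   genes standardized by grand mean and pooled variance, per-batch gene
   effects shrunk toward normal / inverse-gamma priors fitted by moments,
   corrected values back-transformed. Batch correction is performed on the
   log scale (the standard practice; recorded in provenance output).
2. **TLS patterns.** Samples are consensus-clustered on the signature genes:
   `n_reps` (default 1000) subsamples of 80% of samples, hierarchical
   clustering with (1 − Pearson) distance and average linkage, co-assignment
   frequencies accumulated into per-k consensus matrices. The cluster number
   k in 2..9 minimizes the proportion of ambiguous clustering,
   `PAC = F(0.9) − F(0.1)` of the off-diagonal consensus CDF, ties toward
   smaller k.
3. **Differential expression.** Moderated t between the two TLS patterns
   (empirical-Bayes variance shrinkage with prior df fitted by
   digamma/trigamma moment matching), Benjamini–Hochberg adjustment, genes
   kept at adjusted p < 0.01.
4. **Gene clusters and prognostic screen.** Samples are re-clustered on those
   DEGs; a second moderated-t pass between the gene clusters feeds a
   univariate Cox screen (Efron ties, Newton–Raphson, Wald p < 0.05).
5. **The score.** Surviving prognostic genes are z-scored (population
   denominator) and decomposed by SVD; with unit-norm gene loadings
   \(u_1, u_2\) the score of sample \(s\) is
   \[
   \mathrm{TLSscore}_s \;=\; \mathrm{PC1}_s - \mathrm{PC2}_s
   \;=\; \sum_i u_{1i} z_{is} \;-\; \sum_i u_{2i} z_{is}.
   \]
   New cohorts are standardized with the stored means/sds — no refitting.
6. **Dichotomization.** The cutpoint maximizes the absolute standardized
   two-group log-rank statistic over all distinct score values between the
   10% and 90% score quantiles; `high` means strictly above the cutpoint.

## Sign conventions

SVD signs are arbitrary, so the score would otherwise flip between runs.
Component 1 is anchored so its mean loading over the favorable genes
(univariate hazard ratio < 1) is positive: a high score then tracks the
favorable block, and the high group has the better prognosis. Because
component scores are empirically orthogonal on the training cohort, the
correlation of PC1 − PC2 with PC1 is non-negative for either sign of
component 2; we anchor component 2 by the same favorable-gene rule, which is
deterministic and documented in the serialized model.

## Other numerical choices

* **PAC window (0.1, 0.9)**, counted as `lower < x <= upper` — the standard
  published choice.
* **Consensus features are row-standardized** before the sample distances so
  each gene weighs equally.
* **Efron tie handling** in all Cox fits (more accurate than Breslow when
  event times tie); convergence at |Δ log-likelihood| < 1e-9, 50 iterations,
  step-halving; monotone likelihood detected by |beta| escaping 20 —
  reported capped with `converged = FALSE`.
* **Maxstat is not multiplicity-corrected**: the cutpoint only defines
  groups, so the selection-inflated statistic is never interpreted as a
  test; a permutation reference is available by permuting scores.
* **Never-co-sampled pairs** get consensus 0 with a warning (vanishingly
  rare at 1000 reps × 80%).
* **Zero-variance genes** cannot be standardized and pass through batch
  correction untouched (warned, not dropped); in the moderated t they are
  rescued by the variance prior and flagged.
* When PAC chooses k > 2, the DEG stages compare the two largest clusters
  with a warning — the derivation is defined for two patterns.
* **TMB** counts non-silent MAF classifications per 38 Mb of exome (the
  common capture convention; `exome_mb = 1` gives raw counts).

# Companion modules

**ssGSEA** (`ssgsea()`): per sample, genes ranked descending, enrichment =
sum over positions of the rank-weighted in-set ECDF (weights `rank^alpha`,
alpha = 0.25, the original choice) minus the unweighted out-of-set ECDF.
Scores are rank-based, hence invariant to monotone transforms, and depend
only on the sample's own column. `estimate_scores()` maps the stromal+immune
enrichment sum to purity via the published cosine calibration
`cos(0.6049872018 + 0.0001467884 * estimate)`; the constants were calibrated
on a different platform's score scale, so purity from arbitrary gene sets is
indicative. The genuine ESTIMATE gene lists are not redistributed — any GMT
is accepted and the packaged demo sets are synthetic.

**Single cell** (`qc_filter()`, `normalize_log1p()`, `select_hvgs()`,
`module_score()`): QC removes cells with UMI above 50,000 or below 1,000,
detected genes above 5,000 or below 300, hemoglobin fraction > 5% or
mitochondrial fraction > 15% — all strict inequalities, so boundary cells are
retained. Normalization is `ln(1 + 1e4 x / total)`. The module score bins
genes into 24 equal-count bins of average expression and subtracts, per
cell, the mean of 100 bin-matched control genes per module gene from the
mean module expression. Control draws are seeded and gene-order invariant
(id-stable ranks, sorted pools). Adding a constant c to module genes raises
scores by approximately (not exactly) c: the shift also moves module genes
into higher-expression bins, a property shared by the reference
implementation of binned-control scoring.

# The synthetic cohort generator

The generator (`cohort_spec()`, `generate_bulk_cohort()`,
`generate_mutation_table()`, `generate_single_cell()`) supplies ground truth
for every claim the tests make. It emulates:

* two latent TLS states, with per-gene signature shifts of magnitude
  `delta * U(0.5, 1.5)` and 15% of signature genes shifted opposite to the
  rest — real signatures mix favorable and adverse genes, and a
  direction-varying shift is what correlation-based sample distances can
  see (a uniform profile shift cancels in the Pearson correlation);
* exponential survival with log-hazard `beta_surv` per unit latent score.
  The default is −0.7: the high-signature state is protective, so the
  favorable-anchored score correlates positively with the latent score and
  negatively with mutation burden, reproducing the observed geometry
  (protective hazard ratio ≈ 0.5; negative score–TMB correlation).
  Censoring is Uniform(0, τ) with τ solved numerically for the target
  censoring fraction (default 30%);
* batch location/scale effects across three cohorts (defaults +0.5 log2
  per batch step, ×1.2 residual scale);
* negative-binomial mutation counts with log-mean `log(100) +
  tmb_beta * latent_score` (about 2.6 nonsynonymous mutations/Mb), plus 15%
  silent records to exercise classification filters;
* negative-binomial single-cell counts over lognormal gene weights with a
  4× module enrichment in one type, ~3% baseline mitochondrial and ~0.5%
  hemoglobin content (spread evenly within each family so healthy cells stay
  clear of the fraction thresholds), and planted QC violators (10% of cells) whose
  violating quantity is drawn far beyond its threshold with low dispersion,
  so the QC filter's removals can be checked cell-for-cell.

Exponential survival (rather than Weibull) keeps closed-form checks simple;
expression is generated directly on the log-TPM scale and `as_fpkm_like()`
inverts it with arbitrary per-sample factors to exercise the FPKM path.

What it does **not** emulate: dropout structure beyond NB sampling, doublets,
copy-number or spatial structure, gene–gene correlation beyond the signature
block, non-proportional hazards, informative censoring. Passing tests
demonstrate internal correctness and recoverability under this model, not
performance on real cohorts; effect sizes are calibration choices, not
estimates of tumor biology.

# Problem sizes used in validation

The test-suite and acceptance runs use a 300-sample, 1000-gene cohort with
delta = 2 and 100 consensus repetitions (the scientific conclusions are
insensitive to more repetitions; 1000 remains the pipeline default), a
100 × 2000 null cohort for type-I calibration, 200 replicates of n = 500 for
Cox interval coverage, and 500 cells × 600 genes for the single-cell
contract. Under these conditions the pipeline recovers the latent states
with adjusted Rand index ≈ 0.97, scores correlating with the latent score at
|r| ≈ 0.88, a high/low log-rank p ≪ 0.01, and a negative score–TMB
correlation — directions matching the study the methodology derives from.
Per-gene Cox screening power is the binding constraint at these settings:
occasional seeds yield few prognostic genes and a weaker score, which is a
property of the simulated conditions rather than of the estimator.

# Known limitations

* The derivation assumes two TLS patterns; more patterns degrade to a
  two-largest-cluster comparison.
* The score is linear; signatures whose effect is non-monotone in expression
  are out of scope.
* Multivariate Cox uses one-hot factor coding with first-level reference and
  no interactions, proportionality diagnostics, or time-dependent
  covariates.
* ssGSEA here serves both the cell-infiltration and pathway roles;
  kernel-density variants and deconvolution methods are deliberately not
  implemented.
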