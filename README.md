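# tlscore

Tertiary lymphoid structures (TLS) — ectopic T/B-cell aggregates in tumor
tissue — mark patients with better prognosis and stronger response to immune
checkpoint blockade, but histology sees them one section at a time. `tlscore`
derives a per-patient **TLS activity score** from bulk tumor transcriptomes,
for bioinformaticians reproducing or extending TLS signature analyses in
head-and-neck and other solid tumors.

## The method

Starting from a packaged 23-gene TLS-related signature (chemokines CCL18/19/
20/21, CXCL9, CXCL13; receptors CCR5, CXCR3; cytokines IL10, CSF2;
transcription factors CD200, GFI1, IRF4, STAT5A; co-stimulatory molecules
ICOS, CD38, CD40, SH2D1A; inhibitory receptors TIGIT, PDCD1; cytokine
receptors IL2RA, IL1R2; FBLN7), the derivation chain is:

1. FPKM → TPM → log2, empirical-Bayes batch correction across cohorts;
2. consensus clustering of samples on the signature genes (1000 subsampling
   repetitions at 80%), cluster number k chosen by minimal **PAC**
   (proportion of ambiguous clustering, the consensus CDF mass in
   (0.1, 0.9]);
3. moderated-t differential expression between the TLS patterns
   (BH-adjusted p < 0.01), re-clustering on those genes, a second DEG pass,
   and a univariate Cox screen (Efron ties, p < 0.05) for prognostic genes;
4. PCA over the prognostic genes (z-scored), with the score

   TLSscore_s = PC1_s − PC2_s = Σ_i u1_i z_is − Σ_i u2_i z_is,

   components sign-anchored to the favorable (HR < 1) genes so a high score
   means good prognosis;
5. dichotomization at the maximally selected log-rank cutpoint, and
   integration with tumor mutational burden (four score×TMB strata).

Companion modules provide ssGSEA (rank-weighted single-sample enrichment,
α = 0.25), ESTIMATE-style stromal/immune/purity scores, Kaplan–Meier /
log-rank / Cox machinery built from scratch, single-cell QC at fixed
thresholds with binned-control module scoring, and a synthetic cohort
generator with full ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
meta-cohort (300 patients, 1000 genes, three batches, two latent TLS states):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_derive_signature.R
Rscript analysis/03_immune_scores.R
Rscript analysis/04_single_cell_scores.R
```

`02_derive_signature.R` prints, for the default seed:

```
TLS clusters: chosen k = 3 (PAC 0.120)
DEGs between TLS patterns: 23 (adj p < 0.01)
gene clusters: chosen k = 3; second-pass DEGs: 23
prognostic genes (Cox p < 0.05): 11
score cutpoint 0.699 -> 135 high / 165 low; log-rank p = 2.95e-06
score vs latent score: r = 0.870
score vs TMB: Pearson r = -0.348 (p = 5.57e-10); 4-stratum log-rank p = 6.38e-05
```

Reading: consensus clustering recovers the two planted TLS states (PAC
selects k = 3 here, but the third cluster holds only two stray samples, so
the derivation proceeds on the two dominant patterns — adjusted Rand index
0.97 against truth); the 23 signature genes (and only they) pass the DEG
screen; the PCA score tracks
the latent TLS axis (r = 0.87); splitting at the maxstat cutpoint separates
survival sharply (log-rank p ≈ 3e−6); and the score anti-correlates with
mutation burden, so crossing it with TMB refines the stratification —
the directional pattern the methodology was built to capture. Equivalent
calls in R:

```r
library(tlscore)
spec <- cohort_spec(seed = 1)
coh  <- generate_bulk_cohort(spec)
art  <- run_derivation(coh$expression, coh$clinical,
                       signature_genes = coh$truth$signature_gene_ids,
                       config = pipeline_config(n_reps = 100, seed = 1),
                       mutations = generate_mutation_table(spec, coh$truth))
art$logrank$p
```

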