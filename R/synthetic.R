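# Synthetic cohorts with known ground truth. Two latent TLS states separated
# by a mean shift on a signature gene block, exponential survival tied to the
# latent score, cross-batch location/scale effects, negative-binomial mutation
# counts anti-correlated with the score, and NB single-cell counts with a
# module-enriched cell type. Every generator pins the RNG kind so a fixed
# seed gives bit-identical output across platforms.

.pin_rng <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Specification of a synthetic bulk cohort
#'
#' Defaults describe the simulated study conditions used throughout the
#' package's validation: a 300-patient, 1000-gene cohort with a 23-gene
#' signature block shifted by 2 log2 units in latent state B, three batches
#' with modest location/scale effects, exponential survival with log-hazard
#' magnitude 0.7 per unit latent score (protective: the high-signature state
#' has the better prognosis, mirroring a hazard ratio near 0.5 per unit
#' score), 30% censoring, and mutation burden declining with the latent
#' score (so the favorable state carries fewer mutations).
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_signature_genes genes carrying the latent-state shift (default 23,
#'   the size of the TLS signature).
#' @param effect_size mean log2-expression shift (delta) of signature genes in
#'   state B.
#' @param prop_state_B expected fraction of samples in latent state B.
#' @param n_batches number of batches (cohorts merged into the meta-cohort).
#' @param batch_shift additive location offset per batch step (log2 units).
#' @param batch_scale multiplicative residual-scale factor per batch step.
#' @param baseline_hazard exponential baseline hazard (per time unit).
#' @param beta_surv log-hazard per unit latent score.
#' @param censor_rate target fraction of censored samples, in [0, 1).
#' @param tmb_beta slope of log mean mutation count on the latent score
#'   (negative mirrors the observed score-TMB anti-correlation).
#' @param seed integer RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300L, n_genes = 1000L,
                        n_signature_genes = 23L, effect_size = 2,
                        prop_state_B = 0.5, n_batches = 3L,
                        batch_shift = 0.5, batch_scale = 1.2,
                        baseline_hazard = 0.02, beta_surv = -0.7,
                        censor_rate = 0.3, tmb_beta = -0.6, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               n_signature_genes = as.integer(n_signature_genes),
               effect_size = effect_size, prop_state_B = prop_state_B,
               n_batches = as.integer(n_batches), batch_shift = batch_shift,
               batch_scale = batch_scale, baseline_hazard = baseline_hazard,
               beta_surv = beta_surv, censor_rate = censor_rate,
               tmb_beta = tmb_beta, seed = as.integer(seed))
  num <- unlist(spec[setdiff(names(spec), character())])
  if (any(!is.finite(num))) stop("non-finite values in cohort spec")
  if (spec$n_samples < 2L || spec$n_genes < 1L) stop("cohort too small")
  if (spec$n_signature_genes > spec$n_genes)
    stop("n_signature_genes exceeds n_genes")
  if (spec$prop_state_B <= 0 || spec$prop_state_B >= 1)
    stop("prop_state_B must lie in (0,1)")
  if (spec$censor_rate < 0 || spec$censor_rate >= 1)
    stop("censor_rate must lie in [0,1)")
  if (spec$batch_scale <= 0 || spec$baseline_hazard <= 0)
    stop("batch_scale and baseline_hazard must be positive")
  if (spec$n_batches < 1L) stop("n_batches must be >= 1")
  structure(spec, class = "cohort_spec")
}

#' Generate a bulk expression cohort with ground truth
#'
#' Expression is drawn directly on the log2-TPM scale: gene g in sample s is
#' `mu_g + shift_g * I(state B, signature gene) + batch location + scaled
#' Gaussian noise`, where the per-gene shift has magnitude
#' `delta * Uniform(0.5, 1.5)` and a minority (15%) of signature genes shift
#' downward in state B. The latent score is the centered state indicator
#' `I(state B) - prop_state_B`; survival times are exponential with hazard
#' `baseline_hazard * exp(beta_surv * latent_score)` and censoring times are
#' Uniform(0, tau) with tau solved numerically to hit the target censoring
#' fraction in expectation.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `expression` (an [expression_matrix()], unit
#'   `"logTPM"`, batch labels attached), `clinical` (a `data.frame` with
#'   `sample_id`, `time`, `event`, `age`, `gender`, `stage`) and `truth`
#'   (per-sample `latent_state`, `latent_score`, `batch`, plus
#'   `signature_gene_ids`).
#' @export
generate_bulk_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .pin_rng(spec$seed)
  n <- spec$n_samples; G <- spec$n_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  sig_ids <- sprintf("SIG%03d", seq_len(spec$n_signature_genes))
  bg_ids <- sprintf("G%05d", seq_len(G - spec$n_signature_genes))
  gene_ids <- c(sig_ids, bg_ids)

  state <- ifelse(stats::runif(n) < spec$prop_state_B, "B", "A")
  latent_score <- as.numeric(state == "B") - spec$prop_state_B
  batch <- paste0("batch", rep_len(seq_len(spec$n_batches), n))

  mu <- stats::runif(G, 2, 8)
  sigma <- c(rep(1, spec$n_signature_genes),
             stats::runif(G - spec$n_signature_genes, 0.5, 1.5))
  bstep <- match(batch, paste0("batch", seq_len(spec$n_batches))) - 1L
  noise <- matrix(stats::rnorm(G * n), G, n)
  X <- mu + sigma * noise %*% diag(spec$batch_scale^bstep, n)
  X <- X + rep(spec$batch_shift * bstep, each = G)
  # Heterogeneous signature shift with a minority of genes moving the other
  # way, mirroring real signatures' favorable/adverse gene mix; a direction-
  # and magnitude-varying shift is also what makes the latent states visible
  # to correlation-based sample distances (a uniform profile shift cancels in
  # the Pearson correlation).
  n_sig <- spec$n_signature_genes
  n_down <- if (n_sig >= 7L) max(1L, round(0.15 * n_sig)) else 0L
  sig_dir <- rep(1, n_sig)
  if (n_down > 0L) sig_dir[seq_len(n_down)] <- -1
  sig_mag <- stats::runif(n_sig, 0.5, 1.5)
  shift <- spec$effect_size * sig_dir * sig_mag
  X[seq_len(n_sig), state == "B"] <- X[seq_len(n_sig), state == "B"] + shift
  dimnames(X) <- list(gene_ids, sample_ids)

  lambda <- spec$baseline_hazard * exp(spec$beta_surv * latent_score)
  t_event <- stats::rexp(n, rate = lambda)
  if (spec$censor_rate > 0) {
    # P(censored_i) = P(T_i > C_i) with C ~ U(0, tau):
    # (1/tau) int_0^tau exp(-lambda t) dt = (1 - exp(-lambda tau))/(lambda tau)
    cens_frac <- function(tau) mean((1 - exp(-lambda * tau)) / (lambda * tau))
    tau <- stats::uniroot(function(tau) cens_frac(tau) - spec$censor_rate,
                          lower = 1e-6, upper = 1e8, tol = 1e-8)$root
    c_time <- stats::runif(n, 0, tau)
  } else {
    c_time <- rep(Inf, n)
  }
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)

  clinical <- data.frame(
    sample_id = sample_ids,
    time = time,
    event = event,
    age = round(stats::rnorm(n, 62, 10)),
    gender = sample(c("male", "female"), n, replace = TRUE, prob = c(0.7, 0.3)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  truth <- list(latent_state = stats::setNames(state, sample_ids),
                latent_score = stats::setNames(latent_score, sample_ids),
                batch = stats::setNames(batch, sample_ids),
                signature_gene_ids = sig_ids,
                signature_shift = stats::setNames(shift, sig_ids))

  list(expression = expression_matrix(X, "logTPM", batch = batch),
       clinical = clinical, truth = truth)
}

#' Turn a log-TPM matrix into FPKM-like input
#'
#' Inverts the log transform and rescales each sample by an arbitrary positive
#' factor, producing input on which [fpkm_to_tpm()] has real work to do (TPM is
#' invariant to per-sample rescaling of FPKM).
#'
#' @param m an [expression_matrix()] with unit `"logTPM"`.
#' @param seed RNG seed for the per-sample scale factors.
#' @return An [expression_matrix()] with unit `"FPKM"`.
#' @export
as_fpkm_like <- function(m, seed = 1L) {
  tpm <- inverse_log_transform(m)
  .pin_rng(seed)
  fac <- stats::runif(ncol(tpm$values), 0.2, 5)
  expression_matrix(sweep(tpm$values, 2, fac, "*"), "FPKM", batch = m$batch)
}

#' Generate a MAF-like mutation table tied to the latent score
#'
#' Per-sample nonsynonymous mutation counts are negative binomial with log
#' mean `tmb_alpha + tmb_beta * latent_score`; silent mutations are appended
#' at a fixed fraction of the nonsynonymous mean so classification filters are
#' exercised.
#'
#' @param spec a [cohort_spec()] (supplies `tmb_beta` and the seed).
#' @param truth ground truth from [generate_bulk_cohort()].
#' @param tmb_alpha intercept of the log mean nonsynonymous count
#'   (default `log(100)`, i.e. about 100 mutations, ~2.6/Mb over a 38 Mb
#'   exome). `-Inf` gives all-zero counts.
#' @param tmb_size negative-binomial size (inverse overdispersion).
#' @param silent_frac silent mutations as a fraction of the nonsynonymous
#'   mean (Poisson).
#' @return A `data.frame` with columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `Variant_Classification`; the per-sample nonsynonymous counts are
#'   attached as attribute `"nonsyn_counts"`.
#' @export
generate_mutation_table <- function(spec, truth, tmb_alpha = log(100),
                                    tmb_size = 2, silent_frac = 0.15) {
  stopifnot(inherits(spec, "cohort_spec"))
  .pin_rng(spec$seed + 104729L)
  samples <- names(truth$latent_score)
  mu <- exp(tmb_alpha + spec$tmb_beta * truth$latent_score)
  counts <- stats::rnbinom(length(mu), size = tmb_size, mu = mu)
  counts[mu == 0] <- 0L
  silent <- stats::rpois(length(mu), silent_frac * mu)
  silent[mu == 0] <- 0L

  nonsyn_classes <- c(Missense_Mutation = 0.70, Nonsense_Mutation = 0.09,
                      Frame_Shift_Del = 0.06, Frame_Shift_Ins = 0.05,
                      Splice_Site = 0.06, In_Frame_Del = 0.04)
  genes <- c(truth$signature_gene_ids,
             sprintf("G%05d", seq_len(max(1L, spec$n_genes - length(truth$signature_gene_ids)))))
  total <- sum(counts) + sum(silent)
  if (total == 0L) {
    return(structure(data.frame(Tumor_Sample_Barcode = character(),
                                Hugo_Symbol = character(),
                                Variant_Classification = character()),
                     nonsyn_counts = stats::setNames(counts, samples)))
  }
  tab <- data.frame(
    Tumor_Sample_Barcode = c(rep(samples, counts), rep(samples, silent)),
    Hugo_Symbol = sample(genes, total, replace = TRUE),
    Variant_Classification = c(
      sample(names(nonsyn_classes), sum(counts), replace = TRUE,
             prob = nonsyn_classes),
      rep("Silent", sum(silent))),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$Tumor_Sample_Barcode), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, nonsyn_counts = stats::setNames(counts, samples))
}

#' Generate a synthetic single-cell count matrix
#'
#' Negative-binomial counts over lognormal gene weights; module genes get
#' their weight multiplied by `enrichment` in the enriched cell type. A
#' configurable fraction of cells is planted to violate one QC rule each
#' (excess/deficient library size, high mitochondrial fraction, high
#' hemoglobin fraction) with wide margins, so the QC filter's removals can be
#' checked against the plant list. Mitochondrial and hemoglobin genes are
#' named `MT-1..` and `HBA1/HBA2/HBB`.
#'
#' @param n_cells,n_genes matrix dimensions (`n_genes` includes the module,
#'   mitochondrial and hemoglobin genes).
#' @param cell_type_props named proportions of cell types (must sum to 1).
#' @param module_genes gene ids forming the scored module (created if absent
#'   from the generic ids).
#' @param enriched_type name of the type with elevated module expression.
#' @param seed integer RNG seed.
#' @param enrichment multiplicative weight factor for module genes in the
#'   enriched type (1 = null).
#' @param qc_violation_frac fraction of cells planted as QC violators.
#' @return A [cell_matrix()] with `cell_type` labels and a per-cell
#'   `qc_violation` attribute (`"none"` or the planted violation mode).
#' @export
generate_single_cell <- function(n_cells, n_genes, cell_type_props,
                                 module_genes, enriched_type, seed = 1L,
                                 enrichment = 4, qc_violation_frac = 0.1) {
  if (length(module_genes) == 0L) stop("empty module gene set")
  if (abs(sum(cell_type_props) - 1) > 1e-8)
    stop("cell_type_props must sum to 1")
  if (!enriched_type %in% names(cell_type_props))
    stop("enriched_type not among cell types")
  .pin_rng(seed)

  mito_genes <- sprintf("MT-%d", 1:10)
  hgb_genes <- c("HBA1", "HBA2", "HBB")
  n_other <- n_genes - length(module_genes) - length(mito_genes) - length(hgb_genes)
  if (n_other < 0L) stop("n_genes too small for module + QC genes")
  gene_ids <- c(module_genes, mito_genes, hgb_genes,
                if (n_other) sprintf("GENE%05d", seq_len(n_other)))

  w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  names(w) <- gene_ids
  # baseline mito ~3% and hemoglobin ~0.5% of counts, spread evenly within
  # each family: concentrated family weights would let sampling noise push a
  # healthy cell over the fraction thresholds
  s_other <- sum(w[setdiff(gene_ids, c(mito_genes, hgb_genes))])
  w[mito_genes] <- s_other * (0.03 / 0.965) / length(mito_genes)
  w[hgb_genes] <- s_other * (0.005 / 0.965) / length(hgb_genes)

  types <- sample(names(cell_type_props), n_cells, replace = TRUE,
                  prob = cell_type_props)
  cell_ids <- sprintf("C%05d", seq_len(n_cells))

  violation <- rep("none", n_cells)
  n_viol <- round(qc_violation_frac * n_cells)
  if (n_viol > 0L) {
    idx <- sample(n_cells, n_viol)
    violation[idx] <- sample(c("umi_high", "umi_low", "mito", "hgb"),
                             n_viol, replace = TRUE)
  }
  lib <- exp(stats::rnorm(n_cells, log(5000), 0.3))
  lib <- pmin(pmax(lib, 2500), 30000)
  lib[violation == "umi_high"] <- stats::runif(sum(violation == "umi_high"), 8e4, 1.5e5)
  lib[violation == "umi_low"] <- stats::runif(sum(violation == "umi_low"), 100, 600)

  boost_share <- function(wi, family, share) {
    wi[family] <- wi[family] / sum(wi[family]) * share / (1 - share) *
      sum(wi[setdiff(names(wi), family)])
    wi
  }
  counts <- matrix(0L, n_cells, n_genes, dimnames = list(cell_ids, gene_ids))
  for (i in seq_len(n_cells)) {
    wi <- w
    size_i <- rep(1, n_genes)
    names(size_i) <- gene_ids
    if (types[i] == enriched_type) wi[module_genes] <- wi[module_genes] * enrichment
    # planted fraction violators: large target share with low dispersion so
    # the realized fraction clears the threshold with certainty
    if (violation[i] == "mito") {
      wi <- boost_share(wi, mito_genes, 0.40)
      size_i[mito_genes] <- 20
    }
    if (violation[i] == "hgb") {
      wi <- boost_share(wi, hgb_genes, 0.25)
      size_i[hgb_genes] <- 20
    }
    mu_i <- lib[i] * wi / sum(wi)
    counts[i, ] <- stats::rnbinom(n_genes, size = size_i, mu = mu_i)
  }
  cm <- cell_matrix(counts, mito_genes = mito_genes, hgb_genes = hgb_genes,
                    cell_type = types, sample = rep("S1", n_cells))
  attr(cm, "qc_violation") <- stats::setNames(violation, cell_ids)
  cm
}
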