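#' Expression simulation scenario
#'
#' Describes a synthetic bulk RNA cohort: samples carry one of
#' `n_programs` latent expression programs; each program has a disjoint
#' block of marker genes whose log2(TPM + 1) values are shifted upward by
#' `marker_effect` in samples of that program; all values then receive
#' Gaussian noise and zero-inflation ("dropout").
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param n_programs Number of latent programs (>= 1).
#' @param markers_per_program Marker genes per program (blocks disjoint).
#' @param marker_effect Mean log2 shift of a program's markers in samples
#'   of that program.
#' @param noise_sd Per-value Gaussian sd on the log2 scale.
#' @param baseline_shape,baseline_scale Gamma parameters of the per-gene
#'   baseline mean (log2 TPM units).
#' @param mixing Program mixing proportions (sum to 1).
#' @param dropout_rate Probability a value is set to 0.
#' @return An `expression_scenario` list.
#' @export
expression_scenario <- function(n_samples, n_genes, n_programs,
                                markers_per_program, marker_effect,
                                noise_sd, baseline_shape = 2,
                                baseline_scale = 2,
                                mixing = rep(1 / n_programs, n_programs),
                                dropout_rate = 0.05) {
  if (n_programs < 1) stop("n_programs must be >= 1", call. = FALSE)
  if (abs(sum(mixing) - 1) > 1e-8 || length(mixing) != n_programs)
    stop("mixing proportions must have length n_programs and sum to 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (markers_per_program * n_programs > n_genes)
    stop("markers_per_program x n_programs exceeds n_genes", call. = FALSE)
  structure(as.list(environment()), class = "expression_scenario")
}

#' Packaged microenvironmental-subtype scenario (3 programs)
#'
#' 120 samples, 800 genes, three equally mixed programs with 60 markers
#' each, marker effect 2.0 log2 units, noise sd 0.6, 5% dropout.
#' @return An `expression_scenario`.
#' @export
m_default_scenario <- function() {
  expression_scenario(n_samples = 120L, n_genes = 800L, n_programs = 3L,
                      markers_per_program = 60L, marker_effect = 2.0,
                      noise_sd = 0.6)
}

#' Packaged tumor-intrinsic-subtype scenario (4 programs)
#'
#' 220 samples, 1000 genes, four programs with uneven mixing
#' (0.35/0.30/0.20/0.15) emulating adeno / squamous / dedifferentiated /
#' neuroendocrine lineage-marker blocks of 60 genes each.
#' @return An `expression_scenario`.
#' @export
ti_default_scenario <- function() {
  expression_scenario(n_samples = 220L, n_genes = 1000L, n_programs = 4L,
                      markers_per_program = 60L, marker_effect = 2.0,
                      noise_sd = 0.6, mixing = c(0.35, 0.30, 0.20, 0.15))
}

#' Simulate a bulk expression cohort
#'
#' @param scenario An [expression_scenario()].
#' @param seed Integer seed.
#' @return List with `expression` (validated genes x samples matrix) and
#'   `truth` (a `cohort_truth`: per-sample program labels, per-program
#'   marker gene blocks, and a features data.frame seeded with the program
#'   label).
#' @export
simulate_expression <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "expression_scenario"))
  set.seed(seed)
  n <- scenario$n_samples; g <- scenario$n_genes; p <- scenario$n_programs
  genes <- sprintf("G%04d", seq_len(g))
  samples <- sprintf("S%03d", seq_len(n))
  program <- sample.int(p, n, replace = TRUE, prob = scenario$mixing)
  baseline <- rgamma(g, shape = scenario$baseline_shape, scale = scenario$baseline_scale)
  marker_blocks <- split(genes[seq_len(p * scenario$markers_per_program)],
                         rep(seq_len(p), each = scenario$markers_per_program))
  values <- matrix(baseline, g, n)
  for (k in seq_len(p)) {
    rows <- match(marker_blocks[[k]], genes)
    cols <- which(program == k)
    if (length(cols)) values[rows, cols] <- values[rows, cols] + scenario$marker_effect
  }
  if (scenario$noise_sd > 0)
    values <- values + matrix(rnorm(g * n, sd = scenario$noise_sd), g, n)
  values <- pmax(values, 0)
  if (scenario$dropout_rate > 0)
    values[matrix(runif(g * n) < scenario$dropout_rate, g, n)] <- 0
  dimnames(values) <- list(genes, samples)
  truth <- cohort_truth(sample_id = samples, program = program,
                        marker_blocks = marker_blocks)
  list(expression = validate_expression_matrix(values), truth = truth)
}

#' Ground truth container for a synthetic cohort
#' @param sample_id Sample identifiers.
#' @param program Integer program labels (or `NULL`).
#' @param marker_blocks Per-program marker gene lists (or `NULL`).
#' @param exposures Samples x signatures exposure matrix (or `NULL`).
#' @param features data.frame of per-sample true feature values.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(sample_id, program = NULL, marker_blocks = NULL,
                         exposures = NULL,
                         features = data.frame(sample_id = sample_id)) {
  if (!is.null(program)) {
    stopifnot(length(program) == length(sample_id), all(program >= 1))
    features$program <- program
  }
  structure(list(sample_id = sample_id, program = program,
                 marker_blocks = marker_blocks, exposures = exposures,
                 features = features),
            class = "cohort_truth")
}

#' Mutational-signature simulation scenario
#'
#' @param reference S x 96 row-stochastic signature matrix (rows sum to 1)
#'   with unique rownames.
#' @param n_samples Number of samples.
#' @param mutation_range Integer range (min, max) of total SBS counts per
#'   sample, drawn uniformly.
#' @param concentration Dirichlet concentration of exposures over the
#'   active signatures.
#' @param max_active Each sample is active in a uniformly chosen random
#'   subset of at most this many signatures (sparsity).
#' @return A `signature_scenario` list.
#' @export
signature_scenario <- function(reference, n_samples,
                               mutation_range = c(500L, 2000L),
                               concentration = 1, max_active = nrow(reference)) {
  if (any(abs(rowSums(reference) - 1) > 1e-8))
    stop("reference signature rows must sum to 1", call. = FALSE)
  if (ncol(reference) != 96L) stop("reference signatures need 96 channels", call. = FALSE)
  if (is.null(rownames(reference))) stop("reference signatures need rownames", call. = FALSE)
  structure(as.list(environment()), class = "signature_scenario")
}

#' Synthetic SBS96 reference signature set
#'
#' Seven deterministic, well-separated synthetic signatures. Three mimic
#' the qualitative shape of well-known mutational processes so that
#' cosine-similarity labeling can be exercised: `aging_like` (C>T at NpCpG
#' contexts, as in spontaneous CpG deamination), `APOBEC_like` (C>T and
#' C>G at TpCpN contexts) and `smoking_like` (broad C>A). The remaining
#' four occupy largely disjoint channel groups. These are synthetic
#' stand-ins, not COSMIC signatures.
#'
#' @return 7 x 96 row-stochastic matrix with signature rownames.
#' @export
synthetic_signature_set <- function() {
  ch <- sbs96_channels()
  sub <- sub(".*\\[(.*)\\].*", "\\1", ch)
  five <- substr(ch, 1, 1)
  three <- substr(ch, nchar(ch), nchar(ch))
  base <- 0.1 / 96
  sig <- function(weights) {
    w <- weights + base
    w / sum(w)
  }
  S <- rbind(
    aging_like   = sig(ifelse(sub == "C>T" & three == "G", 1, 0)),
    APOBEC_like  = sig(ifelse(sub %in% c("C>T", "C>G") & five == "T", 1, 0)),
    smoking_like = sig(ifelse(sub == "C>A", 0.6, 0) +
                       ifelse(sub == "C>A" & five == "C", 0.6, 0)),
    TC_broad     = sig(ifelse(sub == "T>C", 1, 0)),
    TA_peak      = sig(ifelse(sub == "T>A" & five %in% c("A", "C"), 1, 0)),
    TG_peak      = sig(ifelse(sub == "T>G" & three %in% c("G", "T"), 1, 0)),
    CG_flank     = sig(ifelse(sub == "C>G" & five %in% c("A", "G"), 1.2, 0) +
                       ifelse(sub == "T>A" & five %in% c("G", "T"), 0.8, 0))
  )
  colnames(S) <- ch
  S
}

#' Packaged signature-extraction scenario (7 signatures)
#'
#' 200 samples, 500-2000 mutations per sample, sparse Dirichlet exposures
#' over at most 4 of the 7 synthetic reference signatures.
#' @return A `signature_scenario`.
#' @export
sig_default_scenario <- function() {
  signature_scenario(synthetic_signature_set(), n_samples = 200L,
                     mutation_range = c(500L, 2000L), concentration = 1,
                     max_active = 4L)
}

#' Simulate a mutation catalog as a signature mixture
#'
#' Per sample: draw an active signature subset and Dirichlet exposures,
#' draw a total count uniformly from `mutation_range`, then draw channel
#' counts from the multinomial over the exposure-weighted signature
#' mixture.
#'
#' @param scenario A [signature_scenario()].
#' @param seed Integer seed.
#' @return List with `catalog` (validated samples x 96 counts) and `truth`
#'   (a `cohort_truth` carrying the exposure matrix).
#' @export
simulate_mutation_catalog <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "signature_scenario"))
  set.seed(seed)
  S <- nrow(scenario$reference)
  n <- scenario$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  exposures <- matrix(0, n, S, dimnames = list(samples, rownames(scenario$reference)))
  counts <- matrix(0L, n, 96L, dimnames = list(samples, colnames(scenario$reference)))
  for (i in seq_len(n)) {
    k_active <- sample.int(min(scenario$max_active, S), 1)
    active <- sample.int(S, k_active)
    gam <- rgamma(k_active, shape = scenario$concentration)
    if (sum(gam) == 0) gam <- rep(1, k_active)
    exposures[i, active] <- gam / sum(gam)
    total <- sample(seq(scenario$mutation_range[1], scenario$mutation_range[2]), 1)
    p <- as.vector(exposures[i, ] %*% scenario$reference)
    counts[i, ] <- as.integer(rmultinom(1, total, p))
  }
  truth <- cohort_truth(sample_id = samples, exposures = exposures)
  list(catalog = validate_mutation_catalog(counts), truth = truth)
}

#' Simulate clinical outcomes with a logistic link to features
#'
#' Binary response is drawn from
#' `Bernoulli(plogis(intercept + sum(beta * feature)))` over named columns
#' of `truth$features`; best overall response categories are assigned
#' consistently (responders split CR/PR, nonresponders SD/PD).
#' Progression-free survival is exponential with a higher hazard for
#' nonresponders, with independent exponential censoring.
#'
#' @param truth A `cohort_truth` whose `features` data.frame holds the
#'   linked covariates.
#' @param feature_effects Named numeric vector of logistic coefficients;
#'   names must be feature columns.
#' @param intercept Logistic intercept.
#' @param censoring_rate Rate of the independent exponential censoring
#'   process (0 disables censoring).
#' @param seed Integer seed.
#' @param responder_rate,hazard_ratio Baseline exponential PFS rate for
#'   responders (per month) and the nonresponder hazard multiplier.
#' @param cr_fraction,sd_fraction Probability a responder is CR (vs PR)
#'   and a nonresponder SD (vs PD).
#' @return Validated clinical data.frame.
#' @export
simulate_clinical <- function(truth, feature_effects = numeric(0),
                              intercept = 0, censoring_rate = 0, seed = 1L,
                              responder_rate = 1 / 12, hazard_ratio = 3,
                              cr_fraction = 0.15, sd_fraction = 0.45) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(seed)
  feats <- truth$features
  missing_feats <- setdiff(names(feature_effects), names(feats))
  if (length(missing_feats))
    stop("unknown feature name(s): ", paste(missing_feats, collapse = ", "), call. = FALSE)
  n <- length(truth$sample_id)
  lp <- rep(intercept, n)
  for (f in names(feature_effects)) lp <- lp + feature_effects[[f]] * feats[[f]]
  response <- rbinom(n, 1, stats::plogis(lp))
  bor <- ifelse(response == 1,
                ifelse(runif(n) < cr_fraction, "CR", "PR"),
                ifelse(runif(n) < sd_fraction, "SD", "PD"))
  rate <- ifelse(response == 1, responder_rate, responder_rate * hazard_ratio)
  event_time <- rexp(n, rate)
  cens_time <- if (censoring_rate > 0) rexp(n, censoring_rate) else rep(Inf, n)
  pdl1 <- round(100 * rbeta(n, 0.6, 1.2), 1)
  pdl1[runif(n) < 0.15] <- NA
  validate_clinical_table(data.frame(
    sample_id = truth$sample_id,
    bor = bor,
    response = response,
    pfs_time = pmin(event_time, cens_time),
    pfs_event = as.integer(event_time <= cens_time),
    pdl1_tps = pdl1,
    stringsAsFactors = FALSE
  ))
}
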