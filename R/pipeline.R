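#' End-to-end demonstration pipeline on a synthetic cohort
#'
#' Orchestrates the full analysis on generated data: simulate an
#' expression cohort and a mutation catalog, derive expression subtypes
#' (consensus clustering + B-NMF K selection + factorization + markers),
#' extract and label mutational signatures, assemble per-sample genomic
#' features (log mutational burden, signature-attributable burdens,
#' program metagene z-scores, subtype indicator), simulate linked clinical
#' outcomes, run the univariate logistic screen, the binned log-rank
#' survival screen and the integrative cross-correlation clustering.
#' Stages communicate via TSV files under `outdir`; a JSON run manifest
#' records the seed, parameters and a digest of every file written.
#'
#' @param config Configuration list from [load_config()] /
#'   [default_config()].
#' @param outdir Output directory (created if needed).
#' @param scenario Expression scenario (default [m_default_scenario()]).
#' @param sig_scenario Signature scenario (default
#'   [sig_default_scenario()]).
#' @param consensus_iterations Override of the consensus iteration count
#'   (the packaged demo uses fewer than the full 500 to stay interactive).
#' @return The run manifest (list), invisibly; all outputs on disk.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("icb_run_"),
                         scenario = m_default_scenario(),
                         sig_scenario = sig_default_scenario(),
                         consensus_iterations = config$consensus_iterations) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  path <- function(f) file.path(outdir, f)

  # -- simulate ---------------------------------------------------------
  sim <- stage("simulate", function() {
    ex <- simulate_expression(scenario, seed = derive_seed(seed, "expression"))
    mc <- simulate_mutation_catalog(sig_scenario, seed = derive_seed(seed, "catalog"))
    # align cohort sizes: clinical follows the expression cohort
    write_expression(ex$expression, path("expression.tsv"))
    write_mutation_catalog(mc$catalog, path("catalog.tsv"))
    list(ex = ex, mc = mc)
  })
  outputs <- c(outputs, "expression.tsv", "catalog.tsv")

  # -- subtype ----------------------------------------------------------
  sub <- stage("subtype", function() {
    derive_subtype_model(
      sim$ex$expression, rownames(sim$ex$expression),
      k_range = seq(config$k_range[1], config$k_range[2]),
      iterations = consensus_iterations,
      resample_fraction = config$resample_fraction,
      n_restarts = 10L, n_markers = config$n_markers,
      label_prefix = "M", seed = derive_seed(seed, "subtype"),
      max_iter = config$max_iter)
  })
  stage("subtype-write", function() {
    marker_df <- data.frame(
      cluster = rep(names(sub$model$marker_genes),
                    lengths(sub$model$marker_genes)),
      gene = unlist(sub$model$marker_genes, use.names = FALSE))
    write.table(marker_df, path("subtype_markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = names(sub$model$assignments),
                           subtype = sub$model$assignments),
                path("subtype_assignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(NULL)
  })
  outputs <- c(outputs, "subtype_markers.tsv", "subtype_assignments.tsv")

  # -- signatures -------------------------------------------------------
  sig <- stage("signatures", function() {
    fact <- extract_signatures(sim$mc$catalog, n_restarts = config$n_restarts,
                               k_max = config$k_max,
                               seed = derive_seed(seed, "signatures"),
                               tol = config$tol, max_iter = config$max_iter)
    labels <- label_signatures(fact$W[, fact$active_components, drop = FALSE],
                               sig_scenario$reference,
                               min_cosine = config$min_cosine)
    burden <- attribute_burden(fact, sim$mc$catalog)
    write.table(cbind(component = labels$component, labels[-1]),
                path("signature_labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_numeric_tsv(burden, path("signature_burden.tsv"), id_col = "sample_id")
    list(fact = fact, labels = labels, burden = burden)
  })
  outputs <- c(outputs, "signature_labels.tsv", "signature_burden.tsv")

  # -- features ---------------------------------------------------------
  feat <- stage("features", function() {
    n_expr <- length(sim$ex$truth$sample_id)
    catalog_totals <- rowSums(sim$mc$catalog)
    # the expression cohort and catalog cohort are simulated independently;
    # features are joined positionally up to the smaller cohort
    n <- min(n_expr, nrow(sim$mc$catalog))
    ids <- sim$ex$truth$sample_id[seq_len(n)]
    tmb_ln <- log(catalog_totals[seq_len(n)] / config$territory_mb + 1)
    program <- sim$ex$truth$program[seq_len(n)]
    df <- data.frame(sample_id = ids, tmb_ln = tmb_ln)
    for (k in seq_along(sim$ex$truth$marker_blocks)) {
      gs <- gene_set(paste0("program", k), sim$ex$truth$marker_blocks[[k]])
      df[[paste0("program", k, "_metagene")]] <-
        as.numeric(metagene_score(sim$ex$expression, gs))[seq_len(n)]
    }
    df$immune_program <- as.integer(program == 2)
    kinds <- c(tmb_ln = "burden",
               setNames(rep("continuous", length(sim$ex$truth$marker_blocks)),
                        paste0("program", seq_along(sim$ex$truth$marker_blocks),
                               "_metagene")),
               immune_program = "binary")
    ft <- feature_table(df, kinds)
    write.table(df, path("features.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ft
  })
  outputs <- c(outputs, "features.tsv")

  # -- clinical ---------------------------------------------------------
  clin <- stage("clinical", function() {
    truth <- sim$ex$truth
    truth$features <- merge(truth$features, feat, by = "sample_id",
                            sort = FALSE)
    truth$sample_id <- truth$features$sample_id
    truth$program <- truth$features$program
    cl <- simulate_clinical(truth,
                            feature_effects = c(tmb_ln = 1.0, immune_program = 0.8),
                            intercept = -1.5, censoring_rate = 1 / 24,
                            seed = derive_seed(seed, "clinical"))
    write.table(cl, path("clinical.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cl
  })
  outputs <- c(outputs, "clinical.tsv")

  # -- associate --------------------------------------------------------
  feat_aligned <- feat[match(clin$sample_id, feat$sample_id), ]
  assoc <- stage("associate", function() {
    screened <- prevalence_filter(feat_aligned, config$prevalence_min)
    res <- logistic_screen(screened, clin$response,
                           fdr_significant = config$fdr_significant,
                           fdr_near_significant = config$fdr_near_significant)
    write.table(res, path("associations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res
  })
  outputs <- c(outputs, "associations.tsv")

  # -- survive ----------------------------------------------------------
  surv <- stage("survive", function() {
    binned <- list(
      tmb_ln = bin_feature(feat_aligned$tmb_ln, "burden"),
      immune_program = bin_feature(feat_aligned$immune_program, "alteration"),
      program1_metagene = bin_feature(feat_aligned$program1_metagene, "zscore"))
    res <- survival_screen(binned, clin$pfs_time, clin$pfs_event)
    write.table(res, path("survival.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res
  })
  outputs <- c(outputs, "survival.tsv")

  # -- integrate --------------------------------------------------------
  stage("integrate", function() {
    X <- feat_aligned[, setdiff(names(feat_aligned), "sample_id")]
    cc <- cross_correlation_cluster(X, n_blocks = 2)
    write.table(data.frame(feature = names(cc$blocks), block = cc$blocks),
                path("feature_blocks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cc
  })
  outputs <- c(outputs, "feature_blocks.tsv")

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("icbscreen")),
    master_seed = seed,
    config_digest = digest_object(config),
    parameters = config,
    subtype_k = sub$K,
    signature_k = sig$fact$K_eff,
    outputs = lapply(setNames(outputs, outputs),
                     function(f) digest_file(file.path(outdir, f)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
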