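#' Canonical SBS96 channel labels
#'
#' The 96 single-base-substitution channels in lexicographic COSMIC
#' convention: the six pyrimidine substitutions (C>A, C>G, C>T, T>A, T>C,
#' T>G) in order, each crossed with the 16 five-prime/three-prime flanking
#' base combinations in alphabetical order. A channel is written
#' `"A[C>T]G"` for a C>T substitution with 5' flank A and 3' flank G.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, r) paste0(f, "[", s, "]", r))))
  }))
}

stop_parse <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a genes x samples expression matrix
#'
#' Expression values are log2(TPM + 1): nonnegative where observed, with
#' missing values permitted. Gene identifiers (rownames) and sample
#' identifiers (colnames) must be present and unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix, invisibly usable as-is.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_parse("expression values must be a numeric matrix")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || is.null(s))
    stop_parse("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(g))
    stop_parse("duplicate gene identifier: %s", g[duplicated(g)][1])
  if (anyDuplicated(s))
    stop_parse("duplicate sample identifier: %s", s[duplicated(s)][1])
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_parse("negative expression value at gene %s, sample %s",
               g[bad[1]], s[bad[2]])
  }
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' symbols, and a numeric body in log2(TPM + 1) units. Raw-TPM input can be
#' transformed on read with `tpm = TRUE`.
#'
#' @param path TSV file path.
#' @param tpm If `TRUE`, values on disk are raw TPM and `log2(x + 1)` is
#'   applied after validation.
#' @return Validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, tpm = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_parse("malformed expression file %s: need a gene column plus samples", path)
  genes <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & col != "NA" & is.na(num))
      if (length(bad))
        stop_parse("non-numeric value '%s' at gene %s, sample %s",
                   col[bad[1]], genes[bad[1]], colnames(body)[j])
      body[[j]] <- num
    }
  }
  values <- as.matrix(body)
  rownames(values) <- genes
  values <- validate_expression_matrix(values)
  if (tpm) values <- log2(values + 1)
  values
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a
#' write/read cycle reproduces the doubles bit-exactly.
#'
#' @param values Validated expression matrix.
#' @param path Output TSV path.
#' @export
write_expression <- function(values, path) {
  validate_expression_matrix(values)
  write_numeric_tsv(values, path, id_col = "gene")
}

write_numeric_tsv <- function(values, path, id_col) {
  fmt <- ifelse(is.na(values), "NA", formatC(values, digits = 17, format = "g"))
  dim(fmt) <- dim(values)
  out <- cbind(rownames(values), fmt)
  colnames(out) <- c(id_col, colnames(values))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a samples x 96 mutation catalog
#'
#' @param counts Integer-valued matrix; rownames are sample identifiers,
#'   colnames the 96 canonical SBS channels (any order; reordered to
#'   canonical).
#' @return The validated matrix with channels in canonical order.
#' @export
validate_mutation_catalog <- function(counts) {
  channels <- sbs96_channels()
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_parse("mutation catalog must be a numeric matrix")
  if (ncol(counts) != 96L || !setequal(colnames(counts), channels))
    stop_parse("mutation catalog must have exactly the 96 canonical SBS channels")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_parse("mutation catalog needs unique sample rownames")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_parse("mutation counts must be nonnegative integers")
  counts[, channels, drop = FALSE]
}

#' Read a mutation catalog (samples x 96 channels) from TSV
#' @param path TSV path: first column sample identifiers, 96 channel columns.
#' @return Validated counts matrix in canonical channel order.
#' @export
read_mutation_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  validate_mutation_catalog(counts)
}

#' Write a mutation catalog to TSV
#' @param counts Validated catalog matrix.
#' @param path Output path.
#' @export
write_mutation_catalog <- function(counts, path) {
  counts <- validate_mutation_catalog(counts)
  out <- cbind(sample_id = rownames(counts), as.data.frame(counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

variant_classes <- c("nonsynonymous_snv", "dnv", "indel", "other")

#' Validate a variant table
#'
#' Per-variant records with cancer-cell-fraction (CCF) cluster assignments:
#' columns `sample_id`, `gene`, `variant_class` (one of
#' `nonsynonymous_snv`, `dnv`, `indel`, `other`), `ccf_cluster_id`
#' (integer) and `cluster_ccf` in \[0, 1\].
#'
#' @param variants data.frame of variants.
#' @return The validated data.frame.
#' @export
validate_variant_table <- function(variants) {
  need <- c("sample_id", "gene", "variant_class", "ccf_cluster_id", "cluster_ccf")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop_parse("variant table missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(variants$variant_class), variant_classes)
  if (length(bad)) stop_parse("unknown variant_class: %s", bad[1])
  ccf <- variants$cluster_ccf
  if (any(is.na(ccf)) || any(ccf < 0 | ccf > 1))
    stop_parse("cluster_ccf must lie in [0, 1]")
  variants
}

#' Read a variant table (MAF-lite) from TSV
#' @param path TSV path with the columns of [validate_variant_table()].
#' @return Validated data.frame.
#' @export
read_variant_table <- function(path) {
  validate_variant_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Validate a clinical table
#'
#' Requires `sample_id`, `bor` (CR/PR/SD/PD), `response` (1 for CR/PR, 0
#' for SD/PD), `pfs_time` (months, nonnegative), `pfs_event` (0/1) and
#' optionally `pdl1_tps` in \[0, 100\]; further columns are treated as
#' covariates.
#'
#' @param clinical data.frame.
#' @return The validated data.frame.
#' @export
validate_clinical_table <- function(clinical) {
  need <- c("sample_id", "bor", "response", "pfs_time", "pfs_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop_parse("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(clinical$bor %in% c("CR", "PR", "SD", "PD")))
    stop_parse("bor must be one of CR, PR, SD, PD")
  expected <- as.integer(clinical$bor %in% c("CR", "PR"))
  if (!all(clinical$response == expected))
    stop_parse("response must be 1 for CR/PR and 0 for SD/PD")
  if (any(clinical$pfs_time < 0)) stop_parse("pfs_time must be nonnegative")
  if (!all(clinical$pfs_event %in% c(0, 1))) stop_parse("pfs_event must be 0/1")
  if ("pdl1_tps" %in% names(clinical)) {
    tps <- clinical$pdl1_tps
    if (any(tps < 0 | tps > 100, na.rm = TRUE)) stop_parse("pdl1_tps must lie in [0, 100]")
  }
  clinical
}

#' Read a clinical table from TSV
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_clinical_table <- function(path) {
  validate_clinical_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Validate a per-peptide MHC-I percentile-rank table
#'
#' Columns `sample_id`, `variant_id`, `allele`, `percentile_rank` (>= 0),
#' optionally `peptide`; (sample, variant \[, peptide\], allele) rows must
#' be unique.
#'
#' @param ranks data.frame.
#' @return The validated data.frame.
#' @export
validate_rank_table <- function(ranks) {
  need <- c("sample_id", "variant_id", "allele", "percentile_rank")
  miss <- setdiff(need, names(ranks))
  if (length(miss)) stop_parse("rank table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(ranks$percentile_rank < 0)) stop_parse("percentile_rank must be >= 0")
  keycols <- intersect(c("sample_id", "variant_id", "peptide", "allele"), names(ranks))
  key <- do.call(paste, c(ranks[keycols], sep = "\r"))
  if (anyDuplicated(key)) stop_parse("duplicate (sample, variant, allele) row in rank table")
  ranks
}

#' Read a percentile-rank table from TSV
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_rank_table <- function(path) {
  validate_rank_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Construct a gene set
#' @param name Set name.
#' @param members Unique, nonempty character vector of gene symbols.
#' @return A `gene_set` list with elements `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  if (length(members) == 0) stop_parse("gene set '%s' has no members", name)
  if (anyDuplicated(members)) stop_parse("gene set '%s' has duplicate members", name)
  structure(list(name = name, members = members), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. The description field is discarded.
#'
#' @param path GMT path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3)
      stop_parse("GMT line %d: need name, description and at least one member", i)
    gene_set(parts[1], parts[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults: DE filter
#' p < 0.05 and |log2 fold change| > 0.5; low-quality filter at >10%
#' NA-or-zero or bottom 10% of mean expression; consensus clustering over
#' K = 2..10 with 500 iterations at 80% sample resampling; clonality CCF
#' cutoff 0.85; neoantigen binder percentile rank <= 2; screen prevalence
#' filter 0.05; BH tiers 0.1 (significant) and 0.25 (near-significant);
#' exome territory 33 MB; and the ARD-NMF numerical settings.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    de_p_thresh = 0.05,
    de_lfc_thresh = 0.5,
    k_range = c(2L, 10L),
    consensus_iterations = 500L,
    resample_fraction = 0.8,
    linkage = "average",
    ccf_clonal_threshold = 0.85,
    binder_rank_threshold = 2,
    prevalence_min = 0.05,
    fdr_significant = 0.1,
    fdr_near_significant = 0.25,
    territory_mb = 33,
    n_markers = 50L,
    variance_top_n = 2000L,
    min_cosine = 0.8,
    n_restarts = 20L,
    k_max = 15L,
    prune_threshold = 0.01,
    ard_a = 10,
    tol = 1e-7,
    max_iter = 100000L,
    min_log2tpm = 0.5,
    min_fraction = 0.30
  )
}

#' Load and validate a configuration file
#'
#' Reads YAML (`.yml`/`.yaml`) or JSON (`.json`) overrides and merges them
#' onto [default_config()]. Unknown keys are rejected, and basic range
#' checks are applied.
#'
#' @param path Config path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    overrides <- switch(ext,
      yml = , yaml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop_parse("config must be YAML or JSON, got .%s", ext))
    if (is.null(overrides)) overrides <- list()
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) stop_parse("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  kr <- cfg$k_range
  if (length(kr) != 2 || kr[1] > kr[2] || kr[1] < 1)
    stop_parse("k_range must be a nondecreasing pair of integers >= 1")
  for (key in c("de_p_thresh", "prevalence_min", "fdr_significant",
                "fdr_near_significant", "resample_fraction", "min_cosine")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) stop_parse("%s must lie in [0, 1]", key)
  }
  if (cfg$territory_mb <= 0) stop_parse("territory_mb must be positive")
  if (cfg$ccf_clonal_threshold < 0 || cfg$ccf_clonal_threshold > 1)
    stop_parse("ccf_clonal_threshold must lie in [0, 1]")
  if (cfg$consensus_iterations < 1 || cfg$n_restarts < 0 || cfg$k_max < 1)
    stop_parse("iteration/restart/k_max settings must be positive")
  cfg
}

#' Derive a stage seed from the master seed
#'
#' One master integer seed drives the whole pipeline; per-stage seeds are
#' split off deterministically from the stage name so stages are
#' independently reproducible.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name (character).
#' @return Integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, stage) {
  h <- as.double(master_seed) %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Polynomial rolling hash over raw bytes (mod 2^31 - 1); used for
# config/file digests in run manifests. Not cryptographic.
byte_digest <- function(bytes) {
  b <- as.double(bytes) + 1
  n <- length(b)
  if (n == 0) return("00000000")
  w <- (seq_len(n) * 7919) %% 9973 + 1
  tot <- 0
  for (ii in split(seq_len(n), ceiling(seq_len(n) / 1e5)))
    tot <- (tot + sum(b[ii] * w[ii])) %% 2147483647
  sprintf("%08x", as.integer((tot * 131 + n) %% 2147483647))
}

digest_file <- function(path) byte_digest(readBin(path, "raw", file.info(path)$size))
digest_object <- function(x) byte_digest(serialize(x, NULL, version = 2))
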