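#' Tumor mutational burden
#'
#' TMB is the natural log of the count of nonsynonymous SNVs, DNVs and
#' indels divided by the exome capture territory in megabases, with a
#' pseudocount of one event per MB: `ln(events / territory_mb + 1)`. The
#' raw per-MB rate is reported alongside for binning (e.g. the
#' TMB > 10 mut/MB favorable group).
#'
#' @param variants Validated variant table.
#' @param territory_mb Exome capture territory size in MB (> 0; default 33).
#' @param sample Optional single sample to restrict to.
#' @return data.frame with `sample_id`, `n_events`, `rate_per_mb`,
#'   `tmb_ln`.
#' @export
compute_tmb <- function(variants, territory_mb = 33, sample = NULL) {
  if (territory_mb <= 0) stop("territory_mb must be positive", call. = FALSE)
  variants <- validate_variant_table(variants)
  samples <- if (is.null(sample)) unique(variants$sample_id) else sample
  counted <- c("nonsynonymous_snv", "dnv", "indel")
  n <- vapply(samples, function(s) {
    sum(variants$sample_id == s & variants$variant_class %in% counted)
  }, 0)
  rate <- n / territory_mb
  data.frame(sample_id = samples, n_events = n, rate_per_mb = rate,
             tmb_ln = log(rate + 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify variants as clonal or subclonal
#'
#' A variant is clonal when its CCF cluster sits strictly above the
#' threshold (cluster CCF > 0.85); all others are subclonal.
#'
#' @param variants Validated variant table.
#' @param ccf_threshold Clonality cutoff (default 0.85, strict).
#' @return List with `variants` (input plus a `clonality` column) and
#'   `counts` (per-sample data.frame of `clonal` and `subclonal` counts).
#' @export
classify_clonality <- function(variants, ccf_threshold = 0.85) {
  variants <- validate_variant_table(variants)
  variants$clonality <- ifelse(variants$cluster_ccf > ccf_threshold,
                               "clonal", "subclonal")
  samples <- unique(variants$sample_id)
  counts <- data.frame(
    sample_id = samples,
    clonal = vapply(samples, function(s)
      sum(variants$sample_id == s & variants$clonality == "clonal"), 0L),
    subclonal = vapply(samples, function(s)
      sum(variants$sample_id == s & variants$clonality == "subclonal"), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(variants = variants, counts = counts)
}

#' Number of distinct subclones in a sample
#'
#' @param variants Validated variant table.
#' @param sample Sample identifier.
#' @return Integer count of unique CCF cluster ids (0 if the sample has
#'   no variants).
#' @export
subclone_count <- function(variants, sample) {
  variants <- validate_variant_table(variants)
  length(unique(variants$ccf_cluster_id[variants$sample_id == sample]))
}

#' Count predicted neoantigen binders
#'
#' A peptide is a predicted binder when its MHC-I percentile rank is two
#' or less for any Class I allele of the patient. Counting deduplicates
#' at the peptide level (one peptide binding several alleles counts once);
#' with `per_variant = TRUE`, or when the rank table carries no `peptide`
#' column, the unit is the variant instead.
#'
#' @param ranks Validated percentile-rank table.
#' @param sample Optional single sample to restrict to.
#' @param rank_threshold Binder cutoff (default 2, inclusive).
#' @param per_variant Count distinct variants rather than peptides.
#' @return Named integer vector of binder counts per sample.
#' @export
count_neoantigen_binders <- function(ranks, sample = NULL, rank_threshold = 2,
                                     per_variant = FALSE) {
  ranks <- validate_rank_table(ranks)
  if (!is.null(sample)) ranks <- ranks[ranks$sample_id %in% sample, , drop = FALSE]
  unit <- if (!per_variant && "peptide" %in% names(ranks)) {
    paste(ranks$variant_id, ranks$peptide, sep = "\r")
  } else {
    ranks$variant_id
  }
  samples <- if (is.null(sample)) unique(ranks$sample_id) else sample
  out <- vapply(samples, function(s) {
    sel <- ranks$sample_id == s
    if (!any(sel)) return(0L)
    min_rank <- tapply(ranks$percentile_rank[sel], unit[sel], min)
    sum(min_rank <= rank_threshold)
  }, 0L)
  setNames(as.integer(out), samples)
}

#' Rearranged-receptor burden
#'
#' T-/B-cell burden is `(rearranged receptor reads + 1) / (aligned reads
#' / 1e6)`; its natural log is the value used in significance screens.
#'
#' @param rearranged_reads Nonnegative read count(s) of productive TCR/Ig
#'   rearrangements.
#' @param aligned_reads Total aligned reads (> 0).
#' @return data.frame with `burden` and `log_burden`.
#' @export
receptor_burden <- function(rearranged_reads, aligned_reads) {
  if (any(aligned_reads <= 0)) stop("aligned_reads must be positive", call. = FALSE)
  burden <- (rearranged_reads + 1) / (aligned_reads / 1e6)
  data.frame(burden = burden, log_burden = log(burden))
}

#' Metagene z-score
#'
#' Takes the per-sample mean of log2 TPM over the gene-set members present
#' in the matrix, then z-scores those means across samples (sample
#' standard deviation, n - 1 denominator). Members absent from the matrix
#' are reported via the `missing_genes` attribute.
#'
#' @param expr Expression matrix (>= 3 samples).
#' @param gset A [gene_set()] with >= 1 member present in `expr`.
#' @return Named numeric vector of z-scores (mean 0, sd 1) with a
#'   `missing_genes` attribute.
#' @export
metagene_score <- function(expr, gset) {
  stopifnot(inherits(gset, "gene_set"))
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  present <- intersect(gset$members, rownames(expr))
  if (length(present) == 0)
    stop(sprintf("no members of gene set '%s' present in the matrix", gset$name),
         call. = FALSE)
  m <- colMeans(expr[present, , drop = FALSE], na.rm = TRUE)
  s <- sd(m)
  if (s == 0) stop("gene-set mean is constant across samples", call. = FALSE)
  z <- (m - mean(m)) / s
  attr(z, "missing_genes") <- setdiff(gset$members, present)
  z
}

#' The inducible immunoproteasome gene set
#'
#' The five interferon-gamma-inducible components of the immunoproteasome:
#' the catalytic subunits PSMB8 (beta5i), PSMB9 (beta1i) and PSMB10
#' (beta2i), and the PA28 alpha/beta activator genes PSME1 and PSME2.
#'
#' @return A [gene_set()] of the 5 genes.
#' @export
immunoproteasome_set <- function() {
  gene_set("immunoproteasome", c("PSMB8", "PSMB9", "PSMB10", "PSME1", "PSME2"))
}

#' Assemble a typed feature table
#'
#' @param df data.frame with `sample_id` plus feature columns.
#' @param kinds Named character vector tagging every feature column as
#'   `"binary"`, `"continuous"` or `"burden"`.
#' @return The data.frame with a `kinds` attribute, validated: binary
#'   features in {0, 1}, burden features nonnegative.
#' @export
feature_table <- function(df, kinds) {
  feats <- setdiff(names(df), "sample_id")
  miss <- setdiff(feats, names(kinds))
  if (length(miss)) stop("untyped feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(kinds %in% c("binary", "continuous", "burden")))
    stop("kinds must be binary, continuous or burden", call. = FALSE)
  for (f in feats) {
    if (kinds[[f]] == "binary" && !all(df[[f]] %in% c(0, 1, NA)))
      stop(sprintf("binary feature %s has values outside {0, 1}", f), call. = FALSE)
    if (kinds[[f]] == "burden" && any(df[[f]] < 0, na.rm = TRUE))
      stop(sprintf("burden feature %s has negative values", f), call. = FALSE)
  }
  attr(df, "kinds") <- kinds[feats]
  df
}
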