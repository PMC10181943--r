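#' Construct a reference signature set
#'
#' @param matrix S x 96 nonnegative matrix, each row summing to 1, with
#'   unique rownames (labels) and the canonical channel colnames.
#' @return Validated signature matrix.
#' @export
signature_set <- function(matrix) {
  if (ncol(matrix) != 96L) stop("signature set needs 96 channels", call. = FALSE)
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("signature labels must be unique rownames", call. = FALSE)
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-8))
    stop("signature rows must be nonnegative and sum to 1", call. = FALSE)
  if (!setequal(colnames(matrix), sbs96_channels()))
    stop("signature channels must be the canonical 96 labels", call. = FALSE)
  matrix[, sbs96_channels(), drop = FALSE]
}

#' Read a signature set from TSV (labels in the first column, 96 channels)
#' @param path TSV path.
#' @return Validated S x 96 matrix.
#' @export
read_signature_set <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  signature_set(m)
}

#' Write a signature set to TSV
#' @param sigs Validated signature matrix.
#' @param path Output path.
#' @export
write_signature_set <- function(sigs, path) {
  sigs <- signature_set(sigs)
  write_numeric_tsv(sigs, path, id_col = "signature")
}

#' Unsupervised SBS96 signature extraction
#'
#' Runs ARD-NMF (Poisson divergence, exponential prior) on the transposed
#' catalog (channels x samples) from `n_restarts` random initializations
#' and keeps the modal-rank, maximum-posterior solution — the number of
#' signatures is learned, not fixed.
#'
#' @param catalog Samples x 96 mutation catalog (>= 10 samples).
#' @param n_restarts Number of random initializations (default 20).
#' @param k_max Rank upper bound (default 15).
#' @param seed Integer seed.
#' @param ... Passed to [factorize()].
#' @return A `factorization_result`; `W` is channels x K (signature
#'   profiles, active columns sum to 1) and `H` is K x samples (raw
#'   exposures).
#' @export
extract_signatures <- function(catalog, n_restarts = 20L, k_max = 15L,
                               seed = 1L, ...) {
  catalog <- validate_mutation_catalog(catalog)
  if (nrow(catalog) < 10) stop("need at least 10 samples", call. = FALSE)
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  V <- t(catalog)
  runs <- factorize_restarts(V, K_max = k_max, n_restarts = n_restarts,
                             seed = seed, prior = "exponential",
                             divergence = "poisson", ...)
  select_best_run(runs)
}

#' Label extracted signatures by cosine similarity to a reference
#'
#' Each extracted signature (column of `W`) receives the label of the
#' reference signature with the highest cosine similarity, provided that
#' similarity reaches `min_cosine`; otherwise it is `"unassigned"`.
#'
#' @param W 96 x K matrix of extracted signature profiles (columns are
#'   normalized to sum 1 before comparison).
#' @param reference Reference [signature_set()] (S x 96).
#' @param min_cosine Minimum similarity for assignment (default 0.8).
#' @return data.frame with `component`, `label` and `cosine`.
#' @export
label_signatures <- function(W, reference, min_cosine = 0.8) {
  if (nrow(W) != 96L) stop("W must have 96 channel rows", call. = FALSE)
  reference <- signature_set(reference)
  Wn <- sweep(W, 2, pmax(colSums(W), 1e-12), "/")
  sim <- cosine_similarity(Wn, t(reference))
  best <- max.col(sim, ties.method = "first")
  best_sim <- sim[cbind(seq_len(ncol(W)), best)]
  data.frame(
    component = seq_len(ncol(W)),
    label = ifelse(best_sim >= min_cosine, rownames(reference)[best], "unassigned"),
    cosine = as.numeric(best_sim),
    stringsAsFactors = FALSE
  )
}

#' Per-sample signature-attributable mutation burden
#'
#' A sample's exposure column is normalized to proportions ("relative
#' projection strength") and multiplied by its total mutation count, so
#' attributed counts sum exactly to the sample total. Samples with zero
#' mutations receive an all-zero attribution.
#'
#' @param fact `factorization_result` from [extract_signatures()] on the
#'   same catalog.
#' @param catalog Samples x 96 mutation catalog.
#' @return Samples x K_eff matrix of attributable counts.
#' @export
attribute_burden <- function(fact, catalog) {
  catalog <- validate_mutation_catalog(catalog)
  H <- fact$H[fact$active_components, rownames(catalog), drop = FALSE]
  totals <- rowSums(catalog)
  hsum <- colSums(H)
  prop <- t(sweep(H, 2, pmax(hsum, 1e-12), "/"))
  prop[hsum <= 1e-12, ] <- 0
  att <- prop * totals
  dimnames(att) <- list(rownames(catalog), paste0("signature_", fact$active_components))
  att
}
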