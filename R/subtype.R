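#' Keep genes passing the differential-expression filter
#'
#' Genes enter the subtyping analysis only if they are differentially
#' expressed with respect to response: p below `p_thresh` and absolute
#' log2 fold change strictly above `lfc_thresh`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param de data.frame with columns `gene`, `p`, `lfc` covering every
#'   gene of `expr`.
#' @param p_thresh,lfc_thresh Thresholds (defaults 0.05 and 0.5).
#' @return Character vector of retained genes.
#' @export
filter_de_genes <- function(expr, de, p_thresh = 0.05, lfc_thresh = 0.5) {
  genes <- rownames(expr)
  miss <- setdiff(genes, de$gene)
  if (length(miss))
    stop("gene(s) missing from DE results: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  de <- de[match(genes, de$gene), ]
  genes[de$p < p_thresh & abs(de$lfc) > lfc_thresh]
}

#' Drop sparse or weakly expressed genes
#'
#' Removes genes with more than `max_na_zero_frac` of values missing or
#' zero, and, among the genes passing that test, those whose mean
#' expression falls in the bottom `bottom_mean_quantile` of the
#' distribution.
#'
#' @param expr Expression matrix (>= 10 genes).
#' @param max_na_zero_frac Maximum tolerated NA-or-zero fraction (0.10).
#' @param bottom_mean_quantile Mean-expression decile removed (0.10).
#' @return Character vector of retained genes.
#' @export
filter_low_quality_genes <- function(expr, max_na_zero_frac = 0.10,
                                     bottom_mean_quantile = 0.10) {
  if (nrow(expr) < 10) stop("need at least 10 genes", call. = FALSE)
  sparse_frac <- rowMeans(is.na(expr) | expr == 0)
  dense <- rownames(expr)[sparse_frac <= max_na_zero_frac]
  means <- rowMeans(expr[dense, , drop = FALSE], na.rm = TRUE)
  cut <- quantile(means, bottom_mean_quantile)
  dense[means >= cut]
}

#' Median-center each gene
#'
#' Transforms expression values into per-gene fold changes by subtracting
#' the gene's median, so every output row has median zero.
#'
#' @param expr Expression matrix; every gene needs >= 2 non-missing values.
#' @return Centered matrix of the same shape.
#' @export
median_center <- function(expr) {
  nonmiss <- rowSums(!is.na(expr))
  if (any(nonmiss < 2))
    stop("gene with fewer than 2 non-missing values: ",
         rownames(expr)[nonmiss < 2][1], call. = FALSE)
  meds <- apply(expr, 1, median, na.rm = TRUE)
  sweep(expr, 1, meds)
}

#' Consensus co-clustering over a range of cluster numbers
#'
#' For each K in `k_range`, repeats `iterations` rounds of: subsample
#' `resample_fraction` of the samples without replacement, hierarchically
#' cluster them on distance 1 - Spearman correlation (computed across
#' genes of the fold-change matrix), cut at K, and record co-membership.
#' The per-K consensus is the co-membership count divided by the
#' co-sampling count; `summed_normalized` is the sum of co-membership
#' counts across all K divided by the total number of iterations, the
#' matrix handed to B-NMF for cluster-number selection.
#'
#' @param fc Median-centered fold-change matrix (genes x samples).
#' @param k_range Integer vector of cluster numbers (default 2:10).
#' @param iterations Iterations per K (default 500).
#' @param resample_fraction Fraction of samples drawn each iteration.
#' @param linkage Hierarchical clustering linkage (default "average").
#' @param seed Integer seed.
#' @return A `consensus_result` list: `per_k_consensus` (named list of
#'   samples x samples frequency matrices), `summed_normalized`,
#'   `k_range`, `iterations`, `resample_fraction`.
#' @export
consensus_matrix <- function(fc, k_range = 2:10, iterations = 500L,
                             resample_fraction = 0.8, linkage = "average",
                             seed = 1L) {
  n <- ncol(fc)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n_samples - 1]", call. = FALSE)
  if (n < max(k_range) + 1) stop("too few samples for requested k_range", call. = FALSE)
  set.seed(seed)
  corr <- cor(fc, method = "spearman", use = "pairwise.complete.obs")
  n_sub <- max(2L, round(resample_fraction * n))
  per_k <- vector("list", length(k_range))
  names(per_k) <- paste0("K", k_range)
  total_counts <- matrix(0, n, n, dimnames = dimnames(corr))
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    co_cluster <- matrix(0, n, n)
    co_sample <- matrix(0, n, n)
    for (it in seq_len(iterations)) {
      sub <- sample.int(n, n_sub)
      hc <- hclust(as.dist(1 - corr[sub, sub]), method = linkage)
      cl <- cutree(hc, k = K)
      same <- outer(cl, cl, "==") * 1
      co_cluster[sub, sub] <- co_cluster[sub, sub] + same
      co_sample[sub, sub] <- co_sample[sub, sub] + 1
    }
    cons <- co_cluster / pmax(co_sample, 1)
    dimnames(cons) <- dimnames(corr)
    per_k[[ki]] <- cons
    total_counts <- total_counts + co_cluster
  }
  structure(list(
    per_k_consensus = per_k,
    summed_normalized = total_counts / (length(k_range) * iterations),
    k_range = k_range,
    iterations = iterations,
    resample_fraction = resample_fraction
  ), class = "consensus_result")
}

#' Decide the cluster number from a consensus matrix
#'
#' Factorizes the summed, normalized consensus matrix with
#' half-normal-prior B-NMF over several restarts and returns the modal
#' effective rank of the best run — the empirically determined number of
#' expression clusters.
#'
#' @param consensus A `consensus_result` (or a plain square nonnegative
#'   matrix).
#' @param n_restarts Number of seeded restarts (default 10).
#' @param k_max Upper bound on the rank handed to the factorization
#'   (default: the largest K explored by the consensus step).
#' @param seed Integer seed.
#' @param prune_threshold Fraction of the dominant component scale below
#'   which a component does not count toward K (default 0.25). The summed
#'   consensus matrix carries, besides its dominant cluster blocks, weak
#'   sub-block texture from cluster subdivision at larger K; empirically
#'   the two groups are separated by a wide gap (dominant blocks above
#'   ~0.6 of the largest component, texture below ~0.2), and a quarter of
#'   the dominant scale sits safely inside it.
#' @param tol Convergence tolerance for the decision factorizations
#'   (default 1e-6: only the rank is consumed here, and it stabilizes
#'   well before tight convergence; the effective-rank decision is
#'   unchanged down to 1e-7).
#' @param ... Passed to [factorize()].
#' @return Integer K.
#' @export
determine_k <- function(consensus, n_restarts = 10L, k_max = NULL, seed = 1L,
                        prune_threshold = 0.25, tol = 1e-6, ...) {
  M <- if (inherits(consensus, "consensus_result")) consensus$summed_normalized else consensus
  if (is.null(k_max)) {
    k_max <- if (inherits(consensus, "consensus_result")) max(consensus$k_range) else 10L
  }
  runs <- factorize_restarts(M, K_max = k_max, n_restarts = n_restarts, seed = seed,
                             prior = "half-normal", divergence = "gaussian",
                             prune_threshold = prune_threshold,
                             polish = FALSE, tol = tol, ...)
  best <- select_best_run(runs)
  best$K_eff
}

#' Factorize expression at a fixed K and assign samples
#'
#' Applies B-NMF to the (filtered) log2 TPM expression matrix with
#' `K_max = K`; each sample is assigned to the component where its
#' normalized membership column is largest.
#'
#' @param expr Nonnegative expression matrix (filtered genes x samples).
#' @param K Cluster number from [determine_k()].
#' @param n_restarts Seeded restarts; the modal-K max-posterior run is kept.
#' @param seed Integer seed.
#' @param prior,divergence Passed to [factorize()].
#' @param ... Passed to [factorize()].
#' @return List with `fact` (`factorization_result`) and `assignments`
#'   (named integer vector over active components, 1..K_eff).
#' @export
derive_subtypes <- function(expr, K, n_restarts = 10L, seed = 1L,
                            prior = "half-normal", divergence = "gaussian", ...) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  runs <- factorize_restarts(expr, K_max = K, n_restarts = n_restarts, seed = seed,
                             prior = prior, divergence = divergence, ...)
  fact <- select_best_run(runs)
  assignments <- assign_from_h(fact)
  list(fact = fact, assignments = assignments)
}

assign_from_h <- function(fact) {
  H <- fact$H[fact$active_components, , drop = FALSE]
  Hn <- sweep(H, 2, pmax(colSums(H), 1e-12), "/")
  a <- apply(Hn, 2, which.max)
  setNames(as.integer(a), colnames(fact$H))
}

#' Extract per-cluster marker genes from the W matrix
#'
#' For each cluster, candidate markers are the genes at or above the
#' median of that cluster's normalized gene-weight column (the "top 50%"
#' rule). Each gene can mark only the cluster where its weight is largest.
#' Candidates must be expressed more highly inside the cluster than
#' outside (positive mean difference); the top `n_markers` by that
#' difference are kept. Clusters are then relabeled in decreasing
#' size order as `<prefix>-1`, `<prefix>-2`, ...
#'
#' @param fact `factorization_result` from [derive_subtypes()].
#' @param expr The expression matrix the factorization was run on.
#' @param assignments Named assignment vector covering all samples.
#' @param n_markers Markers kept per cluster (default 50).
#' @param label_prefix Cluster label prefix (e.g. `"M"` or `"TI"`).
#' @return A `subtype_model` list: `K`, `cluster_labels`, `marker_genes`
#'   (named list, disjoint), `W_markers` (markers x K), `assignments`
#'   (training labels).
#' @export
extract_markers <- function(fact, expr, assignments, n_markers = 50L,
                            label_prefix = "C") {
  if (!all(colnames(expr) %in% names(assignments)))
    stop("assignments must cover all samples", call. = FALSE)
  active <- fact$active_components
  # a component that wins no samples cannot define a cluster: drop it
  # (degenerate but possible when the factorization keeps a weak
  # component that never dominates a membership column)
  used <- sort(unique(assignments))
  if (length(used) < length(active)) {
    message("dropping ", length(active) - length(used),
            " empty cluster(s) with no assigned samples")
    active <- active[used]
    assignments <- setNames(match(assignments, used), names(assignments))
  }
  W <- fact$W[, active, drop = FALSE]
  Wn <- sweep(W, 2, pmax(colSums(W), 1e-12), "/")
  K <- length(active)
  best_cluster <- max.col(Wn, ties.method = "first")
  markers <- vector("list", K)
  for (k in seq_len(K)) {
    med <- median(Wn[, k])
    cand <- which(best_cluster == k & Wn[, k] >= med)
    inside <- names(assignments)[assignments == k]
    outside <- setdiff(colnames(expr), inside)
    if (length(inside) == 0 || length(outside) == 0 || length(cand) == 0)
      stop(sprintf("cluster %d has no qualifying marker genes", k), call. = FALSE)
    gdiff <- rowMeans(expr[cand, inside, drop = FALSE], na.rm = TRUE) -
             rowMeans(expr[cand, outside, drop = FALSE], na.rm = TRUE)
    keep <- cand[gdiff > 0]
    if (length(keep) == 0)
      stop(sprintf("cluster %d has no qualifying marker genes", k), call. = FALSE)
    ord <- order(gdiff[gdiff > 0], decreasing = TRUE)
    markers[[k]] <- rownames(expr)[keep[ord][seq_len(min(n_markers, length(keep)))]]
  }
  # relabel clusters by decreasing training size
  sizes <- tabulate(assignments, nbins = K)
  ord <- order(sizes, decreasing = TRUE)
  labels <- paste0(label_prefix, "-", seq_len(K))
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  marker_genes <- setNames(markers[ord], labels)
  all_markers <- unlist(marker_genes, use.names = FALSE)
  W_markers <- Wn[all_markers, ord, drop = FALSE]
  colnames(W_markers) <- labels
  structure(list(
    K = K,
    cluster_labels = labels,
    marker_genes = marker_genes,
    W_markers = W_markers,
    assignments = setNames(labels[relabel[assignments]], names(assignments))
  ), class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("Subtype model with K = %d clusters (%s)\n", x$K,
              paste(x$cluster_labels, collapse = ", ")))
  cat(sprintf("  %d marker genes total\n", nrow(x$W_markers)))
  invisible(x)
}

#' Classify new samples with a subtype model
#'
#' Restricts the new expression matrix to the model's marker genes (at
#' least half of them must be present), solves nonnegative least squares
#' for the membership of each sample against the fixed marker-weight
#' matrix, and assigns the argmax component. Ties break toward the lowest
#' cluster index.
#'
#' @param model A `subtype_model`.
#' @param expr_new Nonnegative expression matrix for the new samples.
#' @return Named character vector of cluster labels.
#' @export
classify_samples <- function(model, expr_new) {
  avail <- intersect(rownames(model$W_markers), rownames(expr_new))
  if (length(avail) < 0.5 * nrow(model$W_markers))
    stop("fewer than 50% of model marker genes present in new data", call. = FALSE)
  if (any(expr_new < 0, na.rm = TRUE))
    stop("negative expression values", call. = FALSE)
  A <- model$W_markers[avail, , drop = FALSE]
  labs <- vapply(seq_len(ncol(expr_new)), function(j) {
    b <- expr_new[avail, j]
    ok <- !is.na(b)
    h <- pracma::lsqnonneg(A[ok, , drop = FALSE], b[ok])$x
    s <- sum(h)
    if (s > 0) h <- h / s
    model$cluster_labels[which(h == max(h))[1]]
  }, "")
  setNames(labs, colnames(expr_new))
}

#' Derive a subtype model from a seed gene list
#'
#' The full subtyping procedure: restrict to the seed genes, drop sparse
#' or weakly expressed genes, median-center, run consensus clustering
#' over `k_range`, determine K with half-normal-prior B-NMF, factorize
#' the filtered log2 TPM matrix at that K, and extract disjoint
#' per-cluster markers.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Seed gene list (e.g. DE-filtered genes for the
#'   microenvironmental variant, high-variance genes for the
#'   tumor-intrinsic variant).
#' @param k_range,iterations,resample_fraction,linkage Consensus settings.
#' @param n_restarts Restarts used for both B-NMF stages.
#' @param n_markers Markers per cluster.
#' @param label_prefix Cluster label prefix.
#' @param seed Integer master seed for the stage.
#' @param ... Passed to [factorize()].
#' @return List with `model` (`subtype_model`), `K`, `consensus`, `fact`
#'   and `assignments`.
#' @export
derive_subtype_model <- function(expr, genes, k_range = 2:10,
                                 iterations = 500L, resample_fraction = 0.8,
                                 linkage = "average", n_restarts = 10L,
                                 n_markers = 50L, label_prefix = "C",
                                 seed = 1L, ...) {
  expr_f <- expr[intersect(rownames(expr), genes), , drop = FALSE]
  keep <- filter_low_quality_genes(expr_f)
  expr_f <- expr_f[keep, , drop = FALSE]
  fc <- median_center(expr_f)
  cons <- consensus_matrix(fc, k_range = k_range, iterations = iterations,
                           resample_fraction = resample_fraction,
                           linkage = linkage, seed = derive_seed(seed, "consensus"))
  K <- determine_k(cons, n_restarts = n_restarts, seed = derive_seed(seed, "determine_k"), ...)
  sub <- derive_subtypes(expr_f, K, n_restarts = n_restarts,
                         seed = derive_seed(seed, "derive_subtypes"), ...)
  model <- extract_markers(sub$fact, expr_f, sub$assignments,
                           n_markers = n_markers, label_prefix = label_prefix)
  list(model = model, K = K, consensus = cons, fact = sub$fact,
       assignments = sub$assignments)
}

#' Tumor-intrinsic subtype derivation
#'
#' The same procedure as the microenvironmental variant, except the seed
#' gene list is the `variance_top_n` highest-variance genes of the
#' reference collection instead of differentially expressed genes.
#'
#' @param expr_reference Reference expression matrix (>= 100 samples).
#' @param variance_top_n Number of high-variance genes kept (default 2000,
#'   capped implicitly by the error below).
#' @param ... Passed to [derive_subtype_model()].
#' @return As [derive_subtype_model()].
#' @export
derive_ti_subtypes <- function(expr_reference, variance_top_n = 2000L, ...) {
  if (ncol(expr_reference) < 100)
    stop("tumor-intrinsic derivation needs >= 100 reference samples", call. = FALSE)
  if (variance_top_n > nrow(expr_reference))
    stop("variance_top_n exceeds the number of genes", call. = FALSE)
  vars <- apply(expr_reference, 1, var, na.rm = TRUE)
  genes <- names(sort(vars, decreasing = TRUE))[seq_len(variance_top_n)]
  derive_subtype_model(expr_reference, genes, label_prefix = "TI", ...)
}
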