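#' Bayesian NMF with automatic relevance determination
#'
#' Factorizes a nonnegative matrix `V` (features x samples) as `W %*% H`
#' under a Bayesian model in which each component k carries a relevance
#' scale shared by the k-th column of `W` and row of `H`, with an
#' inverse-gamma hyperprior. Maximum-a-posteriori optimization by
#' multiplicative majorization-minimization updates shrinks superfluous
#' components toward zero, so the effective rank `K_eff` is learned rather
#' than fixed. This is the shared engine behind consensus-matrix cluster
#' number selection, expression subtyping and SBS96 signature extraction.
#'
#' @param V Nonnegative numeric matrix (no missing values, >= 2 rows and
#'   columns).
#' @param K_max Maximum number of components (upper bound on the rank).
#' @param prior Component prior: `"half-normal"` (L2 shrinkage, the default
#'   used for consensus matrices and expression) or `"exponential"` (L1,
#'   sparser, the default for mutation catalogs).
#' @param divergence Data term: `"gaussian"` (half squared Frobenius) or
#'   `"poisson"` (KL, for counts).
#' @param a Relevance inverse-gamma shape hyperparameter (default 5; a
#'   lighter shape keeps the relevance scales adaptive, which empirically
#'   separates true from superfluous components most reliably).
#' @param b Relevance inverse-gamma scale; `NULL` uses the data-driven
#'   heuristic matching the prior mean of the reconstruction to `mean(V)`.
#' @param phi Dispersion of the data term; `NULL` uses 1 for the poisson
#'   divergence and, for gaussian, a noise-variance estimate (residual
#'   variance after a rank-`K_max` truncated SVD, floored at 2% of the
#'   total variance so near-noiseless input still consolidates).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum multiplicative updates.
#' @param prune_threshold Component considered inactive when the product of
#'   its `W` column and `H` row norms falls below this fraction of the
#'   largest component's.
#' @param eps Numerical floor avoiding division by zero.
#' @param seed Integer seed for the random uniform initialization.
#' @param polish After rank selection, refit the active components with
#'   the prior essentially off (plus one alternating-NNLS round for the
#'   gaussian divergence), removing shrinkage bias from the reported
#'   factors.
#' @return A `factorization_result` list: `W` (features x K_max, active
#'   columns normalized to sum 1), `H` (K_max x samples, compensated),
#'   `relevance`, `active_components`, `K_eff`, `objective_trace`
#'   (negative log-posterior per iteration, non-increasing), `converged`,
#'   `log_posterior`, `n_iter` and `seed`.
#' @export
factorize <- function(V, K_max,
                      prior = c("half-normal", "exponential"),
                      divergence = c("gaussian", "poisson"),
                      a = 5, b = NULL, phi = NULL,
                      tol = 1e-7, max_iter = 100000L,
                      prune_threshold = 0.01, eps = 1e-10, seed = 1L,
                      polish = TRUE) {
  prior <- match.arg(prior)
  divergence <- match.arg(divergence)
  if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix", call. = FALSE)
  if (anyNA(V)) stop("V must not contain missing values", call. = FALSE)
  if (nrow(V) < 2 || ncol(V) < 2) stop("V needs at least 2 rows and 2 columns", call. = FALSE)
  if (any(V < 0)) stop("V must be nonnegative", call. = FALSE)
  if (all(V == 0)) stop("V is identically zero", call. = FALSE)
  if (K_max < 1) stop("K_max must be >= 1", call. = FALSE)

  mV <- mean(V)
  if (is.null(b)) {
    b <- if (prior == "exponential") {
      sqrt((a - 1) * (a - 2) * mV / K_max)
    } else {
      pi / 2 * (a - 1) * mV / K_max
    }
  }
  if (is.null(phi)) {
    if (divergence == "gaussian") {
      # dispersion ~ noise variance: residual variance after a rank-K_max
      # truncated SVD, floored at 1% of the total variance so the prior
      # can still consolidate duplicated components on noiseless input
      r <- min(K_max, nrow(V) - 1L, ncol(V) - 1L)
      sv <- svd(V, nu = 0, nv = 0)$d
      resid <- if (length(sv) > r) sum(sv[(r + 1):length(sv)]^2) / length(V) else 0
      phi <- max(resid, 0.02 * var(as.vector(V)), 1e-4 * mV^2, eps)
    } else {
      phi <- 1
    }
  }

  set.seed(seed)
  scale0 <- sqrt(mV / K_max)
  W0 <- matrix(runif(nrow(V) * K_max, min = 0.5, max = 1.5) * scale0, nrow(V), K_max)
  H0 <- matrix(runif(K_max * ncol(V), min = 0.5, max = 1.5) * scale0, K_max, ncol(V))

  fit <- .ardnmf_fit(V, W0, H0,
                     divergence = if (divergence == "gaussian") 0L else 1L,
                     prior = if (prior == "half-normal") 0L else 1L,
                     a = a, b = b, phi = phi,
                     tol = tol, max_iter = as.integer(max_iter), eps = eps)

  W <- fit$W
  H <- fit$H
  norm_prod <- sqrt(colSums(W^2)) * sqrt(rowSums(H^2))
  active <- which(norm_prod > prune_threshold * max(norm_prod))

  # polish: refit the surviving components with the prior essentially off
  # (dispersion scaled down so the data term dominates), removing the
  # shrinkage bias from the reported factors; rank selection and the
  # reported posterior come from the ARD phase above
  if (polish && length(active) >= 1) {
    ref <- .ardnmf_fit(V, W[, active, drop = FALSE], H[active, , drop = FALSE],
                       divergence = if (divergence == "gaussian") 0L else 1L,
                       prior = if (prior == "half-normal") 0L else 1L,
                       a = a, b = b, phi = phi * 1e-6,
                       tol = tol * 1e-2, max_iter = as.integer(max_iter), eps = eps)
    W[, active] <- ref$W
    H[active, ] <- ref$H
    if (divergence == "gaussian") {
      # one alternating-NNLS round finishes off the slow multiplicative
      # tail on the active components (exact per-row/column least squares)
      refined <- tryCatch({
        Wa <- W[, active, drop = FALSE]
        Ha <- H[active, , drop = FALSE]
        for (j in seq_len(ncol(V))) Ha[, j] <- pracma::lsqnonneg(Wa, V[, j])$x
        for (i in seq_len(nrow(V))) Wa[i, ] <- pracma::lsqnonneg(t(Ha), V[i, ])$x
        list(W = Wa, H = Ha)
      }, error = function(e) NULL)
      if (!is.null(refined)) {
        W[, active] <- refined$W
        H[active, ] <- refined$H
      }
    }
  }
  # column-stochastic reporting: active W columns sum to 1, H compensated
  for (k in active) {
    s <- sum(W[, k])
    if (s > 0) {
      W[, k] <- W[, k] / s
      H[k, ] <- H[k, ] * s
    }
  }
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)

  structure(list(
    W = W, H = H,
    relevance = fit$lambda,
    norm_product = norm_prod,
    active_components = active,
    K_eff = length(active),
    objective_trace = fit$objective_trace,
    converged = fit$converged,
    log_posterior = -fit$objective_trace[length(fit$objective_trace)],
    n_iter = fit$n_iter,
    prior = prior, divergence = divergence,
    a = a, b = b, phi = phi, seed = seed
  ), class = "factorization_result")
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf("ARD-NMF fit: %d x %d, K_max = %d, K_eff = %d (%s prior, %s divergence)\n",
              nrow(x$W), ncol(x$H), ncol(x$W), x$K_eff, x$prior, x$divergence))
  cat(sprintf("  converged: %s after %d iterations; log-posterior %.4g\n",
              x$converged, x$n_iter, x$log_posterior))
  invisible(x)
}

#' Run several seeded factorizations
#'
#' @inheritParams factorize
#' @param n_restarts Number of random initializations.
#' @param seed Master seed; restart i uses a seed derived from it.
#' @param ... Passed to [factorize()].
#' @return List of `factorization_result`s.
#' @export
factorize_restarts <- function(V, K_max, n_restarts = 20L, seed = 1L, ...) {
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  lapply(seq_len(n_restarts), function(i) {
    factorize(V, K_max, seed = derive_seed(seed, paste0("restart", i)), ...)
  })
}

#' Select the representative run among restarts
#'
#' Among converged runs, finds the modal effective rank; among runs with
#' that rank, returns the one with maximal log-posterior (mirroring the
#' modal-K, maximum-posterior selection used for signature extraction).
#' Ties in the mode are broken toward the smaller rank.
#'
#' @param runs Nonempty list of `factorization_result`s.
#' @return The selected `factorization_result`.
#' @export
select_best_run <- function(runs) {
  if (length(runs) == 0) stop("no runs supplied", call. = FALSE)
  conv <- Filter(function(r) isTRUE(r$converged), runs)
  if (length(conv) == 0) stop("no converged runs", call. = FALSE)
  ks <- vapply(conv, `[[`, 0L, "K_eff")
  tab <- table(ks)
  modal_k <- as.integer(names(tab)[tab == max(tab)])[1]
  cand <- conv[ks == modal_k]
  lp <- vapply(cand, `[[`, 0, "log_posterior")
  cand[[which.max(lp)]]
}

#' Cosine similarity between columns of two matrices
#' @param A,B Matrices with matching row count.
#' @return Matrix of pairwise column cosine similarities.
#' @keywords internal
cosine_similarity <- function(A, B) {
  An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), 1e-12), "/")
  Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), 1e-12), "/")
  crossprod(An, Bn)
}
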