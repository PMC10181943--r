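# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force / closed form) and share no code with
# the package internals.

# Plain multiplicative NMF under Frobenius loss, no prior, no pruning.
plain_nmf <- function(V, K, seed, n_iter = 5000) {
  set.seed(seed)
  W <- matrix(runif(nrow(V) * K, 0.1, 1), nrow(V), K)
  H <- matrix(runif(K * ncol(V), 0.1, 1), K, ncol(V))
  eps <- 1e-12
  for (i in seq_len(n_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  list(W = W, H = H, err = norm(V - W %*% H, "F") / norm(V, "F"))
}

# Best reconstruction error over many restarts of plain NMF.
plain_nmf_best_err <- function(V, K, n_restarts = 50) {
  min(vapply(seq_len(n_restarts), function(s) plain_nmf(V, K, seed = s)$err, 0))
}

# Benjamini-Hochberg by the literal step-up definition:
# q_(i) = min_{j >= i} p_(j) * m / j, monotone from the top.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- min(prev, 1)
  }
  q
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# group assignments (no ties allowed).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) # Mann-Whitney U for the first group
  }
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Upper-tail hypergeometric by explicit enumeration over overlap counts.
hyper_enum_p <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Hand-evaluated two-group log-rank chi-square statistic.
logrank_by_hand <- function(time, event, group) {
  stopifnot(all(event == 1) || TRUE)
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(factor(group))[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == levels(factor(group))[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Exhaustive consensus expectation for a small cohort: enumerate every
# subsample of the given size, rerun the clustering deterministically,
# and average co-membership over subsamples containing both items.
consensus_enum <- function(fc, n_sub, K) {
  n <- ncol(fc)
  corr <- stats::cor(fc, method = "spearman")
  combos <- utils::combn(n, n_sub)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (c_i in seq_len(ncol(combos))) {
    sub <- combos[, c_i]
    hc <- stats::hclust(stats::as.dist(1 - corr[sub, sub]), method = "average")
    cl <- stats::cutree(hc, k = K)
    co_cluster[sub, sub] <- co_cluster[sub, sub] + outer(cl, cl, "==")
    co_sample[sub, sub] <- co_sample[sub, sub] + 1
  }
  co_cluster / pmax(co_sample, 1)
}
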