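make_expr <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  values
}

test_that("DE gene filter applies strict inequalities at both thresholds", {
  expr <- make_expr(matrix(1, 4, 5), genes = c("a", "b", "c", "d"))
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   p = c(0.04, 0.04, 0.05, 0.01),
                   lfc = c(0.6, 0.5, 2, -0.7))
  kept <- filter_de_genes(expr, de)
  expect_true("a" %in% kept)        # p < 0.05, |lfc| > 0.5
  expect_false("b" %in% kept)       # |lfc| = 0.5 exactly: dropped
  expect_false("c" %in% kept)       # p = 0.05 exactly: dropped
  expect_true("d" %in% kept)        # negative lfc counts via absolute value
  expect_error(filter_de_genes(expr, de[-1, ]), "missing from DE")
})

test_that("low-quality filter removes sparse genes and the bottom mean decile", {
  set.seed(5)
  n <- 100
  expr <- make_expr(matrix(runif(20 * n, 1, 5), 20, n))
  expr["G001", 1:11] <- 0                      # 11% zeros: sparse
  expr["G002", ] <- runif(n, 4, 5)             # high mean ...
  expr["G002", 1:10] <- 0                      # ... with exactly 10% zeros: allowed
  expr["G003", ] <- 0.01                       # dense but weakest mean
  kept <- filter_low_quality_genes(expr)
  expect_false("G001" %in% kept)
  expect_true("G002" %in% kept)
  expect_false("G003" %in% kept)
  expect_true("G010" %in% kept)
})

test_that("median centering yields zero-median rows", {
  expr <- make_expr(matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE))
  fc <- median_center(expr)
  expect_equal(unname(fc[1, ]), c(-1, 0, 1))
  expect_equal(unname(fc[2, ]), c(0, 0, 0))
  set.seed(6)
  rand <- make_expr(matrix(rnorm(30 * 7), 30, 7))
  expect_equal(unname(apply(median_center(rand), 1, median)), rep(0, 30))
})

test_that("consensus frequencies are valid and duplicated samples always co-cluster", {
  set.seed(7)
  base <- matrix(rnorm(40 * 8), 40, 8)
  base[, 8] <- base[, 7]  # exact duplicate
  fc <- make_expr(base)
  cons <- consensus_matrix(fc, k_range = 2:4, iterations = 60, seed = 1)
  for (M in cons$per_k_consensus) {
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(M, t(M))
    expect_equal(M["S007", "S008"], 1)
  }
  expect_true(all(cons$summed_normalized >= 0 & cons$summed_normalized <= 1))
  expect_error(consensus_matrix(fc, k_range = 2:10), "k_range")
})

test_that("well-separated blobs give near-binary consensus at K = 2", {
  set.seed(8)
  blob <- matrix(rnorm(60 * 12), 60, 12)
  blob[1:30, 1:6] <- blob[1:30, 1:6] + 5     # program A genes, samples 1-6
  blob[31:60, 7:12] <- blob[31:60, 7:12] + 5 # program B genes, samples 7-12
  fc <- make_expr(blob)
  cons <- consensus_matrix(fc, k_range = 2, iterations = 200, seed = 2)
  M <- cons$per_k_consensus$K2
  within <- c(M[1:6, 1:6][upper.tri(M[1:6, 1:6])],
              M[7:12, 7:12][upper.tri(M[7:12, 7:12])])
  expect_true(all(within >= 0.95))
  expect_true(all(M[1:6, 7:12] <= 0.05))
})

test_that("Monte-Carlo consensus matches the exhaustive subsample oracle", {
  set.seed(9)
  blob <- cbind(matrix(rnorm(10 * 3, 0, 0.8), 10, 3),
                matrix(rnorm(10 * 3, 2, 0.8), 10, 3))
  fc <- make_expr(blob)
  n_sub <- round(0.8 * 6)
  expected <- consensus_enum(fc, n_sub, K = 2)
  cons <- consensus_matrix(fc, k_range = 2, iterations = 500, seed = 3)
  got <- cons$per_k_consensus$K2
  # each entry is a ratio of counts over uniformly drawn subsamples;
  # allow 4 binomial standard errors around the enumerated expectation
  n_pairs <- 500 * (n_sub / 6) * ((n_sub - 1) / 5)
  tol <- 4 * sqrt(0.25 / n_pairs)
  off <- upper.tri(expected)
  expect_true(all(abs(got[off] - expected[off]) <= tol + 1e-9))
})

test_that("determine_k recovers block counts and degenerate cases", {
  cl <- rep(1:3, each = 8)
  ideal <- outer(cl, cl, "==") * 1
  expect_equal(determine_k(ideal, n_restarts = 5, seed = 1), 3L)
  expect_equal(determine_k(matrix(1, 20, 20), n_restarts = 5, seed = 1), 1L)
})

test_that("subtype factorization assigns noiseless programs exactly", {
  sc <- expression_scenario(n_samples = 24, n_genes = 60, n_programs = 2,
                            markers_per_program = 15, marker_effect = 3,
                            noise_sd = 0, dropout_rate = 0)
  sim <- simulate_expression(sc, seed = 12)
  sub <- derive_subtypes(sim$expression, K = 2, n_restarts = 5, seed = 1)
  agree <- max(mean((sub$assignments == 1) == (sim$truth$program == 1)),
               mean((sub$assignments == 2) == (sim$truth$program == 1)))
  expect_equal(agree, 1)
  # K = 1 puts everything in one cluster
  one <- derive_subtypes(sim$expression, K = 1, n_restarts = 2, seed = 1)
  expect_true(all(one$assignments == 1))
})

test_that("marker extraction respects the top-weight and expression-difference rules", {
  sc <- expression_scenario(n_samples = 30, n_genes = 80, n_programs = 2,
                            markers_per_program = 20, marker_effect = 3,
                            noise_sd = 0.2, dropout_rate = 0)
  sim <- simulate_expression(sc, seed = 13)
  sub <- derive_subtypes(sim$expression, K = 2, n_restarts = 5, seed = 2)
  model <- extract_markers(sub$fact, sim$expression, sub$assignments,
                           n_markers = 20, label_prefix = "M")
  expect_s3_class(model, "subtype_model")
  expect_equal(model$K, 2L)
  # marker lists are disjoint
  expect_equal(anyDuplicated(unlist(model$marker_genes)), 0L)
  # markers recover the true program blocks well
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  best <- sapply(sim$truth$marker_blocks, function(block)
    max(sapply(model$marker_genes, jac, b = block)))
  expect_true(all(best >= 0.6))
  # a gene high in W for a cluster but expressed higher outside is excluded
  expr2 <- sim$expression
  in_a <- names(sub$assignments)[sub$assignments == 1]
  expr2["G0080", ] <- 5
  expr2["G0080", setdiff(colnames(expr2), in_a)] <- 9
  f2 <- sub$fact
  # give G080 the dominant weight in component 1 (cluster A): it is then
  # eligible only for A, where its expression difference is negative
  f2$W["G0080", f2$active_components[1]] <- max(f2$W[, f2$active_components[1]]) * 2
  f2$W["G0080", f2$active_components[2]] <- 0
  m2 <- extract_markers(f2, expr2, sub$assignments, n_markers = 30)
  expect_false("G0080" %in% unlist(m2$marker_genes))
})

test_that("classification reproduces training labels and handles marker loss", {
  sc <- expression_scenario(n_samples = 40, n_genes = 100, n_programs = 2,
                            markers_per_program = 25, marker_effect = 3,
                            noise_sd = 0, dropout_rate = 0)
  sim <- simulate_expression(sc, seed = 14)
  sub <- derive_subtypes(sim$expression, K = 2, n_restarts = 5, seed = 3)
  model <- extract_markers(sub$fact, sim$expression, sub$assignments,
                           n_markers = 25)
  relabeled <- classify_samples(model, sim$expression)
  expect_equal(unname(relabeled), unname(model$assignments))

  # held-out noiseless samples from the same generative process
  sim2 <- simulate_expression(sc, seed = 15)
  held <- classify_samples(model, sim2$expression)
  # map cluster labels to programs via the training majority
  map <- sapply(model$cluster_labels, function(l) {
    names(which.max(table(sim$truth$program[model$assignments == l])))
  })
  expect_gte(mean(map[held] == as.character(sim2$truth$program)), 0.95)

  few <- sim$expression[unlist(model$marker_genes)[1:10], , drop = FALSE]
  expect_error(classify_samples(model, few), "50%")
})

test_that("tumor-intrinsic derivation validates its inputs", {
  small <- make_expr(matrix(runif(200 * 50, 0, 4), 200, 50))
  expect_error(derive_ti_subtypes(small), ">= 100")
  big <- make_expr(matrix(runif(200 * 120, 0, 4), 200, 120))
  expect_error(derive_ti_subtypes(big, variance_top_n = 500), "exceeds")
})

test_that("sample relabeling permutes assignments consistently", {
  sc <- expression_scenario(n_samples = 20, n_genes = 50, n_programs = 2,
                            markers_per_program = 12, marker_effect = 3,
                            noise_sd = 0, dropout_rate = 0)
  sim <- simulate_expression(sc, seed = 16)
  perm <- sample(ncol(sim$expression))
  sub1 <- derive_subtypes(sim$expression, K = 2, n_restarts = 3, seed = 4)
  sub2 <- derive_subtypes(sim$expression[, perm], K = 2, n_restarts = 3, seed = 4)
  # same partition of samples, up to component relabeling
  part1 <- unname(sub1$assignments[colnames(sim$expression)[perm]])
  part2 <- unname(sub2$assignments)
  agree <- max(mean((part1 == 1) == (part2 == 1)),
               mean((part1 == 1) == (part2 == 2)))
  expect_equal(agree, 1)
})
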