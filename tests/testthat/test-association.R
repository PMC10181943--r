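test_that("minimal-expression filter is inclusive at 30% and coding-restricted", {
  n <- 100
  expr <- matrix(0, 3, n, dimnames = list(c("cod29", "cod30", "nonc"), NULL))
  colnames(expr) <- sprintf("s%03d", 1:n)
  expr["cod29", 1:29] <- 1
  expr["cod30", 1:30] <- 0.5   # exactly the floor, exactly 30%
  expr["nonc", ] <- 5
  kept <- expression_filter(expr, coding_genes = c("cod29", "cod30"))
  expect_false("cod29" %in% kept)
  expect_true("cod30" %in% kept)
  expect_false("nonc" %in% kept)
  expect_error(expression_filter(expr, character(0)), "empty")
})

test_that("differential expression finds planted shifts and is calibrated under the null", {
  set.seed(31)
  n <- 10
  expr <- matrix(rnorm(200 * 2 * n, 5, 1), 200, 2 * n,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:(2 * n))))
  response <- rep(c(1, 0), each = n)
  expr["g001", response == 1] <- rnorm(n, 7, 0.1)
  expr["g001", response == 0] <- rnorm(n, 5, 0.1)
  de <- differential_expression(expr, response)
  expect_lt(de$p[de$gene == "g001"], 1e-6)
  expect_equal(de$lfc[de$gene == "g001"], 2, tolerance = 0.25)

  # global null: p-values approximately uniform
  null_p <- de$p[-1]
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)

  # identical groups: zero fold change, p near 1
  same <- cbind(expr[, 1:5], expr[, 1:5])
  de2 <- differential_expression(same, rep(c(1, 0), each = 5))
  expect_equal(de2$lfc, rep(0, nrow(same)))
  expect_true(all(de2$p > 0.999))
  expect_error(differential_expression(expr, c(rep(1, 2), rep(0, 2 * n - 2))),
               "at least 3")
})

test_that("prevalence filter keeps 5% inclusively and ignores continuous features", {
  df <- data.frame(sample_id = sprintf("s%03d", 1:100),
                   rare = c(rep(1, 4), rep(0, 96)),
                   edge = c(rep(1, 5), rep(0, 95)),
                   burden = rexp(100))
  ft <- feature_table(df, c(rare = "binary", edge = "binary", burden = "burden"))
  out <- prevalence_filter(ft, 0.05)
  expect_false("rare" %in% names(out))
  expect_true("edge" %in% names(out))
  expect_true("burden" %in% names(out))
})

test_that("logistic odds ratios match the 2x2 cross-product oracle", {
  # feature x response layout a=10, b=5, c=5, d=10
  x <- c(rep(1, 15), rep(0, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  res <- logistic_screen(data.frame(sample_id = 1:30, f = x), y)
  expect_equal(res$odds_ratio, (10 * 10) / (5 * 5), tolerance = 1e-6)
  expect_true(res$ci_low < res$odds_ratio && res$odds_ratio < res$ci_high)

  # null feature: OR near 1, p > 0.05 in >= 90% of simulations
  set.seed(32)
  hits <- 0
  for (i in 1:50) {
    xf <- rnorm(120)
    yf <- rbinom(120, 1, 0.4)
    r <- logistic_screen(data.frame(sample_id = 1:120, f = xf), yf)
    if (r$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)

  # complete separation is flagged and excluded from the BH family
  xs <- c(rep(0, 10), rep(1, 10))
  sep <- logistic_screen(data.frame(sample_id = 1:20, f = xs, g = rnorm(20)), xs)
  expect_true(sep$separated[sep$feature == "f"])
  expect_true(is.na(sep$q[sep$feature == "f"]))
  expect_false(is.na(sep$q[sep$feature == "g"]))
})

test_that("BH adjustment equals the step-up oracle on exhaustive small cases", {
  set.seed(33)
  for (n in 1:10) {
    for (rep in 1:20) {
      p <- runif(n)
      expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
    }
  }
  # worked closed form: all q equal max step
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("hypergeometric ORA equals exact enumeration", {
  universe <- letters[1:10]
  q <- gene_set("q", letters[1:5])
  refs <- list(gene_set("hit", letters[1:5]), gene_set("none", letters[6:9]))
  res <- hypergeometric_ora(q, refs, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_gt(res$p[res$set == "none"], 0.99)

  # oracle equivalence over random configurations with universe <= 12
  set.seed(34)
  for (i in 1:25) {
    u <- letters[1:sample(5:12, 1)]
    rs <- sample(u, sample(2:length(u), 1))
    qs <- sample(u, sample(2:length(u), 1))
    got <- hypergeometric_ora(gene_set("q", qs), list(gene_set("r", rs)), u)$p
    k <- length(intersect(qs, rs))
    expect_equal(got, hyper_enum_p(k, length(rs), length(u), length(qs)),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_ora(gene_set("q", "zz"), refs, universe), "subset")
})

test_that("gene-set significance comparison matches exhaustive permutation", {
  de <- data.frame(gene = sprintf("g%d", 1:6),
                   lfc = rep(1, 6),
                   p = 10^-c(1, 2, 3, 4, 5, 6))
  a <- gene_set("a", c("g1", "g2", "g3"))
  b <- gene_set("b", c("g4", "g5", "g6"))
  res <- compare_set_significance(de, a, b)
  # scores are 1..6: fully separated groups, exact two-sided p = 2/C(6,3)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, 0)

  set.seed(35)
  for (i in 1:10) {
    p_vals <- runif(8)
    de2 <- data.frame(gene = sprintf("g%d", 1:8), lfc = rnorm(8), p = p_vals)
    a2 <- gene_set("a", sprintf("g%d", 1:4))
    b2 <- gene_set("b", sprintf("g%d", 5:8))
    got <- compare_set_significance(de2, a2, b2)$p
    want <- mw_exact_p(-log10(p_vals[1:4]), -log10(p_vals[5:8]))
    expect_equal(got, want, tolerance = 1e-9)
  }

  # overlapping members are excluded before testing
  de7 <- data.frame(gene = sprintf("g%d", 1:7), lfc = rep(1, 7),
                    p = 10^-(1:7))
  ab <- gene_set("ab", c("g1", "g2", "g3", "g4"))
  res2 <- compare_set_significance(de7, ab, gene_set("b2", c("g4", "g5", "g6", "g7")))
  expect_equal(res2$excluded_overlap, "g4")
  expect_equal(res2$n_a, 3)
  expect_equal(res2$n_b, 3)
})

test_that("bivariate model reports nested R-squared correctly", {
  set.seed(36)
  x1 <- rnorm(50); x2 <- rnorm(50)
  y <- 2 + 3 * x1 - x2
  fit <- bivariate_expression_model(y, x1, x2)
  expect_equal(fit$r2_combined, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(2, 3, -1), tolerance = 1e-8)

  y2 <- rnorm(200)
  fit2 <- bivariate_expression_model(y2, rnorm(200), rnorm(200))
  expect_lt(fit2$r2_combined, 0.05)
  expect_gte(fit2$r2_combined, max(fit2$r2_x1, fit2$r2_x2))
  expect_error(bivariate_expression_model(y[1:10], x1[1:10], x1[1:10] * 2),
               "collinear")
})

test_that("feature binning follows the documented cut rules", {
  expect_equal(as.character(bin_feature(c(0.3, -0.2, 0), "zscore")),
               c("high", "low", "low"))
  b <- bin_feature(c(1, 2, 3, 3, 9), "burden")  # median 3 -> ties low
  expect_equal(as.character(b), c("low", "low", "low", "low", "high"))
  expect_equal(as.character(bin_feature(c("M-1", "M-2"), "cluster", cluster = "M-2")),
               c("low", "high"))
  expect_equal(as.character(bin_feature(c(1, 0), "alteration")), c("high", "low"))
  expect_error(bin_feature(1, "nope"), "unknown")
})

test_that("log-rank matches the hand-computed toy and detects separation", {
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  grp <- factor(c("A", "A", "B", "B"))
  res <- km_logrank(time, event, grp)
  expect_equal(res$statistic, logrank_by_hand(time, event, grp), tolerance = 1e-6)
  # and against the fully hand-evaluated value for this table
  expect_equal(res$statistic, (2 - (0.5 + 1/3))^2 / (0.25 + 2/9), tolerance = 1e-6)

  # identical groups: statistic ~ 0
  t2 <- rep(c(2, 3, 5, 7), 2); e2 <- rep(1, 8)
  g2 <- rep(c("A", "B"), each = 4)
  res2 <- km_logrank(t2, e2, g2)
  expect_lt(res2$statistic, 1e-10)
  expect_gt(res2$p, 0.99)

  # strongly separated exponential groups are detected
  set.seed(37)
  detected <- 0
  for (i in 1:20) {
    ta <- rexp(100, 1); tb <- rexp(100, 4)
    r <- km_logrank(c(ta, tb), rep(1, 200), rep(c("A", "B"), each = 100))
    if (r$p < 1e-4) detected <- detected + 1
  }
  expect_gte(detected, 19)
  expect_error(km_logrank(c(1, 2), c(0, 0), c("A", "B")), "events")
})

test_that("a global-null screen controls false calls at the nominal FDR", {
  # under a complete null with independent features, BH makes at least one
  # q < 0.1 call in about 10% of screens (the Simes identity); the
  # clean-replicate rate should sit near 90% and per-feature false calls
  # must stay rare
  set.seed(38)
  clean <- 0
  called <- 0
  n_rep <- 20
  for (rep in seq_len(n_rep)) {
    feats <- as.data.frame(matrix(rnorm(200 * 100), 200, 100))
    names(feats) <- sprintf("f%03d", 1:100)
    feats$sample_id <- sprintf("s%03d", 1:200)
    y <- rbinom(200, 1, 0.4)
    res <- logistic_screen(feats, y)
    n_call <- sum(res$q < 0.1, na.rm = TRUE)
    called <- called + n_call
    if (n_call == 0) clean <- clean + 1
  }
  expect_gte(clean / n_rep, 0.70)        # 0.9 minus 3 binomial sd
  expect_lte(called / (n_rep * 100), 0.02)
})

test_that("the TMB effect is ranked near the top of a linked screen", {
  set.seed(39)
  top3 <- 0
  for (rep in 1:10) {
    n <- 150
    truth <- cohort_truth(sample_id = sprintf("s%03d", seq_len(n)))
    truth$features$tmb_ln <- rnorm(n, 2, 0.8)
    clin <- simulate_clinical(truth, feature_effects = c(tmb_ln = 1),
                              intercept = -2, seed = 1000 + rep)
    feats <- data.frame(sample_id = truth$sample_id,
                        tmb_ln = truth$features$tmb_ln)
    for (j in 1:9) feats[[paste0("noise", j)]] <- rnorm(n)
    res <- logistic_screen(feats, clin$response)
    rank_tmb <- rank(res$q, ties.method = "min")[res$feature == "tmb_ln"]
    if (rank_tmb <= 3) top3 <- top3 + 1
  }
  expect_gte(top3, 9)
})

test_that("cross-correlation clustering groups related features", {
  set.seed(40)
  n <- 80
  base1 <- rnorm(n); base2 <- rnorm(n)
  feats <- data.frame(a1 = base1 + rnorm(n, 0, 0.2),
                      a2 = base1 + rnorm(n, 0, 0.2),
                      a2dup = NA,
                      b1 = -base1 + rnorm(n, 0, 0.2),
                      b2 = base2 + rnorm(n, 0, 0.2))
  feats$a2dup <- feats$a2
  cc <- cross_correlation_cluster(feats, n_blocks = 2)
  expect_equal(cc$correlation, t(cc$correlation))
  expect_equal(unname(diag(cc$correlation)), rep(1, 5))
  expect_equal(cc$blocks[["a2"]], cc$blocks[["a2dup"]])
  expect_equal(cc$blocks[["a1"]], cc$blocks[["a2"]])

  feats$const <- 1
  expect_warning(cc2 <- cross_correlation_cluster(feats, 2), "constant")
  expect_false("const" %in% names(cc2$blocks))
})
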