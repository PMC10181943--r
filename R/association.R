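#' Minimal-expression filter for differential analysis
#'
#' Restricts to protein-coding genes expressed at `min_log2tpm` or higher
#' in at least `min_fraction` of samples (both bounds inclusive).
#'
#' @param expr Expression matrix.
#' @param coding_genes Nonempty character vector of protein-coding
#'   symbols.
#' @param min_log2tpm Expression floor (default 0.5 log2 TPM).
#' @param min_fraction Minimum fraction of samples at or above the floor
#'   (default 0.30).
#' @return Character vector of retained genes.
#' @export
expression_filter <- function(expr, coding_genes, min_log2tpm = 0.5,
                              min_fraction = 0.30) {
  if (length(coding_genes) == 0) stop("coding gene list is empty", call. = FALSE)
  keep <- intersect(rownames(expr), coding_genes)
  ge <- expr[keep, , drop = FALSE] >= min_log2tpm
  ge[is.na(ge)] <- FALSE   # a missing value does not count as expressed
  keep[rowMeans(ge) >= min_fraction]
}

#' Gene-wise differential expression between response groups
#'
#' A per-gene unequal-variance (Welch) two-sample test on log2 values
#' with BH adjustment across genes. This is a simple gene-wise stand-in
#' for a moderated linear model: it reports the same quantities (log fold
#' change responders minus nonresponders, p, adjusted p) without sharing
#' variance information across genes.
#'
#' @param expr Expression matrix.
#' @param response Binary vector (1 = responder) aligned with the sample
#'   columns; both groups need >= 3 samples.
#' @return data.frame with `gene`, `lfc`, `p`, `p_adj`.
#' @export
differential_expression <- function(expr, response) {
  response <- as.integer(response)
  if (sum(response == 1) < 3 || sum(response == 0) < 3)
    stop("both response groups need at least 3 samples", call. = FALSE)
  r <- expr[, response == 1, drop = FALSE]
  nr <- expr[, response == 0, drop = FALSE]
  lfc <- rowMeans(r, na.rm = TRUE) - rowMeans(nr, na.rm = TRUE)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- r[i, ]; y <- nr[i, ]
    tryCatch(t.test(x, y)$p.value,
             error = function(e) if (isTRUE(all.equal(mean(x, na.rm = TRUE),
                                                      mean(y, na.rm = TRUE)))) 1 else NA_real_)
  }, 0)
  data.frame(gene = rownames(expr), lfc = lfc, p = p,
             p_adj = p.adjust(p, method = "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Prevalence filter for binary alteration features
#'
#' Binary (mutation / copy-number) features are kept only when present in
#' at least `min_prevalence` of the cohort (inclusive); continuous and
#' burden features pass through untouched.
#'
#' @param features A [feature_table()].
#' @param min_prevalence Minimum prevalence (default 0.05).
#' @return The filtered feature table (kinds attribute preserved).
#' @export
prevalence_filter <- function(features, min_prevalence = 0.05) {
  kinds <- attr(features, "kinds")
  drop <- vapply(names(kinds), function(f) {
    kinds[[f]] == "binary" && mean(features[[f]], na.rm = TRUE) < min_prevalence
  }, TRUE)
  keep_cols <- c("sample_id", names(kinds)[!drop])
  out <- features[, keep_cols, drop = FALSE]
  attr(out, "kinds") <- kinds[!drop]
  out
}

#' Univariate logistic screen of features against binary response
#'
#' Fits `response ~ feature` by maximum likelihood for every feature
#' column, reporting the odds ratio, Wald 95% confidence interval and
#' two-sided Wald p. BH false-discovery-rate adjustment is applied across
#' the screened set and features are tiered as significant (q < 0.1),
#' near-significant (q < 0.25) or ns. Burden features are expected to be
#' log-transformed before entry. Fits showing complete separation are
#' flagged (`separated = TRUE`, infinite CI sentinel) and excluded from
#' the BH family.
#'
#' @param features A [feature_table()] (or plain data.frame with
#'   `sample_id` and numeric feature columns).
#' @param response Binary vector aligned with the rows of `features`.
#' @param fdr_significant,fdr_near_significant Tier thresholds.
#' @return data.frame with one row per feature: `feature`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `q`, `tier`, `separated`.
#' @export
logistic_screen <- function(features, response, fdr_significant = 0.1,
                            fdr_near_significant = 0.25) {
  stopifnot(all(response %in% c(0, 1)))
  feats <- setdiff(names(features), "sample_id")
  rows <- lapply(feats, function(f) {
    x <- features[[f]]
    ok <- !is.na(x)
    fit <- suppressWarnings(glm(response[ok] ~ x[ok], family = binomial()))
    est <- coef(fit)[2]
    se <- sqrt(diag(suppressWarnings(vcov(fit))))[2]
    separated <- !fit$converged || is.na(se) || se > 50 || abs(est) > 15
    if (separated) {
      data.frame(feature = f, odds_ratio = unname(exp(est)), ci_low = 0,
                 ci_high = Inf, p = NA_real_, separated = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      z <- est / se
      data.frame(feature = f, odds_ratio = unname(exp(est)),
                 ci_low = unname(exp(est - qnorm(0.975) * se)),
                 ci_high = unname(exp(est + qnorm(0.975) * se)),
                 p = unname(2 * pnorm(-abs(z))), separated = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[!out$separated] <- p.adjust(out$p[!out$separated], method = "BH")
  out$tier <- ifelse(is.na(out$q), "ns",
                     ifelse(out$q < fdr_significant, "significant",
                            ifelse(out$q < fdr_near_significant,
                                   "near-significant", "ns")))
  out[, c("feature", "odds_ratio", "ci_low", "ci_high", "p", "q", "tier",
          "separated")]
}

#' One-sided hypergeometric over-representation test
#'
#' For each reference set, the upper-tail probability of observing at
#' least the seen overlap between the query set and the reference within
#' the universe, with BH adjustment across reference sets.
#'
#' @param query A [gene_set()]; members must lie within the universe.
#' @param reference_sets Named list of [gene_set()]s.
#' @param universe Character vector of background genes (nonempty).
#' @return data.frame with `set`, `overlap`, `set_size`, `p`, `q`.
#' @export
hypergeometric_ora <- function(query, reference_sets, universe) {
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  universe <- unique(universe)
  if (!all(query$members %in% universe))
    stop("query genes must be a subset of the universe", call. = FALSE)
  qm <- query$members
  rows <- lapply(reference_sets, function(rs) {
    m <- intersect(rs$members, universe)
    k <- length(intersect(qm, m))
    p <- phyper(k - 1, length(m), length(universe) - length(m), length(qm),
                lower.tail = FALSE)
    data.frame(set = rs$name, overlap = k, set_size = length(m), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Compare differential-expression significance between two gene sets
#'
#' Scores every gene by `-log10(p)` (optionally signed by fold-change
#' direction) and compares the score distributions of the two sets with a
#' two-sided Mann-Whitney U test (exact when sample sizes permit and no
#' ties are present). Genes in both sets are excluded.
#'
#' @param de data.frame from [differential_expression()].
#' @param set_a,set_b [gene_set()]s mapping to >= 3 scored genes each.
#' @param signed Multiply scores by `sign(lfc)`.
#' @return List with `p`, `statistic` (U for set_a), `n_a`, `n_b`,
#'   `excluded_overlap`.
#' @export
compare_set_significance <- function(de, set_a, set_b, signed = FALSE) {
  overlap <- intersect(set_a$members, set_b$members)
  a_genes <- setdiff(intersect(set_a$members, de$gene), overlap)
  b_genes <- setdiff(intersect(set_b$members, de$gene), overlap)
  if (length(a_genes) < 3 || length(b_genes) < 3)
    stop("both sets need at least 3 genes with DE results", call. = FALSE)
  score <- function(genes) {
    i <- match(genes, de$gene)
    s <- -log10(de$p[i])
    if (signed) s <- s * sign(de$lfc[i])
    s
  }
  ht <- suppressWarnings(wilcox.test(score(a_genes), score(b_genes),
                                     alternative = "two.sided"))
  list(p = ht$p.value, statistic = unname(ht$statistic),
       n_a = length(a_genes), n_b = length(b_genes),
       excluded_overlap = overlap)
}

#' Bivariate linear model of one gene on two covariates
#'
#' Ordinary least squares `y ~ x1 + x2`, reporting the combined R-squared
#' together with both univariate R-squareds (used e.g. for modeling
#' immunoproteasome subunit expression as a function of two inflammatory
#' cytokines).
#'
#' @param y Response expression vector (>= 4 samples).
#' @param x1,x2 Covariate vectors; exactly collinear covariates are an
#'   error.
#' @return List with `coefficients`, `r2_combined`, `r2_x1`, `r2_x2`.
#' @export
bivariate_expression_model <- function(y, x1, x2) {
  if (length(y) < 4) stop("need at least 4 samples", call. = FALSE)
  if (abs(cor(x1, x2)) > 1 - 1e-12)
    stop("x1 and x2 are collinear", call. = FALSE)
  fit <- lm(y ~ x1 + x2)
  r2 <- function(f) suppressWarnings(summary(f)$r.squared)
  list(coefficients = coef(fit),
       r2_combined = r2(fit),
       r2_x1 = r2(lm(y ~ x1)),
       r2_x2 = r2(lm(y ~ x2)))
}

#' Bin a feature into high/low groups for survival analysis
#'
#' Binning rules by feature kind: z-score features cut at 0; burden
#' features cut at the cohort median (values at the median go to the low
#' group); cluster features compare membership in `cluster` against the
#' rest; alteration features use presence (1) vs absence (0).
#'
#' @param x Feature vector.
#' @param kind One of `"zscore"`, `"burden"`, `"cluster"`, `"alteration"`.
#' @param cluster For `kind = "cluster"`, the label defining the high
#'   group.
#' @return Factor with levels `low`, `high`.
#' @export
bin_feature <- function(x, kind, cluster = NULL) {
  hi <- switch(kind,
    zscore = x > 0,
    burden = x > median(x, na.rm = TRUE),
    cluster = {
      if (is.null(cluster)) stop("cluster binning needs a cluster label", call. = FALSE)
      x == cluster
    },
    alteration = x == 1,
    stop(sprintf("unknown binning kind '%s'", kind), call. = FALSE))
  factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test with Kaplan-Meier medians
#'
#' Standard log-rank chi-square (1 df) between two groups, with the
#' Kaplan-Meier median survival per group.
#'
#' @param pfs_time Nonnegative survival times.
#' @param pfs_event Event indicators (1 = progressed/died, 0 = censored).
#' @param groups Two-level factor/vector; both groups nonempty.
#' @return List with `statistic`, `p`, `medians`, `n`.
#' @export
km_logrank <- function(pfs_time, pfs_event, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("need two nonempty groups", call. = FALSE)
  if (sum(pfs_event) == 0) stop("no events in either group", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(pfs_time, pfs_event) ~ groups)
  fit <- survival::survfit(survival::Surv(pfs_time, pfs_event) ~ groups)
  med <- summary(fit)$table[, "median"]
  list(statistic = sd_$chisq,
       p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       medians = setNames(as.numeric(med), levels(groups)),
       n = as.vector(table(groups)))
}

#' Log-rank screen across binned features with BH adjustment
#'
#' @param binned Named list (or data.frame) of high/low group factors, one
#'   per feature.
#' @param pfs_time,pfs_event Survival data shared by all features.
#' @return data.frame with `feature`, `statistic`, `p`, `q`,
#'   `median_low`, `median_high`.
#' @export
survival_screen <- function(binned, pfs_time, pfs_event) {
  rows <- lapply(names(binned), function(f) {
    res <- km_logrank(pfs_time, pfs_event, binned[[f]])
    data.frame(feature = f, statistic = res$statistic, p = res$p,
               median_low = res$medians[["low"]],
               median_high = res$medians[["high"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("feature", "statistic", "p", "q", "median_low", "median_high")]
}

#' Cross-correlation clustering of features
#'
#' Pairwise Spearman correlation of features across samples, followed by
#' average-linkage hierarchical clustering on 1 - correlation, cut into
#' `n_blocks` blocks. Constant features (undefined correlation) are
#' dropped with a warning.
#'
#' @param features Numeric data.frame/matrix, samples x features.
#' @param n_blocks Number of blocks to cut (<= number of usable features).
#' @return List with `correlation` (ordered matrix), `order` (leaf
#'   order), `blocks` (named assignments).
#' @export
cross_correlation_cluster <- function(features, n_blocks) {
  X <- as.matrix(features)
  keep <- apply(X, 2, function(v) sd(v, na.rm = TRUE) > 0)
  if (any(!keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < n_blocks) stop("fewer usable features than n_blocks", call. = FALSE)
  corr <- cor(X, method = "spearman", use = "pairwise.complete.obs")
  hc <- hclust(as.dist(1 - corr), method = "average")
  blocks <- cutree(hc, k = n_blocks)
  list(correlation = corr[hc$order, hc$order], order = hc$order,
       blocks = blocks)
}
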