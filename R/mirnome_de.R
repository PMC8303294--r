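#' @name mirnome_de
#' @title Negative-binomial exact-test differential expression
#'
#' @description
#' Two-group differential expression for small-RNA count matrices in the
#' style of the first-generation NB exact-test methods: median-of-ratios
#' size factors, a per-miRNA method-of-moments dispersion estimate
#' (variance = mu + alpha * mu^2), a conditional exact test on the summed
#' normalized counts of the two groups, and Benjamini-Hochberg adjustment.
#' The per-miRNA moment estimator is a deliberate simplification of the
#' shared (fitted) dispersion used by the full-scale methods: it keeps each
#' miRNA self-contained and desk-scale testable.
NULL

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over miRNAs (restricted
#' to those with a positive geometric mean across samples) of the ratio of
#' its count to the miRNA's geometric mean.
#'
#' @param counts non-negative count matrix (miRNA x sample).
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  gm <- apply(counts, 1, geomean)
  use <- gm > 0
  if (!any(use)) {
    stopf("no miRNA with all-positive counts; cannot normalize")
  }
  ratios <- counts[use, , drop = FALSE] / gm[use]
  sf <- apply(ratios, 2, stats::median)
  if (any(sf <= 0)) stopf("non-positive size factor; matrix too sparse")
  sf
}

#' Size-factor-normalized log2 expression
#'
#' @param counts count matrix (miRNA x sample).
#' @param sf size factors; computed with [size_factors()] when `NULL`.
#' @param pseudocount added before the log (default 1, for zero counts).
#' @return matrix of `log2(counts / sf + pseudocount)`.
#' @export
normalized_log2 <- function(counts, sf = NULL, pseudocount = 1) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(as.matrix(counts), 2, sf, "/") + pseudocount)
}

#' Method-of-moments NB dispersion per miRNA
#'
#' Estimates `alpha` in `variance = mu + alpha * mu^2` from the pooled
#' within-group variance of the normalized counts:
#' `alpha = max(floor, (v - m) / m^2)` with `m` the overall normalized mean.
#'
#' @param counts count matrix (miRNA x sample).
#' @param groups factor of length `ncol(counts)` with two levels, each with
#'   at least two samples.
#' @param sf size factors; computed when `NULL`.
#' @param floor lower bound for the estimate (default 1e-8).
#' @return numeric vector of dispersions, one per miRNA.
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL, floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("'groups' must have exactly two levels")
  if (length(groups) != ncol(counts)) {
    stopf("'groups' length must match the number of samples")
  }
  n <- table(groups)
  if (any(n < 2)) stopf("each group needs at least two samples")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, !g1, drop = FALSE], 1, stats::var)
  v <- ((n[1] - 1) * v1 + (n[2] - 1) * v2) / (sum(n) - 2)
  m <- rowMeans(norm)
  alpha <- ifelse(m > 0, (v - m) / m^2, floor)
  pmax(alpha, floor)
}

# log NB mass with mean mu and size n/alpha (sum of n iid NB(mu/n, alpha));
# alpha = 0 is the Poisson limit
lognb <- function(x, mu, alpha, n) {
  if (alpha == 0) {
    stats::dpois(x, lambda = mu, log = TRUE)
  } else {
    stats::dnbinom(x, mu = mu, size = n / alpha, log = TRUE)
  }
}

# quantile bounds of the group-sum distribution, for enumeration windows
nb_bounds <- function(p, mu, alpha, n) {
  if (alpha == 0) {
    stats::qpois(p, lambda = mu)
  } else {
    stats::qnbinom(p, mu = mu, size = n / alpha)
  }
}

#' Conditional NB exact test for a two-group count split
#'
#' Conditions on the total `K = ka + kb`: the p-value is the sum, over all
#' splits `(a, K - a)` whose joint probability does not exceed that of the
#' observed split, of those probabilities, normalized by the total over all
#' splits. Joint probabilities are products of the two groups' NB mass
#' functions; the sum of `n` i.i.d. NB counts with common dispersion
#' `alpha` is NB with size `n / alpha`. `alpha = 0` gives the Poisson
#' limit. `K = 0` returns 1 by convention.
#'
#' @param ka,kb observed summed (normalized, rounded) counts per group.
#' @param mu_a,mu_b expected group sums under the null.
#' @param alpha common dispersion.
#' @param n_a,n_b samples per group.
#' @return two-sided p-value in `[0, 1]`.
#' @export
nb_exact_test <- function(ka, kb, mu_a, mu_b, alpha, n_a = 1, n_b = 1) {
  ka <- check_count(ka, "ka"); kb <- check_count(kb, "kb")
  check_number(mu_a, "mu_a", lower = 0)
  check_number(mu_b, "mu_b", lower = 0)
  check_number(alpha, "alpha", lower = 0)
  K <- ka + kb
  if (K == 0) return(1)
  if (mu_a <= 0 || mu_b <= 0) return(1)

  # full enumeration for moderate totals; for large K restrict to the
  # window where either margin carries non-negligible mass (the excluded
  # tail mass is below 1e-15 of the total), always keeping the observed
  # split inside
  if (K <= 1e5) {
    a <- 0:K
  } else {
    qa <- nb_bounds(c(1e-16, 1 - 1e-16), mu_a, alpha, n_a)
    qb <- nb_bounds(c(1e-16, 1 - 1e-16), mu_b, alpha, n_b)
    lo <- max(0, min(qa[1], K - qb[2], ka - 2))
    hi <- min(K, max(qa[2], K - qb[1], ka + 2))
    a <- lo:hi
  }
  lp <- lognb(a, mu_a, alpha, n_a) + lognb(K - a, mu_b, alpha, n_b)
  m <- max(lp)
  w <- exp(lp - m)
  w_obs <- w[a == ka]
  p <- sum(w[w <= w_obs * (1 + 1e-7)]) / sum(w)
  min(1, max(0, p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted p-values in the input order.
#' @export
adjust_bh <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression of a count matrix
#'
#' Composes [size_factors()], [estimate_dispersion()], a per-miRNA
#' [nb_exact_test()] on the rounded summed normalized counts, and
#' [adjust_bh()]. The log2 fold change is
#' `log2((mean_B + 0.5) / (mean_A + 0.5))` on normalized group means (the
#' 0.5 pseudo-mean avoids infinities); group B is the second factor level.
#'
#' @inheritParams estimate_dispersion
#' @return data frame with `mirna_id`, `baseMean`, `log2FC`, `pvalue`,
#'   `padj`, in the input row order.
#' @export
differential_expression <- function(counts, groups, floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  sf <- size_factors(counts)
  alpha <- estimate_dispersion(counts, groups, sf = sf, floor = floor)
  norm <- sweep(counts, 2, sf, "/")
  ga <- groups == levels(groups)[1]
  n_a <- sum(ga); n_b <- sum(!ga)
  ka <- round(rowSums(norm[, ga, drop = FALSE]))
  kb <- round(rowSums(norm[, !ga, drop = FALSE]))
  q <- (ka + kb) / (n_a + n_b)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(ka[i], kb[i], mu_a = n_a * q[i], mu_b = n_b * q[i],
                  alpha = alpha[i], n_a = n_a, n_b = n_b)
  }, numeric(1))
  mean_a <- rowMeans(norm[, ga, drop = FALSE])
  mean_b <- rowMeans(norm[, !ga, drop = FALSE])
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(counts)))
  data.frame(
    mirna_id = ids,
    baseMean = rowMeans(norm),
    log2FC = log2((mean_b + 0.5) / (mean_a + 0.5)),
    pvalue = p,
    padj = adjust_bh(p),
    stringsAsFactors = FALSE
  )
}
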