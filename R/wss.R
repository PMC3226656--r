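# Weighted sum statistic (WSS) comparator for grouped rare variants.
#
# Each selected variant is weighted by the standard deviation of its allele
# count estimated from the unaffected group with pseudocounts
# (q = (m_U + 1) / (2 n_U + 2), w = sqrt(n q (1 - q))); each individual's
# genetic score is the sum of its mutation counts divided by the weights;
# the rank sum of case scores (midranks for ties) is standardized by its
# mean and SD over k phenotype permutations and referred to the one-sided
# upper normal tail.

#' Weighted sum statistic test
#'
#' @param G numeric sample-by-variant dosage matrix (minor-allele counts;
#'   `NA` treated as 0 copies in the score, as unobserved mutations).
#' @param y binary phenotype vector (1 = case).
#' @param maf_cutoff only variants with sample MAF strictly below this are
#'   analyzed (set `1` to keep all columns as given).
#' @param k number of phenotype permutations for the standardization.
#' @return an `htest`-like result with the permutation `statistic` (z),
#'   one-sided `p.value`, the number of variants used (`n_variants`) and
#'   the per-variant weights.
#' @export
wss_test <- function(G, y, maf_cutoff = 0.05, k = 1000) {
  if (!is.matrix(G)) G <- as.matrix(G)
  y <- .check_phenotype(y)
  if (nrow(G) != length(y)) stop("dimension mismatch", call. = FALSE)
  keep <- !is.na(y)
  G <- G[keep, , drop = FALSE]
  y <- y[keep]
  maf <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  sel <- which(maf > 0 & maf < maf_cutoff)
  if (!length(sel))
    stop("no polymorphic variant below the MAF cutoff", call. = FALSE)
  X <- G[, sel, drop = FALSE]
  X[is.na(X)] <- 0
  unaff <- y == 0
  n_u <- sum(unaff)
  m_u <- colSums(X[unaff, , drop = FALSE])
  qhat <- (m_u + 1) / (2 * n_u + 2)
  w <- sqrt(nrow(X) * qhat * (1 - qhat))
  score <- as.vector(X %*% (1 / w))
  if (stats::sd(score) == 0) {
    return(.new_test_result(NULL, NULL, 1, "WSS (degenerate: constant scores)",
                            n = nrow(X), note = "constant-scores"))
  }
  rk <- rank(score)                          # midranks
  n_case <- sum(y == 1)
  x_obs <- sum(rk[y == 1])
  perm <- vapply(seq_len(k),
                 function(i) sum(rk[sample.int(length(rk), n_case)]),
                 numeric(1))
  s <- stats::sd(perm)
  z <- (x_obs - mean(perm)) / s
  res <- .new_test_result(z, NULL, stats::pnorm(z, lower.tail = FALSE),
                          sprintf("WSS (rank sum, %d permutations)", k),
                          n = nrow(X))
  names(res$statistic) <- "z"
  res$n_variants <- length(sel)
  res$weights <- w
  res
}

#' Cumulative-inclusion WSS sweep over a region
#'
#' Orders the variants by minor allele frequency (ascending) and reruns the
#' WSS including one more variant at each step, reporting the P value per
#' inclusion cutoff -- the design used to profile how burden-test power
#' erodes as higher-frequency variants join the set.
#'
#' @inheritParams wss_test
#' @return data frame with columns `n_variants`, `maf_cutoff` (MAF of the
#'   last included variant) and `p`.
#' @export
wss_maf_sweep <- function(G, y, k = 1000) {
  if (!is.matrix(G)) G <- as.matrix(G)
  maf <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  ord <- order(maf)
  ord <- ord[maf[ord] > 0]
  steps <- seq_along(ord)
  p <- vapply(steps, function(s) {
    wss_test(G[, ord[seq_len(s)], drop = FALSE], y, maf_cutoff = 1,
             k = k)$p.value
  }, numeric(1))
  data.frame(n_variants = steps, maf_cutoff = maf[ord], p = p)
}
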