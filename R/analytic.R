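# Closed-form power theory for the CDH test under the recessive + compound
# heterozygote model.
#
# Two low-frequency SNPs in linkage equilibrium each follow HWE, so the 3x3
# cross-genotype frequency matrix is the outer product of two HWE vectors
# ((1-q)^2, 2q(1-q), q^2).  A joint penetrance matrix F places prevalence
# alpha*beta on the risk genotypes and alpha elsewhere (beta = genotype
# relative risk, GRR).  Expected case counts at total sample size n are
# n * (R o F) and control counts n * (R o (1-F)) (elementwise); collapsing
# and applying the Pearson formula to the *expected* table gives the
# noncentrality-style expected chi-square, whose upper-tail probability is
# the "expected P" traced over (q, GRR, n) to map the detectable region.

.hwe_vec <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

.check_q <- function(q, arg = "q") {
  if (any(q <= 0) || any(q > 0.5))
    stop(sprintf("'%s' must lie in (0, 0.5]", arg), call. = FALSE)
  q
}

#' Two-SNP HWE genotype frequency matrix
#'
#' @param q1,q2 minor allele frequencies in (0, 0.5].
#' @return 3x3 matrix `R` with `R[i, j]` the frequency of dosage `i - 1` at
#'   SNP1 and `j - 1` at SNP2 under independent HWE; sums to 1.
#' @export
hwe_pair_frequencies <- function(q1, q2) {
  .check_q(q1, "q1"); .check_q(q2, "q2")
  outer(.hwe_vec(q1), .hwe_vec(q2))
}

#' Compound-heterozygote to homozygote frequency ratio
#'
#' Frequency of the double heterozygote (AaBb) relative to the rare
#' homozygote of SNP1 (AAbb) under independent HWE:
#' `4 q2 (1 - q1) / (q1 (1 - q2))`, which is exactly 4 whenever `q1 = q2`.
#' This factor-4 excess of CH carriers over homozygote carriers is the
#' driving source of the CDH power gain.
#'
#' @inheritParams hwe_pair_frequencies
#' @return the frequency ratio (positive real).
#' @export
ch_to_homozygote_ratio <- function(q1, q2 = q1) {
  R <- hwe_pair_frequencies(q1, q2)
  if (R[3, 1] == 0) stop("homozygote frequency is zero", call. = FALSE)
  R[2, 2] / R[3, 1]
}

#' Joint penetrance matrix of the recessive + CH model
#'
#' @param alpha baseline prevalence in (0, 1).
#' @param beta genotype relative risk (GRR), non-negative; `alpha * beta`
#'   must not exceed 1.
#' @inheritParams collapse_risk_cells
#' @return 3x3 matrix with `alpha * beta` on the risk cells and `alpha`
#'   elsewhere.
#' @export
joint_penetrance <- function(alpha, beta, mode = c("causal", "tagging")) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)", call. = FALSE)
  if (beta < 0) stop("'beta' must be non-negative", call. = FALSE)
  if (alpha * beta > 1)
    stop("invalid model: alpha * beta exceeds 1", call. = FALSE)
  F <- matrix(alpha, 3L, 3L)
  F[.risk_cells(mode)] <- alpha * beta
  F
}

#' Expected case/control cross-genotype counts
#'
#' @inheritParams hwe_pair_frequencies
#' @inheritParams joint_penetrance
#' @param n total (population-based) sample size.
#' @return list with real-valued 3x3 matrices `D` (expected cases) and `U`
#'   (expected controls); `D + U` equals `n * R` elementwise.
#' @export
expected_pair_counts <- function(q1, q2, alpha, beta, n,
                                 mode = c("causal", "tagging")) {
  R <- hwe_pair_frequencies(q1, q2)
  F <- joint_penetrance(alpha, beta, mode)
  list(D = n * R * F, U = n * R * (1 - F))
}

#' Expected CDH chi-square and P value
#'
#' Collapses the expected counts under the chosen mode and evaluates the
#' Pearson statistic on the real-valued expected 2x2 table (no rounding:
#' the derivation is continuous); the expected P is its upper-tail
#' chi-square probability at 1 df.
#'
#' @inheritParams expected_pair_counts
#' @return `expected_cdh_chisq()`: the statistic; `expected_cdh_p()`: the
#'   upper-tail P value.
#' @export
expected_cdh_chisq <- function(q1, q2, alpha, beta, n,
                               mode = c("causal", "tagging")) {
  ec <- expected_pair_counts(q1, q2, alpha, beta, n, mode)
  tab <- collapse_pair_counts(ec, mode)
  if (any(rowSums(tab) <= 0) || any(colSums(tab) <= 0))
    stop("degenerate expected table", call. = FALSE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' @rdname expected_cdh_chisq
#' @export
expected_cdh_p <- function(q1, q2, alpha, beta, n,
                           mode = c("causal", "tagging")) {
  stats::pchisq(expected_cdh_chisq(q1, q2, alpha, beta, n, mode),
                df = 1, lower.tail = FALSE)
}

#' Expected single-SNP 2-df P value under the pair model
#'
#' Marginalizes the expected case/control counts over the partner SNP to a
#' 2x3 genotype table and evaluates the Pearson statistic at 2 df.  By
#' default the partner has the same allele frequency (`q2 = q`), matching
#' the symmetric construction used to compare the two tests.
#'
#' @param q minor allele frequency of the tested SNP.
#' @param q2 minor allele frequency of the partner SNP (defaults to `q`).
#' @inheritParams expected_pair_counts
#' @return the upper-tail P value at 2 df.
#' @export
expected_single_snp_p <- function(q, alpha, beta, n, q2 = q,
                                  mode = c("causal", "tagging")) {
  ec <- expected_pair_counts(q, q2, alpha, beta, n, mode)
  tab <- rbind(case = rowSums(ec$D), control = rowSums(ec$U))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  stats::pchisq(stat, df = 2, lower.tail = FALSE)
}

#' Smallest GRR reaching a target expected P
#'
#' Bisects the genotype relative risk over `bracket` for the smallest value
#' whose expected P (CDH or single-SNP) is at or below `target_p`.
#'
#' @inheritParams expected_single_snp_p
#' @param target_p expected-P target, e.g. `5e-8` for genome-wide
#'   significance.
#' @param test `"cdh"` (1-df collapsed test) or `"single"` (2-df marginal
#'   test).
#' @param bracket search interval for the GRR.
#' @param tol bisection tolerance on the GRR.
#' @return the crossing GRR.
#' @export
grr_threshold <- function(q, alpha, n, target_p = 5e-8,
                          test = c("cdh", "single"),
                          bracket = c(1, 50), tol = 1e-3) {
  test <- match.arg(test)
  if (target_p >= 1) return(bracket[1])
  f <- function(beta) {
    if (test == "cdh") expected_cdh_p(q, q, alpha, beta, n, mode = "causal")
    else expected_single_snp_p(q, alpha, beta, n)
  }
  # the penetrance bound alpha * beta <= 1 caps the usable bracket
  lo <- bracket[1]; hi <- min(bracket[2], 1 / alpha)
  if (f(hi) > target_p)
    stop("expected P does not reach 'target_p' within the bracket",
         call. = FALSE)
  if (f(lo) <= target_p) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= target_p) hi <- mid else lo <- mid
  }
  hi
}

#' Expected power grid for the CDH and single-SNP tests
#'
#' Evaluates the expected CDH chi-square/P and the expected single-SNP 2-df
#' P over a grid of allele frequencies and genotype relative risks (with
#' `q1 = q2 = q`), the table behind power-surface plots.
#'
#' @param q vector of minor allele frequencies.
#' @param grr vector of genotype relative risks.
#' @param n total sample size (scalar or vector).
#' @param alpha baseline prevalence.
#' @return data frame with columns `q`, `grr`, `n`, `expected_chi2_cdh`,
#'   `expected_p_cdh`, `expected_p_single2df`.
#' @export
cdh_power_grid <- function(q, grr, n = 10000, alpha = 0.05) {
  grid <- expand.grid(q = q, grr = grr, n = n,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$expected_chi2_cdh <- mapply(function(qq, bb, nn)
    expected_cdh_chisq(qq, qq, alpha, bb, nn, mode = "causal"),
    grid$q, grid$grr, grid$n)
  grid$expected_p_cdh <- stats::pchisq(grid$expected_chi2_cdh, 1,
                                       lower.tail = FALSE)
  grid$expected_p_single2df <- mapply(function(qq, bb, nn)
    expected_single_snp_p(qq, alpha, bb, nn), grid$q, grid$grr, grid$n)
  grid
}
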