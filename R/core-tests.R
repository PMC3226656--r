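# Contingency-table machinery shared by every test in the package:
# cross-tabulation of two dosage vectors by case/control status, uncorrected
# Pearson chi-square with empty-margin dropping, Fisher's exact test for 2x2
# tables, and the two single-SNP tests (2-df genotypic, Cochran-Armitage).

.check_dosage <- function(g, arg = deparse(substitute(g))) {
  if (!is.numeric(g))
    stop(sprintf("'%s' must be a numeric dosage vector", arg), call. = FALSE)
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad))
    stop(sprintf("'%s' contains dosages outside {0,1,2,NA}", arg),
         call. = FALSE)
  invisible(g)
}

.check_phenotype <- function(y) {
  if (!is.numeric(y) && !is.logical(y))
    stop("phenotype must be numeric 0/1", call. = FALSE)
  y <- as.numeric(y)
  bad <- !is.na(y) & !(y %in% c(0, 1))
  if (any(bad))
    stop("phenotype contains values outside {0,1,NA}", call. = FALSE)
  y
}

.new_test_result <- function(statistic, df, p, method, table = NULL,
                             n = NULL, note = NULL) {
  out <- list(
    statistic = if (is.null(statistic)) NULL else c("X-squared" = statistic),
    parameter = if (is.null(df)) NULL else c(df = df),
    p.value = p,
    method = method,
    data.name = "case/control genotype counts",
    table = table,
    n = n,
    note = note
  )
  class(out) <- c("cdh_htest", "htest")
  out
}

#' Minor-allele frequency of a dosage vector
#'
#' @param g numeric vector of allele dosages in \{0, 1, 2\}, `NA` allowed.
#' @return frequency of the counted allele among non-missing entries.
#' @export
dosage_maf <- function(g) {
  .check_dosage(g)
  if (all(is.na(g))) stop("all dosages missing", call. = FALSE)
  mean(g, na.rm = TRUE) / 2
}

#' Orient a dosage vector to count the minor allele
#'
#' Flips `g` to `2 - g` when the counted allele has frequency above 0.5, so
#' that downstream tests always see minor-allele dosage.  A frequency of
#' exactly 0.5 keeps the input orientation.
#'
#' @inheritParams dosage_maf
#' @return the (possibly flipped) dosage vector with attribute `"maf"`.
#' @export
orient_minor <- function(g) {
  f <- dosage_maf(g)
  if (f > 0.5) {
    g <- 2 - g
    f <- 1 - f
  }
  attr(g, "maf") <- f
  g
}

#' Cross-tabulate two SNPs by case/control status
#'
#' Builds the pair of 3x3 genotype count matrices `D` (cases) and `U`
#' (controls) indexed by the dosages of the two SNPs.  Samples missing any of
#' the two genotypes or the phenotype are excluded (pairwise complete case).
#'
#' @param g1,g2 dosage vectors in \{0, 1, 2, NA\}.
#' @param y binary phenotype vector (1 = case, 0 = control, `NA` allowed).
#' @return an object of class `"pair_counts"`: list with 3x3 integer matrices
#'   `D` and `U` (rows = dosage of `g1`, columns = dosage of `g2`) and the
#'   usable sample count `n`.
#' @examples
#' pc <- cross_tabulate(c(0, 1, 2), c(0, 1, 0), c(0, 1, 1))
#' pc$D
#' @export
cross_tabulate <- function(g1, g2, y) {
  .check_dosage(g1, "g1"); .check_dosage(g2, "g2")
  y <- .check_phenotype(y)
  if (length(g1) != length(g2) || length(g1) != length(y))
    stop("g1, g2 and y must have equal lengths", call. = FALSE)
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y)
  if (!any(keep)) stop("no samples with complete data", call. = FALSE)
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  code <- 3L * as.integer(g1) + as.integer(g2) + 1L
  dn <- list(g1 = 0:2, g2 = 0:2)
  D <- matrix(tabulate(code[y == 1], nbins = 9L), 3L, 3L,
              byrow = TRUE, dimnames = dn)
  U <- matrix(tabulate(code[y == 0], nbins = 9L), 3L, 3L,
              byrow = TRUE, dimnames = dn)
  structure(list(D = D, U = U, n = sum(keep)), class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("Cross-genotype counts (", x$n, " samples)\nCases:\n", sep = "")
  print(x$D)
  cat("Controls:\n")
  print(x$U)
  invisible(x)
}

#' Pearson chi-square test on a count table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction anywhere in
#' this package: the collapsed-genotype theory is built on the plain
#' statistic).  Rows and columns with zero marginal total are dropped before
#' computing the degrees of freedom; if fewer than two non-empty rows or
#' columns remain, the table is degenerate and an error is raised.
#'
#' @param table numeric matrix of non-negative counts (real-valued expected
#'   tables are accepted, which the analytic power theory relies on).
#' @return an `htest`-like result with `statistic`, `parameter` (df),
#'   `p.value` and `method`.
#' @export
pearson_chi2 <- function(table) {
  if (!is.matrix(table) || any(table < 0) || any(!is.finite(table)))
    stop("'table' must be a matrix of non-negative finite counts",
         call. = FALSE)
  tab <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: fewer than 2 non-empty rows or columns",
         call. = FALSE)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  .new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                   "Pearson chi-square (no continuity correction)",
                   table = tab, n = n)
}

# Two-sided Fisher exact p for a 2x2 table given as four counts; sums the
# hypergeometric probabilities of all tables with fixed margins whose
# probability does not exceed that of the observed table (with the same
# relative tolerance fisher.test uses for the comparison).
.fisher2x2_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  c2 <- b + d
  n <- a + b + c + d
  if (n == 0) return(1)
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p.obs <- stats::dhyper(a, c1, c2, r1)
  min(1, sum(probs[probs <= p.obs * (1 + 1e-7)]))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test summing hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed one
#' (the same definition as [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return an `htest`-like result (no statistic or df; exact test).
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2L))
    stop("'table' must be a 2x2 matrix", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must contain non-negative integers", call. = FALSE)
  p <- .fisher2x2_p(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  .new_test_result(NULL, NULL, p, "Fisher's exact test (two-sided)",
                   table = table, n = sum(table))
}

#' Single-SNP genotypic association test (2 df)
#'
#' Pearson chi-square on the 2x3 case/control-by-genotype table, the
#' genotypic single-SNP test used as the comparator for the CDH test.  The df
#' shrinks if a genotype class is absent.
#'
#' @inheritParams cross_tabulate
#' @param g dosage vector in \{0, 1, 2, NA\}.
#' @return an `htest`-like result.
#' @export
single_snp_2df <- function(g, y) {
  .check_dosage(g, "g")
  y <- .check_phenotype(y)
  if (length(g) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(g) & !is.na(y)
  if (!any(keep)) stop("no samples with complete data", call. = FALSE)
  g <- g[keep]; y <- y[keep]
  tab <- matrix(0, 2L, 3L, dimnames = list(c("case", "control"), 0:2))
  tab[1, ] <- tabulate(g[y == 1] + 1L, 3L)
  tab[2, ] <- tabulate(g[y == 0] + 1L, 3L)
  res <- pearson_chi2(tab)
  res$method <- "single-SNP genotypic chi-square (2 df before class dropping)"
  res$n <- sum(keep)
  res
}

#' Cochran-Armitage trend test
#'
#' Trend in case proportion across genotype classes with scores (0, 1, 2),
#' 1 df.  Implemented through [stats::prop.trend.test()].
#'
#' @inheritParams single_snp_2df
#' @return an `htest`-like result.
#' @export
cochran_armitage_trend <- function(g, y) {
  .check_dosage(g, "g")
  y <- .check_phenotype(y)
  if (length(g) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  ntot <- tabulate(g + 1L, 3L)
  present <- ntot > 0L
  if (sum(present) < 2L)
    stop("degenerate input: genotype has no variation", call. = FALSE)
  cases <- vapply(0:2, function(d) sum(y[g == d] == 1), numeric(1))
  # prop.trend.test warns through its internal anova when the weighted fit
  # is exact (e.g. zero cases in every class); the score statistic is fine
  pt <- suppressWarnings(stats::prop.trend.test(cases[present], ntot[present],
                                                score = (0:2)[present]))
  .new_test_result(unname(pt$statistic), 1, pt$p.value,
                   "Cochran-Armitage trend test (scores 0,1,2)",
                   n = sum(keep))
}
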