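# The collapsed double heterozygosity (CDH) test.
#
# Two biallelic SNPs with minor alleles A and B define a 3x3 cross-genotype
# table.  Under the recessive + compound-heterozygote (CH) model the risk
# genotypes are the homozygotes (AAbb, aaBB) and the compound heterozygote
# (AaBb); "causal" collapsing also pools the near-empty AABb/AaBB/AABB cells
# with them.  When the tested markers are tags in LD with unobserved causal
# alleles, the C-D haplotype carries no causal allele, so the CCDd/CcDD/CCDD
# genotypes belong with the wildtypes: "tagging" collapsing pools only
# AAbb-, aaBB- and AaBb-analogous cells.  Either way a 2x2 case/control x
# {risk, reference} table is tested on 1 df.

# Risk cells as (row, col) 1-based indices into the 3x3 dosage table
# (row = dosage of SNP1, col = dosage of SNP2; dosage 0,1,2 -> index 1,2,3).
.risk_cells <- function(mode = c("causal", "tagging")) {
  mode <- match.arg(mode)
  base <- rbind(c(3L, 1L), c(1L, 3L), c(2L, 2L))   # AAbb, aaBB, AaBb
  if (mode == "causal")
    base <- rbind(base, c(3L, 2L), c(2L, 3L), c(3L, 3L)) # AABb, AaBB, AABB
  base
}

#' Risk-genotype cells of a collapse mode
#'
#' @param mode `"causal"` collapses every genotype carrying two or more
#'   minor alleles in homozygote/CH configuration (dosage pairs 2/0, 0/2,
#'   1/1, 2/1, 1/2, 2/2); `"tagging"` collapses only 2/0, 0/2 and 1/1,
#'   sending the double-minor tag genotypes to the reference group.
#' @return integer matrix of (row, col) 1-based indices into the 3x3 table.
#' @export
collapse_risk_cells <- function(mode = c("causal", "tagging")) {
  .risk_cells(mode)
}

#' Collapse a 3x3 cross-genotype count pair to the CDH 2x2 table
#'
#' @param pc a `"pair_counts"` object from [cross_tabulate()], or a list with
#'   3x3 matrices `D` and `U`.
#' @inheritParams collapse_risk_cells
#' @return 2x2 matrix with rows `case`/`control` and columns
#'   `risk`/`reference`; totals are conserved.
#' @export
collapse_pair_counts <- function(pc, mode = c("causal", "tagging")) {
  cells <- .risk_cells(mode)
  D <- pc$D; U <- pc$U
  stopifnot(all(dim(D) == 3L), all(dim(U) == 3L))
  out <- matrix(c(sum(D[cells]), sum(U[cells]),
                  sum(D) - sum(D[cells]), sum(U) - sum(U[cells])),
                2L, 2L,
                dimnames = list(c("case", "control"), c("risk", "reference")))
  out
}

# 2x2 chi-square / Fisher decision on a collapsed table.  `exact_threshold`
# is the minimum-expected-cell rule: Fisher's exact test replaces the
# chi-square when the smallest expected count falls below it (0 disables the
# switch, as in the pure-theory simulations).
.collapsed_test <- function(tab, exact_threshold = 5, n = sum(tab)) {
  if (sum(tab[, 1]) == 0) {
    return(.new_test_result(0, 1, 1,
                            "CDH test (degenerate: no risk genotypes)",
                            table = tab, n = n,
                            note = "no-risk-genotypes"))
  }
  use_fisher <- FALSE
  if (exact_threshold > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- min(E) < exact_threshold
  } else if (exact_threshold > 0) {
    use_fisher <- TRUE                       # an empty margin: exact test
  }
  if (use_fisher) {
    res <- fisher_exact_2x2(tab)
    res$n <- n
    return(res)
  }
  res <- pearson_chi2(tab)
  res$n <- n
  res
}

#' Collapsed double heterozygosity (CDH) test of two SNPs
#'
#' Cross-tabulates the two SNPs by case/control status, collapses the 3x3
#' genotype table to a 2x2 {risk, reference} table under the chosen mode, and
#' tests association with a 1-df Pearson chi-square.  When the smallest
#' expected cell count falls below `exact_threshold`, Fisher's exact test is
#' used instead (the method field records which).  If no individual carries a
#' risk genotype the result is degenerate with `p = 1` and note
#' `"no-risk-genotypes"`.
#'
#' @inheritParams cross_tabulate
#' @inheritParams collapse_risk_cells
#' @param exact_threshold minimum expected cell count below which Fisher's
#'   exact test replaces the chi-square (default 5, the usual expected-count
#'   rule; set 0 to always use the chi-square).
#' @return an `htest`-like result carrying the collapsed `table`, usable `n`,
#'   `p.value`, and for the chi-square branch `statistic` and df.
#' @examples
#' set.seed(1)
#' g1 <- stats::rbinom(5000, 2, 0.04)
#' g2 <- stats::rbinom(5000, 2, 0.04)
#' risk <- (g1 + g2 >= 2) & pmin(g1, g2) >= 0 & (g1 >= 2 | g2 >= 2 | (g1 == 1 & g2 == 1))
#' y <- stats::rbinom(5000, 1, ifelse(risk, 0.3, 0.05))
#' cdh_test(g1, g2, y, mode = "causal")
#' @export
cdh_test <- function(g1, g2, y, mode = c("causal", "tagging"),
                     exact_threshold = 5) {
  mode <- match.arg(mode)
  pc <- cross_tabulate(g1, g2, y)
  tab <- collapse_pair_counts(pc, mode)
  res <- .collapsed_test(tab, exact_threshold, n = pc$n)
  res$method <- paste0("CDH (", mode, " collapse): ", res$method)
  res
}
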