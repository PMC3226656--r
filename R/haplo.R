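# Two-SNP haplotype frequency estimation (EM), LD statistics, and the
# diplotype follow-up contrast between compound heterozygotes (trans) and
# double heterozygotes in cis.

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four two-locus haplotype
#' frequencies from unphased genotypes.  Only the double-heterozygote class
#' is phase-ambiguous; each E-step splits it between the cis (11/00) and
#' trans (10/01) resolutions in proportion to their current likelihood.
#' Initialization is at linkage-equilibrium product frequencies.
#'
#' @inheritParams cross_tabulate
#' @param tol convergence tolerance on the largest frequency change.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   last iterate.
#' @return a [haplotype_model()] with extra fields `iterations`, `loglik`
#'   and `n`.  If either SNP is monomorphic the closed-form degenerate
#'   solution is returned with `r2 = 0`.
#' @export
em_two_locus <- function(g1, g2, tol = 1e-8, max_iter = 1000) {
  .check_dosage(g1, "g1"); .check_dosage(g2, "g2")
  keep <- !is.na(g1) & !is.na(g2)
  if (sum(keep) < 10)
    stop("need at least 10 samples with both genotypes", call. = FALSE)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  cnt <- matrix(tabulate(3L * g1 + g2 + 1L, 9L), 3L, 3L, byrow = TRUE)
  q1 <- mean(g1) / 2; q2 <- mean(g2) / 2
  # fixed haplotype contributions from the 8 unambiguous classes
  # order: 00, 01, 10, 11
  H0 <- c(
    2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1],            # 00
    2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],            # 01
    2 * cnt[3, 1] + cnt[2, 1] + cnt[3, 2],            # 10
    2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3])            # 11
  ndh <- cnt[2, 2]
  if (q1 == 0 || q2 == 0 || q1 == 1 || q2 == 1) {
    f <- c((1 - q1) * (1 - q2), (1 - q1) * q2, q1 * (1 - q2), q1 * q2)
    hm <- haplotype_model(f)
    hm$iterations <- 0L
    hm$n <- n
    hm$note <- "monomorphic SNP: r2 = 0 by convention"
    return(hm)
  }
  f <- c((1 - q1) * (1 - q2), (1 - q1) * q2, q1 * (1 - q2), q1 * q2)
  loglik <- function(f) {
    pr <- c(f[1]^2, 2 * f[1] * f[2], f[2]^2,
            2 * f[1] * f[3], NA, 2 * f[2] * f[4],
            f[3]^2, 2 * f[3] * f[4], f[4]^2)
    pdh <- 2 * (f[1] * f[4] + f[2] * f[3])
    cells <- as.vector(t(cnt))             # row-major: (g1, g2) = (0,0)...
    lp <- 0
    for (i in seq_len(9)) {
      if (cells[i] == 0) next
      p <- if (i == 5) pdh else pr[i]
      lp <- lp + cells[i] * log(p)
    }
    lp
  }
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- f[1] * f[4]
    trans <- f[2] * f[3]
    wc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    H <- H0 + ndh * c(wc, 1 - wc, 1 - wc, wc)
    f_new <- H / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf(
        "EM did not converge in %d iterations (last delta %.3g; freqs %s)",
        max_iter, delta, paste(signif(f, 6), collapse = ", ")),
        call. = FALSE)
  }
  hm <- haplotype_model(f)
  hm$iterations <- it
  hm$loglik <- loglik(hm$freqs)
  hm$n <- n
  hm
}

#' LD statistics of a haplotype model
#'
#' @param hm a [haplotype_model()] (e.g. from [em_two_locus()]).
#' @return list with `r2`, `dprime`, `d` and the haplotype frequencies.
#'   Monomorphic models report `r2 = 0` with a note.
#' @export
ld_stats <- function(hm) {
  stopifnot(inherits(hm, "haplotype_model"))
  out <- list(r2 = hm$r2, dprime = hm$dprime, d = hm$d, freqs = hm$freqs)
  if (hm$q1 %in% c(0, 1) || hm$q2 %in% c(0, 1))
    out$note <- "monomorphic SNP: r2 = 0 by convention"
  out
}

#' Compound-heterozygote versus cis double-heterozygote contrast
#'
#' Among double heterozygotes of two SNPs, contrasts the case/control
#' frequencies of the trans diplotype (the two minor alleles on opposite
#' chromosomes: a true compound heterozygote) against the cis diplotype
#' (both on one chromosome, phenotypically a single-allele carrier under
#' the CH model).  Phase can be supplied per sample (from phased data or
#' simulation truth); otherwise every double heterozygote is assigned the
#' maximum-posterior resolution under `hm`, which for two SNPs is the same
#' for all of them, so the contrast then requires supplied phase and the
#' genotype-only call errors with an explanation.
#'
#' @inheritParams cross_tabulate
#' @param hm optional [haplotype_model()]; estimated by [em_two_locus()]
#'   when missing and `phase` is `NULL`.
#' @param phase optional logical vector (length of `g1`): `TRUE` where the
#'   sample's two minor alleles are in trans, `NA` for non-double
#'   heterozygotes (ignored).
#' @param exact_threshold Fisher switch as in [cdh_test()].
#' @return an `htest`-like result on the 2x2 case/control x \{CH, DH\}
#'   table.
#' @export
ch_vs_dh_test <- function(g1, g2, y, hm = NULL, phase = NULL,
                          exact_threshold = 5) {
  .check_dosage(g1, "g1"); .check_dosage(g2, "g2")
  y <- .check_phenotype(y)
  dh <- which(!is.na(g1) & !is.na(g2) & !is.na(y) & g1 == 1 & g2 == 1)
  if (!length(dh))
    stop("no double heterozygotes present", call. = FALSE)
  if (is.null(phase)) {
    if (is.null(hm)) hm <- em_two_locus(g1, g2)
    f <- hm$freqs
    p_trans <- f[["01"]] * f[["10"]] /
      (f[["01"]] * f[["10"]] + f[["00"]] * f[["11"]])
    is_trans <- rep(p_trans >= 0.5, length(dh))
  } else {
    if (length(phase) != length(g1))
      stop("'phase' must have one entry per sample", call. = FALSE)
    is_trans <- phase[dh]
    if (anyNA(is_trans))
      stop("'phase' is missing for some double heterozygotes", call. = FALSE)
  }
  ydh <- y[dh]
  tab <- matrix(c(sum(ydh == 1 & is_trans), sum(ydh == 0 & is_trans),
                  sum(ydh == 1 & !is_trans), sum(ydh == 0 & !is_trans)),
                2L, 2L,
                dimnames = list(c("case", "control"), c("CH", "DH")))
  if (any(colSums(tab) == 0))
    stop(paste("only one diplotype class present among double",
               "heterozygotes; with two-SNP genotype-only data the",
               "maximum-posterior assignment is necessarily all-or-nothing",
               "-- supply per-sample 'phase' (phased data or flanking-tag",
               "diplotypes) to contrast CH against DH"), call. = FALSE)
  res <- .collapsed_test(tab, exact_threshold, n = length(dh))
  res$method <- paste0("CH vs DH diplotype contrast: ", res$method)
  res
}
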