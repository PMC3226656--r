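# Independent oracles used across the suite.

# Fisher two-sided p by brute-force enumeration over all tables with the
# observed margins, using exact binomial coefficients.
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Cochran-Armitage trend statistic from the direct score formula on a 2x3
# case/control-by-genotype table (cases row 1), scores (0, 1, 2).
trend_stat_direct <- function(cases, totals, score = 0:2) {
  n <- sum(totals); r <- sum(cases)
  num <- sum(score * (cases - totals * r / n))
  pbar <- r / n
  var <- pbar * (1 - pbar) *
    (sum(score^2 * totals) - sum(score * totals)^2 / n)
  num^2 / var
}

# Closed-form 2x2 chi-square n(ad - bc)^2 / (row and column margins).
chi2_2x2_closed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Empirical r2 between two dosage vectors (squared Pearson correlation;
# equals the haplotype r2 under random mating).
emp_r2 <- function(g1, g2) stats::cor(g1, g2)^2
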