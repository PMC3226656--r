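# Synthetic genotype/phenotype generation for the pair-level simulation
# designs: independent HWE SNP pairs, LD-linked tagging SNPs at a target r2,
# the recessive + CH phenotype model, and the Monte Carlo power/type-I table.

#' Simulate an independent HWE SNP pair
#'
#' @param q1,q2 minor allele frequencies in (0, 0.5].
#' @param n number of individuals.
#' @return list with dosage vectors `g1` and `g2`, independent
#'   `Binomial(2, q)` draws per sample.
#' @export
simulate_hwe_pair <- function(q1, q2, n) {
  .check_q(q1, "q1"); .check_q(q2, "q2")
  list(g1 = stats::rbinom(n, 2, q1), g2 = stats::rbinom(n, 2, q2))
}

#' Construct a two-locus haplotype model
#'
#' @param freqs frequencies of the four haplotypes in the order `00`, `01`,
#'   `10`, `11`, where the first digit flags the minor allele at locus 1 and
#'   the second at locus 2; must be non-negative and sum to 1.
#' @return an object of class `"haplotype_model"` with the frequencies,
#'   marginal allele frequencies `q1`/`q2`, disequilibrium `d`, `r2` and
#'   `dprime`.
#' @export
haplotype_model <- function(freqs) {
  if (length(freqs) != 4 || any(freqs < -1e-12))
    stop("'freqs' must be four non-negative haplotype frequencies",
         call. = FALSE)
  freqs <- pmax(freqs, 0)
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  freqs <- freqs / sum(freqs)
  names(freqs) <- c("00", "01", "10", "11")
  q1 <- freqs[["10"]] + freqs[["11"]]
  q2 <- freqs[["01"]] + freqs[["11"]]
  d <- freqs[["11"]] - q1 * q2
  denom <- q1 * (1 - q1) * q2 * (1 - q2)
  r2 <- if (denom > 0) d^2 / denom else 0
  dmax <- if (d >= 0) min(q1 * (1 - q2), (1 - q1) * q2)
          else min(q1 * q2, (1 - q1) * (1 - q2))
  dprime <- if (dmax > 0) abs(d) / dmax else 0
  structure(list(freqs = freqs, q1 = q1, q2 = q2, d = d,
                 r2 = r2, dprime = dprime),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("Two-locus haplotype model\n")
  print(round(x$freqs, 6))
  cat(sprintf("q1 = %.4f, q2 = %.4f, D = %.6f, r2 = %.4f, D' = %.4f\n",
              x$q1, x$q2, x$d, x$r2, x$dprime))
  invisible(x)
}

#' Haplotype frequencies achieving a target r2
#'
#' Builds the two-locus haplotype model for a causal allele (frequency
#' `q_causal`) coupled to a tagging allele (frequency `q_tag`) with positive
#' disequilibrium `D = sqrt(r2 * q_c(1-q_c) q_t(1-q_t))`, so the causal
#' allele preferentially rides on tag-allele haplotypes.  Errors if the
#' requested r2 exceeds the maximum attainable for the frequency pair.
#'
#' @param q_causal,q_tag minor allele frequencies of the causal and tagging
#'   locus.
#' @param r2_target target squared correlation in `[0, 1]`.
#' @return a [haplotype_model()] whose recomputed `r2` equals `r2_target`.
#' @export
haplotypes_for_target_r2 <- function(q_causal, q_tag, r2_target) {
  .check_q(q_causal, "q_causal"); .check_q(q_tag, "q_tag")
  if (r2_target < 0 || r2_target > 1)
    stop("'r2_target' must be in [0, 1]", call. = FALSE)
  denom <- q_causal * (1 - q_causal) * q_tag * (1 - q_tag)
  d <- sqrt(r2_target * denom)
  dmax <- min(q_causal * (1 - q_tag), (1 - q_causal) * q_tag)
  if (d > dmax + 1e-12)
    stop(sprintf(
      "r2 = %.4g infeasible for this frequency pair (max attainable %.4g)",
      r2_target, dmax^2 / denom), call. = FALSE)
  haplotype_model(c(
    (1 - q_causal) * (1 - q_tag) + d,   # 00
    (1 - q_causal) * q_tag       - d,   # 01
    q_causal       * (1 - q_tag) - d,   # 10
    q_causal       * q_tag       + d))  # 11
}

# Draw 2n chromosomes from a haplotype model; returns a list of two 0/1
# allele matrices (columns: locus1, locus2) for the two chromosomes.
.draw_chromosomes <- function(hm, n) {
  alleles1 <- c(0L, 0L, 1L, 1L)
  alleles2 <- c(0L, 1L, 0L, 1L)
  idx <- sample.int(4L, 2L * n, replace = TRUE, prob = hm$freqs)
  list(h1 = cbind(alleles1[idx[1:n]], alleles2[idx[1:n]]),
       h2 = cbind(alleles1[idx[n + 1:n]], alleles2[idx[n + 1:n]]))
}

#' Simulate two causal SNPs with their tagging SNPs
#'
#' Draws, per individual, two chromosomes from each of two independent
#' two-locus haplotype models (causal/tag pairs).  The two causal SNPs are
#' independent of each other; each tag tracks its causal partner at the
#' model's r2.
#'
#' @param hm1,hm2 [haplotype_model()]s for the (causal1, tag1) and
#'   (causal2, tag2) locus pairs.
#' @param n number of individuals.
#' @return list of dosage vectors `g_causal1`, `g_tag1`, `g_causal2`,
#'   `g_tag2`, plus logical phase vectors `trans_causal` (`TRUE` where the
#'   two causal minor alleles sit on opposite chromosomes).
#' @export
simulate_linked_quartet <- function(hm1, hm2, n) {
  c1 <- .draw_chromosomes(hm1, n)
  c2 <- .draw_chromosomes(hm2, n)
  list(
    g_causal1 = c1$h1[, 1] + c1$h2[, 1],
    g_tag1    = c1$h1[, 2] + c1$h2[, 2],
    g_causal2 = c2$h1[, 1] + c2$h2[, 1],
    g_tag2    = c2$h1[, 2] + c2$h2[, 2],
    # phase of the causal pair: chromosome 1 carries (A, not-B) and
    # chromosome 2 (not-A, B), or vice versa
    trans_causal = (c1$h1[, 1] == 1 & c2$h1[, 1] == 0 &
                    c1$h2[, 1] == 0 & c2$h2[, 1] == 1) |
                   (c1$h1[, 1] == 0 & c2$h1[, 1] == 1 &
                    c1$h2[, 1] == 1 & c2$h2[, 1] == 0)
  )
}

#' Simulate a binary phenotype under the recessive + CH model
#'
#' Each sample is a Bernoulli draw with probability `alpha * grr` if its
#' genotype pair falls in the risk cells of the chosen collapse mode and
#' `alpha` otherwise.
#'
#' @inheritParams cross_tabulate
#' @param alpha baseline prevalence; `alpha * grr` must not exceed 1.
#' @param grr genotype relative risk of the risk genotypes.
#' @inheritParams collapse_risk_cells
#' @return integer 0/1 phenotype vector.
#' @export
simulate_phenotype_ch <- function(g1, g2, alpha, grr,
                                  mode = c("causal", "tagging")) {
  if (alpha * grr > 1) stop("alpha * grr exceeds 1", call. = FALSE)
  cells <- .risk_cells(mode)
  risk_code <- (cells[, 1] - 1L) * 3L + (cells[, 2] - 1L)
  code <- as.integer(g1) * 3L + as.integer(g2)
  p <- ifelse(code %in% risk_code, alpha * grr, alpha)
  stats::rbinom(length(g1), 1, p)
}

#' Uniform minor-allele-frequency sampler
#'
#' @param lo,hi bounds of the uniform MAF band.
#' @return a function of `k` returning `k` frequencies.
#' @export
maf_uniform <- function(lo = 0.01, hi = 0.05) {
  force(lo); force(hi)
  function(k) stats::runif(k, lo, hi)
}

#' Monte Carlo power and type-I error table
#'
#' For each genotype relative risk, repeatedly draws a pair of minor allele
#' frequencies, simulates an independent HWE genotype pair and a recessive +
#' CH phenotype, and runs the causal-mode CDH test (plain 1-df chi-square)
#' together with the single-SNP Cochran-Armitage trend test on each SNP.
#' Reports, per GRR and per P-value threshold, the percentage of replicates
#' at or below the threshold.  `grr = 1` rows measure type-I error.
#'
#' @param grr vector of genotype relative risks.
#' @param n_reps replicates per GRR.
#' @param n individuals per replicate.
#' @param alpha baseline prevalence.
#' @param maf_sampler function of `k` returning `k` allele frequencies
#'   (default uniform on `[0.01, 0.05]`).
#' @param thresholds P-value cutoffs.
#' @param seed optional integer; per-replicate substreams are derived from
#'   it so results are reproducible.
#' @return data frame with one row per GRR: columns `snp1_<t>`, `snp2_<t>`
#'   and `cdh_<t>` (percentages) for each threshold `t`, plus a `grr`
#'   column.
#' @export
power_table <- function(grr = 1:10, n_reps = 1000, n = 10213, alpha = 0.05,
                        maf_sampler = maf_uniform(),
                        thresholds = c(0.05, 5e-8, 5e-11), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, length(grr) * n_reps)
  dim(rep_seeds) <- c(n_reps, length(grr))
  out <- vector("list", length(grr))
  for (gi in seq_along(grr)) {
    p_cdh <- p_s1 <- p_s2 <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(rep_seeds[r, gi])
      q <- maf_sampler(2L)
      gp <- simulate_hwe_pair(q[1], q[2], n)
      y <- simulate_phenotype_ch(gp$g1, gp$g2, alpha, grr[gi],
                                 mode = "causal")
      p_cdh[r] <- cdh_test(gp$g1, gp$g2, y, mode = "causal",
                           exact_threshold = 0)$p.value
      p_s1[r] <- tryCatch(cochran_armitage_trend(gp$g1, y)$p.value,
                          error = function(e) 1)
      p_s2[r] <- tryCatch(cochran_armitage_trend(gp$g2, y)$p.value,
                          error = function(e) 1)
    }
    row <- list(grr = grr[gi])
    for (t in thresholds) {
      key <- format(t, scientific = FALSE, drop0trailing = TRUE)
      row[[paste0("snp1_", key)]] <- 100 * mean(p_s1 <= t)
      row[[paste0("snp2_", key)]] <- 100 * mean(p_s2 <= t)
      row[[paste0("cdh_", key)]] <- 100 * mean(p_cdh <= t)
    }
    out[[gi]] <- as.data.frame(row, check.names = FALSE)
  }
  do.call(rbind, out)
}
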