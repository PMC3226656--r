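# Multi-SNP region simulator under the recessive-set model.
#
# A region is built from a pool of K founder haplotypes with random
# (Dirichlet) population weights: every chromosome in the sample is a copy
# of one founder, with a small per-site copy error that perturbs perfect
# founder LD.  Low-frequency sites are placed on a single founder (so their
# frequency is that founder's weight and they are in LD with everything
# else that founder carries); common sites are placed on as many founders
# as needed to reach their target frequency.  A subset of the realized
# MAF<0.05 sites is flagged causal; an individual is "exposed" when it is
# homozygous for any causal variant or heterozygous at two or more distinct
# causal variants (the genotype-level compound-heterozygote criterion), and
# exposed individuals have phenotype probability alpha * grr versus alpha.

#' Region model for the recessive-set simulations
#'
#' @param m number of SNPs in the region.
#' @param k_founders founder-haplotype pool size.
#' @param rare_frac fraction of sites targeted at the low-frequency band.
#' @param rare_range,common_range target MAF bands for low-frequency and
#'   common sites.
#' @param mutation_rate per-site probability that a copied chromosome flips
#'   its founder allele (breaks perfect founder LD).
#' @param portion_causal fraction of realized MAF<0.05 sites flagged causal
#'   (at least 2 are always flagged so the compound-heterozygote state
#'   exists).
#' @param grr genotype relative risk of exposed individuals.
#' @param alpha baseline prevalence.
#' @return an object of class `"region_model"`.
#' @export
region_model <- function(m = 70, k_founders = 20, rare_frac = 0.6,
                         rare_range = c(0.01, 0.05),
                         common_range = c(0.05, 0.5),
                         mutation_rate = 0.002, portion_causal = 0.08,
                         grr = 10, alpha = 0.05) {
  stopifnot(m >= 4, k_founders >= 2, rare_frac >= 0, rare_frac <= 1,
            portion_causal >= 0, portion_causal <= 1, alpha * grr <= 1)
  structure(list(m = m, k_founders = k_founders, rare_frac = rare_frac,
                 rare_range = rare_range, common_range = common_range,
                 mutation_rate = mutation_rate,
                 portion_causal = portion_causal, grr = grr, alpha = alpha),
            class = "region_model")
}

#' Simulate one region under the recessive-set model
#'
#' @param rm a [region_model()].
#' @param n number of individuals.
#' @param phase_aware if `TRUE`, double-heterozygote exposure additionally
#'   requires the two causal alleles to lie on opposite chromosomes (true
#'   compound heterozygosity); the default matches what genotype-level
#'   tests can see.
#' @return list with the `n x m` dosage matrix `G`, realized minor allele
#'   frequencies `maf`, indices `causal` of the flagged causal SNPs, the
#'   logical `exposed` vector, phenotype `y`, and a map data frame with
#'   1-based positions.
#' @export
simulate_region <- function(rm, n, phase_aware = FALSE) {
  K <- rm$k_founders; m <- rm$m
  w <- stats::rgamma(K, 1)
  w <- w / sum(w)
  n_rare <- round(rm$rare_frac * m)
  target <- c(stats::runif(n_rare, rm$rare_range[1], rm$rare_range[2]),
              stats::runif(m - n_rare, rm$common_range[1],
                           rm$common_range[2]))
  target <- target[sample.int(m)]
  founders <- matrix(0L, K, m)
  for (j in seq_len(m)) {
    if (target[j] < rm$rare_range[2]) {
      founders[sample.int(K, 1L), j] <- 1L
    } else {
      ord <- sample.int(K)
      take <- ord[seq_len(which(cumsum(w[ord]) >= target[j])[1])]
      founders[take, j] <- 1L
    }
  }
  idx <- sample.int(K, 2L * n, replace = TRUE, prob = w)
  H <- founders[idx, , drop = FALSE]
  if (rm$mutation_rate > 0) {
    flips <- stats::rbinom(length(H), 1L, rm$mutation_rate)
    H <- (H + flips) %% 2L
  }
  h1 <- H[seq_len(n), , drop = FALSE]
  h2 <- H[n + seq_len(n), , drop = FALSE]
  G <- h1 + h2
  freq <- colMeans(G) / 2
  flip <- freq > 0.5
  if (any(flip)) {
    G[, flip] <- 2L - G[, flip]
    h1[, flip] <- 1L - h1[, flip]
    h2[, flip] <- 1L - h2[, flip]
    freq[flip] <- 1 - freq[flip]
  }
  rare_idx <- which(freq > 0 & freq < 0.05)
  if (rm$portion_causal > 0 && length(rare_idx) < 2)
    stop("region has fewer than 2 polymorphic MAF<0.05 sites", call. = FALSE)
  n_causal <- if (rm$portion_causal == 0) 0L
              else min(max(2L, floor(rm$portion_causal * length(rare_idx))),
                       length(rare_idx))
  causal <- sort(rare_idx[sample.int(length(rare_idx), n_causal)])
  Gc <- G[, causal, drop = FALSE]
  hom_any <- rowSums(Gc == 2L) > 0
  if (phase_aware) {
    ch <- rowSums(h1[, causal, drop = FALSE]) > 0 &
          rowSums(h2[, causal, drop = FALSE]) > 0 &
          rowSums(Gc == 1L) >= 2
  } else {
    ch <- rowSums(Gc == 1L) >= 2
  }
  exposed <- hom_any | ch
  y <- stats::rbinom(n, 1, ifelse(exposed, rm$alpha * rm$grr, rm$alpha))
  map <- data.frame(chrom = "1",
                    pos = sort(sample.int(200000L, m)),
                    id = sprintf("snp%03d", seq_len(m)),
                    stringsAsFactors = FALSE)
  list(G = G, maf = freq, causal = causal, exposed = exposed, y = y,
       map = map)
}

#' Regional CDH-versus-WSS power benchmark
#'
#' Simulates independent regions under the recessive-set model and, per
#' region, runs (a) the all-pairs CDH scan with Bonferroni correction by the
#' number of pairs and (b) the weighted sum statistic over the MAF<0.05
#' variants, optionally masking the causal variants from both analyzed sets
#' (the tagging-only scenario).  Power is the fraction of regions whose
#' corrected (CDH) or raw (WSS) P value is at or below `threshold`.
#'
#' @param n_regions number of simulated regions.
#' @param rm a [region_model()].
#' @param n individuals per region.
#' @param threshold rejection threshold (default genome-wide 5e-8).
#' @param mask_causal drop the causal variants from the analyzed sets.
#' @param mode CDH collapse mode for the pairwise scan.
#' @param exact_threshold Fisher switch for the pairwise scan.
#' @param wss_k permutations for the WSS standardization.
#' @param wss_maf_cutoff WSS variant-inclusion MAF cutoff.
#' @param seed optional integer seed; per-region substreams are derived
#'   from it.
#' @return list with the per-region data frame `results`
#'   (`p_cdh_bonf`, `p_wss`, `n_snps`, `n_causal`) and the two powers
#'   `power_cdh` and `power_wss`.
#' @export
region_benchmark <- function(n_regions = 300, rm = region_model(),
                             n = 10000, threshold = 5e-8,
                             mask_causal = TRUE, mode = "tagging",
                             exact_threshold = 5, wss_k = 1000,
                             wss_maf_cutoff = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region_seeds <- sample.int(.Machine$integer.max, n_regions)
  p_cdh <- p_wss <- rep(NA_real_, n_regions)
  n_snps <- n_causal <- integer(n_regions)
  for (r in seq_len(n_regions)) {
    set.seed(region_seeds[r])
    reg <- simulate_region(rm, n)
    keep <- if (mask_causal) setdiff(seq_len(rm$m), reg$causal)
            else seq_len(rm$m)
    G <- reg$G[, keep, drop = FALSE]
    maf <- reg$maf[keep]
    poly <- maf > 0
    G <- G[, poly, drop = FALSE]
    maf <- maf[poly]
    n_snps[r] <- ncol(G)
    n_causal[r] <- length(reg$causal)
    scan <- pairwise_region_scan(G, reg$y, mode = mode,
                                 exact_threshold = exact_threshold)
    p_cdh[r] <- scan$p_bonf
    sel <- which(maf < wss_maf_cutoff)
    p_wss[r] <- if (length(sel) >= 1)
      wss_test(G[, sel, drop = FALSE], reg$y, maf_cutoff = wss_maf_cutoff,
               k = wss_k)$p.value
    else NA_real_
  }
  results <- data.frame(region = seq_len(n_regions), p_cdh_bonf = p_cdh,
                        p_wss = p_wss, n_snps = n_snps, n_causal = n_causal)
  list(results = results,
       power_cdh = mean(p_cdh <= threshold, na.rm = TRUE),
       power_wss = mean(p_wss <= threshold, na.rm = TRUE))
}
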