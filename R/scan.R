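# Genome-wide sliding-window CDH scan and regional all-pairs scan.
#
# The sliding window pairs every SNP with the following `window_n` SNPs on
# the same chromosome (truncated at the chromosome end), keeps the minimal P
# per window, and Bonferroni-corrects it by the number of tests actually
# performed in that window.  The regional scan tests all unordered pairs and
# corrects the minimum by m(m-1)/2.

#' Exact number of tests in a truncated sliding-window scan
#'
#' For one chromosome of `n_snps` SNPs and window size `window_n`, each SNP
#' is paired with the following `min(window_n, remaining)` SNPs, so the total
#' is `n_snps * window_n - window_n * (window_n + 1) / 2` when
#' `n_snps > window_n`, and `choose(n_snps, 2)` otherwise.
#'
#' @param n_snps SNPs on the chromosome.
#' @param window_n partners per index SNP.
#' @return total number of pairwise tests.
#' @export
scan_test_count <- function(n_snps, window_n) {
  if (n_snps <= window_n) return(choose(n_snps, 2))
  n_snps * window_n - window_n * (window_n + 1) / 2
}

# CDH test from precomputed column dosage codes; cheap path for scans.
.cdh_pair_p <- function(code1, code2, case, mode, exact_threshold) {
  code <- 3L * code1 + code2 + 1L
  D <- matrix(tabulate(code[case], 9L), 3L, 3L, byrow = TRUE)
  U <- matrix(tabulate(code[!case], 9L), 3L, 3L, byrow = TRUE)
  tab <- collapse_pair_counts(list(D = D, U = U), mode)
  res <- .collapsed_test(tab, exact_threshold)
  list(p = res$p.value,
       method = if (!is.null(res$note)) "degenerate"
                else if (grepl("Fisher", res$method)) "fisher" else "chi2")
}

#' Sliding-window CDH scan
#'
#' Runs the CDH test of every SNP against the following `window_n` SNPs on
#' the same chromosome.  The minimal P value of each window is assigned to
#' the window's first (index) SNP and Bonferroni-corrected by the number of
#' tests performed in that window.  Monomorphic SNPs (and SNPs outside
#' `maf_range`, if given) are excluded from the scan and from the test
#' counts, with a message.
#'
#' @param G numeric sample-by-SNP dosage matrix (entries 0/1/2/NA).
#' @param map data frame with columns `chrom`, `pos` (1-based) and `id`,
#'   one row per column of `G`, sorted by position within chromosome.
#' @param y binary phenotype vector (one value per row of `G`).
#' @param window_n number of following SNPs tested against each index SNP.
#' @param mode CDH collapse mode; `"tagging"` is the default for chip-style
#'   markers, `"causal"` suits directly observed causal variants.
#' @param exact_threshold minimum expected cell count for the chi-square;
#'   below it Fisher's exact test is used.
#' @param maf_range optional length-2 numeric; SNPs with MAF outside the
#'   interval are excluded.
#' @return data frame with one row per index SNP: `chrom`, `pos`, `id`,
#'   `partner_id`, `partner_pos` (the best partner), `n_tests`, `p_raw`
#'   (window minimum), `p_bonf = min(1, p_raw * n_tests)` and `method`.
#' @export
sliding_window_scan <- function(G, map, y, window_n = 100,
                                mode = c("tagging", "causal"),
                                exact_threshold = 5, maf_range = NULL) {
  mode <- match.arg(mode)
  if (window_n < 1) stop("'window_n' must be at least 1", call. = FALSE)
  if (ncol(G) < 2) stop("need at least 2 SNPs", call. = FALSE)
  if (nrow(map) != ncol(G))
    stop("'map' must have one row per SNP column", call. = FALSE)
  y <- .check_phenotype(y)
  keep_s <- !is.na(y)
  G <- G[keep_s, , drop = FALSE]
  case <- y[keep_s] == 1
  maf <- apply(G, 2, function(g) mean(g, na.rm = TRUE) / 2)
  maf <- pmin(maf, 1 - maf)
  usable <- maf > 0
  if (!is.null(maf_range))
    usable <- usable & maf >= maf_range[1] & maf <= maf_range[2]
  if (sum(!usable) > 0)
    message(sum(!usable), " SNP(s) excluded (monomorphic or outside MAF range)")
  out <- list()
  for (chr in unique(map$chrom)) {
    cols <- which(map$chrom == chr & usable)
    if (length(cols) < 2) next
    pos <- map$pos[cols]
    if (is.unsorted(pos))
      stop("SNPs must be sorted by position within chromosome", call. = FALSE)
    nc <- length(cols)
    for (ii in seq_len(nc - 1)) {
      partners <- (ii + 1):min(ii + window_n, nc)
      p <- numeric(length(partners))
      meth <- character(length(partners))
      for (k in seq_along(partners)) {
        r <- .cdh_pair_p(G[, cols[ii]], G[, cols[partners[k]]], case,
                         mode, exact_threshold)
        p[k] <- r$p; meth[k] <- r$method
      }
      best <- which.min(p)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, pos = map$pos[cols[ii]], id = map$id[cols[ii]],
        partner_id = map$id[cols[partners[best]]],
        partner_pos = map$pos[cols[partners[best]]],
        n_tests = length(partners), p_raw = p[best],
        p_bonf = min(1, p[best] * length(partners)),
        method = meth[best], stringsAsFactors = FALSE)
    }
    message("chromosome ", chr, ": ", nc, " SNPs scanned")
  }
  if (!length(out)) stop("no testable windows", call. = FALSE)
  do.call(rbind, out)
}

#' All-pairs regional CDH scan
#'
#' Tests every unordered SNP pair in a region with the CDH test and
#' Bonferroni-corrects the minimal P value by the number of pairs tested,
#' m(m-1)/2 for m polymorphic SNPs.  With complete genotype data the 3x3
#' pair counts for all pairs are obtained at once from nine case and nine
#' control indicator cross-products, so regions of ~100 SNPs and 10^4
#' samples run in well under a second; pairs whose collapsed table fails
#' the expected-count rule are re-tested exactly.
#'
#' @inheritParams sliding_window_scan
#' @return list with `p_raw` (minimum over pairs), `p_bonf`, `n_tests`,
#'   the index pair `best` (column indices into `G`), and `method` of the
#'   best pair.
#' @export
pairwise_region_scan <- function(G, y, mode = c("tagging", "causal"),
                                 exact_threshold = 5) {
  mode <- match.arg(mode)
  y <- .check_phenotype(y)
  keep_s <- !is.na(y)
  G <- G[keep_s, , drop = FALSE]
  case <- y[keep_s] == 1
  freq <- apply(G, 2, function(g) mean(g, na.rm = TRUE) / 2)
  poly <- pmin(freq, 1 - freq) > 0
  cols <- which(poly)
  m <- length(cols)
  if (m < 2) stop("need at least 2 polymorphic SNPs", call. = FALSE)
  n_tests <- m * (m - 1) / 2
  if (anyNA(G[, cols])) {
    # missing genotypes: per-pair complete-case loop
    pm <- matrix(NA_real_, m, m)
    methm <- matrix("", m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      r <- .cdh_pair_p(G[, cols[i]], G[, cols[j]], case, mode,
                       exact_threshold)
      pm[i, j] <- r$p; methm[i, j] <- r$method
    }
    best <- which(pm == min(pm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    p_raw <- pm[best[1], best[2]]
    method <- methm[best[1], best[2]]
  } else {
    X <- G[, cols, drop = FALSE]
    ncase <- sum(case); nctrl <- sum(!case)
    ind <- function(rows, d) matrix(as.numeric(X[rows, ] == d),
                                    nrow = sum(rows))
    Ic <- lapply(0:2, function(d) ind(case, d))
    Iu <- lapply(0:2, function(d) ind(!case, d))
    cells <- .risk_cells(mode)
    Rcase <- matrix(0, m, m); Rctrl <- matrix(0, m, m)
    for (k in seq_len(nrow(cells))) {
      a <- cells[k, 1]; b <- cells[k, 2]
      Rcase <- Rcase + crossprod(Ic[[a]], Ic[[b]])
      Rctrl <- Rctrl + crossprod(Iu[[a]], Iu[[b]])
    }
    n <- ncase + nctrl
    rt <- Rcase + Rctrl                     # risk-column total per pair
    ok <- rt > 0 & rt < n
    aa <- Rcase; bb <- ncase - Rcase; cc <- Rctrl; dd <- nctrl - Rctrl
    stat <- ifelse(ok,
                   n * (aa * dd - bb * cc)^2 /
                     (as.numeric(ncase) * nctrl * rt * (n - rt)), 0)
    pm <- ifelse(ok, stats::pchisq(stat, 1, lower.tail = FALSE), 1)
    minE <- pmin(ncase * rt, nctrl * rt,
                 ncase * (n - rt), nctrl * (n - rt)) / n
    need_exact <- exact_threshold > 0 & ok & minE < exact_threshold
    need_exact[lower.tri(need_exact, diag = TRUE)] <- FALSE
    for (ij in which(need_exact))
      pm[ij] <- .fisher2x2_p(aa[ij], bb[ij], cc[ij], dd[ij])
    pm[lower.tri(pm, diag = TRUE)] <- NA_real_
    best <- which(pm == min(pm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    p_raw <- pm[best[1], best[2]]
    method <- if (need_exact[best[1], best[2]]) "fisher"
              else if (rt[best[1], best[2]] == 0 ||
                       rt[best[1], best[2]] == n) "degenerate" else "chi2"
  }
  list(p_raw = p_raw, p_bonf = min(1, p_raw * n_tests), n_tests = n_tests,
       best = c(snp1 = cols[best[1]], snp2 = cols[best[2]]),
       method = method)
}
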