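
make_scan_data <- function(n = 400, m = 12, seed = 1, q = NULL) {
  set.seed(seed)
  if (is.null(q)) q <- runif(m, 0.05, 0.4)
  G <- sapply(q, function(qq) rbinom(n, 2, qq))
  colnames(G) <- sprintf("s%02d", seq_len(m))
  map <- data.frame(chrom = rep("1", m), pos = seq_len(m) * 1000L,
                    id = colnames(G), stringsAsFactors = FALSE)
  y <- rbinom(n, 1, 0.3)
  list(G = G, map = map, y = y)
}

test_that("window truncation and test counts match exact enumeration", {
  for (N in c(5, 12, 50)) for (w in c(1, 3, 10)) {
    # enumeration oracle: pairs (i, j), j in i+1 .. i+w, j <= N
    pairs <- 0
    for (i in seq_len(N)) pairs <- pairs + max(0, min(i + w, N) - i)
    expect_equal(scan_test_count(N, w), pairs)
  }
  d <- make_scan_data(n = 200, m = 5, seed = 3)
  res <- suppressMessages(sliding_window_scan(d$G, d$map, d$y, window_n = 3))
  expect_equal(sum(res$n_tests), scan_test_count(5, 3))
  # window_n = 1 reduces to adjacent pairs: N - 1 tests
  res1 <- suppressMessages(sliding_window_scan(d$G, d$map, d$y, window_n = 1))
  expect_equal(nrow(res1), 4)
  expect_equal(sum(res1$n_tests), 4)
})

test_that("scan output is consistent with per-pair cdh_test calls", {
  d <- make_scan_data(n = 300, m = 6, seed = 5)
  res <- suppressMessages(sliding_window_scan(d$G, d$map, d$y, window_n = 2,
                                              mode = "tagging"))
  for (r in seq_len(nrow(res))) {
    i <- match(res$id[r], d$map$id)
    partners <- (i + 1):min(i + 2, 6)
    p <- vapply(partners, function(j)
      cdh_test(d$G[, i], d$G[, j], d$y, "tagging")$p.value, numeric(1))
    expect_equal(res$p_raw[r], min(p), tolerance = 1e-12)
    expect_equal(res$p_bonf[r], min(1, min(p) * length(partners)))
  }
  expect_true(all(res$p_bonf >= res$p_raw))
})

test_that("windows never span chromosomes", {
  d <- make_scan_data(n = 200, m = 8, seed = 7)
  d$map$chrom <- rep(c("1", "2"), each = 4)
  d$map$pos <- rep(1:4 * 100L, 2)
  res <- suppressMessages(sliding_window_scan(d$G, d$map, d$y, window_n = 5))
  expect_equal(sum(res$n_tests), 2 * scan_test_count(4, 5))
  expect_false(any(res$chrom == "1" &
                   res$partner_id %in% d$map$id[d$map$chrom == "2"]))
})

test_that("monomorphic SNPs are excluded from tests and bookkeeping", {
  d <- make_scan_data(n = 200, m = 6, seed = 9)
  d$G[, 3] <- 0
  expect_message(res <- sliding_window_scan(d$G, d$map, d$y, window_n = 10),
                 "excluded")
  expect_equal(sum(res$n_tests), scan_test_count(5, 10))
  expect_false("s03" %in% c(res$id, res$partner_id))
})

test_that("scan errors on unsorted or undersized input", {
  d <- make_scan_data(n = 100, m = 4, seed = 11)
  bad <- d$map; bad$pos <- rev(bad$pos)
  expect_error(suppressMessages(sliding_window_scan(d$G, bad, d$y, 2)),
               "sorted")
  expect_error(sliding_window_scan(d$G[, 1, drop = FALSE],
                                   d$map[1, ], d$y, 2), "at least 2")
})

test_that("scan results are invariant to sample order", {
  d <- make_scan_data(n = 250, m = 6, seed = 13)
  perm <- sample(250)
  r1 <- suppressMessages(sliding_window_scan(d$G, d$map, d$y, window_n = 3))
  r2 <- suppressMessages(sliding_window_scan(d$G[perm, ], d$map, d$y[perm],
                                             window_n = 3))
  expect_equal(r1, r2)
})

test_that("pairwise region scan agrees with the per-pair loop", {
  d <- make_scan_data(n = 300, m = 8, seed = 15,
                      q = c(runif(4, 0.01, 0.05), runif(4, 0.1, 0.4)))
  res <- pairwise_region_scan(d$G, d$y, mode = "tagging")
  # exhaustive per-pair oracle
  pm <- Inf; best <- NULL
  for (i in 1:7) for (j in (i + 1):8) {
    p <- cdh_test(d$G[, i], d$G[, j], d$y, "tagging")$p.value
    if (p < pm) { pm <- p; best <- c(i, j) }
  }
  expect_equal(res$p_raw, pm, tolerance = 1e-10)
  expect_equal(unname(res$best), best)
  expect_equal(res$n_tests, 28)
  expect_equal(res$p_bonf, min(1, pm * 28))
  # m = 2 gives a single test, Bonferroni factor 1
  res2 <- pairwise_region_scan(d$G[, 1:2], d$y)
  expect_equal(res2$n_tests, 1)
  # missing genotypes fall back to the complete-case path, same answers
  Gna <- d$G; Gna[1:5, 2] <- NA
  res_na <- pairwise_region_scan(Gna, d$y, mode = "tagging")
  pm_na <- Inf
  for (i in 1:7) for (j in (i + 1):8) {
    p <- cdh_test(Gna[, i], Gna[, j], d$y, "tagging")$p.value
    pm_na <- min(pm_na, p)
  }
  expect_equal(res_na$p_raw, pm_na, tolerance = 1e-10)
})

test_that("90 SNPs give the Bonferroni factor 4005", {
  d <- make_scan_data(n = 60, m = 90, seed = 17)
  res <- pairwise_region_scan(d$G, d$y)
  expect_equal(res$n_tests, 4005)
})

test_that("permuted phenotypes show no excess of significant windows", {
  set.seed(19)
  d <- make_scan_data(n = 300, m = 15, seed = 21,
                      q = runif(15, 0.02, 0.3))
  n_windows <- 14
  hits <- replicate(100, {
    y <- sample(d$y)
    res <- suppressMessages(
      sliding_window_scan(d$G, d$map, y, window_n = 5))
    any(res$p_bonf <= 0.05 / n_windows)
  })
  # Bonferroni across windows is conservative: family-wise rate <= 0.05
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})
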