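test_that("cross_tabulate counts cells and conserves totals", {
  pc <- cross_tabulate(c(0, 1, 2), c(0, 1, 0), c(0, 1, 1))
  expect_equal(pc$D["1", "1"], 1)
  expect_equal(pc$D["2", "0"], 1)
  expect_equal(pc$U["0", "0"], 1)
  expect_equal(sum(pc$D) + sum(pc$U), 3)

  # conservation at scale, with missingness excluded pairwise
  set.seed(101)
  g1 <- rbinom(1000, 2, 0.05); g2 <- rbinom(1000, 2, 0.05)
  y <- rbinom(1000, 1, 0.3)
  g1[1:7] <- NA; y[5:12] <- NA
  pc <- cross_tabulate(g1, g2, y)
  expect_equal(sum(pc$D) + sum(pc$U), sum(!is.na(g1) & !is.na(y)))

  expect_error(cross_tabulate(c(0, 1), c(0, 1, 2), c(1, 0, 1)), "length")
  expect_error(cross_tabulate(c(0, 1), c(0, 1), c(NA, NA)), "complete")
  expect_error(cross_tabulate(c(0, 3), c(0, 1), c(1, 0)), "dosage")
})

test_that("pearson_chi2 matches hand evaluation and drops empty margins", {
  res <- pearson_chi2(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)

  # oracle value computed by direct sum((O-E)^2/E) and chisq.test
  tab <- matrix(c(20, 10, 5, 25), 2, 2)
  res <- pearson_chi2(tab)
  expect_equal(unname(res$statistic), 15.4286, tolerance = 1e-4)
  expect_equal(unname(res$parameter), 1)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(unname(res$statistic), unname(ct$statistic))
  expect_equal(res$p.value, ct$p.value)

  # 2x3 with an all-zero column -> df 1 after the column drop
  res <- pearson_chi2(matrix(c(5, 10, 0, 0, 10, 5), 2, 3))
  expect_equal(unname(res$parameter), 1)

  expect_error(pearson_chi2(matrix(c(5, 5, 0, 0), 2, 2)), "degenerate")
})

test_that("pearson_chi2 on 2x2 equals the closed form", {
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    expect_equal(unname(pearson_chi2(tab)$statistic), chi2_2x2_closed(tab))
  }
})

test_that("fisher_exact_2x2 matches enumeration and fisher.test", {
  res <- fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2, 2))
  expect_equal(res$p.value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p.value, 1)

  set.seed(11)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2, 2)
    p <- fisher_exact_2x2(tab)$p.value
    expect_equal(p, enumerate_fisher_p(tab), tolerance = 1e-10)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("single_snp_2df is the 2x3 Pearson chi-square", {
  # identical class-wise case fractions -> statistic 0
  g <- rep(c(0, 1, 2), times = c(9000, 900, 100))
  y <- unlist(lapply(c(9000, 900, 100),
                     function(k) rep(c(1, 0), c(k * 0.05, k * 0.95))))
  res <- single_snp_2df(g, y)
  expect_equal(unname(res$statistic), 0, tolerance = 1e-10)
  expect_equal(unname(res$parameter), 2)

  # equals pearson_chi2 of the tabulation, on random data
  set.seed(5)
  g <- rbinom(400, 2, 0.3); y <- rbinom(400, 1, 0.4)
  tab <- rbind(tabulate(g[y == 1] + 1, 3), tabulate(g[y == 0] + 1, 3))
  expect_equal(single_snp_2df(g, y)$p.value, pearson_chi2(tab)$p.value)

  expect_error(single_snp_2df(rep(1, 50), rbinom(50, 1, 0.5)), "degenerate")
})

test_that("cochran_armitage_trend matches the direct score formula", {
  # flat case fractions -> statistic 0
  g <- rep(c(0, 1, 2), each = 200)
  y <- rep(rep(c(1, 0), c(50, 150)), 3)
  expect_equal(unname(cochran_armitage_trend(g, y)$statistic), 0,
               tolerance = 1e-10)

  # perfect separation
  g <- rep(c(2, 0), each = 10); y <- rep(c(1, 0), each = 10)
  expect_lt(cochran_armitage_trend(g, y)$p.value, 1e-4)

  # fixed 2x3 table vs independent score-formula oracle
  cases <- c(30, 25, 12); totals <- c(300, 120, 30)
  g <- rep(rep(0:2, totals), 1)
  y <- unlist(lapply(1:3, function(i)
    rep(c(1, 0), c(cases[i], totals[i] - cases[i]))))
  res <- cochran_armitage_trend(g, y)
  expect_equal(unname(res$statistic), trend_stat_direct(cases, totals),
               tolerance = 1e-8)

  expect_error(cochran_armitage_trend(rep(0, 20), rbinom(20, 1, 0.5)),
               "degenerate")
})

test_that("single-SNP P values are uniform under label permutation", {
  set.seed(23)
  g <- rbinom(300, 2, 0.3)
  y0 <- rep(c(1, 0), c(90, 210))
  p <- replicate(400, single_snp_2df(g, sample(y0))$p.value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("minor-allele orientation flips major-allele dosage", {
  g <- c(2, 2, 2, 1, 0, 2)
  og <- orient_minor(g)
  expect_equal(as.numeric(og), c(0, 0, 0, 1, 2, 0))
  expect_equal(attr(og, "maf"), 1 - mean(g) / 2)
  # exactly 0.5 keeps input orientation
  g <- c(0, 2, 1, 1)
  expect_equal(as.numeric(orient_minor(g)), g)
})
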