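test_that("HWE pair simulation recovers MAF and independence", {
  set.seed(13)
  n <- 100000
  gp <- simulate_hwe_pair(0.05, 0.05, n)
  se <- sqrt(0.05 * 0.95 / (2 * n))
  expect_lt(abs(mean(gp$g1) / 2 - 0.05), 3 * se)
  expect_lt(abs(mean(gp$g2) / 2 - 0.05), 3 * se)
  expect_lt(emp_r2(gp$g1, gp$g2), 0.001)
  # fixed seed replays bitwise
  set.seed(99); a <- simulate_hwe_pair(0.03, 0.04, 1000)
  set.seed(99); b <- simulate_hwe_pair(0.03, 0.04, 1000)
  expect_identical(a, b)
})

test_that("haplotype models hit a target r2 and respect feasibility", {
  hm <- haplotypes_for_target_r2(0.03, 0.2, 0.1)
  expect_equal(hm$r2, 0.1, tolerance = 1e-9)
  expect_equal(sum(hm$freqs), 1, tolerance = 1e-12)
  expect_gt(hm$d, 0)
  # r2 = 0 gives product frequencies
  hm0 <- haplotypes_for_target_r2(0.1, 0.3, 0)
  expect_equal(unname(hm0$freqs[["11"]]), 0.1 * 0.3, tolerance = 1e-12)
  # perfect LD at equal MAFs: coupling haplotypes only
  hm1 <- haplotypes_for_target_r2(0.2, 0.2, 1)
  expect_equal(unname(hm1$freqs[["10"]]), 0, tolerance = 1e-12)
  expect_equal(unname(hm1$freqs[["01"]]), 0, tolerance = 1e-12)
  # infeasible request errors with the attainable maximum
  expect_error(haplotypes_for_target_r2(0.03, 0.4, 0.9), "max attainable")
})

test_that("linked quartets show the modeled LD and cross-independence", {
  set.seed(17)
  n <- 100000
  hm <- haplotypes_for_target_r2(0.05, 0.1, 0.3)
  q <- simulate_linked_quartet(hm, hm, n)
  # within-pair r2 near the model value (3 SE on the correlation scale)
  se_r <- (1 - 0.3) / sqrt(n)
  expect_lt(abs(sqrt(emp_r2(q$g_causal1, q$g_tag1)) - sqrt(0.3)), 3 * se_r)
  expect_lt(abs(sqrt(emp_r2(q$g_causal2, q$g_tag2)) - sqrt(0.3)), 3 * se_r)
  # cross-pair independence
  expect_lt(emp_r2(q$g_causal1, q$g_causal2), 0.001)
  # perfect coupling: tag dosage equals causal dosage
  hmP <- haplotypes_for_target_r2(0.2, 0.2, 1)
  qp <- simulate_linked_quartet(hmP, hmP, 2000)
  expect_identical(qp$g_causal1, qp$g_tag1)
})

test_that("phenotype simulation applies alpha*GRR on risk cells", {
  set.seed(19)
  n <- 200000
  gp <- simulate_hwe_pair(0.03, 0.03, n)
  y <- simulate_phenotype_ch(gp$g1, gp$g2, 0.05, 5, "causal")
  ch <- gp$g1 == 1 & gp$g2 == 1
  p_ch <- mean(y[ch])
  expect_lt(abs(p_ch - 0.25), 3 * sqrt(0.25 * 0.75 / sum(ch)))
  base <- gp$g1 == 0 & gp$g2 == 0
  expect_lt(abs(mean(y[base]) - 0.05), 3 * sqrt(0.05 * 0.95 / sum(base)))
  # null model: case fraction ~ alpha
  y0 <- simulate_phenotype_ch(gp$g1, gp$g2, 0.05, 1, "causal")
  expect_lt(abs(mean(y0) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_error(simulate_phenotype_ch(gp$g1, gp$g2, 0.3, 5, "causal"),
               "exceeds 1")
})

test_that("power_table is reproducible and nested across thresholds", {
  a <- power_table(grr = c(1, 8), n_reps = 60, n = 2000, seed = 5)
  b <- power_table(grr = c(1, 8), n_reps = 60, n = 2000, seed = 5)
  expect_identical(a, b)
  # weakly decreasing power across nested thresholds
  cdh_cols <- grep("^cdh_", names(a))
  for (r in seq_len(nrow(a)))
    expect_true(all(diff(unlist(a[r, cdh_cols])) <= 0))
  # strong effect at permissive threshold has near-total power
  expect_gt(a$cdh_0.05[a$grr == 8], 90)
})

test_that("region simulator produces the declared structure", {
  set.seed(29)
  rm0 <- region_model(m = 40, portion_causal = 0.1, grr = 10, alpha = 0.05)
  reg <- simulate_region(rm0, 4000)
  expect_equal(dim(reg$G), c(4000, 40))
  expect_true(all(reg$G %in% 0:2))
  expect_true(all(reg$maf[reg$causal] < 0.05))
  expect_gte(length(reg$causal), 2)
  # exposure definition: homozygote at any causal or het at >= 2 causal
  Gc <- reg$G[, reg$causal, drop = FALSE]
  expect_equal(reg$exposed,
               rowSums(Gc == 2) > 0 | rowSums(Gc == 1) >= 2)
  # null region: no causal flags, prevalence ~ alpha
  rm_null <- region_model(m = 40, portion_causal = 0, grr = 1)
  regn <- simulate_region(rm_null, 4000)
  expect_length(regn$causal, 0)
  expect_lt(abs(mean(regn$y) - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("two-causal exposure frequency matches the closed form", {
  # for two independent causal SNPs at frequency q the exposed fraction is
  # P(hom1) + P(hom2) + P(CH) ~ 2q^2 + 4q^2(1-q)^2 + O(q^3)
  set.seed(37)
  q <- 0.03; n <- 300000
  gp <- simulate_hwe_pair(q, q, n)
  exposed <- gp$g1 == 2 | gp$g2 == 2 | (gp$g1 == 1 & gp$g2 == 1)
  # direct cell-sum oracle rather than the O(q^3) series approximation
  R <- hwe_pair_frequencies(q, q)
  cells <- collapse_risk_cells("causal")
  p_exact <- sum(R[cells])
  expect_lt(abs(mean(exposed) - p_exact), 3 * sqrt(p_exact / n))
})
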