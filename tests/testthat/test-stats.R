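test_that("cytotoxicity and CBPI match direct arithmetic", {
  expect_equal(cytotoxicityCN(400, 400), 0)
  expect_equal(cytotoxicityCN(400, 343), 14.25)
  expect_equal(cytotoxicityCN(400, 0), 100)
  expect_error(cytotoxicityCN(0, 10), "positive")
  expect_equal(cbpi(c(100, 0, 0)), 1)
  expect_equal(cbpi(c(0, 100, 0)), 2)
  expect_equal(cbpi(c(0, 0, 50)), 3)
  expect_equal(cbpi(c(59, 41, 0)), 1.41)
  expect_error(cbpi(c(0, 0, 0)), "zero total")
  expect_equal(cytotoxicityCBPI(c(59, 41, 0), c(59, 41, 0)), 0)
  expect_equal(cytotoxicityCBPI(c(100, 0, 0), c(59, 41, 0)), 100)
  expect_error(cytotoxicityCBPI(c(10, 10, 0), c(100, 0, 0)), "undefined")
})

test_that("CBPI and cytostasis agree with a brute-force oracle", {
  # independent oracle: literal formula evaluation, element by element
  oracleCbpi <- function(n1, n2, n3) (n1 + 2 * n2 + 3 * n3) / (n1 + n2 + n3)
  set.seed(77)
  for (i in 1:1000) {
    n <- rpois(3, c(60, 40, 3)) + c(1, 1, 0)
    expect_identical(cbpi(n), oracleCbpi(n[1], n[2], n[3]))
    expect_true(cbpi(n) >= 1 && cbpi(n) <= 3)
    ctrl <- rpois(3, c(60, 40, 3)) + c(1, 1, 0)
    expected <- 100 - 100 * (oracleCbpi(n[1], n[2], n[3]) - 1) /
      (oracleCbpi(ctrl[1], ctrl[2], ctrl[3]) - 1)
    expect_identical(cytotoxicityCBPI(n, ctrl), expected)
  }
  # inversion example: the cytostasis scale of the positive control
  treated <- c(100000 - 26404, 26404, 0)
  expect_equal(cytotoxicityCBPI(treated, c(59, 41, 0)), 35.6, tolerance = 1e-3)
})

test_that("micronucleus frequency honours both denominator conventions", {
  s <- data.frame(N1 = 1400, N2 = 1000, N3 = 100, n_bi_with_mn = 56)
  expect_equal(mnFrequency(s)$freq_pct, 5.6)
  expect_equal(mnFrequency(s, "per_total_cells")$freq_pct,
               100 * 56 / 2500)
  s$total_cells <- 2500
  expect_equal(mnFrequency(s, "per_total_cells")$freq_pct, 2.24)
  # per-binucleated >= per-total whenever total >= binucleated count
  expect_gte(mnFrequency(s)$freq_pct,
             mnFrequency(s, "per_total_cells")$freq_pct)
  z <- data.frame(N1 = 10, N2 = 20, N3 = 0, n_bi_with_mn = 0)
  expect_equal(mnFrequency(z)$freq_pct, 0)
  expect_error(mnFrequency(data.frame(N1 = 1, N2 = 0, N3 = 0,
                                      n_bi_with_mn = 0)),
               "denominator")
})

test_that("relative effects reproduce the reported contrasts and invert", {
  s <- data.frame(condition = c("NC", "MMC-0.025", "EXT-50+MMC"),
                  freq_pct = c(1.0, 5.6, 3.696))
  r <- relativeEffects(s)
  expect_equal(r$fold_vs_NC[r$condition == "MMC-0.025"], 5.6)
  expect_equal(r$pct_reduction_vs_MMC[r$condition == "MMC-0.025"], 0)
  expect_equal(r$pct_reduction_vs_MMC[r$condition == "EXT-50+MMC"], 34,
               tolerance = 1e-9)
  # round trip: inverting the reduction recovers the frequency exactly
  red <- r$pct_reduction_vs_MMC[r$condition == "EXT-50+MMC"]
  expect_equal(5.6 * (1 - red / 100), 3.696, tolerance = 1e-12)
  expect_error(relativeEffects(s[-1, ]), "missing reference")
})

test_that("the 4PL fit recovers the dose-response", {
  conc <- 9.375 * 2^(0:6)
  clean <- generateViabilityTable(228, 1.5, 100, 0, conc, 3, 0, seed = 1)
  f <- fitIC50(clean)
  expect_lt(abs(f$ic50 - 228) / 228, 0.01)
  expect_equal(f$hill, 1.5, tolerance = 0.05)
  # a seeded 5%-noise table recovers within 10%
  noisy <- generateViabilityTable(228, 1.5, 100, 0, conc, 3, 5, seed = 7)
  fn <- fitIC50(noisy)
  expect_lt(abs(fn$ic50 - 228) / 228, 0.10)
  # all-plateau data are unidentifiable
  flat <- data.frame(concentration = conc, viability = 100)
  expect_error(fitIC50(flat), "no dose response")
  expect_error(fitIC50(clean[clean$concentration < 20, ]), "4 distinct")
})

test_that("4PL recovery is unbiased and tight over repeated simulations", {
  conc <- 9.375 * 2^(0:6)
  est <- vapply(1:100, function(s)
    fitIC50(generateViabilityTable(228, 1.5, 100, 0, conc, 3, 5,
                                   seed = s))$ic50, 0)
  expect_lt(abs(mean(est) - 228) / 228, 0.02)          # bias < 2%
  expect_lt(sqrt(mean((est - 228)^2)) / 228, 0.10)     # RMSE < 10%
})

test_that("group comparison matches textbook ANOVA and detects effects", {
  # identical group patterns: zero between-group variance
  g <- list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3))
  r <- compareGroups(g, "A")
  expect_equal(r$F, 0)
  expect_true(all(r$tukey$p_adj > 0.99))
  # two groups: F equals the hand-computed variance ratio
  a <- c(10, 12, 14)
  b <- c(20, 19, 24)
  gm <- mean(c(a, b))
  ssb <- 3 * ((mean(a) - gm)^2 + (mean(b) - gm)^2)
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  manual <- (ssb / 1) / (ssw / 4)
  r2 <- compareGroups(list(ctrl = a, trt = b), "ctrl")
  expect_equal(r2$F, manual, tolerance = 1e-9)
  # a 10-sd shifted group is flagged against the control
  set.seed(3)
  g3 <- list(ctrl = rnorm(3, 0, 1), same = rnorm(3, 0, 1),
             far = rnorm(3, 10, 1))
  r3 <- compareGroups(g3, "ctrl")
  expect_lt(r3$tukey$p_adj[r3$tukey$condition == "far"], 0.001)
  expect_error(compareGroups(list(A = 1, B = c(1, 2)), "A"), "replicates")
  expect_error(compareGroups(list(A = c(1, 2)), "A"), "2 groups")
})
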