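# Agreement statistics: risk classification, weighted kappa, CCC,
# Bland-Altman, and the packaged cross-classification fixtures.

test_that("risk categories bin Agatston scores without rounding", {
  expect_equal(as.character(classify_risk(c(0, 0.5, 10, 10.5, 100, 100.5,
                                            400, 400.1, 5000))),
               c("0", "1-10", "1-10", "11-100", "11-100", "101-400",
                 "101-400", ">400", ">400"))
  expect_error(classify_risk(-1), class = "cac_contract_error")
})

test_that("cross-tabulation counts pairs in the right cells", {
  tab <- cross_tabulate(c(5, 5, 5), c(5, 5, 5))
  expect_equal(sum(diag(tab)), 3L)
  tab2 <- cross_tabulate(c(5, 0), c(50, 0))
  expect_equal(tab2["1-10", "11-100"], 1L)
  expect_equal(sum(tab2), 2L)
  expect_error(cross_tabulate(numeric(0), numeric(0)),
               class = "cac_validation_error")
})

test_that("packaged matrices reproduce the published agreement statistics", {
  ti <- risk_table_fixture("internal")
  te <- risk_table_fixture("external")
  expect_equal(sum(ti), 198L)
  expect_equal(sum(te), 113L)

  expect_equal(round(100 * accuracy(ti), 1), 91.9)
  expect_equal(round(100 * accuracy(te), 1), 85.8)
  expect_equal(round(weighted_kappa(ti, "linear"), 3), 0.945)
  expect_equal(round(weighted_kappa(te, "linear"), 3), 0.906)

  ri <- reclassification(ti)
  expect_equal(ri$reclassified, 16L)
  expect_equal(round(100 * ri$reclassified_fraction, 1), 8.1)
  expect_equal(ri$downward, 14L)
  expect_equal(round(100 * ri$downward_fraction, 1), 87.5)

  re <- reclassification(te)
  expect_equal(re$reclassified, 16L)
  expect_equal(round(100 * re$reclassified_fraction, 1), 14.2)
  expect_equal(re$downward, 9L)
  expect_equal(round(100 * re$downward_fraction, 1), 56.2)
})

test_that("weighted kappa behaves across weighting schemes and edge cases", {
  diag_tab <- risk_table(diag(c(5, 4, 3, 2, 1)))
  expect_equal(weighted_kappa(diag_tab), 1)
  expect_equal(accuracy(diag_tab), 1)

  ti <- risk_table_fixture("internal")
  expect_gt(weighted_kappa(ti, "quadratic"), weighted_kappa(ti, "linear"))

  # adjacent-only disagreements: linear weighted kappa >= unweighted kappa
  m <- matrix(0L, 5, 5)
  diag(m) <- c(10, 8, 9, 7, 6)
  m[1, 2] <- 3; m[3, 2] <- 2; m[4, 5] <- 1
  tab <- risk_table(m)
  po <- sum(diag(m)) / sum(m)
  pe <- sum(rowSums(m) * colSums(m)) / sum(m)^2
  unweighted <- (po - pe) / (1 - pe)
  expect_gte(weighted_kappa(tab, "linear"), unweighted)

  degenerate <- matrix(0L, 5, 5); degenerate[1, 1] <- 10
  expect_warning(k <- weighted_kappa(risk_table(degenerate)))
  expect_true(is.nan(k))
})

test_that("reclassification of a diagonal table is zero with flagged fraction", {
  rc <- reclassification(risk_table(diag(rep(2L, 5))))
  expect_equal(rc$reclassified, 0L)
  expect_equal(rc$downward, 0L)
  expect_true(is.nan(rc$downward_fraction))
})

test_that("Lin's CCC matches its closed form", {
  expect_equal(lin_ccc(1:10, 1:10)$ccc, 1)
  # hand-evaluated: population moments give 2*(2/3) / (2/3 + 2/3 + 1) = 4/7
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7)
  # ccc never exceeds |pearson r|
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30, 2, 0.7)
    cc <- lin_ccc(x, y)
    expect_lte(cc$ccc, abs(cor(x, y)) + 1e-12)
    expect_lte(cc$lower, cc$ccc)
    expect_gte(cc$upper, cc$ccc)
  }
  expect_warning(res <- lin_ccc(rep(1, 5), rep(1, 5)))
  expect_true(is.nan(res$ccc))
})

test_that("Bland-Altman limits are symmetric around the bias", {
  ba <- bland_altman(1:5, 1:5)
  expect_equal(c(ba$bias, ba$lower, ba$upper), c(0, 0, 0))
  # differences (1, -1, 0): sample sd = 1
  ba2 <- bland_altman(c(2, 0, 1), c(1, 1, 1))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$upper, 1.96 * sd(c(1, -1, 0)))
  expect_equal(ba2$upper - ba2$bias, ba2$bias - ba2$lower)
})

test_that("pearson and paired t wrap the standard tests", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(9)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(pearson_r(a, b)$r), 0.05)
  expect_warning(res <- pearson_r(rep(1, 5), 1:5))
  expect_true(is.nan(res$r))

  tt <- paired_t_test(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_true(tt$degenerate)
  # constant shift d with spread: t = d sqrt(n) / sd(diff)... here diff has
  # spread from y noise
  set.seed(2)
  y <- x + 1 + rnorm(4, 0, 0.1)
  tt2 <- paired_t_test(y, x)
  d <- y - x
  expect_equal(tt2$t, mean(d) * sqrt(4) / sd(d))
})

test_that("paired t-test agrees with a permutation oracle", {
  set.seed(11)
  x <- rnorm(20, 0.6, 1); y <- rnorm(20, 0, 1)
  p_t <- paired_t_test(x, y)$p
  d <- x - y
  obs <- abs(mean(d))
  # exact-ish sign-flip permutation distribution of |mean difference|
  set.seed(12)
  perm <- replicate(20000, abs(mean(d * sample(c(-1, 1), 20, TRUE))))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.03)
})

test_that("statistics are invariant to subject order", {
  set.seed(21)
  x <- rexp(40) * 100; y <- x * 0.8 + rnorm(40, 0, 5)
  y <- pmax(y, 0)
  o <- sample(40)
  expect_equal(lin_ccc(x, y)$ccc, lin_ccc(x[o], y[o])$ccc)
  expect_equal(weighted_kappa(cross_tabulate(x, y)),
               weighted_kappa(cross_tabulate(x[o], y[o])))
  expect_equal(bland_altman(x, y)$upper, bland_altman(x[o], y[o])$upper)
})

test_that("agreement report bundles the statistics coherently", {
  set.seed(31)
  ref <- c(0, 0, 5, 8, 50, 80, 200, 350, 500, 900)
  auto <- ref * 0.7 + c(0, 0, rnorm(8, 0, 3))
  auto <- pmax(auto, 0)
  rep <- agreement_report(auto, ref)
  expect_equal(rep$n, 10)
  expect_equal(sum(rep$risk_table), 10L)
  expect_equal(rep$reclassification$reclassified,
               10L - sum(diag(rep$risk_table)))
  expect_lte(abs(rep$weighted_kappa), 1)
  expect_output(print(rep), "agreement_report")
})
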