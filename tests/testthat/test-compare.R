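curve_pair <- function(n = 50, shift = 0, seed = 17) {
  s <- seq(0.01, 0.5, length.out = n)
  base <- exp(-s * 4) * 100
  a <- noisy_curve(saxs_curve(s, base), sigma = 0.02, seed = seed)
  b <- noisy_curve(saxs_curve(s, base + shift * 0.02 * base),
                   sigma = 0.02, seed = seed + 5000)
  list(a = a, b = b)
}

test_that("identical curves give chi2 0 and zero residuals", {
  crv <- saxs_curve(1:20 / 40, exp(-(1:20) / 8), sigma = rep(0.1, 20))
  res <- residuals_curves(crv, crv)
  expect_true(all(unclass(res) == 0))
  r2 <- reduced_chi2(crv, crv)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
})

test_that("reduced chi2 p-values reproduce the published comparisons", {
  ## printed statistics are rounded to 3 decimals, bounding agreement
  expect_equal(pchisq(1776 * 1.081, df = 1776, lower.tail = FALSE),
               0.0091, tolerance = 0.0005 / 0.0091)
  expect_equal(pchisq(2652 * 1.007, df = 2652, lower.tail = FALSE),
               0.3942, tolerance = 0.004 / 0.3942)
  ## and via the curve interface: calibrated noise gives chi2 ~ 1
  p <- curve_pair(n = 2000)
  out <- reduced_chi2(p$a, p$b)
  expect_lt(abs(out$statistic - 1), 3 * sqrt(2 / 2000))
})

test_that("cormap_pvalue reproduces the published exact values", {
  expect_lt(abs(cormap_pvalue(2652, 13) - 0.2759), 5e-5)
  expect_lt(abs(cormap_pvalue(1434, 11) - 0.5031), 5e-5)
  expect_lt(abs(cormap_pvalue(1776, 13) - 0.1941), 5e-5)
  expect_equal(cormap_pvalue(1, 1), 1)
  expect_equal(cormap_pvalue(5, 6), 0)
})

test_that("cormap_pvalue matches brute-force enumeration for small n", {
  for (n in c(5, 9, 12)) {
    for (C in c(2, 3, 5, n)) {
      expect_equal(cormap_pvalue(n, C), brute_force_longest_run_p(n, C),
                   tolerance = 1e-12)
    }
  }
})

test_that("cormap statistic counts the longest same-sign run", {
  s <- 1:8 / 10
  a <- saxs_curve(s, c(1, 1, 1, 1, 0, 0, 1, 0))
  b <- saxs_curve(s, c(0, 0, 0, 0, 1, 1, 0, 1))
  out <- cormap(a, b)
  expect_equal(out$statistic, 4L)
  expect_equal(out$p, cormap_pvalue(8, 4))
  ## zero differences count as positive sign
  z <- saxs_curve(s, rep(1, 8))
  expect_equal(cormap(z, z)$statistic, 8L)
})

test_that("Anderson-Darling p-values reproduce the published values", {
  expect_equal(ad_pvalue(0.320), 0.9226, tolerance = 0.001 / 0.9226)
  expect_equal(ad_pvalue(0.611), 0.6374, tolerance = 0.001 / 0.6374)
  expect_equal(ad_pvalue(2.284), 0.0644, tolerance = 0.001 / 0.0644)
})

test_that("the asymptotic AD distribution matches an independent inversion", {
  for (z in c(0.2, 1.0, 3.5))
    expect_lt(abs(ad_pvalue(z) - ad_sf_imhof(z)), 5e-5)
})

test_that("all three p-values decrease in their statistic", {
  expect_true(all(diff(vapply(seq(0.2, 5, by = 0.4), ad_pvalue,
                              numeric(1))) < 0))
  cp <- vapply(2:14, function(C) cormap_pvalue(500, C), numeric(1))
  expect_true(all(diff(cp) <= 0))        # saturates at 1 in doubles for C <= 4
  expect_true(all(diff(cp[5:13]) < 0))
  expect_true(all(diff(pchisq(500 * seq(0.8, 1.5, by = 0.1), df = 500,
                              lower.tail = FALSE)) < 0))
})

test_that("a 5-sigma shift is detected and residuals sit near 5", {
  p <- curve_pair(n = 300, shift = 5 * sqrt(2))
  r <- unclass(residuals_curves(p$a, p$b))
  expect_lt(abs(mean(r) + 5), 0.5)
  expect_lt(anderson_darling(p$a, p$b)$p, 1e-6)
  expect_lt(reduced_chi2(p$a, p$b)$p, 1e-6)
})

test_that("independent replicates keep ~99% of residuals within 3", {
  p <- curve_pair(n = 3000)
  res <- residuals_curves(p$a, p$b)
  expect_gte(attr(res, "frac_within_3"), 0.99)
})

test_that("datcmp aggregates the three tests consistently", {
  p <- curve_pair(n = 500)
  cmp <- datcmp(p$a, p$b)
  expect_equal(cmp$chi2_red, reduced_chi2(p$a, p$b)$statistic)
  expect_equal(cmp$cormap_C, cormap(p$a, p$b)$statistic)
  expect_equal(cmp$ad_A2, anderson_darling(p$a, p$b)$statistic)
  expect_true(all(c(cmp$cormap_p, cmp$chi2_p, cmp$ad_p) >= 0 &
                  c(cmp$cormap_p, cmp$chi2_p, cmp$ad_p) <= 1))
  expect_gte(cmp$cormap_C, 1)
  expect_lte(cmp$cormap_C, cmp$n)
})

test_that("resampling is seed-deterministic with the requested spread", {
  s <- seq(0.01, 0.3, length.out = 100)
  crv <- saxs_curve(s, exp(-s * 5) * 50, sigma = 0.04 * exp(-s * 5) * 50)
  r1 <- resample_curve(crv, n = 3, seed = 7)
  r2 <- resample_curve(crv, n = 3, seed = 7)
  expect_identical(r1[[2]]$I, r2[[2]]$I)
  expect_identical(r1[[1]]$sigma, crv$sigma)   # sigma carried unchanged
  ## scale = 0 reproduces the input exactly
  r0 <- resample_curve(crv, n = 2, scale = 0, seed = 1)
  expect_equal(r0[[1]]$I, crv$I)
  ## per-point sample SD ~ scale * sigma at n = 1000
  reps <- resample_curve(crv, n = 1000, scale = 0.5, seed = 21)
  M <- vapply(reps, function(r) r$I, numeric(100))
  sds <- apply(M, 1, sd)
  expect_lt(median(abs(sds / (0.5 * crv$sigma) - 1)), 0.05)
})

test_that("resampled Guinier spread matches the reported standard error", {
  ## the variance-validation workflow: SD of Rg over resampled replicates
  ## against the regression standard error of the original fit
  s <- seq(0.005, 0.12, length.out = 150)
  true_rg <- 20
  base <- saxs_curve(s, 100 * exp(-s^2 * true_rg^2 / 3))
  crv <- noisy_curve(base, sigma = 0.01, seed = 3)
  fit <- guinier_fit(crv, srg_limit = 1.3)
  rgs <- vapply(resample_curve(crv, n = 400, seed = 11),
                function(r) guinier_fit(r, srg_limit = 1.3)$Rg, numeric(1))
  expect_lt(abs(sd(rgs) / fit$Rg_se - 1), 0.25)
  expect_lt(abs(fit$Rg - true_rg) / true_rg, 0.02)
})

test_that("missing errors are rejected where required", {
  s <- 1:10 / 20
  bare <- saxs_curve(s, 10:1)
  expect_error(reduced_chi2(bare, bare), "error estimates")
  expect_error(resample_curve(bare, 2, seed = 1), "error estimates")
  expect_silent(cormap(bare, bare))
})
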