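test_that("ols_fit recovers exact lines and degenerate responses", {
  fit <- ols_fit(c(0, 1, 2), c(1, 3, 5))
  expect_equal(fit$coefficients, c(1, 2))
  expect_equal(fit$rss, 0)
  expect_equal(fit$n_params, 2L)

  flat <- ols_fit(c(0, 1, 2), c(5, 5, 5))
  expect_equal(flat$coefficients, c(5, 0))
  expect_equal(flat$rss, 0)
})

test_that("ols_fit matches the normal-equations oracle on random data", {
  set.seed(101)
  x <- rnorm(50)
  y <- 2 + 0.7 * x + rnorm(50)
  fit <- ols_fit(x, y)
  ref <- oracle_ols(x, y)
  expect_equal(fit$coefficients, ref$coefficients, tolerance = 1e-10)
  expect_equal(fit$rss, ref$rss, tolerance = 1e-10)
  expect_equal(fit$n_samples, 50L)
})

test_that("ols_fit signals unfittable input instead of crashing", {
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), class = "fedchow_unfittable")
  expect_error(ols_fit(c(1, 2), c(1, 2)), class = "fedchow_unfittable")
  expect_error(ols_fit(1:3, 1:4), class = "fedchow_invalid")
})

test_that("chow test is null on replicated identical groups", {
  set.seed(7)
  x <- rnorm(20); y <- 1 + x + rnorm(20)
  fits <- list(ols_fit(x, y), ols_fit(x, y), ols_fit(x, y))
  comb <- ols_fit(rep(x, 3), rep(y, 3))
  res <- chow_test(fits, comb)
  expect_equal(res$f_value, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
})

test_that("chow test degrees of freedom follow (G-1)k and N - Gk", {
  set.seed(8)
  xs <- replicate(3, rnorm(10), simplify = FALSE)
  ys <- lapply(xs, function(x) x + rnorm(10))
  fits <- Map(ols_fit, xs, ys)
  x_all <- unlist(xs)
  y_all <- unlist(ys)
  res <- chow_test(fits, ols_fit(x_all, y_all))
  expect_equal(res$df_num, 4L)   # 2k with k = 2
  expect_equal(res$df_den, 24L)  # 30 - 3k

  # two groups reduce to the classic statistic with numerator df = k
  res2 <- chow_test(fits[1:2], ols_fit(c(xs[[1]], xs[[2]]), y_all[1:20]))
  expect_equal(res2$df_num, 2L)
})

test_that("chow test matches direct formula evaluation under a break", {
  set.seed(11)
  g <- rep(1:3, each = 12)
  x <- rnorm(36)
  y <- ifelse(g == 3, 5 * x, 1 * x) + rnorm(36, sd = 0.3)
  fits <- lapply(split(seq_along(x), g), function(i) ols_fit(x[i], y[i]))
  res <- chow_test(fits, ols_fit(x, y))
  ref <- oracle_chow(x, y, g)
  expect_equal(res$f_value, ref$f, tolerance = 1e-10)
  expect_equal(res$p_value, ref$p, tolerance = 1e-10)
})

test_that("chow F is invariant to affine rescaling of y across all groups", {
  set.seed(12)
  g <- rep(1:3, each = 15)
  x <- rnorm(45)
  y <- ifelse(g == 1, 2 * x, 0.5 * x) + rnorm(45, sd = 0.4)
  f0 <- oracle_chow(x, y, g)$f
  fits <- lapply(split(seq_along(x), g),
                 function(i) ols_fit(x[i], 10 * y[i] - 3))
  res <- chow_test(fits, ols_fit(x, 10 * y - 3))
  expect_equal(res$f_value, f0, tolerance = 1e-8)
})

test_that("chow test validates its preconditions", {
  set.seed(13)
  f1 <- ols_fit(rnorm(10), rnorm(10))
  expect_error(chow_test(list(f1), f1), class = "fedchow_degenerate")
  # N = G * k leaves no denominator degrees of freedom
  tiny <- regression_fit(c(0, 0), 1, 2)
  expect_error(chow_test(list(tiny, tiny), regression_fit(c(0, 0), 3, 4)),
               class = "fedchow_insufficient")
})

test_that("hypergeometric conventions agree with published-style counts", {
  # worked example: 1625 genes selected from a 20211-gene universe, 73 in a
  # 632-gene reference list
  e_tail <- hypergeom_enrichment(20211, 632, 1625, 73, convention = "greater")
  e_pmf <- hypergeom_enrichment(20211, 632, 1625, 73, convention = "pmf")
  expect_equal(signif(e_pmf$p_value, 2), 0.00039)
  expect_lt(e_tail$p_value, 0.001)
  expect_gt(e_tail$p_value, e_pmf$p_value)

  # maximal overlap leaves no more-extreme outcome
  e_max <- hypergeom_enrichment(100, 20, 10, 10)
  expect_equal(e_max$p_value, 0)
})

test_that("hypergeometric tail equals brute-force enumeration of PMF terms", {
  ref <- oracle_hyper_pmf(10, 4, 5)
  expect_equal(hypergeom_enrichment(10, 4, 5, 3)$p_value,
               sum(ref$p[ref$k > 3]), tolerance = 1e-12)
  expect_equal(sum(ref$p), 1, tolerance = 1e-12)
})

test_that("hypergeometric enrichment rejects impossible counts", {
  expect_error(hypergeom_enrichment(10, 4, 5, 6), class = "fedchow_invalid")
  expect_error(hypergeom_enrichment(10, 12, 5, 1), class = "fedchow_invalid")
  expect_error(hypergeom_enrichment(10, 4, 5, -1), class = "fedchow_invalid")
})

test_that("pearson_with_p matches the definitional formulas", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  set.seed(21)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  got <- pearson_with_p(x, y)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_ref <- r_ref * sqrt(28 / (1 - r_ref^2))
  expect_equal(got$r, r_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_ref), 28), tolerance = 1e-12)
  expect_equal(got$n, 30L)
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), class = "fedchow_unfittable")
})

test_that("bh_fdr reproduces the step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))

  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(bh_fdr(p), c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  set.seed(31)
  pr <- runif(40)
  expect_equal(bh_fdr(pr), oracle_bh(pr))

  # NAs preserved and excluded from the test count
  p_na <- c(0.01, NA, 0.02)
  expect_equal(bh_fdr(p_na), c(0.02, NA, 0.02))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "fedchow_invalid")
})

test_that("HWE exact test handles monomorphic and extreme counts", {
  expect_equal(hwe_exact_test(0, 0, 40), 1)
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), class = "fedchow_invalid")
  expect_error(hwe_exact_test(-1, 2, 3), class = "fedchow_invalid")
})

test_that("HWE exact test matches full enumeration for small totals", {
  for (n_tot in c(4, 7, 10)) {
    for (aa in 0:n_tot) for (ab in 0:(n_tot - aa)) {
      bb <- n_tot - aa - ab
      if (aa + ab + bb == 0) next
      expect_equal(hwe_exact_test(aa, ab, bb), oracle_hwe(aa, ab, bb),
                   tolerance = 1e-9,
                   label = sprintf("counts (%d,%d,%d)", aa, ab, bb))
    }
  }
})

test_that("HWE mid-p values are approximately uniform under the null", {
  set.seed(77)
  n <- 2000; f <- 0.5
  ps <- replicate(2000, {
    g <- sample(0:2, n, TRUE, prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2), midp = TRUE)
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
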