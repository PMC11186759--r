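test_that("signed-rank p-values match full enumeration on small fixtures", {
  # the tied all-equal-differences fixture
  w <- paired_wilcoxon(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$p_value, 0.25)
  expect_equal(w$method, "exact")
  # random fixtures, some with ties and zeros, against the 2^n oracle
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    x <- round(rnorm(n, sd = 2), 1)
    y <- round(rnorm(n, sd = 2), 1)
    if (all(x == y)) next
    got <- paired_wilcoxon(x, y)
    expect_equal(got$p_value, enumerate_wilcoxon_p(x, y), tolerance = 1e-12,
      label = sprintf("fixture %d", i))
  }
})

test_that("signed-rank agrees with wilcox.test when ties are absent", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(8)
    y <- rnorm(8)
    got <- paired_wilcoxon(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("signed-rank input contracts are enforced", {
  expect_error(paired_wilcoxon(1:3, 1:4), "paired")
  expect_error(paired_wilcoxon(c(1, 2), c(2, 3)), "at least 3")
  expect_error(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  w <- paired_wilcoxon(c(1, 2, 3, 4), c(1, 3, 4, 5))
  expect_equal(w$n_zero_dropped, 1)
  expect_equal(w$n, 3)
})

test_that("Mann-Whitney p-values match enumeration and wilcox.test", {
  got <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1 / 3, tolerance = 1e-12)
  # single-element groups: U = 0, two-sided p = 1
  g1 <- mannwhitney_u(1, 2)
  expect_equal(g1$statistic, 0)
  expect_equal(g1$p_value, 1)
  # identical multisets: U = mn/2
  gi <- mannwhitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gi$statistic, 4.5)
  set.seed(11)
  for (i in 1:10) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    x <- round(rnorm(m), 1)
    y <- round(rnorm(n), 1)
    expect_equal(mannwhitney_u(x, y)$p_value, enumerate_mw_p(x, y),
      tolerance = 1e-12, label = sprintf("fixture %d", i))
    if (length(unique(c(x, y))) == m + n) {
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(mannwhitney_u(x, y)$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_error(mannwhitney_u(numeric(), 1:3), "non-empty")
})

test_that("normal-approximation branches are close to stats:: references", {
  set.seed(3)
  x <- rnorm(40)
  y <- rnorm(40, 0.3)
  w <- paired_wilcoxon(x, y)
  expect_equal(w$method, "normal_approx")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
  mw <- mannwhitney_u(x, y)
  refu <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$p_value, refu$p.value, tolerance = 1e-9)
})

test_that("the exact signed-rank test holds its size at n = 15", {
  set.seed(123)
  rejections <- sum(vapply(1:2000, function(i) {
    x <- rnorm(15)
    y <- rnorm(15)
    paired_wilcoxon(x, y)$p_value < 0.05
  }, logical(1)))
  expect_lte(rejections / 2000, 0.06)
})

test_that("Pearson correlation handles exact and null cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(1, 5)), "variance")
  set.seed(9)
  small <- vapply(1:100, function(i) {
    abs(pearson_corr(rnorm(1000), rnorm(1000))$r) < 0.1
  }, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("chi-squared proportions match the closed form", {
  even <- matrix(c(10, 10, 10, 10), nrow = 2)
  out <- chisq_proportions(even)
  expect_equal(out$chisq, 0)
  expect_equal(out$p_value, 1)
  diag2 <- matrix(c(10, 0, 0, 10), nrow = 2)
  expect_equal(chisq_proportions(diag2)$chisq, 20)
  expect_error(chisq_proportions(matrix(c(0, 0, 5, 5), nrow = 2)), "marginal")
})
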