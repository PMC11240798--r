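test_that("Friedman statistic matches closed forms", {
  # identical rank order in every row, n = 3, k = 3 -> chi-square 6, df 2
  x <- matrix(c(1, 2, 3), nrow = 3, ncol = 3, byrow = TRUE) +
    matrix(c(0, 10, 20), 3, 3)
  f <- friedman_rm(x)
  expect_equal(f$statistic, 6)
  expect_identical(f$df, 2L)

  # all values equal -> statistic 0, p = 1
  f0 <- friedman_rm(matrix(5, 4, 3))
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p.value, 1)

  expect_error(friedman_rm(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
  expect_error(friedman_rm(matrix(1:3, 1, 3)), "n >= 2")
})

test_that("Friedman agrees with base R and the counting-rank oracle on random tables", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:8, 1); k <- sample(3:9, 1)
    x <- matrix(sample(1:4, n * k, replace = TRUE) + rnorm(n * k, 0, 0.01),
                n, k)
    if (i %% 2 == 0) x <- round(x)  # force heavy ties half the time
    f <- friedman_rm(x)
    expect_equal(f$statistic, oracle_friedman(x), tolerance = 1e-12)
    base <- suppressWarnings(stats::friedman.test(x))
    if (is.finite(base$statistic))
      expect_equal(f$statistic, unname(base$statistic), tolerance = 1e-12)
  }
})

test_that("Dunn-Bonferroni post hoc has the pairwise structure and adjustment", {
  x <- matrix(rep(c(2, 2, 2), 5), 5, 3, byrow = TRUE)
  d <- dunn_bonferroni(x)
  expect_equal(d$z, rep(0, 3))
  expect_equal(d$p.adjusted, rep(1, 3))

  set.seed(3)
  x9 <- matrix(rnorm(12 * 9), 12, 9,
               dimnames = list(NULL, roi_labels()))
  d9 <- dunn_bonferroni(x9)
  expect_identical(nrow(d9), 36L)          # k(k-1)/2 for k = 9
  expect_true(all(d9$p.adjusted >= d9$p.value))
  expect_true(all(d9$p.adjusted <= 1))
  # z formula check on one pair
  mr <- colMeans(t(apply(x9, 1, rank)))
  se <- sqrt(9 * 10 / (6 * 12))
  expect_equal(d9$z[1], (mr[["A"]] - mr[["A_R"]]) / se)
})

test_that("Mann-Whitney U, z and r follow the rank conventions", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)            # complete separation -> U = 0

  a <- c(1, 2, 3, 4)
  mw2 <- mann_whitney_u(a, a)              # identical groups
  expect_equal(mw2$statistic, length(a)^2 / 2)
  expect_equal(mw2$z, 0)
  expect_equal(mw2$p.value, 1)

  set.seed(13)
  x <- rnorm(26); y <- rnorm(31, 0.8)
  mw3 <- mann_whitney_u(x, y)
  expect_equal(mw3$effect_r, abs(mw3$z) / sqrt(57))
  # p agrees with base wilcox.test (normal approximation, continuity)
  base <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(mw3$p.value, base$p.value, tolerance = 1e-10)
  # U = min convention: min(W, n1*n2 - W) with W from base
  expect_equal(mw3$statistic,
               min(unname(base$statistic), 26 * 31 - unname(base$statistic)))
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney U is invariant under strictly monotone transforms", {
  set.seed(23)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  u0 <- mann_whitney_u(a, b)$statistic
  expect_equal(mann_whitney_u(exp(a), exp(b))$statistic, u0)
  expect_equal(mann_whitney_u(a^3, b^3)$statistic, u0)
  expect_equal(mann_whitney_u(stats::pnorm(a), stats::pnorm(b))$statistic,
               u0)
})

test_that("effect size r reproduces the printed sex-difference effect sizes", {
  expect_equal(round(effect_size_r(-3.65, 57), 2), 0.48)
  expect_equal(round(effect_size_r(-2.4, 57), 2), 0.32)
  expect_equal(round(effect_size_r(-2.19, 57), 2), 0.29)
  expect_equal(effect_size_r(0, 57), 0)
  expect_error(effect_size_r(1, 1), "at least 2")
})

test_that("Spearman rho matches hand ranks, symmetry and base R", {
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  sp <- spearman_rho(x, y)
  expect_equal(sp$statistic, 0.8)
  expect_equal(spearman_rho(x, 2 * x + 3)$statistic, 1)
  expect_equal(spearman_rho(x, -x)$statistic, -1)
  expect_equal(spearman_rho(y, x)$statistic, sp$statistic)
  expect_equal(spearman_rho(x, -y)$statistic, -sp$statistic)

  set.seed(41)
  a <- rnorm(30); b <- a + rnorm(30, 0, 2)
  got <- spearman_rho(a, b)
  base <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(got$statistic, unname(base$estimate), tolerance = 1e-12)
  expect_equal(got$p.value, base$p.value, tolerance = 1e-10)

  const <- spearman_rho(rep(1, 5), 1:5)
  expect_true(is.na(const$statistic))
  expect_match(const$reason, "zero rank variance")
})

test_that("independent t-test matches the pooled hand formula and prints Cohen's d", {
  same <- ttest_ind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$cohens_d, 0)

  # a = {0, 2}, b = {1, 3}: means 1, 2; pooled var = 2; t = -1/sqrt(2*2/2)
  tt <- ttest_ind(c(0, 2), c(1, 3))
  sp <- sqrt(((1) * 2 + (1) * 2) / 2)
  expect_equal(tt$statistic, (1 - 2) / (sp * sqrt(1 / 2 + 1 / 2)))
  expect_identical(tt$df, 2)
  expect_equal(tt$cohens_d, 1 / sp)
  expect_error(ttest_ind(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("Cohen's d from t reproduces the printed value and the algebraic identity", {
  expect_equal(round(cohens_d_from_t(-1.12, 26, 31), 2), 0.30)
  expect_equal(cohens_d_from_t(0, 5, 5), 0)
  set.seed(53)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), 0.3)
    tt <- ttest_ind(a, b)
    expect_equal(cohens_d_from_t(tt$statistic, length(a), length(b)),
                 tt$cohens_d, tolerance = 1e-12)
  }
})
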