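# Correlation inference, residualization, FDR and the Fisher-z comparison.

test_that("Pearson test matches cor.test and a permutation oracle", {
  set.seed(11)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  ct <- correlation_test(x, y, "pearson")
  ref <- cor.test(x, y)
  expect_equal(ct$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ct$df, 28L)

  expect_equal(correlation_test(x, x)$estimate, 1)
  expect_equal(correlation_test(x, x)$p, 0)

  # Monte-Carlo permutation oracle at n = 10 (t null is exact under
  # normality, so the permutation p should agree closely)
  set.seed(12)
  x10 <- rnorm(10)
  y10 <- 0.5 * x10 + rnorm(10)
  r_obs <- cor(x10, y10)
  B <- 100000L
  perms <- replicate(B, cor(x10, sample(y10)))
  p_perm <- (1 + sum(abs(perms) >= abs(r_obs))) / (B + 1)
  p_t <- correlation_test(x10, y10)$p
  expect_equal(p_t, p_perm, tolerance = 0.02)

  expect_error(correlation_test(x, y[1:10]), "equal length")
  expect_error(correlation_test(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlation_test(rnorm(3), rnorm(3)), "at least 4")
})

test_that("Spearman is Pearson on ranks with a t-approximate p", {
  set.seed(13)
  x <- rnorm(50)                # continuous: no ties
  y <- x^3 + rnorm(50)
  sp <- correlation_test(x, y, "spearman")
  pr <- correlation_test(rank(x), rank(y), "pearson")
  expect_identical(sp$estimate, pr$estimate)
  expect_identical(sp$p, pr$p)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(sp$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(sp$p, ref$p.value, tolerance = 1e-10)
})

test_that("residualize projects out covariates exactly", {
  set.seed(14)
  n <- 8
  Z <- cbind(rnorm(n), rnorm(n))
  y <- 2 + Z %*% c(1, -1) + rnorm(n)
  res <- residualize(as.numeric(y), Z)
  X <- cbind(1, Z)
  oracle <- as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
  expect_equal(res, oracle, tolerance = 1e-10)
  expect_equal(mean(res), 0, tolerance = 1e-12)
  expect_lt(max(abs(t(Z) %*% res)), 1e-8)

  # y inside the covariate span -> zero residuals
  y2 <- 3 + 2 * Z[, 1]
  expect_lt(max(abs(residualize(y2, Z))), 1e-10)
  # y orthogonal to (centered) covariates -> y minus its mean
  expect_error(residualize(y, cbind(Z, Z[, 1])), "rank-deficient")
})

test_that("partial rank correlation matches an explicit projection oracle", {
  set.seed(15)
  n <- 20
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  x <- z1 + rnorm(n)
  y <- -z1 + 0.5 * z2 + rnorm(n)
  Z <- cbind(z1, z2)
  pc <- partial_rank_correlation(x, y, Z)
  # oracle: rank everything, residualize by explicit least squares
  rx <- rank(x); ry <- rank(y); rz <- apply(Z, 2, rank)
  X <- cbind(1, rz)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ex <- rx - H %*% rx
  ey <- ry - H %*% ry
  r_or <- cor(ex, ey)
  df <- n - 2 - 2
  t_or <- r_or * sqrt(df / (1 - r_or^2))
  expect_equal(pc$estimate, as.numeric(r_or), tolerance = 1e-12)
  expect_equal(pc$p, as.numeric(2 * pt(-abs(t_or), df)), tolerance = 1e-12)
  expect_equal(pc$df, df)

  # no covariates: reduces to the Spearman test
  pc0 <- partial_rank_correlation(x, y, matrix(numeric(0), n, 0))
  sp <- correlation_test(x, y, "spearman")
  expect_equal(pc0$estimate, sp$estimate, tolerance = 1e-12)
  expect_equal(pc0$p, sp$p, tolerance = 1e-12)

  # covariate duplicating y leaves nothing to explain
  pcy <- partial_rank_correlation(x, y, cbind(y))
  expect_equal(pcy$estimate, 0)
  expect_equal(pcy$p, 1)
})

test_that("BH adjustment matches the independent step-up oracle", {
  set.seed(16)
  for (i in 1:20) {
    p <- runif(sample(3:15, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  # permutation invariance
  p <- runif(9)
  o <- sample(9)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  # adjusted values never fall below the raw p and are capped at 1
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher-z comparison behaves as the formula dictates", {
  eq <- compare_correlations(0.3, 50, 0.3, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- compare_correlations(0.5, 60, 0.1, 60)
  b <- compare_correlations(0.1, 60, 0.5, 60)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # strictly increasing |z| in the atanh gap
  g1 <- abs(compare_correlations(0.40, 60, 0.10, 60)$z)
  g2 <- abs(compare_correlations(0.55, 60, 0.10, 60)$z)
  expect_gt(g2, g1)
  expect_error(compare_correlations(1, 10, 0.2, 10), "< 1")
  expect_error(compare_correlations(0.5, 3, 0.2, 10), "> 3")
})

test_that("association tables run one test per unit with family-wise FDR", {
  set.seed(17)
  n <- 40
  y <- rnorm(n)
  measures <- rbind(
    signal_unit = -y + rnorm(n, sd = 0.5),
    noise_1 = rnorm(n),
    noise_2 = rnorm(n)
  )
  tab <- association_table(measures, y, "pearson", fdr = TRUE)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$unit, rownames(measures))
  expect_lt(tab$estimate[1], -0.5)
  expect_equal(tab$p_fdr, oracle_bh(tab$p))
  expect_equal(attr(tab, "family_size"), 3L)
  # row-by-row equality with the scalar test
  for (i in 1:3) {
    ct <- correlation_test(measures[i, ], y, "pearson")
    expect_equal(tab$estimate[i], ct$estimate)
    expect_equal(tab$p[i], ct$p)
  }
  expect_error(association_table(measures[, 1:3], y[1:3]), "at least 4")
})
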