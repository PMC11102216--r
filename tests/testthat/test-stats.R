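# independent enumeration oracle for the two-sided Fisher p-value:
# sum of hypergeometric probabilities of margin-preserving tables no more
# likely than the observed one
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("bootstrap mean-difference test: degenerate, separated, reproducible", {
  same <- rep(2, 10)
  r <- bootstrap_mean_diff(same, same, n_boot = 999, seed = 1)
  expect_equal(r$estimate, 0)
  expect_equal(r$p, 1)

  set.seed(2)
  x <- stats::rnorm(50, 1, 0.1); y <- stats::rnorm(50, 0, 0.1)
  r2 <- bootstrap_mean_diff(x, y, n_boot = 4999, seed = 3)
  expect_lt(r2$p, 0.001)
  expect_gt(r2$ci_lo, 0)
  expect_true(r2$ci_lo <= r2$estimate && r2$estimate <= r2$ci_hi)

  r3 <- bootstrap_mean_diff(x, y, n_boot = 4999, seed = 3)
  expect_identical(r2, r3)
  # RNG state of the caller is untouched
  set.seed(9); before <- stats::runif(1)
  set.seed(9); invisible(bootstrap_mean_diff(x, y, n_boot = 99, seed = 1))
  expect_identical(stats::runif(1), before)

  # one-tailed p in the stated direction is smaller than the wrong one
  g <- bootstrap_mean_diff(x, y, tails = 1, alternative = "greater",
                           n_boot = 999, seed = 4)
  l <- bootstrap_mean_diff(x, y, tails = 1, alternative = "less",
                           n_boot = 999, seed = 4)
  expect_lt(g$p, l$p)
  expect_error(bootstrap_mean_diff(numeric(0), y), "n >= 2")
})

test_that("spearman matches the d^2 formula and flags degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman(x, c(1, 3, 4, 7, 20), n_boot = 99)$rho, 1)
  expect_equal(spearman(x, -x, n_boot = 99)$rho, -1)
  # hand rank computation: d = (-1, 1, -1, 1, 0), d^2 sum = 4
  # -> rho = 1 - 6 * 4 / 120 = 0.8
  s <- spearman(x, c(2, 1, 4, 3, 5), n_boot = 999, seed = 5)
  expect_equal(s$rho, 0.8)
  expect_true(s$ci_lo <= 0.8 & 0.8 <= s$ci_hi)
  expect_error(spearman(x, rep(1, 5)), "constant")
  expect_error(spearman(1:3, 1:3), "n >= 4")

  # tie-free random data: rho identical to the closed-form 1 - 6 sum d^2 / (n^3 - n)
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    a <- sample(1000, n); b <- sample(1000, n)
    d2 <- sum((rank(a) - rank(b))^2)
    expect_equal(spearman(a, b, n_boot = 9)$rho, 1 - 6 * d2 / (n^3 - n))
  }
})

test_that("spearman bootstrap CI covers the true rank correlation", {
  set.seed(7)
  rho_xy <- 0.5
  true_rs <- 6 / pi * asin(rho_xy / 2)
  hits <- vapply(1:200, function(i) {
    x <- stats::rnorm(35)
    y <- rho_xy * x + sqrt(1 - rho_xy^2) * stats::rnorm(35)
    ci <- spearman(x, y, n_boot = 400, seed = i)
    ci$ci_lo <= true_rs && true_rs <= ci$ci_hi
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("partial spearman reduces to the plug-in formula", {
  # covariate constructed with zero rank correlation against both x and
  # y: partial equals the plain rank correlation
  x <- 1:8
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  z <- c(6, 3, 7, 2, 1, 8, 4, 5)
  expect_equal(stats::cor(rank(x), rank(z)), 0)
  expect_equal(stats::cor(rank(y), rank(z)), 0)
  rho <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_partial(x, y, z), rho, tolerance = 1e-12)

  expect_error(spearman_partial(x, y, y), "degenerate covariate")
  expect_error(spearman_partial(1:4, 1:4, c(1, 2, 1, 2)), "n >= 5")

  # generic case: verify against the formula computed by hand from ranks
  set.seed(8)
  a <- stats::rnorm(20); b <- stats::rnorm(20); c <- stats::rnorm(20)
  r_xy <- stats::cor(rank(a), rank(b))
  r_xz <- stats::cor(rank(a), rank(c))
  r_yz <- stats::cor(rank(b), rank(c))
  expect_equal(spearman_partial(a, b, c),
               (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)))
})

test_that("fisher exact matches hypergeometric enumeration", {
  r <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)
  expect_identical(r$odds_ratio, Inf)

  r2 <- fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2, 2))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)

  r3 <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(r3$p, fisher_enum_p(3, 1, 1, 3), tolerance = 1e-9)
  expect_equal(r3$p, 0.4857, tolerance = 1e-4)

  set.seed(10)
  for (rep in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    expect_equal(fisher_exact_2x2(cnt)$p,
                 fisher_enum_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)), "non-negative")
})

test_that("chi-squared proportion comparison reproduces printed counts", {
  eq <- chi2_proportions(10, 20, 15, 30, n_boot = 99, seed = 1)
  expect_equal(eq$x2, 0)
  expect_equal(eq$p, 1)

  # study sex composition: 22 F / 40 controls vs 18 F / 48 stroke
  sex <- chi2_proportions(22, 40, 18, 48, n_boot = 999, seed = 2)
  expect_equal(sex$diff, 0.175)
  expect_equal(sex$p, 0.101, tolerance = 0.005)

  ext <- chi2_proportions(25, 25, 0, 30, n_boot = 99, seed = 3)
  expect_equal(ext$diff, 1)
  expect_lt(ext$p, 0.001)
  expect_error(chi2_proportions(1, 0, 1, 2), "positive")
})

test_that("holm correction matches hand-computed step-down", {
  expect_equal(holm_correct(0.04)$p_adjusted, 0.04)
  h <- holm_correct(c(0.01, 0.04, 0.03))
  expect_equal(h$p_adjusted, c(0.03, 0.06, 0.06))
  expect_identical(h$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_correct(rep(1, 4))$p_adjusted, rep(1, 4))
  expect_false(any(holm_correct(rep(1, 4))$reject))
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")

  # adjusted >= raw and order-preserving
  set.seed(11)
  for (rep in 1:10) {
    p <- stats::runif(sample(3:12, 1))
    adj <- holm_correct(p)$p_adjusted
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})
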