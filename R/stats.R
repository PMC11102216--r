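#' Bootstrap test for a difference in group means
#'
#' Nonparametric bootstrap of `mean(x) - mean(y)`: each group is resampled
#' with replacement `n_boot` times; the confidence interval is the 2.5/97.5
#' percentile interval of the resampled differences, and the p-value is
#' the percentile-of-zero with the +1 continuity correction (so the
#' smallest attainable two-tailed p is 2 / (n_boot + 1)). One-tailed tests
#' give the probability mass on the side of zero opposite the stated
#' alternative.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param tails 1 or 2.
#' @param alternative For one-tailed tests: `"greater"` (mean(x) >
#'   mean(y)) or `"less"`.
#' @param n_boot Number of resamples, default 99999.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval, default 0.95.
#' @return List of class `"bootstrap_result"`: `estimate`, `ci_lo`,
#'   `ci_hi`, `p`, `n_boot`, `tails`, `seed`.
#' @export
bootstrap_mean_diff <- function(x, y, tails = 2L,
                                alternative = c("greater", "less"),
                                n_boot = 99999L, seed = 1L, conf = 0.95) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  stopifnot(tails %in% c(1L, 2L))
  alternative <- match.arg(alternative)
  est <- mean(x) - mean(y)
  diffs <- with_seed(seed, {
    bx <- matrix(sample(x, length(x) * n_boot, replace = TRUE), ncol = n_boot)
    by <- matrix(sample(y, length(y) * n_boot, replace = TRUE), ncol = n_boot)
    colMeans(bx) - colMeans(by)
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  p_le <- (sum(diffs <= 0) + 1) / (n_boot + 1)
  p_ge <- (sum(diffs >= 0) + 1) / (n_boot + 1)
  p <- if (tails == 2L) {
    min(2 * min(p_le, p_ge), 1)
  } else if (alternative == "greater") p_le else p_ge
  structure(list(estimate = est, ci_lo = min(ci[1], est),
                 ci_hi = max(ci[2], est), p = p,
                 n_boot = n_boot, tails = tails, seed = seed),
            class = "bootstrap_result")
}

#' Spearman correlation with bootstrap confidence interval
#'
#' Rank correlation on midranks (tie-corrected), p-value by the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom, and a percentile bootstrap CI over paired
#' resamples.
#'
#' @param x,y Paired numeric samples, n >= 4, neither constant.
#' @param n_boot Bootstrap resamples for the CI, default 99999.
#' @param seed Integer seed.
#' @param conf Confidence level, default 0.95.
#' @return List: `rho`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
spearman <- function(x, y, n_boot = 99999L, seed = 1L, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need n >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) == 0 || stats::sd(yb) == 0) return(NA_real_)
      stats::cor(xb, yb, method = "spearman")
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(rho = rho, ci_lo = ci[1], ci_hi = ci[2], p = p, n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y and the covariate z, then applies the first-order
#' partial correlation formula
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` to the rank
#' (Pearson) correlations.
#'
#' @param x,y Paired samples.
#' @param z Covariate to partial out.
#' @return Partial Spearman rho.
#' @export
spearman_partial <- function(x, y, z) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (length(x) < 5L) stop("need n >= 5 complete triples", call. = FALSE)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0) {
    stop("undefined correlation: constant ranks", call. = FALSE)
  }
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("degenerate covariate: |correlation with covariate| = 1",
         call. = FALSE)
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Fisher's exact test of independence for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule (sum of hypergeometric
#' probabilities of all margin-preserving tables no more likely than the
#' observed one, via [stats::fisher.test()]); the reported odds ratio is
#' the sample cross-product ratio ad/bc (infinite or zero for empty
#' cells).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or the four
#'   counts `c(a, b, c, d)` row-wise.
#' @return List: `odds_ratio`, `p`, `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2, byrow = !is.matrix(tab))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p, table = tab)
}

#' Compare two proportions (chi-squared, no continuity correction)
#'
#' Pearson chi-squared on the 2x2 table of successes/failures (df = 1,
#' without Yates correction), with a percentile-bootstrap CI on the
#' difference in proportions.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @param n_boot Bootstrap resamples for the CI, default 99999.
#' @param seed Integer seed.
#' @return List: `diff` (k1/n1 - k2/n2), `ci_lo`, `ci_hi`, `x2`, `p`.
#' @export
chi2_proportions <- function(k1, n1, k2, n2, n_boot = 99999L, seed = 1L) {
  if (n1 <= 0 || n2 <= 0) stop("group totals must be positive", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  diff <- k1 / n1 - k2 / n2
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
  if (k1 + k2 == 0 || k1 + k2 == n1 + n2) {
    x2 <- 0; p <- 1    # no variation in the pooled outcome
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    x2 <- unname(ct$statistic); p <- ct$p.value
  }
  ci <- with_seed(seed, {
    b1 <- stats::rbinom(n_boot, n1, k1 / n1) / n1
    b2 <- stats::rbinom(n_boot, n2, k2 / n2) / n2
    stats::quantile(b1 - b2, c(0.025, 0.975), names = FALSE, type = 7)
  })
  list(diff = diff, ci_lo = ci[1], ci_hi = ci[2], x2 = x2, p = p)
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjusted p-values (monotone by construction) and
#' rejection flags at level `alpha`.
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param alpha Significance level, default 0.05.
#' @return List: `p_adjusted`, `reject`.
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(pvals, method = "holm")
  list(p_adjusted = adj, reject = adj < alpha)
}
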