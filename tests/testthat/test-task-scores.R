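# synthetic normative APM-style metric table with known structure
make_norm_metrics <- function(n, seed = 100) {
  proprioadapt:::with_seed(seed, data.frame(
    ae_x = stats::rlnorm(n, log(0.01), 0.3),
    ae_y = stats::rlnorm(n, log(0.012), 0.3),
    var_x = stats::rlnorm(n, log(0.008), 0.25),
    var_y = stats::rlnorm(n, log(0.009), 0.25),
    area_xy = stats::rnorm(n, 0.95, 0.12),
    shift_x = stats::rnorm(n, 0, 0.015),
    shift_y = stats::rnorm(n, -0.01, 0.015)))
}

test_that("zeta transform hits its printed anchors", {
  expect_equal(zeta_from_probability(0), 0)
  expect_equal(zeta_from_probability(0.95), 1.959964, tolerance = 1e-6)
  expect_equal(zeta_from_probability(0.5), 0.67449, tolerance = 1e-5)
  expect_identical(impairment_cutoff(), zeta_from_probability(0.95))
  # strictly increasing
  p <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(zeta_from_probability(p)) > 0))
  expect_error(zeta_from_probability(1), "\\[0, 1\\)")
  expect_error(zeta_from_probability(-0.1), "\\[0, 1\\)")
})

test_that("RSS combines scores Pythagorean-style", {
  expect_equal(rss_score(c(3, 4)), 5)
  expect_equal(rss_score(rep(0, 7)), 0)
  expect_equal(rss_score(rep(1, 4)), 2)
  expect_error(rss_score(numeric(0)), "no scores")
})

test_that("profile-ML Box-Cox exponent matches the MASS grid oracle", {
  skip_if_not_installed("MASS")
  set.seed(5)
  for (lam_true in c(0, 0.3, 1.5)) {
    z <- stats::rnorm(500, 2, 0.3)
    y <- if (lam_true == 0) exp(z) else (1 + lam_true * z)^(1 / lam_true)
    lam_hat <- proprioadapt:::boxcox_lambda(y)
    bc <- MASS::boxcox(y ~ 1, data = data.frame(y = y),
                       lambda = seq(-4, 4, 0.005), plotit = FALSE)
    lam_oracle <- bc$x[which.max(bc$y)]
    expect_equal(lam_hat, lam_oracle, tolerance = 0.01)
  }
})

test_that("normative model fitting guards degenerate input and is deterministic", {
  const <- make_norm_metrics(60)
  const[] <- lapply(const, function(v) rep(v[1], length(v)))
  expect_error(fit_normative_model(const, apm_score_variables()), "zero SD")

  nm <- make_norm_metrics(60)
  expect_error(fit_normative_model(nm[1:20, ], apm_score_variables()),
               "too small")
  expect_error(fit_normative_model(nm[-1], apm_score_variables()),
               "unknown variable")

  m1 <- fit_normative_model(nm, apm_score_variables())
  m2 <- fit_normative_model(nm, apm_score_variables())
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$rss_mean, m2$rss_mean)
})

test_that("renormalized RSS z-scores are close to normal on a large cohort", {
  nm <- make_norm_metrics(200, seed = 42)
  model <- fit_normative_model(nm, apm_score_variables())
  z <- vapply(seq_len(nrow(nm)), function(i) {
    rss <- proprioadapt:::rss_score(variable_scores(nm[i, ], model))
    (proprioadapt:::boxcox_transform(rss, model$lambda) - model$rss_mean) /
      model$rss_sd
  }, numeric(1))
  sk <- mean((z - mean(z))^3) / stats::sd(z)^3
  expect_lt(abs(sk), 0.5)
})

test_that("variable scores follow the z / zeta split", {
  nm <- make_norm_metrics(2000, seed = 9)
  model <- fit_normative_model(nm, apm_score_variables())
  at_mean <- nm[1, ]
  for (v in names(nm)) at_mean[[v]] <- model$mean[v]
  sc <- variable_scores(at_mean, model)
  expect_equal(sc[["area_xy"]], 0)
  expect_equal(sc[["shift_x"]], 0)
  # one-sided variable at the mean maps to zeta(0.5)
  expect_equal(sc[["ae_x"]], zeta_from_probability(0.5), tolerance = 1e-12)

  # one-sided value at the empirical normative 95th percentile -> ~1.96
  at_q <- at_mean
  at_q$ae_x <- stats::quantile(nm$ae_x, 0.95, names = FALSE)
  z <- (at_q$ae_x - model$mean["ae_x"]) / model$sd["ae_x"]
  sc_q <- variable_scores(at_q, model)
  expect_equal(sc_q[["ae_x"]],
               unname(zeta_from_probability(stats::pnorm(z))),
               tolerance = 1e-12)

  # below the normative mean: bounded by zeta(0.5)
  at_lo <- at_mean
  at_lo$var_x <- model$mean["var_x"] - model$sd["var_x"]
  expect_lt(variable_scores(at_lo, model)[["var_x"]], 0.675)

  expect_error(variable_scores(at_mean[-1], model), "unknown variable")
})

test_that("task score is monotone in one-sided variables and flags extremes", {
  nm <- make_norm_metrics(120, seed = 3)
  model <- fit_normative_model(nm, apm_score_variables())

  base <- as.list(nm[5, ])
  vals <- seq(0.5, 6, length.out = 12)
  scores <- vapply(vals, function(k) {
    m <- base
    m$ae_x <- model$mean["ae_x"] + k * model$sd["ae_x"]
    task_score(m, model)$value
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))

  extreme <- base
  extreme$ae_x <- model$mean["ae_x"] + 10 * model$sd["ae_x"]
  expect_true(task_score(extreme, model)$impaired)
  expect_true(is.finite(task_score(extreme, model)$value))

  central <- as.list(stats::setNames(model$mean, names(model$mean)))
  expect_lt(task_score(central, model)$value, impairment_cutoff())

  # deterministic scoring
  expect_identical(task_score(base, model)$value,
                   task_score(base, model)$value)
})

test_that("normative-drawn participants are flagged at about the 5% rate", {
  nm <- make_norm_metrics(400, seed = 77)
  model <- fit_normative_model(nm, apm_score_variables())
  fresh <- make_norm_metrics(1000, seed = 78)
  flags <- vapply(seq_len(nrow(fresh)), function(i) {
    task_score(fresh[i, ], model)$impaired
  }, logical(1))
  expect_gte(mean(!flags), 0.92)
  expect_lte(mean(!flags), 0.98)
})

test_that("covariate-adjusted models score against demographic residuals", {
  set.seed(12)
  n <- 150
  cov <- data.frame(age = stats::runif(n, 20, 90),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    handedness = sample(c("R", "L"), n, replace = TRUE,
                                        prob = c(0.9, 0.1)))
  nm <- make_norm_metrics(n, seed = 13)
  nm$ae_x <- nm$ae_x + 0.0004 * cov$age     # strong age effect
  plain <- fit_normative_model(nm, apm_score_variables())
  adj <- fit_normative_model(nm, apm_score_variables(), covariates = cov)
  # an old but age-typical participant: adjusted score must not inflate
  old <- as.list(vapply(nm, mean, numeric(1)))
  old$ae_x <- mean(nm$ae_x) + 0.0004 * (85 - mean(cov$age))
  old_cov <- data.frame(age = 85, sex = "F", handedness = "R")
  z_adj <- variable_scores(old, adj, covariates = old_cov)[["ae_x"]]
  z_plain <- variable_scores(old, plain)[["ae_x"]]
  expect_lt(z_adj, z_plain)
  expect_error(variable_scores(old, adj), "covariate")
})

test_that("normative model JSON round-trip preserves scoring", {
  nm <- make_norm_metrics(80, seed = 21)
  model <- fit_normative_model(nm, apm_score_variables())
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_normative_model(model, path)
  back <- read_normative_model(path)
  expect_equal(task_score(nm[3, ], back)$value,
               task_score(nm[3, ], model)$value, tolerance = 1e-12)
})
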