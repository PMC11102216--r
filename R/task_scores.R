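#' One-sided zeta transform of a cumulative probability
#'
#' Maps a one-sided cumulative probability p onto the positive half of the
#' standard normal scale: `zeta(p) = qnorm((1 + p) / 2)`. The best possible
#' score is 0 (p = 0) and the 95th percentile maps to 1.96, so a score
#' above 1.96 lies outside 95% of the normative range.
#'
#' @param p Cumulative probability in [0, 1).
#' @return Zeta score (>= 0), vectorised over `p`.
#' @export
zeta_from_probability <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  stats::qnorm((1 + p) / 2)
}

#' Impairment cutoff on the zeta scale
#'
#' The task-score threshold: scores above this value are outside 95% of
#' the normative range and flag impairment. Exposed as a function so the
#' cutoff and the zeta transform cannot drift apart.
#'
#' @return `zeta_from_probability(0.95)` (about 1.96).
#' @export
impairment_cutoff <- function() zeta_from_probability(0.95)

# default variable sets for the two matching tasks: variables decomposed
# into x/y where applicable; one-sided variables (higher = worse) go
# through the zeta transform, two-sided variables stay as z-scores
apm_score_variables <- function() {
  list(one_sided = c("ae_x", "ae_y", "var_x", "var_y"),
       two_sided = c("area_xy", "shift_x", "shift_y"))
}

amm_score_variables <- function(include_failed = FALSE) {
  one <- c("rl", "ide")
  if (include_failed) one <- c(one, "n_failed")
  list(one_sided = one, two_sided = c("psr", "plr"))
}

# design matrix for demographic adjustment: intercept, age, sex M,
# handedness R (fixed coding so fit and prediction agree)
covariate_design <- function(covariates) {
  cbind(1, as.numeric(covariates$age),
        as.numeric(covariates$sex == "M"),
        as.numeric(covariates$handedness == "R"))
}

# profile maximum-likelihood Box-Cox exponent for positive data,
# one-parameter shift-free form
boxcox_lambda <- function(y, interval = c(-5, 5)) {
  if (any(y <= 0)) {
    stop("degenerate normative data: Box-Cox needs positive values",
         call. = FALSE)
  }
  n <- length(y)
  logy <- sum(log(y))
  profile_ll <- function(lambda) {
    z <- boxcox_transform(y, lambda)
    -n / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * logy
  }
  stats::optimize(profile_ll, interval, maximum = TRUE, tol = 1e-7)$maximum
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' Fit a normative scoring model
#'
#' The reference half of the task-score chain: per-variable normative
#' means and SDs, plus the Box-Cox renormalization of the root-sum-square
#' (RSS) stage. Each normative participant's variable scores (z for
#' two-sided, zeta for one-sided variables) are combined by RSS; a
#' one-parameter Box-Cox exponent is fitted to the positive RSS values by
#' profile maximum likelihood, and the post-transform mean and SD are
#' stored so new RSS values can be renormalized to z-scores.
#'
#' @param normative_metrics Data frame of normative-cohort metrics, one
#'   row per participant, containing every scored variable.
#' @param variables List with character elements `one_sided` (higher =
#'   worse, zeta-scored) and `two_sided` (z-scored), e.g.
#'   `apm_score_variables()`.
#' @param min_n Minimum normative cohort size, default 40.
#' @param covariates Optional data frame (columns `age`, `sex`,
#'   `handedness`, rows aligned with `normative_metrics`). When supplied,
#'   each variable is adjusted by a linear model
#'   `value ~ age + sex + handedness` and z-scores are taken from the
#'   residual distribution, emulating demographic adjustment against a
#'   normative database. Off (`NULL`) by default.
#' @return A list of class `"normative_model"`.
#' @export
fit_normative_model <- function(normative_metrics, variables, min_n = 40L,
                                covariates = NULL) {
  vars <- c(variables$one_sided, variables$two_sided)
  missing_vars <- setdiff(vars, names(normative_metrics))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  x <- normative_metrics[vars]
  if (nrow(x) < min_n) {
    stop(sprintf("normative cohort too small: %d < %d", nrow(x), min_n),
         call. = FALSE)
  }
  if (!all(vapply(x, function(v) all(is.finite(v)), logical(1)))) {
    stop("normative metrics must be finite", call. = FALSE)
  }
  adjust <- NULL
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(x),
              all(c("age", "sex", "handedness") %in% names(covariates)))
    mm <- covariate_design(covariates)
    adjust <- lapply(x, function(v) stats::lm.fit(mm, v)$coefficients)
    resid <- vapply(vars, function(v) {
      x[[v]] - drop(mm %*% adjust[[v]])
    }, numeric(nrow(x)))
    mu <- rep(0, length(vars)); names(mu) <- vars
    sdv <- apply(resid, 2, stats::sd)
    x[vars] <- as.data.frame(resid)
  } else {
    mu <- vapply(x, mean, numeric(1))
    sdv <- vapply(x, stats::sd, numeric(1))
  }
  if (any(sdv <= 0)) {
    stop("degenerate normative data: zero SD for ",
         paste(vars[sdv <= 0], collapse = ", "), call. = FALSE)
  }
  model <- structure(list(
    variables = variables, mean = mu, sd = sdv, adjust = adjust,
    lambda = NA_real_, rss_mean = NA_real_, rss_sd = NA_real_,
    n = nrow(x)
  ), class = "normative_model")
  model_resid <- model
  model_resid$adjust <- NULL   # x already holds residuals when adjusting
  rss <- vapply(seq_len(nrow(x)), function(i) {
    rss_score(variable_scores(x[i, ], model_resid))
  }, numeric(1))
  if (any(rss <= 0)) {
    stop("degenerate normative data: non-positive RSS", call. = FALSE)
  }
  model$lambda <- boxcox_lambda(rss)
  bc <- boxcox_transform(rss, model$lambda)
  model$rss_mean <- mean(bc)
  model$rss_sd <- stats::sd(bc)
  if (model$rss_sd <= 0) {
    stop("degenerate normative data: zero RSS spread", call. = FALSE)
  }
  model
}

#' Per-variable normative scores
#'
#' Two-sided variables are standard z-scores against the normative mean
#' and SD. One-sided variables (where only high values are abnormal) are
#' z-scored, mapped to a cumulative probability p = pnorm(z), and
#' converted to zeta scores so the best attainable score is 0.
#'
#' @param metrics One participant's metrics (list or one-row data frame).
#' @param model A fitted [fit_normative_model()].
#' @param covariates One-row data frame with `age`, `sex`, `handedness`;
#'   required if (and only if) the model was fitted with covariate
#'   adjustment.
#' @return Named numeric vector of scores, one per model variable.
#' @export
variable_scores <- function(metrics, model, covariates = NULL) {
  vars <- c(model$variables$one_sided, model$variables$two_sided)
  missing_vars <- setdiff(vars, names(metrics))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(vars, function(v) as.numeric(metrics[[v]]), numeric(1))
  if (!is.null(model$adjust)) {
    if (is.null(covariates)) {
      stop("model was fitted with covariate adjustment; supply covariates",
           call. = FALSE)
    }
    mm <- covariate_design(covariates)
    vals <- vals - vapply(vars, function(v) {
      drop(mm %*% model$adjust[[v]])
    }, numeric(1))
  }
  z <- (vals - model$mean[vars]) / model$sd[vars]
  one <- vars %in% model$variables$one_sided
  z[one] <- zeta_from_probability(pmin(stats::pnorm(z[one]), 1 - 1e-12))
  z
}

#' Root-sum-square of variable scores
#' @param scores Numeric vector of z/zeta variable scores (non-empty).
#' @return `sqrt(sum(scores^2))`.
#' @export
rss_score <- function(scores) {
  if (length(scores) < 1L) stop("no scores", call. = FALSE)
  sqrt(sum(scores^2))
}

#' Global task score with impairment flag
#'
#' The full scoring chain for one participant: variable z/zeta scores,
#' RSS, Box-Cox renormalization to a z-score using the stored normative
#' moments, conversion of the cumulative probability to a final zeta
#' score, and the 1.96 impairment cutoff. The probability is clipped just
#' below 1 so extreme participants get large finite scores.
#'
#' @param metrics One participant's metrics (list or one-row data frame).
#' @param model A fitted [fit_normative_model()].
#' @param covariates Passed to [variable_scores()] for covariate-adjusted
#'   models.
#' @return A list of class `"task_score"`: `value` (zeta units, >= 0),
#'   `impaired` (`value > 1.96`), and the intermediate `rss`.
#' @export
task_score <- function(metrics, model, covariates = NULL) {
  if (!is.finite(model$lambda)) stop("model not fitted", call. = FALSE)
  rss <- rss_score(variable_scores(metrics, model, covariates))
  z <- (boxcox_transform(rss, model$lambda) - model$rss_mean) / model$rss_sd
  p <- min(max(stats::pnorm(z), 0), 1 - 1e-12)
  value <- zeta_from_probability(p)
  structure(list(value = value, impaired = value > impairment_cutoff(),
                 rss = rss), class = "task_score")
}

#' Serialize / restore a normative model
#'
#' @param model A [fit_normative_model()] result.
#' @param path JSON file path.
#' @return `write_normative_model` returns `path` invisibly;
#'   `read_normative_model` returns the restored model.
#' @export
write_normative_model <- function(model, path) {
  obj <- list(variables = model$variables,
              mean = as.list(model$mean), sd = as.list(model$sd),
              lambda = model$lambda, rss_mean = model$rss_mean,
              rss_sd = model$rss_sd, n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    variables = lapply(obj$variables, as.character),
    mean = unlist(obj$mean), sd = unlist(obj$sd),
    lambda = obj$lambda, rss_mean = obj$rss_mean, rss_sd = obj$rss_sd,
    n = obj$n
  ), class = "normative_model")
}
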