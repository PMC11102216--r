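# truncated-normal draw by rejection (vectors of length 1)
rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
}

#' Default prevalence / effect-size configuration for stroke simulation
#'
#' Controls the mixture structure of the simulated stroke group:
#' probabilities of proprioceptive and adaptation impairment, their
#' dependence (a Gaussian-copula correlation; 0 = the two impairments are
#' assigned independently), and the shift of baseline direction
#' variability in the adaptation-impaired component relative to controls.
#'
#' @param p_proprioception Probability a stroke participant carries the
#'   proprioception-impaired parameter set, default 0.58.
#' @param p_adaptation Probability of the adaptation-impaired parameter
#'   set, default 0.52.
#' @param impairment_correlation Copula correlation between the two
#'   impairment assignments, default 0 (independent).
#' @param baseline_sd_shift Added baseline direction SD (deg) of the
#'   stroke group relative to controls (a group-level elevation of
#'   execution noise), default 3.27.
#' @return A named list.
#' @export
prevalence_config <- function(p_proprioception = 0.58,
                              p_adaptation = 0.52,
                              impairment_correlation = 0,
                              baseline_sd_shift = 3.27) {
  stopifnot(p_proprioception >= 0, p_proprioception <= 1,
            p_adaptation >= 0, p_adaptation <= 1,
            impairment_correlation >= -1, impairment_correlation <= 1)
  list(p_proprioception = p_proprioception, p_adaptation = p_adaptation,
       impairment_correlation = impairment_correlation,
       baseline_sd_shift = baseline_sd_shift)
}

# healthy hyper-distribution: one draw of control-like behavioural params.
# The learner is parametrized by its adaptation asymptote (most healthy
# adults compensate 24.5-30 deg; a small weak-adapter tail reaches lower)
# and learning rate; retention follows from asymptote = 30 b / (1 - a + b).
draw_control_params <- function() {
  asym <- if (stats::runif(1) < 0.05) {
    stats::runif(1, 16, 24)
  } else {
    rtruncnorm1(27.5, 1.5, 24.5, 29.9)
  }
  b <- min(max(stats::rlnorm(1, log(0.18), 0.40), 0.05), 0.80)
  a <- max(1 - b * (30 / asym - 1), 0.5)
  list(
    apm_noise_sd = stats::rlnorm(1, log(0.009), 0.25),
    apm_contraction = rtruncnorm1(0.97, 0.06, 0.70, 1.30),
    apm_shift = c(stats::rnorm(1, 0, 0.012), stats::rnorm(1, -0.005, 0.012)),
    amm_latency = rtruncnorm1(0.15, 0.04, 0.05, 0.40),
    amm_speed_ratio = rtruncnorm1(1.00, 0.10, 0.50, 1.60),
    amm_dir_error_sd = stats::rlnorm(1, log(4), 0.3),
    amm_path_ratio = rtruncnorm1(1.00, 0.08, 0.50, 1.60),
    learner_retention = a,
    learner_rate = b,
    baseline_dir_sd = rtruncnorm1(2.0, 0.4, 1.0, 3.5)
  )
}

# stroke proprioception-impaired overrides applied on top of control draws
draw_proprio_impaired <- function(p) {
  p$apm_noise_sd <- p$apm_noise_sd * stats::runif(1, 2, 5)
  p$apm_contraction <- rtruncnorm1(0.80, 0.12, 0.40, 1.40)
  p$apm_shift <- c(stats::rnorm(1, 0, 0.025), stats::rnorm(1, -0.02, 0.025))
  p$amm_latency <- p$amm_latency + stats::runif(1, 0.10, 0.35)
  p$amm_speed_ratio <- rtruncnorm1(0.80, 0.20, 0.30, 1.60)
  p$amm_dir_error_sd <- p$amm_dir_error_sd * stats::runif(1, 2, 4)
  p$amm_path_ratio <- rtruncnorm1(1.15, 0.25, 0.30, 2.00)
  p
}

# stroke adaptation-impaired overrides: slow/non-learner
draw_adaptation_impaired <- function(p) {
  p$learner_rate <- stats::runif(1, 0, 0.02)
  p
}

# ordinal TLT from the proprioceptive-noise latent via a monotone link
tlt_from_noise <- function(apm_noise_sd, jitter_sd = 0.15) {
  latent <- log(apm_noise_sd / 0.009) + stats::rnorm(1, 0, jitter_sd)
  as.integer(cut(latent, c(-Inf, 0.45, 0.85, 1.25, Inf), labels = FALSE)) - 1L
}

#' Generate a synthetic assessment cohort
#'
#' Draws control and stroke participants from the generative
#' hyper-distributions, then simulates every task for every participant.
#' Controls are drawn from a single healthy distribution. Stroke
#' participants are a mixture: with probability `prevalence$p_proprioception`
#' they receive the proprioception-impaired parameter set (larger matching
#' noise, contracted and shifted workspace, longer latency, poorer
#' speed/direction/length matching) and with probability
#' `prevalence$p_adaptation` the adaptation-impaired set (learning rate
#' near zero, noisier baseline directions); the two assignments are
#' sampled independently unless `impairment_correlation` is nonzero.
#' Everything is deterministic under `seed` (participant-level RNG streams
#' are fanned out from it, so cohorts of different sizes share their
#' leading participants).
#'
#' @param n_stroke,n_control Group sizes; defaults 48 and 40.
#' @param prevalence A [prevalence_config()].
#' @param spec A [protocol_spec()].
#' @param seed Integer master seed.
#' @param tasks Character subset of `c("apm", "amm", "vmr")` to simulate.
#' @param group_label Optional label overriding the control group name
#'   (used to mark synthetic normative cohorts).
#' @return A list of class `"pa_cohort"`: `participants` (data frame of
#'   metadata + true generative parameters), `data` (per-participant task
#'   data from [simulate_participant()]), `spec`, `seed`.
#' @export
generate_cohort <- function(n_stroke = 48L, n_control = 40L,
                            prevalence = prevalence_config(),
                            spec = protocol_spec(), seed = 1L,
                            tasks = c("apm", "amm", "vmr"),
                            group_label = "control") {
  stopifnot(n_stroke >= 0L, n_control >= 0L, n_stroke + n_control > 0L)
  groups <- c(rep("control", n_control), rep("stroke", n_stroke))
  n <- length(groups)
  params_list <- vector("list", n)
  rho <- prevalence$impairment_correlation
  for (i in seq_len(n)) {
    params_list[[i]] <- with_seed(derive_seed(seed, i), {
      g <- groups[i]
      if (g == "control") {
        p <- draw_control_params()
        age <- round(rtruncnorm1(62, 10, 40, 80))
        sex <- if (stats::runif(1) < 0.55) "F" else "M"
        hand <- if (stats::runif(1) < 0.85) "R" else "L"
        tlt <- 0L
        prop_imp <- FALSE; adapt_imp <- FALSE
      } else {
        p <- draw_control_params()
        z1 <- stats::rnorm(1)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
        prop_imp <- z1 < stats::qnorm(prevalence$p_proprioception)
        adapt_imp <- z2 < stats::qnorm(prevalence$p_adaptation)
        # elevated execution noise is a group-level stroke effect: the
        # baseline-SD shift applies to every stroke participant
        p$baseline_dir_sd <- p$baseline_dir_sd + prevalence$baseline_sd_shift
        if (prop_imp) p <- draw_proprio_impaired(p)
        if (adapt_imp) p <- draw_adaptation_impaired(p)
        age <- round(rtruncnorm1(63, 14, 27, 88))
        sex <- if (stats::runif(1) < 0.38) "F" else "M"
        hand <- if (stats::runif(1) < 0.94) "R" else "L"
        tlt <- tlt_from_noise(p$apm_noise_sd)
      }
      pp <- participant_params(
        group = g, age = age, sex = sex, handedness = hand,
        apm_noise_sd = p$apm_noise_sd, apm_contraction = p$apm_contraction,
        apm_shift = p$apm_shift, amm_latency = p$amm_latency,
        amm_speed_ratio = p$amm_speed_ratio,
        amm_dir_error_sd = p$amm_dir_error_sd,
        amm_path_ratio = p$amm_path_ratio,
        learner_retention = p$learner_retention,
        learner_rate = p$learner_rate,
        baseline_dir_sd = p$baseline_dir_sd, tlt = tlt,
        rng_seed = derive_seed(seed, n + i),
        id = sprintf("%s%03d", if (g == "control") "C" else "S", i)
      )
      pp$prop_impaired_true <- prop_imp
      pp$adapt_impaired_true <- adapt_imp
      pp
    })
  }
  participants <- do.call(rbind, lapply(params_list, function(pp) {
    data.frame(id = pp$id,
               group = if (pp$group == "control") group_label else pp$group,
               age = pp$age, sex = pp$sex,
               handedness = pp$handedness, tlt = pp$tlt,
               apm_noise_sd = pp$apm_noise_sd,
               apm_contraction = pp$apm_contraction,
               apm_shift_x = pp$apm_shift[1], apm_shift_y = pp$apm_shift[2],
               amm_latency = pp$amm_latency,
               amm_speed_ratio = pp$amm_speed_ratio,
               amm_dir_error_sd = pp$amm_dir_error_sd,
               amm_path_ratio = pp$amm_path_ratio,
               learner_retention = pp$learner_retention,
               learner_rate = pp$learner_rate,
               baseline_dir_sd = pp$baseline_dir_sd,
               prop_impaired_true = pp$prop_impaired_true,
               adapt_impaired_true = pp$adapt_impaired_true,
               rng_seed = pp$rng_seed)
  }))
  data <- lapply(params_list, simulate_participant, spec = spec, tasks = tasks)
  names(data) <- participants$id
  structure(list(participants = participants, data = data, spec = spec,
                 seed = seed, params = params_list),
            class = "pa_cohort")
}
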