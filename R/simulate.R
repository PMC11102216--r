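#' Simulate arm position-matching responses
#'
#' Generative model for APM matching: the active hand's matched position is
#' the mirrored target, contracted about the centroid of the mirrored
#' targets, translated by a systematic shift, plus isotropic Gaussian
#' matching noise:
#' `matched_i = C + contraction * (mirror(target_i) - C) + shift + eps_i`.
#' This structure makes the downstream Area (contraction^2), Shift and
#' Var/AE metrics identifiable.
#'
#' @param targets n x 2 matrix of passive-arm target positions (m),
#'   typically 54 rows from the 6-block APM protocol.
#' @param params A [participant_params()].
#' @param midline_x Participant midline (m), default 0.
#' @return n x 2 matrix of matched positions in the active arm's frame.
#' @export
simulate_apm_matching <- function(targets, params, midline_x = 0) {
  targets <- as.matrix(targets)
  m <- mirror_x(targets, midline_x)
  ctr <- colMeans(m)
  n <- nrow(m)
  eps <- matrix(stats::rnorm(2 * n, 0, params$apm_noise_sd), ncol = 2)
  sweep(params$apm_contraction * sweep(m, 2, ctr), 2, -ctr) +
    matrix(params$apm_shift, n, 2, byrow = TRUE) + eps
}

# fraction of movement duration at which a minimum-jerk speed profile
# crosses 12.5% of its peak (root of 16 tau^2 (1-tau)^2 = 1/8)
.mj_onset_tau <- (1 - sqrt(1 - 4 * sqrt(1 / 128))) / 2

#' Simulate one arm movement-matching trial
#'
#' The robot moves the passive arm along a minimum-jerk reach; the
#' simulated participant mirrors it with the active arm after a response
#' latency, with peak speed scaled by `amm_speed_ratio`, movement length
#' scaled by `amm_path_ratio`, and direction perturbed by a Gaussian error
#' (SD `amm_dir_error_sd`). The active movement is timed so that its 12.5%
#' peak-speed onset trails the passive arm's by exactly the latency.
#'
#' @param from,to Passive-arm movement endpoints (m).
#' @param params A [participant_params()].
#' @param spec A [protocol_spec()] (sampling rate, passive peak speed).
#' @param midline_x Participant midline (m).
#' @return List with `passive` and `active` [trajectory()] objects (the
#'   active one in the active arm's own, un-mirrored frame).
#' @export
simulate_amm_trial <- function(from, to, params, spec = protocol_spec(),
                               midline_x = 0) {
  d <- sqrt(sum((to - from)^2))
  dur_p <- min_jerk_duration(d, spec$passive_peak_speed_amm)
  lead <- 0.25
  passive <- min_jerk_trajectory(from, to, dur_p, spec$sample_rate,
                                 lead_in = lead, lead_out = 0.15)
  # active geometry: mirrored start, mirrored direction + angular error
  m_from <- mirror_x(from, midline_x)
  theta_p <- atan2(to[2] - from[2], to[1] - from[1])
  theta_m <- pi - theta_p                       # mirrored direction
  delta <- stats::rnorm(1, 0, params$amm_dir_error_sd) * pi / 180
  theta_a <- theta_m + delta
  d_a <- params$amm_path_ratio * d
  peak_a <- params$amm_speed_ratio * spec$passive_peak_speed_amm
  dur_a <- min_jerk_duration(d_a, peak_a)
  # align detected onsets: both arms cross 12.5% of peak at a fixed
  # fraction of movement duration
  onset_p <- lead + .mj_onset_tau * dur_p
  start_a <- onset_p + params$amm_latency - .mj_onset_tau * dur_a
  if (start_a < 0) start_a <- 0
  to_a <- m_from + d_a * c(cos(theta_a), sin(theta_a))
  active <- min_jerk_trajectory(m_from, to_a, dur_a, spec$sample_rate,
                                lead_in = start_a, lead_out = 0.15)
  list(passive = passive, active = active)
}

#' Simulate a visuomotor rotation session
#'
#' Trial-by-trial state-space learner: internal compensation
#' `x_{t+1} = a x_t + b e_t` with error `e_t = r_t - x_t`, where the
#' rotation r_t is `rotation_deg` during the adaptation phase and 0 in
#' baseline and washout, and `x_0 = 0`. The observed initial reach
#' direction is `y_t = x_t + N(0, baseline_dir_sd^2)`, in the compensatory
#' sign convention (full compensation of a 30 deg CCW rotation = +30).
#'
#' @param params A [participant_params()].
#' @param spec A [protocol_spec()].
#' @return A [vmr_session()] with 175 directions and phase labels.
#' @export
simulate_vmr_session <- function(params, spec = protocol_spec()) {
  nph <- spec$vmr_trials
  n <- sum(nph)
  r <- rep(c(0, spec$rotation_deg, 0), nph)
  a <- params$learner_retention
  b <- params$learner_rate
  x <- numeric(n)
  for (t in seq_len(n - 1L)) {
    x[t + 1L] <- a * x[t] + b * (r[t] - x[t])
  }
  y <- x + stats::rnorm(n, 0, params$baseline_dir_sd)
  vmr_session(y, phases = nph, rotation_deg = spec$rotation_deg)
}

#' Simulate a single VMR reach trajectory
#'
#' Straight minimum-jerk reach of the protocol target distance whose
#' direction deviates from the start-target line by `direction_deg` in the
#' compensatory (clockwise-positive) convention. Used to exercise the
#' trajectory route of the adaptation analysis (onset detection + 150 ms
#' direction probe).
#'
#' @param direction_deg Initial direction relative to the target line
#'   (deg, compensatory positive).
#' @param spec A [protocol_spec()].
#' @param origin Start position (m).
#' @return A [trajectory()]; the target sits `spec$target_distance` ahead
#'   (+y) of `origin`.
#' @export
simulate_vmr_reach <- function(direction_deg, spec = protocol_spec(),
                               origin = c(0, 0.20)) {
  phi <- (90 - direction_deg) * pi / 180   # absolute heading
  d <- spec$target_distance
  end <- origin + d * c(cos(phi), sin(phi))
  dur <- min_jerk_duration(d, 0.35)
  min_jerk_trajectory(origin, end, dur, spec$sample_rate,
                      lead_in = 0.2, lead_out = 0.1)
}

#' Simulate all task data for one participant
#'
#' Runs the APM, AMM and VMR protocols for a single set of generative
#' parameters, deterministically under `params$rng_seed`.
#'
#' @param params A [participant_params()].
#' @param spec A [protocol_spec()].
#' @param tasks Character subset of `c("apm", "amm", "vmr")`.
#' @return List with elements `apm` (data frame: trial, target, target_x,
#'   target_y, matched_x, matched_y), `amm` (list of trials, each with
#'   `passive`/`active` trajectories), `vmr` (a [vmr_session()]), plus the
#'   per-participant passive APM peak speed used.
#' @export
simulate_participant <- function(params, spec = protocol_spec(),
                                 tasks = c("apm", "amm", "vmr")) {
  with_seed(params$rng_seed, {
    out <- list(id = params$id)
    if ("apm" %in% tasks) {
      ord <- apm_trial_order(spec)
      tg <- apm_targets(spec)[ord, , drop = FALSE]
      matched <- simulate_apm_matching(tg, params)
      out$apm <- data.frame(trial = seq_along(ord), target = ord,
                            target_x = tg[, 1], target_y = tg[, 2],
                            matched_x = matched[, 1], matched_y = matched[, 2])
      out$apm_peak_speed <- stats::runif(1, spec$apm_speed_range[1],
                                         spec$apm_speed_range[2])
    }
    if ("amm" %in% tasks) {
      moves <- amm_movement_sequence(spec)
      vt <- amm_targets(spec)
      out$amm <- lapply(seq_len(nrow(moves)), function(i) {
        simulate_amm_trial(vt[moves[i, 1], ], vt[moves[i, 2], ], params, spec)
      })
    }
    if ("vmr" %in% tasks) {
      out$vmr <- simulate_vmr_session(params, spec)
    }
    out
  })
}
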