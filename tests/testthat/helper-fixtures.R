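# noiseless participant: every generative parameter at its ideal value
# unless overridden, so downstream metrics are exactly predictable
ideal_params <- function(...) {
  defaults <- list(apm_noise_sd = 0, apm_contraction = 1,
                   apm_shift = c(0, 0), amm_latency = 0,
                   amm_speed_ratio = 1, amm_dir_error_sd = 0,
                   amm_path_ratio = 1, learner_retention = 1,
                   learner_rate = 1, baseline_dir_sd = 0, rng_seed = 1L)
  do.call(participant_params, utils::modifyList(defaults, list(...)))
}

# wrap one participant's simulated data as a minimal cohort object
as_mini_cohort <- function(...) {
  data <- list(...)
  names(data) <- vapply(data, `[[`, character(1), "id")
  structure(list(data = data), class = "pa_cohort")
}

# a VMR session with explicit per-phase directions
session_from_phases <- function(baseline, adaptation, washout = rep(0, 25)) {
  vmr_session(c(baseline, adaptation, washout),
              phases = c(length(baseline), length(adaptation),
                         length(washout)))
}

# straight uniform-speed trajectory along a given absolute heading (deg)
straight_trajectory <- function(angle_deg, speed = 0.2, duration = 1,
                                rate = 100, origin = c(0, 0)) {
  t <- seq(0, duration, by = 1 / rate)
  phi <- angle_deg * pi / 180
  trajectory(t, origin[1] + speed * t * cos(phi),
             origin[2] + speed * t * sin(phi))
}
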