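#' Generative parameters for one simulated participant
#'
#' Houses every behavioural quantity the analysis pipeline later tries to
#' recover: position-matching noise, workspace contraction and shift for
#' the APM task; response latency, speed/path ratios and direction-error
#' SD for the AMM task; and a trial-by-trial state-space learner
#' (retention `a`, learning rate `b`) plus baseline execution noise for
#' the VMR task.
#'
#' @param group `"control"` or `"stroke"`.
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param handedness `"L"` or `"R"`.
#' @param apm_noise_sd Trial-to-trial matching noise SD (m), per axis.
#' @param apm_contraction Workspace scale factor about the matched
#'   centroid (1 = veridical, < 1 = contracted); must be > 0.
#' @param apm_shift Systematic workspace translation (dx, dy) in metres.
#' @param amm_latency Response latency of the active arm (s, >= 0).
#' @param amm_speed_ratio Active/passive peak-speed ratio (> 0).
#' @param amm_dir_error_sd SD of the active arm's direction error (deg).
#' @param amm_path_ratio Active/passive movement-length ratio (> 0).
#' @param learner_retention Retention factor `a` of the state-space
#'   learner, in [0, 1].
#' @param learner_rate Error-correction rate `b`, in [0, 1].
#' @param baseline_dir_sd SD of reach-direction execution noise (deg).
#' @param tlt Thumb Localization Test score, integer 0 (normal) to 3.
#' @param rng_seed Integer seed driving this participant's task data.
#' @param id Participant identifier string.
#' @return A list of class `"participant_params"`.
#' @export
participant_params <- function(group = "control", age = 60, sex = "F",
                               handedness = "R",
                               apm_noise_sd = 0.009, apm_contraction = 1,
                               apm_shift = c(0, 0),
                               amm_latency = 0.15, amm_speed_ratio = 1,
                               amm_dir_error_sd = 4, amm_path_ratio = 1,
                               learner_retention = 0.98, learner_rate = 0.18,
                               baseline_dir_sd = 3.5, tlt = 0L,
                               rng_seed = 1L, id = "p1") {
  stopifnot(group %in% c("control", "stroke"), sex %in% c("F", "M"),
            handedness %in% c("L", "R"))
  if (learner_retention < 0 || learner_retention > 1 ||
      learner_rate < 0 || learner_rate > 1) {
    stop("learner_retention and learner_rate must lie in [0, 1]", call. = FALSE)
  }
  if (apm_noise_sd < 0 || amm_dir_error_sd < 0 || baseline_dir_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (apm_contraction <= 0) stop("apm_contraction must be > 0", call. = FALSE)
  if (amm_latency < 0) stop("amm_latency must be >= 0", call. = FALSE)
  if (!(tlt %in% 0:3)) stop("tlt must be an integer in 0..3", call. = FALSE)
  structure(list(
    id = id, group = group, age = age, sex = sex, handedness = handedness,
    apm_noise_sd = apm_noise_sd, apm_contraction = apm_contraction,
    apm_shift = apm_shift, amm_latency = amm_latency,
    amm_speed_ratio = amm_speed_ratio, amm_dir_error_sd = amm_dir_error_sd,
    amm_path_ratio = amm_path_ratio, learner_retention = learner_retention,
    learner_rate = learner_rate, baseline_dir_sd = baseline_dir_sd,
    tlt = as.integer(tlt), rng_seed = as.integer(rng_seed)
  ), class = "participant_params")
}

# deterministic seed fan-out: stream `k` derived from a master seed via a
# fixed affine map mod a Mersenne prime, so adding analyses never shifts
# earlier streams; result always a valid positive 32-bit integer seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 16807) %% 2147483629 + 1)
}

# evaluate `expr` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
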