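#' Visuomotor rotation session
#'
#' Container for one participant's VMR session: the initial reach
#' direction of every trial (degrees, compensatory sign convention) with
#' the baseline / adaptation / washout phase partition.
#'
#' @param directions Numeric vector of signed initial reach directions
#'   (deg), one per trial, in trial order.
#' @param phases Integer triple of phase lengths (baseline, adaptation,
#'   washout); default c(25, 125, 25).
#' @param rotation_deg Imposed cursor rotation (deg CCW), default 30.
#' @return A list of class `"vmr_session"`.
#' @export
vmr_session <- function(directions, phases = c(25L, 125L, 25L),
                        rotation_deg = 30) {
  phases <- as.integer(phases)
  if (length(phases) != 3L || any(phases <= 0L)) {
    stop("phases must be three positive trial counts", call. = FALSE)
  }
  if (length(directions) != sum(phases)) {
    stop(sprintf("expected %d trial directions, got %d",
                 sum(phases), length(directions)), call. = FALSE)
  }
  if (!all(is.finite(directions))) {
    stop("directions must be finite", call. = FALSE)
  }
  structure(list(
    directions = as.numeric(directions),
    phase = rep(c("baseline", "adaptation", "washout"), phases),
    phases = phases, rotation_deg = rotation_deg
  ), class = "vmr_session")
}

# adaptation-phase directions of a session
adaptation_directions <- function(s) {
  s$directions[s$phase == "adaptation"]
}

#' Summarise a VMR session
#'
#' Baseline mean and SD over the baseline phase, Initial Adaptation (mean
#' initial reach direction of the first 15 adaptation trials) and Final
#' Adaptation (mean of the last 15 adaptation trials). Washout contents do
#' not enter any summary.
#'
#' @param s A [vmr_session()].
#' @param window Trials averaged at each end of the adaptation phase,
#'   default 15.
#' @return A list: `baseline_mean`, `baseline_sd`, `initial_adaptation`,
#'   `final_adaptation` (all degrees).
#' @export
summarize_session <- function(s, window = 15L) {
  if (!inherits(s, "vmr_session")) stop("not a vmr_session", call. = FALSE)
  if (s$phases[2] < window) {
    stop("adaptation phase shorter than the summary window", call. = FALSE)
  }
  base <- s$directions[s$phase == "baseline"]
  ad <- adaptation_directions(s)
  n <- length(ad)
  list(baseline_mean = mean(base),
       baseline_sd = stats::sd(base),
       initial_adaptation = mean(ad[seq_len(window)]),
       final_adaptation = mean(ad[(n - window + 1L):n]))
}

#' Empirical 95% normative range of a control measure
#'
#' The range containing 95% of the control data, taken as the empirical
#' 2.5th and 97.5th percentiles with the linear-interpolation quantile
#' definition (R type 7).
#'
#' @param values Numeric control values (>= 20 required).
#' @param coverage Central coverage, default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @export
control_range <- function(values, coverage = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 20L) {
    stop("insufficient normative data: need >= 20 control values", call. = FALSE)
  }
  alpha <- (1 - coverage) / 2
  q <- stats::quantile(values, c(alpha, 1 - alpha), names = FALSE, type = 7)
  if (q[1] >= q[2]) {
    warning("degenerate control range: lower bound >= upper bound")
  }
  q
}

#' Trials to Adapt
#'
#' The first adaptation trial beginning a run of 15 consecutive trials
#' whose initial directions all strictly exceed the control-derived
#' threshold; the run must fit within the adaptation phase (latest
#' admissible start = 111 of 125). Failure to adapt scores 125, the number
#' of adaptation trials.
#'
#' @param s A [vmr_session()].
#' @param threshold Direction threshold (deg), normally the lower bound of
#'   the control range for Final Adaptation.
#' @param run_length Required consecutive trials, default 15.
#' @return Integer trial index in 1..125 (1-based within the adaptation
#'   phase), or the phase length when the criterion is never met.
#' @export
trials_to_adapt <- function(s, threshold, run_length = 15L) {
  ad <- adaptation_directions(s)
  n <- length(ad)
  above <- ad > threshold
  if (n >= run_length) {
    run <- 0L
    for (k in seq_len(n)) {
      run <- if (above[k]) run + 1L else 0L
      if (run == run_length) return(k - run_length + 1L)
    }
  }
  n
}

#' Normative control ranges for the adaptation measures
#'
#' Fits the empirical 95% ranges of Initial Adaptation, Final Adaptation
#' and Trials to Adapt from a control sample, and fixes the
#' Trials-to-Adapt threshold as the lower bound of the Final Adaptation
#' range (the threshold is therefore fitted before per-participant
#' Trials-to-Adapt values exist; `fit_control_ranges` computes them
#' internally from the control sessions).
#'
#' @param sessions List of control [vmr_session()] objects (>= 20).
#' @param coverage Central coverage, default 0.95.
#' @return A list of class `"control_ranges"`: per-measure `c(lo, hi)`
#'   plus `threshold` (deg) and `n_controls`.
#' @export
fit_control_ranges <- function(sessions, coverage = 0.95) {
  summaries <- lapply(sessions, summarize_session)
  initial <- vapply(summaries, `[[`, numeric(1), "initial_adaptation")
  final <- vapply(summaries, `[[`, numeric(1), "final_adaptation")
  rng_final <- control_range(final, coverage)
  threshold <- rng_final[1]
  tta <- vapply(sessions, trials_to_adapt, numeric(1), threshold = threshold)
  structure(list(
    initial = control_range(initial, coverage),
    final = rng_final,
    trials = control_range(tta, coverage),
    threshold = threshold,
    n_controls = length(sessions)
  ), class = "control_ranges")
}

#' Classify adaptation impairment
#'
#' A participant is impaired on Initial or Final Adaptation when the
#' measure falls strictly below the lower bound of the control range, and
#' on Trials to Adapt when it strictly exceeds the upper bound; values
#' exactly at a bound are not impaired. `any_impaired` flags impairment on
#' at least one measure.
#'
#' @param metrics List with `initial_adaptation`, `final_adaptation`,
#'   `trials_to_adapt`.
#' @param ranges A [fit_control_ranges()] result.
#' @return Logical list: `initial_impaired`, `final_impaired`,
#'   `trials_impaired`, `any_impaired`.
#' @export
classify_adaptation <- function(metrics, ranges) {
  ii <- metrics$initial_adaptation < ranges$initial[1]
  fi <- metrics$final_adaptation < ranges$final[1]
  ti <- metrics$trials_to_adapt > ranges$trials[2]
  list(initial_impaired = ii, final_impaired = fi, trials_impaired = ti,
       any_impaired = ii || fi || ti)
}
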