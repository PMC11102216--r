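#' Arm position-matching (APM) metrics
#'
#' Computes the four APM performance variables from matched positions that
#' have already been mirrored into the passive arm's frame:
#' \describe{
#'   \item{Absolute Error (AE)}{`ae_x = mean(|matched_x - target_x|)` over
#'     all trials (likewise y); `ae_xy` is the root-sum-square of the two.}
#'   \item{Variability (Var)}{trial-to-trial variability in the matched
#'     location: per-target SD of matched x across repetitions, averaged
#'     over the nine targets (likewise y); `var_xy` by root-sum-square.}
#'   \item{Area}{convex-hull area of the nine per-target mean matched
#'     positions relative to the hull of the nine targets; 1 is ideal.}
#'   \item{Spatial Shift}{`shift_x = mean(matched_x) - mean(target_x)`
#'     (likewise y); `shift_xy` is the shift magnitude; 0 is ideal.}
#' }
#'
#' @param targets n x 2 matrix of passive target positions (m); the full
#'   protocol presents each of 9 targets the same number of times.
#' @param matched n x 2 matrix of matched positions, pre-mirrored into the
#'   passive arm's frame.
#' @return A list of class `"apm_metrics"` with fields `ae_x, ae_y, ae_xy,
#'   var_x, var_y, var_xy, area_xy, shift_x, shift_y, shift_xy`.
#' @export
compute_apm <- function(targets, matched) {
  targets <- as.matrix(targets)
  matched <- as.matrix(matched)
  if (!identical(dim(targets), dim(matched))) {
    stop("targets and matched must have identical dimensions", call. = FALSE)
  }
  key <- paste(signif(targets[, 1], 10), signif(targets[, 2], 10))
  reps <- table(key)
  if (length(reps) != 9L || length(unique(as.integer(reps))) != 1L ||
      any(reps < 2L)) {
    stop("incomplete protocol: need equal repetitions (>= 2) of 9 targets",
         call. = FALSE)
  }
  ae_x <- mean(abs(matched[, 1] - targets[, 1]))
  ae_y <- mean(abs(matched[, 2] - targets[, 2]))
  grp <- split(seq_along(key), key)
  var_x <- mean(vapply(grp, function(i) stats::sd(matched[i, 1]), numeric(1)))
  var_y <- mean(vapply(grp, function(i) stats::sd(matched[i, 2]), numeric(1)))
  mean_matched <- t(vapply(grp, function(i) colMeans(matched[i, , drop = FALSE]),
                           numeric(2)))
  uniq_targets <- t(vapply(grp, function(i) targets[i[1], ], numeric(2)))
  area_xy <- hull_area(mean_matched) / hull_area(uniq_targets)
  shift_x <- mean(matched[, 1]) - mean(targets[, 1])
  shift_y <- mean(matched[, 2]) - mean(targets[, 2])
  structure(list(
    ae_x = ae_x, ae_y = ae_y, ae_xy = sqrt(ae_x^2 + ae_y^2),
    var_x = var_x, var_y = var_y, var_xy = sqrt(var_x^2 + var_y^2),
    area_xy = area_xy,
    shift_x = shift_x, shift_y = shift_y,
    shift_xy = sqrt(shift_x^2 + shift_y^2)
  ), class = "apm_metrics")
}

# convex-hull area (shoelace over grDevices::chull vertices)
hull_area <- function(pts) {
  pts <- as.matrix(pts)
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' Flag a failed movement-matching trial
#'
#' A trial is failed when the active arm shows no detectable movement
#' onset or when its path length is below 25% of the passive arm's.
#'
#' @param active,passive Active and passive [trajectory()] objects (any
#'   frame; path length is mirror-invariant).
#' @return Logical.
#' @export
flag_failed_trial <- function(active, passive) {
  onset_ok <- !inherits(try(detect_onset(active, axis = "speed"),
                            silent = TRUE), "try-error")
  !onset_ok || path_length(active) < 0.25 * path_length(passive)
}

#' Arm movement-matching (AMM) metrics
#'
#' Per-trial comparison of the active arm's movement to the robot-driven
#' passive movement, averaged over non-failed trials:
#' \describe{
#'   \item{Response Latency (RL)}{difference in movement onset times
#'     (12.5% of peak speed), seconds.}
#'   \item{Peak Speed Ratio (PSR)}{active / passive peak hand speed.}
#'   \item{Initial Direction Error (IDE)}{absolute difference of movement
#'     directions at peak hand speed, wrapped to [0, 180] degrees.}
#'   \item{Path Length Ratio (PLR)}{active / passive path length.}
#' }
#'
#' @param trials List of trials, each a list with elements `passive` and
#'   `active` ([trajectory()] objects). The active trajectory must be
#'   pre-mirrored into the passive arm's frame (see [mirror_x()]).
#' @param failed Optional logical vector; when omitted, failures are
#'   flagged with [flag_failed_trial()].
#' @return A list of class `"amm_metrics"`: `rl` (s), `psr`, `ide` (deg),
#'   `plr`, `n_failed`.
#' @export
compute_amm <- function(trials, failed = NULL) {
  if (length(trials) < 1L) stop("no trials", call. = FALSE)
  if (is.null(failed)) {
    failed <- vapply(trials, function(tr) {
      flag_failed_trial(tr$active, tr$passive)
    }, logical(1))
  }
  if (all(failed)) {
    stop("undefined metrics: all movement-matching trials failed",
         call. = FALSE)
  }
  ok <- which(!failed)
  per <- vapply(trials[ok], function(tr) {
    rl <- detect_onset(tr$active, axis = "speed") -
      detect_onset(tr$passive, axis = "speed")
    psr <- peak_speed(tr$active) / peak_speed(tr$passive)
    ide <- angle_diff_deg(direction_at_peak_speed(tr$active),
                          direction_at_peak_speed(tr$passive))
    plr <- path_length(tr$active) / path_length(tr$passive)
    c(rl = rl, psr = psr, ide = ide, plr = plr)
  }, numeric(4))
  structure(c(as.list(rowMeans(per)), list(n_failed = sum(failed))),
            class = "amm_metrics")
}

#' Per-participant proprioception metrics for a simulated cohort
#'
#' Mirrors each participant's matched APM positions and active AMM
#' trajectories into the passive frame, then computes [compute_apm()] and
#' [compute_amm()] for everyone.
#'
#' @param cohort A [generate_cohort()] result.
#' @param midline_x Participant midline (m), default 0.
#' @return Data frame, one row per participant: id plus all APM and AMM
#'   metric columns.
#' @export
cohort_proprioception_metrics <- function(cohort, midline_x = 0) {
  rows <- lapply(cohort$data, function(d) {
    out <- list(id = d$id)
    if (!is.null(d$apm)) {
      tg <- cbind(d$apm$target_x, d$apm$target_y)
      mm <- mirror_x(cbind(d$apm$matched_x, d$apm$matched_y), midline_x)
      out <- c(out, unclass(compute_apm(tg, mm)))
    }
    if (!is.null(d$amm)) {
      trials <- lapply(d$amm, function(tr) {
        list(passive = tr$passive, active = mirror_x(tr$active, midline_x))
      })
      out <- c(out, unclass(compute_amm(trials)))
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}
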