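#' Planar hand trajectory
#'
#' A trajectory is a uniformly sampled planar hand path: time (s), x (m),
#' y (m). The workspace convention throughout the package is x rightward,
#' y away from the body, with the participant midline at x = 0.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   with a uniform step.
#' @param x,y Numeric vectors of hand position in metres, same length as `t`.
#' @return A data frame of class `"trajectory"` with columns `t`, `x`, `y`.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 0.01), seq(0, 0.1, length.out = 101),
#'                  numeric(101))
#' peak_speed(tr)
#' @export
trajectory <- function(t, x, y) {
  if (length(t) < 3L) {
    stop("trajectory needs at least 3 samples", call. = FALSE)
  }
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("t, x, y must have equal length", call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("trajectory values must be finite", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9) {
    stop("trajectory must be uniformly sampled (within 1e-9 s)", call. = FALSE)
  }
  structure(data.frame(t = t, x = x, y = y),
            class = c("trajectory", "data.frame"))
}

is_trajectory <- function(obj) inherits(obj, "trajectory")

as_trajectory <- function(df) trajectory(df$t, df$x, df$y)

#' Per-sample hand speed
#'
#' Velocity by central differences (one-sided at the endpoints), no
#' smoothing; speed is the magnitude of the planar velocity. An optional
#' zero-phase low-pass hook for noisy real recordings can be applied
#' beforehand with [smooth_position()].
#'
#' @param traj A [trajectory()].
#' @return Numeric vector of speeds (m/s), one per sample.
#' @export
speed_profile <- function(traj) {
  v <- velocity_components(traj)
  sqrt(v$vx^2 + v$vy^2)
}

# central-difference planar velocity; endpoints one-sided
velocity_components <- function(traj) {
  if (!is_trajectory(traj)) traj <- as_trajectory(traj)
  n <- nrow(traj)
  dt <- traj$t[2] - traj$t[1]
  cd <- function(p) {
    d <- numeric(n)
    d[1] <- (p[2] - p[1]) / dt
    d[n] <- (p[n] - p[n - 1]) / dt
    if (n > 2) d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    d
  }
  list(vx = cd(traj$x), vy = cd(traj$y))
}

#' Optional zero-phase moving-average position smoother
#'
#' Off by default everywhere in the pipeline; synthetic trajectories are
#' noise-free in position. Applies a centred moving average forward and
#' backward (zero phase lag) to x and y.
#'
#' @param traj A [trajectory()].
#' @param window Odd window length in samples.
#' @return A smoothed [trajectory()].
#' @export
smooth_position <- function(traj, window = 5L) {
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  if (window == 1L) return(traj)
  k <- rep(1 / window, window)
  pad_filter <- function(p) {
    half <- (window - 1L) / 2L
    pp <- c(rep(p[1], half), p, rep(p[length(p)], half))
    once <- stats::filter(pp, k, sides = 2)
    once <- once[(half + 1L):(half + length(p))]
    pp2 <- c(rep(once[1], half), rev(once), rep(once[length(once)], half))
    twice <- stats::filter(pp2, k, sides = 2)
    rev(twice[(half + 1L):(half + length(p))])
  }
  trajectory(traj$t, pad_filter(traj$x), pad_filter(traj$y))
}

#' Movement-onset detection by velocity threshold
#'
#' Onset is the first sample at which the chosen velocity signal strictly
#' exceeds `fraction` of its peak. For visuomotor-rotation reaches the
#' signal is the forward (+y, toward-target) velocity component; for the
#' matching tasks it is hand speed.
#'
#' @param traj A [trajectory()].
#' @param fraction Threshold as a fraction of the signal peak (default
#'   0.125, i.e. 12.5% of peak).
#' @param axis `"speed"` for hand-speed magnitude or `"forward_y"` for the
#'   +y velocity component.
#' @return Onset time in seconds (a sample time, no interpolation).
#' @export
detect_onset <- function(traj, fraction = 0.125, axis = c("speed", "forward_y")) {
  axis <- match.arg(axis)
  v <- velocity_components(traj)
  sig <- if (axis == "speed") sqrt(v$vx^2 + v$vy^2) else v$vy
  pk <- max(sig)
  if (!is.finite(pk) || pk <= 0) {
    stop("no movement onset: velocity signal has no positive peak",
         call. = FALSE)
  }
  idx <- which(sig > fraction * pk)[1]
  if (is.na(idx)) {
    stop("no movement onset: threshold never exceeded", call. = FALSE)
  }
  traj$t[idx]
}

#' Initial reach direction at a fixed latency after onset
#'
#' Signed angle, in degrees, between the vector from `origin` to the hand
#' position `latency` seconds after `onset` and the straight line from
#' `origin` to `target`. Position is linearly interpolated between samples.
#' Sign convention: positive angles are clockwise of the target line, the
#' direction that compensates a counter-clockwise cursor rotation, so
#' complete adaptation to a 30 deg CCW rotation reads +30.
#'
#' @param traj A [trajectory()].
#' @param onset Onset time (s), e.g. from [detect_onset()].
#' @param latency Probe latency after onset (s); default 0.150.
#' @param origin Numeric (x, y) start position (m).
#' @param target Numeric (x, y) end-target position (m).
#' @return Signed direction in degrees.
#' @export
direction_at_latency <- function(traj, onset, latency = 0.150,
                                 origin, target) {
  tq <- onset + latency
  if (tq < traj$t[1] || tq > traj$t[nrow(traj)]) {
    stop("truncated trial: probe time outside trajectory span", call. = FALSE)
  }
  px <- stats::approx(traj$t, traj$x, xout = tq)$y
  py <- stats::approx(traj$t, traj$y, xout = tq)$y
  v <- c(px - origin[1], py - origin[2])
  u <- c(target[1] - origin[1], target[2] - origin[2])
  if (sum(v^2) == 0) stop("no movement onset: hand still at origin", call. = FALSE)
  # CCW-positive angle of v relative to u, then negated: compensatory
  # (clockwise) deviations are positive
  ang <- atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2])
  -ang * 180 / pi
}

#' Movement direction at peak hand speed
#'
#' Direction (degrees, standard mathematical convention: CCW from +x) of the
#' instantaneous velocity at the sample of peak speed. Used for the
#' initial-direction error of the movement-matching task.
#'
#' @param traj A [trajectory()].
#' @return Angle in degrees in (-180, 180].
#' @export
direction_at_peak_speed <- function(traj) {
  v <- velocity_components(traj)
  sp <- sqrt(v$vx^2 + v$vy^2)
  if (max(sp) <= 0) stop("no movement onset: trajectory has zero motion", call. = FALSE)
  i <- which.max(sp)
  atan2(v$vy[i], v$vx[i]) * 180 / pi
}

#' Peak hand speed
#' @param traj A [trajectory()].
#' @return Maximum speed (m/s).
#' @export
peak_speed <- function(traj) max(speed_profile(traj))

#' Path length
#' @param traj A [trajectory()].
#' @return Sum of inter-sample segment lengths (m).
#' @export
path_length <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Mirror about the participant midline
#'
#' Reflects x about a vertical midline (`x -> 2 * midline_x - x`), the
#' transform that maps the active arm's workspace onto the passive arm's
#' for the bimanual matching tasks.
#'
#' @param obj A [trajectory()], or a numeric (x, y) point, or an n x 2
#'   matrix/data frame of points.
#' @param midline_x Midline x coordinate (m); default 0.
#' @return Mirrored object of the same type.
#' @export
mirror_x <- function(obj, midline_x = 0) {
  if (is_trajectory(obj)) {
    return(trajectory(obj$t, 2 * midline_x - obj$x, obj$y))
  }
  if (is.numeric(obj) && is.null(dim(obj)) && length(obj) == 2L) {
    return(c(2 * midline_x - obj[1], obj[2]))
  }
  obj <- as.matrix(obj)
  obj[, 1] <- 2 * midline_x - obj[, 1]
  obj
}

# angle wrap helper: absolute angular difference in [0, 180]
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d <- ifelse(d > 180, 360 - d, d)
  abs(d)
}
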