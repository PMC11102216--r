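#' Minimum-jerk point-to-point trajectory
#'
#' Straight reach with the classic minimum-jerk position polynomial
#' s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5, giving the bell-shaped speed
#' profile of robot-guided passive movements: zero speed at both endpoints,
#' a single interior maximum, and analytic peak speed 15/8 * distance /
#' duration at the movement midpoint.
#'
#' @param start,end Numeric (x, y) endpoints in metres; must differ.
#' @param duration Movement duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz (> 0); default 200.
#' @param lead_in,lead_out Stationary padding (s) before and after the
#'   movement, default 0.
#' @param t0 Time of the first sample (s).
#' @return A [trajectory()].
#' @examples
#' tr <- min_jerk_trajectory(c(0, 0), c(0, 0.10), duration = 1)
#' max(speed_profile(tr))  # ~ 0.1875 m/s = 15/8 * 0.10 / 1
#' @export
min_jerk_trajectory <- function(start, end, duration, sample_rate = 200,
                                lead_in = 0, lead_out = 0, t0 = 0) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  if (all(start == end)) stop("start and end must differ", call. = FALSE)
  dt <- 1 / sample_rate
  total <- lead_in + duration + lead_out
  t <- seq(0, total, by = dt)
  tau <- pmin(pmax((t - lead_in) / duration, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  trajectory(t0 + t,
             start[1] + s * (end[1] - start[1]),
             start[2] + s * (end[2] - start[2]))
}

# duration that yields a requested minimum-jerk peak speed for a distance
min_jerk_duration <- function(distance, peak_speed) {
  (15 / 8) * distance / peak_speed
}
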