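#' Assessment protocol specification
#'
#' Defaults mirror the robotic assessment battery: a 3 x 3 arm
#' position-matching (APM) grid with 10 cm spacing presented in 6
#' pseudorandomized blocks (54 trials), arm movement-matching (AMM)
#' movements of 20 cm between three targets in a triangle over 6 blocks
#' (36 trials), and a visuomotor rotation (VMR) session of 25 baseline,
#' 125 adaptation and 25 washout reaches of 10 cm with a 30 deg
#' counter-clockwise cursor rotation. The passive (robot-moved) arm
#' workspace is centred to one side of the participant midline (x = 0);
#' the grid centre stands for the arm at 30 deg shoulder flexion and
#' 90 deg elbow flexion, expressed in planar hand coordinates.
#'
#' @param apm_centre Centre of the APM grid (x, y) in metres.
#' @param apm_spacing Grid spacing (m), default 0.10.
#' @param apm_blocks Number of APM blocks of 9 trials, default 6.
#' @param amm_centre Centroid of the AMM target triangle (m).
#' @param amm_length Movement length between AMM targets (m), default 0.20.
#' @param amm_blocks Number of AMM blocks of 6 movements, default 6.
#' @param vmr_trials Integer triple: baseline, adaptation, washout trial
#'   counts, default c(25, 125, 25).
#' @param rotation_deg Cursor rotation (deg, counter-clockwise positive),
#'   default 30.
#' @param target_distance VMR reach distance (m), default 0.10.
#' @param passive_peak_speed_apm Mean passive peak speed for APM moves
#'   (m/s), default 0.283; per-participant values are drawn within
#'   `apm_speed_range`.
#' @param apm_speed_range Range of participant-mean passive peak speeds
#'   (m/s), default c(0.167, 0.406).
#' @param passive_peak_speed_amm Passive peak speed for AMM movements
#'   (m/s), default 0.20.
#' @param sample_rate Trajectory sampling rate (Hz), default 200.
#' @return A list of class `"protocol_spec"`.
#' @export
protocol_spec <- function(apm_centre = c(0.15, 0.30),
                          apm_spacing = 0.10,
                          apm_blocks = 6L,
                          amm_centre = c(0.15, 0.30),
                          amm_length = 0.20,
                          amm_blocks = 6L,
                          vmr_trials = c(25L, 125L, 25L),
                          rotation_deg = 30,
                          target_distance = 0.10,
                          passive_peak_speed_apm = 0.283,
                          apm_speed_range = c(0.167, 0.406),
                          passive_peak_speed_amm = 0.20,
                          sample_rate = 200) {
  stopifnot(apm_spacing > 0, amm_length > 0, length(vmr_trials) == 3L,
            all(vmr_trials > 0), target_distance > 0, sample_rate > 0,
            apm_blocks >= 1L, amm_blocks >= 1L)
  structure(list(
    apm_centre = apm_centre, apm_spacing = apm_spacing,
    apm_blocks = as.integer(apm_blocks),
    amm_centre = amm_centre, amm_length = amm_length,
    amm_blocks = as.integer(amm_blocks),
    vmr_trials = as.integer(vmr_trials), rotation_deg = rotation_deg,
    target_distance = target_distance,
    passive_peak_speed_apm = passive_peak_speed_apm,
    apm_speed_range = apm_speed_range,
    passive_peak_speed_amm = passive_peak_speed_amm,
    sample_rate = sample_rate
  ), class = "protocol_spec")
}

#' The nine APM target positions
#' @param spec A [protocol_spec()].
#' @return A 9 x 2 matrix of (x, y) positions, row order column-major over
#'   the grid.
#' @export
apm_targets <- function(spec = protocol_spec()) {
  off <- spec$apm_spacing * c(-1, 0, 1)
  g <- expand.grid(x = spec$apm_centre[1] + off, y = spec$apm_centre[2] + off)
  as.matrix(g)
}

# pseudorandomized APM trial order: each block a permutation of the nine
# positions, no position repeated across a block boundary
apm_trial_order <- function(spec = protocol_spec()) {
  order <- integer(0)
  for (b in seq_len(spec$apm_blocks)) {
    repeat {
      perm <- sample.int(9L)
      if (length(order) == 0L || perm[1] != order[length(order)]) break
    }
    order <- c(order, perm)
  }
  order
}

#' The three AMM targets (equilateral triangle)
#' @param spec A [protocol_spec()].
#' @return A 3 x 2 matrix of vertex positions; pairwise distance equals
#'   `spec$amm_length`.
#' @export
amm_targets <- function(spec = protocol_spec()) {
  r <- spec$amm_length / sqrt(3)
  ang <- c(90, 210, 330) * pi / 180
  cbind(x = spec$amm_centre[1] + r * cos(ang),
        y = spec$amm_centre[2] + r * sin(ang))
}

# AMM movement sequence: a random walk over the triangle vertices (the arm
# is never returned to centre), blocks x 6 movements; consecutive trials
# never revisit the same vertex by construction
amm_movement_sequence <- function(spec = protocol_spec()) {
  n_moves <- spec$amm_blocks * 6L
  seq_v <- integer(n_moves + 1L)
  seq_v[1] <- sample.int(3L, 1L)
  for (i in seq_len(n_moves)) {
    seq_v[i + 1L] <- sample(setdiff(1:3, seq_v[i]), 1L)
  }
  cbind(from = seq_v[-length(seq_v)], to = seq_v[-1])
}
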