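# fixed-precision numeric formatting for byte-stable CSV diffs
fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), NA, formatC(x, digits = digits, format = "g"))
}

write_stable_csv <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the participants table
#'
#' Participants CSV: `id, group, age, sex, handedness, tlt` (the clinical
#' metadata the analysis consumes; generative parameters are kept in the
#' cohort object, not in the interchange file).
#'
#' @param cohort A [generate_cohort()] result.
#' @param path CSV path.
#' @return The path (write) or a data frame (read).
#' @export
write_participants_csv <- function(cohort, path) {
  keep <- c("id", "group", "age", "sex", "handedness", "tlt")
  write_stable_csv(cohort$participants[keep], path)
}

#' @rdname write_participants_csv
#' @export
read_participants_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read long-format trajectory data
#'
#' Trajectory CSV dialect: one row per sample with columns
#' `participant_id, task, trial, arm, phase, t_s, x_m, y_m`. APM rows
#' carry the final matched/target positions as single-sample rows; AMM
#' rows carry the full passive and active traces.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path CSV path.
#' @param tasks Tasks to export (AMM trajectories dominate file size).
#' @return The path (write) or a data frame (read).
#' @export
write_trajectories_csv <- function(cohort, path, tasks = c("apm", "amm")) {
  pieces <- list()
  for (id in names(cohort$data)) {
    d <- cohort$data[[id]]
    if ("apm" %in% tasks && !is.null(d$apm)) {
      a <- d$apm
      pieces[[length(pieces) + 1L]] <- data.frame(
        participant_id = id, task = "apm",
        trial = rep(a$trial, 2),
        arm = rep(c("passive", "active"), each = nrow(a)),
        phase = "match", t_s = 0,
        x_m = c(a$target_x, a$matched_x),
        y_m = c(a$target_y, a$matched_y))
    }
    if ("amm" %in% tasks && !is.null(d$amm)) {
      for (k in seq_along(d$amm)) {
        tr <- d$amm[[k]]
        for (arm in c("passive", "active")) {
          tj <- tr[[arm]]
          pieces[[length(pieces) + 1L]] <- data.frame(
            participant_id = id, task = "amm", trial = k, arm = arm,
            phase = "match", t_s = tj$t, x_m = tj$x, y_m = tj$y)
        }
      }
    }
  }
  write_stable_csv(do.call(rbind, pieces), path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# rebuild the per-participant AMM trial list from a long trajectory table
amm_trials_from_table <- function(df, participant_id) {
  df <- df[df$participant_id == participant_id & df$task == "amm", ]
  if (nrow(df) == 0) stop("no AMM rows for ", participant_id, call. = FALSE)
  lapply(sort(unique(df$trial)), function(k) {
    tk <- df[df$trial == k, ]
    make <- function(arm) {
      a <- tk[tk$arm == arm, ]
      trajectory(a$t_s, a$x_m, a$y_m)
    }
    list(passive = make("passive"), active = make("active"))
  })
}

# rebuild APM target/matched matrices from a long trajectory table
apm_positions_from_table <- function(df, participant_id) {
  df <- df[df$participant_id == participant_id & df$task == "apm", ]
  if (nrow(df) == 0) stop("no APM rows for ", participant_id, call. = FALSE)
  p <- df[df$arm == "passive", ]
  a <- df[df$arm == "active", ]
  p <- p[order(p$trial), ]; a <- a[order(a$trial), ]
  list(targets = cbind(p$x_m, p$y_m), matched = cbind(a$x_m, a$y_m))
}

#' Write / read the VMR trial-summary table
#'
#' One row per reach: `participant_id, trial, phase, initial_direction_deg`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path CSV path.
#' @return The path (write) or a data frame (read).
#' @export
write_vmr_csv <- function(cohort, path) {
  pieces <- lapply(names(cohort$data), function(id) {
    s <- cohort$data[[id]]$vmr
    if (is.null(s)) return(NULL)
    data.frame(participant_id = id, trial = seq_along(s$directions),
               phase = s$phase, initial_direction_deg = s$directions)
  })
  write_stable_csv(do.call(rbind, pieces), path)
}

#' @rdname write_vmr_csv
#' @export
read_vmr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$participant_id)
  sessions <- lapply(ids, function(id) {
    d <- df[df$participant_id == id, ]
    d <- d[order(d$trial), ]
    phases <- c(sum(d$phase == "baseline"), sum(d$phase == "adaptation"),
                sum(d$phase == "washout"))
    vmr_session(d$initial_direction_deg, phases = phases)
  })
  names(sessions) <- ids
  sessions
}

#' Read / write a pipeline configuration
#'
#' YAML or JSON (by extension) with an explicit top-level `seed`; missing
#' fields fall back to [pipeline_config()] defaults.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config A [pipeline_config()] list.
#' @return A config list (read) or the path (write).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(pipeline_config(), raw)
  if (!is.null(raw$prevalence)) {
    cfg$prevalence <- utils::modifyList(prevalence_config(), raw$prevalence)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
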