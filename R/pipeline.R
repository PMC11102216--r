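#' Moving-average smoother for adaptation curves
#'
#' Sliding mean with window length `window` and `overlap` shared samples
#' between consecutive windows (step = window - overlap). The defaults
#' (window 5, overlap 4, i.e. step 1) reproduce the smoothing used for
#' group adaptation curves; only full windows are emitted, indexed at the
#' window centres.
#'
#' @param series Numeric vector.
#' @param window Window length (>= 1).
#' @param overlap Samples shared between consecutive windows (0 <=
#'   overlap < window).
#' @return Numeric vector of window means (length
#'   `floor((n - window) / (window - overlap)) + 1`).
#' @export
moving_average <- function(series, window = 5L, overlap = 4L) {
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (overlap < 0L || overlap >= window) {
    stop("overlap must satisfy 0 <= overlap < window", call. = FALSE)
  }
  n <- length(series)
  if (n < window) stop("series shorter than window", call. = FALSE)
  step <- window - overlap
  starts <- seq(1L, n - window + 1L, by = step)
  vapply(starts, function(s) mean(series[s:(s + window - 1L)]), numeric(1))
}

#' Quadrant counts for a pair of impairment flags
#'
#' Cross-tabulates two boolean impairment flags into the four quadrants
#' of an impairment-profile plot (both, x-only, y-only, neither) with
#' proportions summing to 1.
#'
#' @param flags_x,flags_y Equal-length logical vectors.
#' @return List: `counts` (named integer vector), `proportions`, `n`,
#'   and the corresponding 2x2 `table` (rows: x impaired yes/no, cols: y
#'   impaired yes/no) for Fisher's exact test.
#' @export
quadrant_counts <- function(flags_x, flags_y) {
  if (length(flags_x) != length(flags_y)) {
    stop("flag vectors must have equal length", call. = FALSE)
  }
  flags_x <- as.logical(flags_x); flags_y <- as.logical(flags_y)
  n <- length(flags_x)
  counts <- c(both = sum(flags_x & flags_y),
              x_only = sum(flags_x & !flags_y),
              y_only = sum(!flags_x & flags_y),
              neither = sum(!flags_x & !flags_y))
  tab <- matrix(c(counts["both"], counts["x_only"],
                  counts["y_only"], counts["neither"]),
                2, 2, byrow = TRUE,
                dimnames = list(x = c("impaired", "not"),
                                y = c("impaired", "not")))
  list(counts = counts, proportions = counts / n, n = n, table = tab)
}

#' Pipeline configuration
#'
#' All knobs of a full synthetic-cohort analysis run; a run is
#' reproducible from the config alone.
#'
#' @param seed Master seed for every source of randomness.
#' @param n_stroke,n_control Cohort sizes (defaults 48 / 40).
#' @param n_normative Size of the separate synthetic normative cohort the
#'   task-score models are fitted on, default 120.
#' @param prevalence A [prevalence_config()].
#' @param n_boot Bootstrap resamples for all tests, default 99999.
#' @param alpha Significance level, default 0.05.
#' @param output_dir Output directory.
#' @param write_trajectories Also export the (large) AMM trajectory CSV.
#' @return A named list.
#' @export
pipeline_config <- function(seed = 1L, n_stroke = 48L, n_control = 40L,
                            n_normative = 120L,
                            prevalence = prevalence_config(),
                            n_boot = 99999L, alpha = 0.05,
                            output_dir = "pa_output",
                            write_trajectories = FALSE) {
  list(seed = as.integer(seed), n_stroke = as.integer(n_stroke),
       n_control = as.integer(n_control),
       n_normative = as.integer(n_normative), prevalence = prevalence,
       n_boot = as.integer(n_boot), alpha = alpha,
       output_dir = output_dir, write_trajectories = write_trajectories)
}

# 32-bit polynomial rolling hash of the serialized config (minus the
# output location), recorded in every output so reports can be matched to
# the exact scientific configuration
config_hash <- function(config) {
  config$output_dir <- NULL
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in as.integer(charToRaw(s))) {
    h <- (h * 31 + b) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' VMR adaptation summaries and classification for a cohort
#'
#' Summarises every session, fits the control normative ranges, computes
#' Trials to Adapt with the control-derived threshold, and classifies
#' adaptation impairment.
#'
#' @param sessions Named list of [vmr_session()] objects.
#' @param control_ids Ids (names in `sessions`) of the control group the
#'   95% ranges are fitted on.
#' @return List: `table` (data frame of per-participant measures and
#'   flags) and `ranges` (a `control_ranges` object).
#' @export
cohort_adaptation <- function(sessions, control_ids) {
  ranges <- fit_control_ranges(sessions[control_ids])
  rows <- lapply(names(sessions), function(id) {
    s <- sessions[[id]]
    m <- summarize_session(s)
    m$trials_to_adapt <- trials_to_adapt(s, ranges$threshold)
    fl <- classify_adaptation(m, ranges)
    data.frame(id = id, baseline_mean = m$baseline_mean,
               baseline_sd = m$baseline_sd,
               initial_adaptation = m$initial_adaptation,
               final_adaptation = m$final_adaptation,
               trials_to_adapt = m$trials_to_adapt,
               initial_impaired = fl$initial_impaired,
               final_impaired = fl$final_impaired,
               trials_impaired = fl$trials_impaired,
               adaptation_impaired = fl$any_impaired)
  })
  list(table = do.call(rbind, rows), ranges = ranges)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> proprioception metrics -> normative task scores -> VMR
#' adaptation summaries -> statistics -> report. The task-score normative
#' models are fitted on a separate synthetic normative cohort generated
#' within the run (the run is labelled accordingly in the report);
#' adaptation normative ranges come from the run's own control group.
#' All output files carry the config hash and seed in a header comment
#' line, and a run with the same config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort, metric tables, impairment
#'   profiles, statistics tables and file paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  log_lines <- c(sprintf("run config hash: %s", hash),
                 sprintf("seed: %d", seed))
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    invisible(NULL)
  }

  # --- simulate -------------------------------------------------------
  note("stage simulate: n_stroke=%d n_control=%d n_normative=%d",
       config$n_stroke, config$n_control, config$n_normative)
  cohort <- generate_cohort(config$n_stroke, config$n_control,
                            prevalence = config$prevalence,
                            seed = derive_seed(seed, 1001L))
  normative <- generate_cohort(0L, config$n_normative,
                               seed = derive_seed(seed, 2002L),
                               tasks = c("apm", "amm"),
                               group_label = "normative")

  # --- proprioception metrics + task scores ---------------------------
  note("stage metrics")
  metrics <- cohort_proprioception_metrics(cohort)
  norm_metrics <- cohort_proprioception_metrics(normative)
  note("stage scores")
  apm_model <- fit_normative_model(norm_metrics, apm_score_variables())
  amm_model <- fit_normative_model(norm_metrics, amm_score_variables())
  apm_scores <- lapply(seq_len(nrow(metrics)),
                       function(i) task_score(metrics[i, ], apm_model))
  amm_scores <- lapply(seq_len(nrow(metrics)),
                       function(i) task_score(metrics[i, ], amm_model))
  metrics$apm_task_score <- vapply(apm_scores, `[[`, numeric(1), "value")
  metrics$apm_impaired <- vapply(apm_scores, `[[`, logical(1), "impaired")
  metrics$amm_task_score <- vapply(amm_scores, `[[`, numeric(1), "value")
  metrics$amm_impaired <- vapply(amm_scores, `[[`, logical(1), "impaired")

  # --- adaptation -----------------------------------------------------
  note("stage adaptation")
  sessions <- lapply(cohort$data, `[[`, "vmr")
  control_ids <- cohort$participants$id[cohort$participants$group == "control"]
  adapt <- cohort_adaptation(sessions, control_ids)

  # --- impairment profiles -------------------------------------------
  prof <- merge(cohort$participants[c("id", "group", "age", "sex",
                                      "handedness", "tlt")],
                metrics[c("id", "apm_task_score", "apm_impaired",
                          "amm_task_score", "amm_impaired")], by = "id")
  prof <- merge(prof, adapt$table, by = "id")
  prof$proprioception_impaired <- prof$apm_impaired | prof$amm_impaired
  prof$tlt_impaired <- prof$tlt > 0
  prof <- prof[order(prof$id), ]

  # --- statistics -----------------------------------------------------
  note("stage stats: n_boot=%d", config$n_boot)
  stats_tab <- pipeline_statistics(prof, metrics, config)
  stroke <- prof[prof$group == "stroke", ]
  pairs <- list(
    c("apm_impaired", "adaptation_impaired"),
    c("amm_impaired", "adaptation_impaired"),
    c("proprioception_impaired", "adaptation_impaired"),
    c("tlt_impaired", "adaptation_impaired"))
  fisher_rows <- list(); quad_rows <- list()
  fisher_p <- numeric(0)
  for (pr in pairs) {
    q <- quadrant_counts(stroke[[pr[1]]], stroke[[pr[2]]])
    fe <- fisher_exact_2x2(q$table)
    fisher_rows[[length(fisher_rows) + 1L]] <- data.frame(
      analysis = "fisher_independence", measure_x = pr[1], measure_y = pr[2],
      estimate = fe$odds_ratio, ci_lo = NA_real_, ci_hi = NA_real_,
      p_raw = fe$p, p_holm = NA_real_, n = q$n)
    fisher_p <- c(fisher_p, fe$p)
    quad_rows[[length(quad_rows) + 1L]] <- data.frame(
      measure_x = pr[1], measure_y = pr[2],
      quadrant = names(q$counts), count = as.integer(q$counts),
      proportion = as.numeric(q$proportions))
  }
  holm_f <- holm_correct(fisher_p, config$alpha)
  for (i in seq_along(fisher_rows)) {
    fisher_rows[[i]]$p_holm <- holm_f$p_adjusted[i]
  }
  stats_tab <- rbind(stats_tab, do.call(rbind, fisher_rows))
  quadrants <- do.call(rbind, quad_rows)

  # --- prevalence table ----------------------------------------------
  flags <- c("apm_impaired", "amm_impaired", "proprioception_impaired",
             "initial_impaired", "final_impaired", "trials_impaired",
             "adaptation_impaired", "tlt_impaired")
  prevalence <- do.call(rbind, lapply(flags, function(f) {
    data.frame(flag = f, n_impaired = sum(stroke[[f]]),
               n = nrow(stroke),
               proportion = mean(stroke[[f]]))
  }))

  # --- write outputs --------------------------------------------------
  note("stage report")
  out <- function(name) file.path(config$output_dir, name)
  paths <- list(
    participants = write_participants_csv(cohort, out("participants.csv")),
    metrics = write_stable_csv(metrics, out("metrics.csv")),
    adaptation = write_stable_csv(adapt$table, out("adaptation.csv")),
    profiles = write_stable_csv(prof, out("impairment_profiles.csv")),
    stats = write_stable_csv(stats_tab, out("stats_results.csv")),
    prevalence = write_stable_csv(prevalence, out("prevalence.csv")),
    quadrants = write_stable_csv(quadrants, out("quadrants.csv")),
    vmr = write_vmr_csv(cohort, out("vmr_trials.csv")))
  if (isTRUE(config$write_trajectories)) {
    paths$trajectories <- write_trajectories_csv(cohort, out("trajectories.csv"))
  }
  jsonlite::write_json(
    list(config_hash = hash,
         initial = adapt$ranges$initial, final = adapt$ranges$final,
         trials = adapt$ranges$trials, threshold = adapt$ranges$threshold,
         n_controls = adapt$ranges$n_controls),
    out("control_ranges.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_normative_model(apm_model, out("normative_model_apm.json"))
  write_normative_model(amm_model, out("normative_model_amm.json"))
  report_path <- write_report(out("report.md"), config, hash, prevalence,
                              stats_tab, adapt$ranges)
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(cohort = cohort, normative = normative, metrics = metrics,
                 adaptation = adapt, profiles = prof, stats = stats_tab,
                 prevalence = prevalence, quadrants = quadrants,
                 config = config, config_hash = hash, paths = paths))
}

# group comparisons + correlation matrices, as one tidy results table
pipeline_statistics <- function(prof, metrics, config) {
  seed <- config$seed
  nb <- config$n_boot
  stroke <- prof[prof$group == "stroke", ]
  ctrl <- prof[prof$group == "control", ]
  rows <- list()
  add <- function(analysis, mx, my, est, lo, hi, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, measure_x = mx, measure_y = my, estimate = est,
      ci_lo = lo, ci_hi = hi, p_raw = p, p_holm = NA_real_, n = n)
  }

  # group comparisons, estimate = stroke - control
  comps <- list(
    list(var = "age", tails = 2L, alt = "greater"),
    list(var = "baseline_mean", tails = 2L, alt = "greater"),
    list(var = "baseline_sd", tails = 2L, alt = "greater"),
    list(var = "initial_adaptation", tails = 1L, alt = "less"),
    list(var = "final_adaptation", tails = 1L, alt = "less"),
    list(var = "trials_to_adapt", tails = 1L, alt = "greater"))
  for (k in seq_along(comps)) {
    cm <- comps[[k]]
    b <- bootstrap_mean_diff(stroke[[cm$var]], ctrl[[cm$var]],
                             tails = cm$tails, alternative = cm$alt,
                             n_boot = nb, seed = derive_seed(seed, 100L + k))
    add("group_comparison", cm$var, "stroke_minus_control",
        b$estimate, b$ci_lo, b$ci_hi, b$p, nrow(stroke) + nrow(ctrl))
  }
  sx <- chi2_proportions(sum(ctrl$sex == "F"), nrow(ctrl),
                         sum(stroke$sex == "F"), nrow(stroke),
                         n_boot = nb, seed = derive_seed(seed, 199L))
  add("sex_composition", "prop_female", "control_minus_stroke",
      sx$diff, sx$ci_lo, sx$ci_hi, sx$p, nrow(stroke) + nrow(ctrl))

  # Spearman matrices within the stroke group, Holm per task family
  sm <- merge(stroke, metrics[c("id", "ae_xy", "var_xy", "area_xy",
                                "shift_xy", "rl", "psr", "ide", "plr")],
              by = "id")
  vmr_measures <- c("initial_adaptation", "final_adaptation",
                    "trials_to_adapt")
  fams <- list(
    apm = c("apm_task_score", "ae_xy", "var_xy", "area_xy", "shift_xy"),
    amm = c("amm_task_score", "rl", "psr", "ide", "plr"),
    tlt = "tlt")
  k <- 0L
  for (fam in names(fams)) {
    fam_idx <- integer(0)
    for (vx in fams[[fam]]) {
      for (vy in vmr_measures) {
        k <- k + 1L
        sp <- tryCatch(
          spearman(sm[[vx]], sm[[vy]], n_boot = nb,
                   seed = derive_seed(seed, 300L + k)),
          error = function(e) list(rho = NA_real_, ci_lo = NA_real_,
                                   ci_hi = NA_real_, p = NA_real_,
                                   n = nrow(sm)))
        add(paste0("spearman_", fam), vx, vy, sp$rho, sp$ci_lo, sp$ci_hi,
            sp$p, sp$n)
        fam_idx <- c(fam_idx, length(rows))
      }
    }
    praw <- vapply(rows[fam_idx], function(r) r$p_raw, numeric(1))
    ok <- fam_idx[!is.na(praw)]
    if (length(ok)) {
      ph <- holm_correct(praw[!is.na(praw)], config$alpha)
      for (j in seq_along(ok)) rows[[ok[j]]]$p_holm <- ph$p_adjusted[j]
    }
  }
  do.call(rbind, rows)
}

# short Markdown run report
write_report <- function(path, config, hash, prevalence, stats_tab, ranges) {
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c(
    "# Synthetic-cohort assessment report",
    "",
    sprintf("- config hash: `%s`, seed %d", hash, config$seed),
    sprintf("- cohort: %d stroke, %d control; normative cohort n = %d (synthetic, fitted in-run)",
            config$n_stroke, config$n_control, config$n_normative),
    sprintf("- bootstrap resamples: %d; alpha = %s", config$n_boot,
            fmt(config$alpha)),
    "",
    "Task-score normative models are fitted on the synthetic normative",
    "cohort generated within this run, not on any proprietary normative",
    "database; scores are comparable within the run only.",
    "",
    "## Control 95% ranges (adaptation)",
    sprintf("- Initial Adaptation: [%s, %s] deg", fmt(ranges$initial[1]),
            fmt(ranges$initial[2])),
    sprintf("- Final Adaptation: [%s, %s] deg (Trials-to-Adapt threshold = %s)",
            fmt(ranges$final[1]), fmt(ranges$final[2]), fmt(ranges$threshold)),
    sprintf("- Trials to Adapt: [%s, %s]", fmt(ranges$trials[1]),
            fmt(ranges$trials[2])),
    "",
    "## Impairment prevalence (stroke group)",
    sprintf("- %s: %d/%d (%s%%)", prevalence$flag, prevalence$n_impaired,
            prevalence$n, fmt(100 * prevalence$proportion)),
    "",
    "## Statistics",
    "See `stats_results.csv` (tidy: analysis, measure_x, measure_y,",
    "estimate, ci_lo, ci_hi, p_raw, p_holm, n).")
  writeLines(lines, path)
  invisible(path)
}
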