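test_that("minimum-jerk trajectories satisfy the analytic contracts", {
  # peak speed = 15/8 * distance / duration
  tr <- min_jerk_trajectory(c(0, 0), c(0, 0.20), duration = 1.875)
  expect_equal(peak_speed(tr), 0.20, tolerance = 1e-3)
  expect_equal(min_jerk_duration(0.20, 0.20), 1.875)

  # boundary conditions and straight path length
  tr2 <- min_jerk_trajectory(c(0, 0), c(0, 0.10), duration = 1)
  expect_equal(unlist(tr2[1, c("x", "y")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(tr2[nrow(tr2), c("x", "y")], use.names = FALSE),
               c(0, 0.10))
  expect_equal(path_length(tr2), 0.10, tolerance = 1 / 200 * 0.1875)

  # bell shape: zero speed at endpoints, single interior maximum
  sp <- speed_profile(tr2)
  expect_lt(sp[1], 1e-3)
  expect_lt(sp[length(sp)], 1e-3)
  d <- diff(sp[sp > 1e-9])
  expect_equal(sum(diff(sign(d)) != 0), 1)

  expect_error(min_jerk_trajectory(c(0, 0), c(0, 0.1), duration = 0),
               "duration")
  expect_error(min_jerk_trajectory(c(0, 0), c(0, 0.1), 1, sample_rate = -1),
               "sample_rate")
  expect_error(min_jerk_trajectory(c(0, 0), c(0, 0), 1), "differ")
})

test_that("protocols emit the exact trial counts without consecutive repeats", {
  spec <- protocol_spec()
  p <- ideal_params(rng_seed = 5L)
  d <- simulate_participant(p, spec)
  expect_identical(nrow(d$apm), 54L)
  expect_identical(length(d$amm), 36L)
  expect_identical(length(d$vmr$directions), 175L)
  expect_identical(sum(d$vmr$phase == "adaptation"), 125L)

  for (seed in 1:20) {
    ord <- proprioadapt:::with_seed(seed, proprioadapt:::apm_trial_order(spec))
    expect_identical(length(ord), 54L)
    expect_true(all(sort(unique(ord)) == 1:9))
    expect_true(all(diff(ord) != 0))
    mv <- proprioadapt:::with_seed(seed,
                                   proprioadapt:::amm_movement_sequence(spec))
    expect_identical(nrow(mv), 36L)
    expect_true(all(mv[, "from"] != mv[, "to"]))
    # walk continuity: each movement starts where the previous ended
    expect_true(all(mv[-1, "from"] == mv[-nrow(mv), "to"]))
  }
})

test_that("APM matching model reproduces contraction, shift and identity", {
  spec <- protocol_spec()
  tg <- apm_targets(spec)[rep(1:9, 6), ]
  set.seed(1)
  ident <- simulate_apm_matching(tg, ideal_params())
  expect_equal(ident, mirror_x(tg), tolerance = 1e-12, ignore_attr = TRUE)

  contr <- simulate_apm_matching(tg, ideal_params(apm_contraction = 0.8))
  expect_equal(proprioadapt:::hull_area(contr) /
                 proprioadapt:::hull_area(mirror_x(tg)), 0.64,
               tolerance = 1e-12)

  shifted <- simulate_apm_matching(tg, ideal_params(apm_shift = c(0.03, -0.02)))
  expect_equal(colMeans(shifted) - colMeans(mirror_x(tg)), c(0.03, -0.02),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("AMM trial simulation round-trips latency and speed ratio", {
  spec <- protocol_spec()
  vt <- amm_targets(spec)
  expect_equal(sqrt(sum((vt[1, ] - vt[2, ])^2)), 0.20)

  set.seed(2)
  tr <- simulate_amm_trial(vt[1, ], vt[2, ], ideal_params(amm_latency = 0.3),
                           spec)
  rl <- detect_onset(tr$active, axis = "speed") -
    detect_onset(tr$passive, axis = "speed")
  expect_equal(rl, 0.3, tolerance = 1 / spec$sample_rate)

  tr2 <- simulate_amm_trial(vt[1, ], vt[2, ],
                            ideal_params(amm_speed_ratio = 0.5), spec)
  expect_equal(peak_speed(tr2$active) / peak_speed(tr2$passive), 0.5,
               tolerance = 1e-3)
})

test_that("state-space learner produces the expected adaptation curves", {
  # one-step convergence: a = 1, b = 1, no noise
  s <- simulate_vmr_session(ideal_params())
  ad <- s$directions[s$phase == "adaptation"]
  expect_equal(ad[1], 0)
  expect_equal(ad[-1], rep(30, 124))
  expect_true(all(s$directions[s$phase == "baseline"] == 0))

  # fixed point of x = x + b(30 - x) is 30 for any b > 0 when a = 1
  for (b in c(0.1, 0.3, 0.7)) {
    s2 <- simulate_vmr_session(ideal_params(learner_rate = b))
    ad2 <- s2$directions[s2$phase == "adaptation"]
    expect_equal(ad2[125], 30, tolerance = 1e-4)
  }

  # non-learner: flat at zero, trials-to-adapt hits the failure score
  s3 <- simulate_vmr_session(ideal_params(learner_rate = 0))
  expect_true(all(s3$directions == 0))
  expect_identical(trials_to_adapt(s3, threshold = 5), 125L)
})

test_that("cohort generation is deterministic and prefix-stable", {
  c1 <- generate_cohort(3, 3, seed = 42, tasks = "vmr")
  c2 <- generate_cohort(3, 3, seed = 42, tasks = "vmr")
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$data, c2$data)
  c3 <- generate_cohort(3, 3, seed = 43, tasks = "vmr")
  expect_false(identical(c1$participants, c3$participants))
})

test_that("stroke mixture respects prevalence probabilities and correlation", {
  cfg0 <- prevalence_config(p_proprioception = 0, p_adaptation = 0)
  c0 <- generate_cohort(30, 0, prevalence = cfg0, seed = 7, tasks = "vmr")
  expect_true(all(!c0$participants$prop_impaired_true))
  expect_true(all(!c0$participants$adapt_impaired_true))

  cfg1 <- prevalence_config(p_proprioception = 1, p_adaptation = 1)
  c1 <- generate_cohort(20, 0, prevalence = cfg1, seed = 7, tasks = "vmr")
  expect_true(all(c1$participants$prop_impaired_true))
  expect_true(all(c1$participants$adapt_impaired_true))

  cfg_cpl <- prevalence_config(p_proprioception = 0.5, p_adaptation = 0.5,
                               impairment_correlation = 1)
  cc <- generate_cohort(40, 0, prevalence = cfg_cpl, seed = 7, tasks = "vmr")
  expect_identical(cc$participants$prop_impaired_true,
                   cc$participants$adapt_impaired_true)
})

test_that("participant parameter validation guards its invariants", {
  expect_error(participant_params(learner_rate = 1.5), "\\[0, 1\\]")
  expect_error(participant_params(apm_contraction = 0), "apm_contraction")
  expect_error(participant_params(apm_noise_sd = -1), "non-negative")
  expect_error(participant_params(tlt = 5), "tlt")
})
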