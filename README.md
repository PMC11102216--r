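# proprioadapt

Analysis pipeline for robotic (Kinarm-style) assessments of upper-limb
**proprioception** and **visuomotor adaptation** after stroke, plus a
synthetic-cohort generator that stands in for patient data that cannot
be shared.

Stroke frequently impairs proprioception — the sense of limb position
and motion — and may separately impair the ability to adapt reaching
movements to altered visual feedback. Robotic batteries quantify both:
bimanual matching tasks yield position-sense metrics (absolute error
AE, variability Var, workspace Area, spatial Shift) and kinesthesia
metrics (response latency RL, peak-speed ratio PSR, initial-direction
error IDE, path-length ratio PLR), while a visuomotor rotation (VMR)
task imposes a 30° counter-clockwise cursor rotation and measures how
initial reach directions adapt over 125 trials. This package implements
the full measurement-and-inference chain for researchers analysing such
batteries:

* **Kinematics** — minimum-jerk reference reaches, onset detection at
  12.5% of peak velocity, initial direction at 150 ms after onset,
  peak speed, path length, midline mirroring.
* **Metrics** — APM metrics from 54 matching trials, AMM metrics from
  36 movement-matching trials with failed-trial handling.
* **Task scores** — normative z-scores; one-sided variables mapped to
  zeta scores `ζ(p) = Φ⁻¹((1+p)/2)` (best score 0); root-sum-square;
  Box-Cox renormalization; final zeta score with impairment flagged
  above 1.96 (outside 95% of the normative range).
* **Adaptation** — Initial/Final Adaptation (mean direction of the
  first/last 15 adaptation trials), Trials to Adapt (first run of 15
  consecutive trials above the control-derived threshold; 125 on
  failure), empirical 95% control ranges, impairment classification.
* **Statistics** — bootstrap mean-difference tests (99,999 resamples),
  Spearman correlations with bootstrap CIs, partial Spearman, Fisher's
  exact independence tests, chi-squared proportion comparison,
  Bonferroni-Holm correction.
* **Synthetic cohorts** — controls and stroke participants with
  configurable impairment prevalences, built on a trial-by-trial
  state-space learner `x_{t+1} = a·x_t + b·(r_t − x_t)`.

See `vignettes/assessment-pipeline.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

```r
library(proprioadapt)
cfg <- pipeline_config(seed = 7, n_boot = 2000, output_dir = "pa_output")
res <- run_pipeline(cfg)
print(res$prevalence, row.names = FALSE)
```

```
                    flag n_impaired  n proportion
            apm_impaired         31 48  0.6458333
            amm_impaired         29 48  0.6041667
 proprioception_impaired         31 48  0.6458333
        initial_impaired         22 48  0.4583333
          final_impaired         23 48  0.4791667
         trials_impaired          0 48  0.0000000
     adaptation_impaired         24 48  0.5000000
            tlt_impaired         30 48  0.6250000
```

About half of the simulated stroke cohort is impaired on at least one
adaptation measure and roughly 60% on a proprioception task score,
mirroring the configured prevalences (0.52 / 0.58). In this particular
run the control range for Trials to Adapt saturated at the 125-trial
ceiling, so that flag fired for nobody — a documented property of the
empirical-percentile criterion (see the vignette).

```r
subset(res$stats, analysis %in% c("group_comparison", "sex_composition"),
       select = c(measure_x, estimate, ci_lo, ci_hi, p_raw))
```

```
          measure_x estimate    ci_lo  ci_hi  p_raw
                age   -1.475  -5.7253  2.871 0.4958
      baseline_mean    0.252  -0.0395  0.565 0.1029
        baseline_sd    3.477   3.1455  3.813 0.0010
 initial_adaptation   -7.084  -9.8850 -4.315 0.0005
   final_adaptation   -7.843 -10.8376 -5.060 0.0005
    trials_to_adapt   63.846  49.3060 79.031 0.0005
        prop_female    0.229   0.0292  0.433 0.0323
```

Estimates are stroke minus control: groups are age-matched, stroke
baseline directions are ~3.5° more variable (the generator's calibrated
group effect is 3.27°), and the stroke group adapts less (−7.1° initial,
−7.8° final) while needing ~64 more trials to adapt. Fisher tests of
independence between proprioceptive and adaptation impairment flags,
Spearman matrices with Holm correction, quadrant counts and all output
files land in `pa_output/` together with a run log carrying the config
hash and seed; the same config reproduces byte-identical outputs.

A thin CLI wrapper is installed at `inst/cli/proprioadapt.R`:

```sh
Rscript inst/cli/proprioadapt.R all --seed 7 --out pa_output
```

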