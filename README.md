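# trailgait

Field studies of trail-running footwear instrument each runner with a
heel-mounted IMU (a ±16 g accelerometer and ±2000 °/s gyroscope at 1125 Hz
plus a ±200 g accelerometer at 1600 Hz), plantar-pressure insoles (100 Hz),
and a GPS/heart-rate watch (1 Hz), then have them run a fixed trail loop
four times in an A-B-B-A counterbalanced order contrasting two closure
configurations of the same shoe (a Wrap and a Lace). `trailgait` implements
the complete analysis chain for such a study:

* **sensor ingest & fusion** — CSV/GPX readers with validation; the high-g
  accelerometer is interpolated onto the low-g timestamps and substituted
  per sample-axis wherever the low-g channel saturates at ±16 g;
* **gait events** — three synchronization hops gate the start of each lap;
  running strides are segmented from the smoothed squared-jerk magnitude
  with an adaptive threshold;
* **running speed** — gravity-corrected double integration between
  midstance zero-velocity updates (ZUPT) with linear de-drifting:
  speed = stride length / stride time;
* **IMU stride metrics** — peak acceleration and jerk norms and the
  medial-lateral acceleration range from the 50 Hz zero-phase-filtered
  signal; peak eversion angular velocity from the 30 Hz-filtered gyroscope
  within the first 20 % of the stride;
* **plantar pressure** — stance detection on the total insole force
  (gradient-refined contact/toe-off), heel/toe contact area (rear/front
  20 % of the sensor, loaded-sensel fraction averaged over stance) and
  regional peak pressures;
* **course segmentation** — GPS samples assigned to the uphill / technical
  top / downhill legs of the loop, per-section path lengths by haversine
  summation, per-section heart rate, and the one-minute lap-time exclusion
  rule;
* **statistics** — per-section linear mixed-effects contrasts via
  `lme4`/`lmerTest`/`emmeans`:
  `Outcome ~ Config + (1 | Subject)` for heart rate and questionnaire
  items, `Outcome ~ Config + (Config | Subject)` for stride/step-level
  outcomes, optionally adding `Speed` as a covariate, with estimated
  marginal means, percent differences and Satterthwaite p-values;
* **synthetic studies** — a generator that draws stride-level ground truth
  (population cell means per section × configuration, subject random
  intercepts and condition slopes, stride noise) and renders raw sensor
  streams from it, so the whole pipeline is testable end to end without
  raw recordings.

The methods vignette (`vignettes/trailgait-methods.Rmd`) documents the
models, the waveform template, the parameter choices and their rationale.

## Worked example

```r
library(trailgait)

cfg <- study_config(n_subjects = 4, lap_scale = 0.12, seed = 11)
ps  <- process_study(cfg)      # simulate + run the full pipeline, in memory
ps
#> <processed_study> 4 subjects, 1638 strides, 1638 steps, 4 retained

rep <- analyze_study(ps)
subset(rep$contrasts, metric == "eversion_vel",
       select = c(section, emm_wrap, emm_lace, percent_difference, p))
```

On this small four-subject study it prints (one row per trail section):

```
  section emm_wrap emm_lace percent_difference       p
   uphill    311.7    325.4              -4.22 0.08200
      top    308.9    322.4              -4.17 0.00043
 downhill    439.7    454.9              -3.34 0.01000
```

i.e. the pipeline measures a ~4 % lower peak eversion velocity in the Wrap
closure in every section — close to the ~5 % effect injected by the
generator — with the per-section mixed-model p-values alongside (at four
subjects the uphill contrast is underpowered; the study-scale run in
`scripts/acceptance.R` uses 29). `rep$summary_table` holds the
per-condition mean ± SD of subject means for all nine biomechanical
outcomes plus heart rate, and `rep$qc` the lap-time exclusions.

The same chain runs from an on-disk study bundle:

```r
generate_study(cfg, "study/")          # manifest + CSV/GPX per lap + truth
ps  <- run_pipeline("study/", out_dir = "out/")
rep <- analyze_study(ps)
```

A thin command-line front-end with `simulate` / `process` / `analyze`
subcommands is installed at `inst/cli/trailgait.R`.

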