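# proxhrv

Analysis toolkit for **stop-distance (proxemics) experiments recorded together
with a chest-strap heart-rate monitor**. In this paradigm two people start five
metres apart and repeatedly approach each other under crossed conditions — eye
contact (yes/no) × attribution (judging the comfortable distance for oneself
vs. for the other person) × role (approaching actively vs. standing passively)
— while a wearable proximity sensor (~10 cm absolute precision) logs their
distance and a chest strap logs the interbeat (RR) intervals of the heart.
The scientific questions such designs ask: do clinical groups (e.g. autistic
adults vs. matched controls) prefer different interpersonal distances, and is
autonomic regulation — indexed by heart rate variability — altered at baseline
and under the social demand of the task?

`proxhrv` implements the full measurement-and-analysis chain for researchers
running or reanalysing such experiments:

* **Synthetic sessions** (`simulate_rr_series`, `simulate_session`,
  `simulate_cohort`): a generator whose defaults are the published group
  presets (22 ASD / 21 control participants; preferred distance
  103.670 ± 47.322 cm vs. 67.690 ± 28.589 cm; baseline RMSSD 32.90 vs.
  48.26 ms), with planted ground truth for every stream — so the whole
  pipeline is testable without any data download.
* **Stream I/O** (`read_rr_export`, `read_proximity`,
  `reconstruct_timestamps`): plain-text RR exports (one ms value per line,
  recording start in the filename `YYYY-MM-DD_HH-MM-SS.txt`) and proximity
  CSVs (`t_ms,distance_cm`). Per-beat timestamps are rebuilt from the
  intervals themselves: `t_i = Σ_{j≤i} rr_j / 1000` s.
* **Preprocessing** (`resample_proximity`, `correct_artifacts`,
  `align_triggers`, `drop_incomplete`): median-per-second resampling of the
  proximity stream; single-pass artifact replacement of any beat with
  `rr ≥ 1200` ms or `|Z| > 2` by the recording median; trigger snapping to
  local distance minima; listwise missing-data policy for HRV analyses.
* **HRV metrics** (`rmssd`, `window_rmssd`, `pre_trigger_rmssd`): the
  time-domain index

  `RMSSD = sqrt( (1/(N-1)) * Σ_i (RR_{i+1} - RR_i)^2 )`

  over 60 s baseline/task windows and ultra-short 10 s windows ending at the
  moment the reported distance is reached; mean heart rate as `60000 /
  mean(RR)` bpm.
* **Paradigm extraction** (`detect_episode_minima`,
  `extract_condition_distances`, `pool_active_passive`, `standardize_hrv`):
  the eight per-episode distance minima, their condition labels, pooling of
  active/passive into four cells, and per-person HRV standardised as the
  ratio to the same person's baseline.
* **Statistics** (`mixed_anova`, `bonferroni_posthoc`, `mann_whitney_rb`,
  `chi_square_test`, `spearman_fdr`, `bootstrap_regression`,
  `power_simulation`): mixed-design (split-plot) ANOVA/ANCOVA with Type III
  tests and partial η² = F·df1/(F·df1 + df2); Mann-Whitney U with
  rank-biserial r = 1 − 2U/(n1·n2) and Fisher-z confidence intervals;
  uncorrected Pearson χ²; Spearman matrices screened with Benjamini-Hochberg
  FDR; case-resampling bootstrap regression; simulation-based power.

## Worked example

```r
library(proxhrv)

cfg    <- sim_config(seed = 1)   # published presets, 22 ASD / 21 CP
bundle <- run_pipeline(pipeline_config("simulate", sim = cfg,
                                       out_dir = "demo_run", seed = 1))
st <- bundle$stats
sprintf("ASD %.1f cm vs CP %.1f cm", st$group_means["ASD"], st$group_means["CP"])
#> "ASD 104.5 cm vs CP 67.0 cm"
st$anova_distance[, c("effect", "df1", "df2", "f", "p", "partial_eta_sq")]
#>                          effect df1 df2        f        p partial_eta_sq
#> 1                         group   1  41 13.31027 0.000738       0.245078
#> 2                   eye_contact   1  41  0.00428 0.948140       0.000104
#> 3             eye_contact:group   1  41  3.13873 0.083886       0.071111
#> 4                   attribution   1  41  0.20775 0.650945       0.005041
#> 5             attribution:group   1  41  0.36435 0.549425       0.008808
#> 6       eye_contact:attribution   1  41  0.50076 0.483171       0.012066
#> 7 eye_contact:attribution:group   1  41  0.05853 0.810046       0.001425
```

At seed 1 the simulated cohort shows the preset group difference in pooled
preferred distance (ASD ≈ 104 cm vs. CP ≈ 67 cm; group main effect
F(1,41) = 13.3, η²p = 0.245) and no eye-contact or attribution effects — the
generator plants none. The HRV battery runs on the same bundle:

```r
st$anova_hrv_time[, c("effect", "df1", "df2", "f", "p", "partial_eta_sq")]
#>       effect df1 df2     f        p partial_eta_sq
#> 1      group   1  41  8.05 7.05e-03         0.1641
#> 2       time   1  41 18.90 8.89e-05         0.3155
#> 3 time:group   1  41  1.30 2.61e-01         0.0307
```

i.e. RMSSD drops from baseline to the interpersonal task (Time main effect),
with lower HRV in the ASD group. `run_pipeline` writes the bundle
(`distances.csv`, `hrv.csv`, `stats.json`, `cleaning_report.json`,
`anova_distance.csv`, `run_log.txt`) to `out_dir`; reruns with the same seed
are bit-identical.

A command-line wrapper ships in `inst/scripts/proxhrv`:

```sh
Rscript inst/scripts/proxhrv fixtures --out fix_cohort
Rscript inst/scripts/proxhrv run --input fix_cohort --out fix_report
Rscript inst/scripts/proxhrv report --bundle fix_report
```

## Data dialects (byte-level)

RR export `2019-11-03_10-15-00.txt`:

```
1000
990
1010
```

Proximity CSV:

```
t_ms,distance_cm
0,500
100,499.2
200,498.1
```

See `vignettes/proxhrv-methods.Rmd` for the model, parameter rationale, and
limitations of the synthetic generator.
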