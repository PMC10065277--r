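---
title: "proxhrv: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proxhrv: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxhrv)
```

## The measurement chain

`proxhrv` analyses stop-distance experiments with concurrent cardiac
recording. A session produces three streams:

1. **RR intervals** (ms), exported as a bare text file with the recording
   start encoded in the filename. The device supplies no per-beat timestamps,
   so elapsed time is reconstructed from the intervals themselves: each
   interval is appended to the time of the previous beat,
   $t_i = \sum_{j \le i} rr_j / 1000$ seconds. The first beat therefore sits
   at $rr_1$ after recording start; under this cumulative convention the last
   timestamp equals the total recorded duration exactly, which the test suite
   asserts as a conservation property.
2. **Proximity** (cm), a high-rate distance trace between two worn tags,
   resampled to 1 Hz by taking the median of each half-open second bin
   $[k, k+1)$ anchored at the trace start. Medians rather than means because
   radio ranging produces occasional heavy-tailed glitches. Empty interior
   bins are linearly interpolated and flagged; edge bins carry the nearest
   value.
3. **Triggers**: the eight moments the pair reached the reported distance,
   one per condition of the crossed design — eye contact (yes/no) ×
   attribution (self/other) × role (active/passive), actives preceding
   passives within each eye-contact block.

### Artifact correction

A single pass over the raw RR stream flags any beat with $rr \ge 1200$ ms
(missed-beat fusion on a chest strap) or $|Z| > 2$, where the mean, the
*sample* standard deviation and the replacement median are all computed on
the raw, pre-replacement series. Flagged beats are replaced by the raw
median; timestamps are untouched, so the correction never changes stream
length or the windowing. The rules are deliberately not iterated: iterating
would make the replacement set depend on evaluation order and is harder to
reason about; with a one-shot rule the flagged set is a pure function of the
raw series. A beat caught by both rules is counted once, under the threshold
rule. A zero raw SD makes the Z rule inert (logged), so constant streams pass
through unchanged rather than erroring.

### HRV windows

RMSSD, $\sqrt{\tfrac{1}{N-1}\sum_i (RR_{i+1}-RR_i)^2}$ with the denominator
equal to the number of successive differences, is computed over three window
types: a 60 s baseline at the start of the recording, a 60 s task window one
minute after task onset (+60 s to +120 s, skipping the movement artifacts of
taking up position), and ultra-short 10 s windows ending at each trigger.
Windows are half-open $(a, b]$ so adjacent windows partition beats without
duplication; fewer than two beats yields an *invalid* measure, never an
exception, and the listwise missing-data policy (`drop_incomplete`) excludes
such participants from HRV analyses while keeping them for distance-only
analyses. Mean heart rate is the beat-weighted $60000/\overline{RR}$ bpm
rather than $\overline{60000/RR}$; the two differ in the third decimal for
physiological streams but the choice pins down floating-point expectations.

Because baseline HRV differs between groups, condition-level HRV enters
group comparisons standardised to the person's own baseline. The source
protocol says only that values were "standardised to the given person's
baseline"; we implement the dimensionless ratio
$RMSSD_{cond}/RMSSD_{baseline}$ — scale-free, undefined only for a zero or
invalid baseline (which then invalidates all of that person's conditions).
This is a documented open choice; a difference-based z-standardisation would
change coefficient scales but not the group-comparison contract.

### From trace to behavioural measures

Episodes are segmented at crossings of a 300 cm separation threshold. The
protocol specifies only that "eight local minimums" were identified; 300 cm
sits between plausible stop distances (≲ 200 cm) and the 500 cm reset, so at
the paradigm's pace segments are unambiguous. Within each segment the
*earliest* sample attaining the minimum is the trigger — a deterministic
tie-break matching "the time the reported distance was reached", exercised
explicitly on plateau fixtures. Preferred distance per condition is the 1 Hz
trace value at the trigger; the four analysis cells are the arithmetic means
of the matching active and passive cells ("pooled (averaged) together" —
read as the mean of the two cells, the alternative of entering both as
repeated measures is noted as an open question of the source design).
Triggers supplied externally can be snapped to the nearest local minimum
within ±5 s (`align_triggers`) — small enough never to jump episodes — and a
per-trigger override table replaces the interactive adjustment of the
original workflow.

## The statistics battery

* **Mixed ANOVA/ANCOVA** uses the per-subject contrast-score decomposition:
  with every factor at two levels, each within effect (and its interaction
  with the group) is a one-df test on per-subject contrast scores, and the
  between effect is a test on subject means. Under sum coding this reproduces
  Type III (unweighted-means) F tests — the convention of the mainstream GUI
  statistics packages — and is *exact*: on balanced designs it agrees with
  `aov()`'s error-stratum decomposition to 1e-10 (asserted in the tests).
  One-df effects are always spherical, so no sphericity correction is needed
  or offered. Covariates enter the between stratum only, reducing its error
  df, which is how the ANCOVA F(1, N−2−k) arises. The reported `sum_sq` is on
  the contrast scale (the classic split-plot SS is $2^w$ times larger for
  $w$ within factors); F, p and η²p are scale-free and are what the table is
  for. Partial η² is emitted via the identity $F \cdot df_1/(F \cdot df_1 +
  df_2)$ and asserted against it for every table.
* **Mann-Whitney**: U is the number of pairs with $x > y$ (ties half), so
  complete separation with the first sample below the second gives $U = 0$
  and $r = 1 - 2U/(n_1 n_2) = 1$; positive $r$ means the first sample tends
  lower. p values come from exact enumeration of group assignments while
  $\binom{n_1+n_2}{n_1} \le 2\times10^5$ and from the tie-corrected normal
  approximation (no continuity correction) otherwise. The confidence
  interval Fisher-z-transforms $r$ with $SE = \sqrt{(n_1+n_2+1)/(3 n_1
  n_2)}$ — the convention that reproduces published rank-biserial intervals
  to all printed digits — but CI construction for rank-biserial r has no
  unique standard, so the interval is descriptive.
* **Chi-square** is the uncorrected Pearson statistic (the convention
  consistent with the published demographics table); Yates' correction sits
  behind a flag.
* **Spearman + FDR**: rho with midranks over pairwise-complete observations,
  p from the t approximation, Benjamini-Hochberg step-up over the family of
  unique off-diagonal cells, and a significance mask at the configured
  level. Constant variables are flagged rather than producing spurious NaN
  correlations. The emitted q matrix is asserted against a hand-written BH
  oracle and against its two invariants (q ≥ p, q monotone in p rank).
* **Bootstrap regression**: OLS point fit; case-resampling bootstrap for SE
  and percentile CIs (the distribution-free choice when residuals violate
  normality, which is why the original analysis bootstrapped); p from a
  two-sided normal approximation on the bootstrap SE — the source reports
  bootstrap p values without naming a method, so this documented
  approximation is used. Model F, df and R² come from the point fit and
  satisfy $R^2 = F \cdot df_1/(F \cdot df_1 + df_2)$ by construction.
* **Power** is simulation-based. The original report's "98% post hoc power"
  cannot be reconstructed (tool and conventions unstated; plausible
  reconstructions give lower values), so the package does not target it;
  instead `power_simulation` draws cohorts from explicit normal group
  parameters and reports the rejection fraction with a binomial MC error.
  The acceptance suite checks it against an independent closed-form
  noncentral-t (Welch-Satterthwaite) oracle at the published distance
  presets.

## What the generator emulates — and what it does not

The generator's defaults are the stated world of the emulated study: group
sizes 22/21; person-level preferred distance $\mathcal N(103.670,
47.322^2)$ (ASD) and $\mathcal N(67.690, 28.589^2)$ (CP) truncated at 30 cm
(the intimate-zone floor — only means and SDs are published, so a truncated
normal is the minimal assumption); baseline/task RMSSD presets 32.90/26.57 ms
(ASD) and 48.26/31.60 ms (CP); mean RR from the published baseline heart
rates (662/689 ms); ±10 cm uniform proximity noise (the sensor's stated
absolute precision), with the first sample anchored at the 500 cm start
mark.

RR streams are white Gaussian around a constant mean with
$sd = \text{target}/\sqrt{2}$, which makes the expected RMSSD equal the
target in closed form ($E[(RR_{i+1}-RR_i)^2] = 2\sigma^2$). This is a
deliberate simplification: real RR series are autocorrelated
(respiratory sinus arrhythmia, slow drifts), and an IPFM or AR-based
generator would be needed for spectral indices. RMSSD — the only index this
package computes — is a function of successive differences alone, so the
white model is sufficient for calibration, and the suite verifies the
generator hits targets in 10–60 ms within 5% over 100 replicates. Artifact
spikes are drawn uniformly from 1200–2000 ms so every planted artifact
trips the ≥ 1200 ms rule, giving exact ground truth for recovery tests.

Values the source leaves unstated were fixed once, a priori: approach speed
50 cm/s and hold duration 10 s (a comfortable walking pace; each episode
then exceeds the 10 s pre-trigger window), 90 s stationary baseline (≥ 60 s
with margin), artifact rate 0.02/beat (typical chest-strap burden),
within-person between-condition SD 10 cm, person-level RR jitter 40 ms, and
lifestyle covariate rates approximating the published demographics table.
The generator defaults to a 10 Hz raw proximity rate rather than the
device's ~1 kHz: the analysis consumes only the median-per-second resampled
trace, so the higher rate changes nothing downstream while multiplying
runtime and fixture size by two orders of magnitude; the rate is a config
field for users who want the native contract.

Movement kinematics (linear approach, instantaneous turn-around) are a
stand-in, not a claim about how participants walked; the generator makes no
attempt at respiratory coupling, skin conductance, or experimenter
behaviour. Consequently a green end-to-end test establishes that the
*pipeline arithmetic* is right — planted parameters are recovered, effect
directions at the presets are reproduced — not that the physiological model
is realistic.

## Numerical choices and degenerate inputs

* Even-count medians use R's convention (mean of the two middle values),
  relevant to both resampling bins and the artifact replacement value.
* `rmssd` on fewer than two intervals, windows with fewer than two beats,
  and triggers inside the first 10 s all yield *invalid measures* (NA +
  flag), not exceptions; hard errors are reserved for contract violations
  (nonexistent files, unparsable lines, non-positive durations, rank
  deficiency, wrong episode counts).
* The exact Mann-Whitney path enumerates assignments, so its p values are
  permutation-exact even under ties; the 2e5 cap keeps it under a second.
* Bootstrap resamples that happen to be rank-deficient are redrawn (up to
  100 attempts) rather than contaminating the percentile distribution.
* All randomness flows through explicit seeds via an internal
  state-restoring `with_seed`; cohort generation, bootstrap and power
  simulation are bit-reproducible, and the pipeline writes byte-identical
  bundles on reruns with the same config.

## Known limitations

* The mixed ANOVA supports the design family it was built for — one 2-level
  between factor, up to two 2-level within factors — and rejects anything
  else loudly. General multi-level designs belong to dedicated modelling
  packages.
* Rank-biserial CIs and bootstrap p values are documented conventions, not
  uniquely standard quantities; do not compare them across software without
  checking conventions.
* The Bayesian model-averaged analyses of the source report (exclusion Bayes
  factors under default JASP priors) are out of scope, as are questionnaire
  scoring, diagnostics, and the radio-ranging layer itself.
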