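---
title: "Models and methods behind somnotag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somnotag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnotag)
```

`somnotag` analyses combined EEG/EMG, single-unit and behavioral
recordings from rodent pain–sleep experiments. This vignette documents the
models each stage assumes, the parameters that matter and their defaults,
the numerical choices, and what the synthetic-data tests do and do not
establish about real recordings.

## Sleep staging

Signals are cut into 5-s epochs (`epoch_s`, half-open intervals, 0-based
indices). Per epoch we compute FFT periodogram band powers — delta
0.1–4 Hz, theta 5–10 Hz, total 0.1–30 Hz — and the EMG root-mean-square.
The total-power band is capped at 30 Hz for ratio stability even when the
acquisition chain passes much higher frequencies: the staging bands
themselves stop at 10 Hz.

The scorer follows the standard rodent criteria as a fixed decision list:

1. `emg_rms >= emg_thresh` → **Wake** (high muscle tone overrides the
   spectrum; "desynchronized EEG" is deliberately operationalized through
   this EMG-first rule because published criteria give no numeric EEG
   threshold for wakefulness);
2. otherwise `theta_power / delta_power >= theta_ratio_thresh` → **REM**;
3. otherwise → **NREM**.

`calibrate_thresholds()` places `emg_thresh` at the geometric midpoint of
the two modes of the log EMG-RMS distribution (deterministic 2-means with
quantile-based initialization), and the theta-ratio threshold at the
analogous midpoint among low-EMG epochs. If a distribution fails a
bimodality check (upper/lower mode ratio below 2), the function warns and
falls back to a fixed quantile (0.75 for EMG, 0.85 for the ratio). Because
thresholds are calibrated per recording they need not match any particular
lab's fixed settings; on recordings lacking one of the states (e.g. no
REM) the ratio calibration will warn and the fallback should be reviewed.

An optional smoothing pass merges bouts shorter than `min_bout_epochs`
(default 2 epochs = 10 s) into the preceding bout; before smoothing the
scorer is strictly per-epoch (permutation-equivariant), which the tests
exploit.

Epochs containing non-finite samples abort feature extraction with the
first offending sample index; we prefer failing loudly over silently
interpolating artifacts.

## Optotagging

For each laser pulse the evoked response is the first spike in the
half-open window (onset, onset + 10 ms]; the window default is wider than
typical 1–3 ms latencies so that slow responders are measured rather than
missed, and it is configurable. Reliability is the fraction of pulses with
a response; latency is summarized by the median (robust to the occasional
background spike captured by the window); jitter is the SD of first-spike
latencies over responding pulses. Waveform similarity is the Pearson
correlation between the mean evoked and mean spontaneous snippet
(spontaneous = outside all trains); correlating the means rather than the
spike-by-spike distribution matches how the criterion is normally applied
to average waveforms. A unit is tagged when reliability > 0.7, latency
< 3 ms, jitter < 3 ms and, when snippets exist, correlation > 0.95 — all
strict inequalities, thresholds configurable. Without snippets the rule
degrades to three criteria with a warning.

QC metrics for already-sorted units: the refractory-violation fraction
counts inter-spike intervals below 2 ms against the *total spike count*
(the conventional acceptance bound is 0.2%), and the isolation distance is
the Mahalanobis distance — under the unit's own cluster covariance — from
the cluster centroid to the nearest other cluster's centroid (acceptance
bound 20). That centroid-to-centroid definition is unusual (the common
variant uses the n-th nearest non-cluster spike) but is implemented
literally as the primary method because it is what the accompanying
recording methodology specifies; the conventional variant is available via
`method = "nearest-spike"`. Singular covariances are ridge-regularized
with a logged epsilon rather than failing.

## State-dependent firing

`state_rates()` divides spike counts within a state's scored epochs by the
total scored time in that state. Epochs overlapping laser trains are
excluded from numerator and denominator by default whenever a protocol is
supplied, so stimulation-evoked spikes do not inflate spontaneous rates
(toggle with `exclude_laser`). States scored for less than 30 s are
flagged `reliable = FALSE` — rate estimates from, say, a single short REM
bout are reported but should not be averaged into population figures.

Modulation indices are the normalized contrasts
$(R_A - R_B)/(R_A + R_B)$ for wake–NREM and REM–NREM; they are bounded in
$[-1, 1]$ by construction and `NaN` (with a warning) only when both rates
are zero.

Peri-transition histograms align spikes to epoch boundaries where the
label switches between the requested states, requiring at least 3 epochs
(15 s) of both flanking bouts to exclude flicker transitions. The SEM is
taken across transitions, not across time bins, so the ribbon reflects
event-to-event variability; a single event yields `NA` SEM rather than a
fabricated zero. Peri-stimulus analysis reports per-event before/after
rates (for external paired tests) plus the pooled histogram; overlapping
events are dropped with a warning and edge events with a message.
`compare_transition_rates()` wraps the two-sided paired Wilcoxon
signed-rank test; an all-zero difference vector returns p = 1 with a
warning instead of erroring.

## Brain-state transitions and the hierarchical bootstrap

Trials are state time series on a 60-s bin grid aligned to laser-train
onsets; a bin's label is the majority of its twelve 5-s epochs, with ties
going to the state of the earliest epoch in the bin (the mapping from
epochs to bins is not standardized anywhere, so we fixed the simplest
deterministic rule and documented it). The transition probability into bin
$i$ for the ordered pair $X \to Y$ is $m/n$: among the $n$ trials in $X$
at bin $i-1$, the $m$ that are in $Y$ at bin $i$. Bins with $n = 0$ are
`NA`, outgoing probabilities sum to 1 wherever defined, and the
implementation is tested for exact agreement with a brute-force counter.

Uncertainty respects the nesting of trials within mice: each bootstrap
iteration redraws, for every mouse $i$, $m_i$ of its trials with
replacement, recomputes the statistic per mouse (pooling that mouse's
trials for ratio statistics), and averages across mice with equal weights.
Percentile 2.5/97.5 intervals are taken from the (default) 10,000
resampled means — percentile rather than BCa, matching the usual practice
of reading CIs directly off the resampled distribution. The laser-effect
test records, per iteration, the difference between the mean statistic
during stimulation bins and during the immediately preceding period of
identical duration; the two-sided p-value is
$2\min(\Pr(d \le 0), \Pr(d \ge 0))$ with add-one smoothing, and
significance is declared when the 95% CI of the difference excludes zero.
No correction is applied across the nine transition pairs; all p-values
are reported and multiplicity is left to the analyst.

**Known property — finite-sample narrowness.** Resampling only trials
within mice makes the bootstrap variance of a within-mouse mean
$s^2 (m-1)/m^2$ instead of $s^2/m$: with $m = 5$ trials per mouse the CI
is narrow by a factor $\sqrt{4/5} \approx 0.89$, which the package's own
calibration runs measure as ~90% realized coverage of a nominal 95% CI
(5 mice × 5 trials) and a null rejection rate near 9% at $\alpha = 0.05$;
coverage approaches nominal as the per-mouse trial count grows, since the
shrinkage factor tends to 1. We implement the procedure as specified rather
than patching it (e.g. with an $m{-}1$ resample size), and flag this so
users interpret marginal significance calls at small trial counts with
care. Separately, percentile CIs of sparse $m/n$ statistics need not
bracket the point estimate; such rows are flagged (`ci_ordered`), not
forced.

## Behavioral endpoints

The up-down von Frey procedure starts at the 0.16 g mid-range filament,
steps down after a withdrawal and up after none, and terminates four
responses after the first change in response direction (the standard
small-sample convention; the exact filament series is configurable, with
the usual 0.008–2 g mouse set as default). Monotone runs off either end of
the set terminate at the boundary, and the session is assigned the floor
or ceiling force with an explicit flag rather than an extrapolated value.

The 50% threshold is $10^{(X_f + \kappa\delta)}/10^4$ grams, with $X_f$
the log10 of the final tested force in $10^{-4}$ g units and $\delta$ the
mean log10 spacing of the configured filament set (computed from the
actual set rather than assumed, since spacing is uneven at the ends of the
series). The pattern correction $\kappa$ is resolved by maximizing the
likelihood of the full observed response sequence under a cumulative-
normal psychometric with SD $= \delta$ — the model from which the
published small-sample correction tables were derived. Computing $\kappa$
from that model, rather than hard-coding a transcribed table, keeps the
estimator defined for every pattern the rule can generate (including
saturated sequences that retest a boundary filament) and is verified in
the tests against an independent grid-search of the same likelihood and
against simulation recovery of a known threshold. Patterns with no
direction change that did not reach a boundary are unresolvable and raise
an error naming the response string.

PWL is the arithmetic mean of three radiant-heat applications; fewer
trials average with a warning, and cutoff-capped trials propagate a flag.

## The synthetic-data generator

The generator exists so every stage has ground truth. It emulates:

- a 3-state semi-Markov hypnogram: exponential bout durations by default
  (memoryless; gamma available via `dwell_law`) with means
  Wake 120 s / NREM 150 s / REM 60 s — typical light-phase mouse bouts —
  rounded to the epoch grid with a one-epoch minimum, chained by an
  embedded next-state matrix (defaults: Wake→NREM always; NREM→Wake 0.6,
  NREM→REM 0.4; REM→Wake 0.9, REM→NREM 0.1, approximating the dominant
  Wake→NREM→REM→Wake cycle). `expected_occupancy()` gives the closed-form
  long-run occupancy including the grid-rounding effect, and
  `init_state = "stationary"` starts the chain from it;
- EEG as per-epoch sums of band-limited Gaussian noise (delta, theta,
  broadband components with state-dependent variances) and EMG as white
  noise with state-dependent RMS. Defaults separate the states clearly
  (NREM delta-dominated, REM theta-dominated with the lowest EMG, Wake
  broadband with ~8× the sleep EMG);
- spikes as state-modulated Poisson processes plus, for tagged units, one
  evoked spike per pulse with configurable reliability/latency/jitter;
  background and evoked spikes closer than 1 ms are merged keeping the
  earlier one (an absolute refractory period the analysis side never
  assumes);
- laser effects as per-epoch transition-hazard deltas active only while a
  train is on, matching how stimulation contrasts are analysed;
- up-down response sequences from a logistic psychometric in log force
  (`slope = Inf` gives a deterministic step at the threshold).

All draws flow from per-component sub-streams of one seed, so toggling one
component leaves the others bit-identical. `simulate_cohort()` spaces
stimulation trains with a 600-s recovery gap beyond each trial window —
protocols stimulate every several minutes precisely so that trials sample
independent sleep dynamics; tiling windows back-to-back would correlate
consecutive trials and is not representative.

**What passing tests do not show.** The generator's states are spectrally
clean and stationary: no artifacts, microarousals, electrode drift,
transitional epochs, light/dark rhythm, or inter-mouse heterogeneity
(mice differ only by random stream). Staging accuracy near 99% here is an
upper bound — real recordings stage in the low-to-mid 90s at best and need
the calibration fallbacks; likewise the bootstrap calibration results
quantify the method's intrinsic behavior, not biological variability
between animals, which within-mouse resampling cannot capture at all.

## Problem sizes and numerical choices

Test and calibration runs use sizes chosen to make Monte-Carlo error small
relative to the tolerances they check: 1-h recordings (720 epochs) for
staging recovery; 200-unit populations with ≥ 600 s per state and rates
1–10 Hz for modulation recovery (±0.05); 1,000 simulated cohorts of
5 mice × 5 trials (1,000 bootstrap iterations each) for CI coverage and
null calibration, and 500 cohorts of 10 mice × 6 trials for detection
power; 500 up-down sessions for threshold recovery; an exhaustive
16-outcome enumeration (2 mice × 2 trials) against 200,000 bootstrap
iterations for correctness of the resampling scheme itself. Tie-breaks,
half-open intervals, strict threshold inequalities and the degenerate-
input policies (zero responding pulses, single transitions, all-zero
differences, singular covariances, unimodal calibrations) are each pinned
by a dedicated test.

## Limitations

- No machine-learned stager, microarousal scoring or human re-scoring
  workflow; the rule-based scorer is intended for calibrated long
  recordings with clear state separation.
- Spike sorting itself is out of scope: inputs are sorted spike times
  (with optional snippets), and only acceptance metrics are computed.
- The bootstrap machinery implements the two-level trials-within-mice
  scheme only; mouse-level resampling, BCa intervals and multiplicity
  control are deliberately not included.
- Signal I/O uses the package's plain-text formats (CSV + JSON sidecar);
  EDF/HDF5 containers are not read directly.
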