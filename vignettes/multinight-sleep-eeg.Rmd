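---
title: "Methods: multi-night sleep EEG microarchitecture and next-day cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-night sleep EEG microarchitecture and next-day cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnocog)
```

# What the package computes

`somnocog` implements the analysis chain of a multi-night, in-home
sleep-EEG study in older adults: wearable-EEG nights are reduced to
per-night sleep metrics (macroarchitecture from the hypnogram;
slow-oscillation and spindle events from the signal), morning executive
tasks are scored into daily outcomes, and the two are linked with
participant random-intercept mixed models. Because raw study recordings
are not required to exercise any of this machinery, the package also
ships a synthetic-data generator whose output has known ground truth at
every level — injected events, known variance components, known null or
non-null sleep effects — so each stage is validated by *recovery*, not
by inspection.

# Preprocessing

Signals are single frontal–occipital derivations sampled at 250 Hz.
The standard chain is:

1. **Channel selection.** Each night carries a per-channel quality
   fraction (the proportion of scoreable data). The best of the four
   candidate derivations (F7-O1, F8-O2, Fpz-O1, Fpz-O2) is used if it
   reaches the 50% threshold; otherwise the night is discarded. Ties
   break by candidate order.
2. **Bandpass.** 0.3–40 Hz, 300th-order FIR (Hamming), applied
   zero-phase (forward–backward) so event timing is unshifted. The
   effective magnitude response is the squared single-pass response;
   the transition width scales as `fs/order`, so a 300th-order filter
   at 250 Hz does *not* reject frequencies just below 0.3 Hz sharply —
   tests of the stopband use a higher order on purpose.
3. **Epoching and artifact rejection.** 30-s epochs anchored at
   recording start, half-open `[t, t + 30)`. Each epoch is demeaned and
   rejected if any |sample| exceeds 200 µV. The amplitude rule is
   absolute-amplitude, not peak-to-peak (the convention is exposed as a
   parameter). Epochs are usable only when scored N2 or N3 and
   artifact-free; rejected epochs carry a reason code
   (`not_N2N3` takes precedence over `amplitude_artifact`).

# Slow-oscillation detection

On the 0.3–4 Hz band (same zero-phase FIR machinery), candidates are
consecutive negative-then-positive half-waves delimited by zero
crossings. A candidate becomes an event when all four criteria hold:

* negative-peak magnitude ≥ 33 µV,
* peak-to-peak (negative trough to following positive peak) ≥ 61 µV,
* negative half-wave duration in [125, 1500] ms,
* positive half-wave duration ≤ 1000 ms.

The amplitude thresholds are treated as minima, and no cap is placed on
the total event duration beyond the two half-wave bounds (the criteria
do not state one). Events must lie wholly inside usable epochs; events
straddling a masked epoch boundary are dropped. Because candidates are
delimited by shared zero crossings they can never overlap. Detection is
exactly invariant to constant offsets: the trace is demeaned on entry.

# Spindle detection

A sliding-window sigma-feature detector (0.3-s window, 0.1-s step) in
the correlation/covariance family. Per window, from the sigma-band
(11–16 Hz) and broadband (0.4–30 Hz) traces:

* **relative sigma power** — sigma power / broadband power (raw ratio);
* **correlation** — Pearson correlation of the two traces;
* **covariance** — sliding-window covariance, expressed as a robust
  z-score against a 30-s sliding baseline (median/MAD).

An absolute sigma-power criterion is deliberately omitted: with dry
frontal–occipital electrodes the absolute scale is montage-dependent,
so only relative/normalised features are used. Feature tracks are
smoothed over 3 adjacent windows; a window is spindle-positive when all
three features exceed their thresholds; at least 2 consecutive positive
windows form a candidate (adjacent positives merge; gaps of ≥ 0.1 s are
never bridged). Candidate boundaries are then refined on the smoothed
Hilbert sigma envelope, extending to where the envelope falls below 30%
of the candidate peak (floored at 1.25× the night median envelope);
overlapping refined intervals merge. Events are kept when the refined
duration lies in [0.5, 2.5] s, the peak envelope reaches 3.5× the night
median, and the event sits wholly inside usable epochs. The reported
amplitude is the mean sigma envelope over the event.

**Why these thresholds.** The feature definitions here are raw ratios
and robust z-scores, not the log-transformed, baseline-z-scored
features of the algorithm family's reference implementation, so that
family's published threshold values do not transfer. The defaults
(relative power 0.25, correlation 0.60, covariance-z 5) were fixed once
by a specificity/sensitivity study on the package's own synthetic
background: at 15 µV-RMS pink noise they produce zero false events per
200 minutes of event-free background while recovering > 90% of 20 µV
Hann bursts. Two further choices came out of that study. First, the
covariance baseline is median/MAD rather than mean/SD because
co-occurring slow oscillations inflate a mean/SD baseline enough to
halve spindle sensitivity. Second, the event-level relative-envelope
criterion (peak ≥ 3.5× median) is what removes the residual
noise-burst false positives that all three window features let through
a few times per hour; it is a relative measure and therefore consistent
with omitting absolute power. All thresholds are exposed in
`spindle_params()`.

# Sleep metrics

Stage minutes are 0.5 × epoch counts. TST = N1 + N2 + N3 + REM minutes
(`tst_from_stages()` keeps this identity available for stage-duration
summaries directly; it is linear, so it applies equally to cohort
means). WASO is wake time between the first and last non-wake epoch;
the number of awakenings is the count of maximal wake runs in that
span; sleep efficiency is 100 × TST / time-in-bed (full hypnogram
span). These conventions are stated because hypnogram summaries beyond
stage minutes vary across devices; they are conventional AASM-style
definitions. Event density is count / minutes scored N2+N3 — scored
minutes, not artifact-free minutes, which is the literal definition of
density used with these detectors; a switch selects the artifact-free
variant. Nights whose best candidate channel falls below 50% quality
are dropped, then participants with fewer than 4 surviving nights.

# Task scoring

Go/NoGo: mean RT over correct go responses with RT in [200, 900] ms
(strictly-outside values excluded, boundaries kept); hit% over go
trials; commission% = responses on no-go trials / all no-go trials
(the denominator convention is configurable, since "relative to correct
responses" is ambiguous in common usage). Simon switch: RT cells use
correct responses in [300, 3000] ms (the correct-only restriction is
standard practice and configurable); Simon effect RT =
incongruent − congruent; switch effect RT = switch − non-switch
(negative when switch trials are faster). Accuracy effects default to
incongruent − congruent (Simon) and non-switch − switch (switch), the
orientations under which the usual pattern gives a negative Simon and
positive switch accuracy effect; both orientations are supported
because the two sign conventions coexist in the literature. The first
trial of each block carries no switch label.

# Statistical layer

Participant-level means characterise between-participant differences;
SDs across nights characterise within-participant variability (single
observations give `NA`, not 0). Correlations are two-tailed Pearson, or
Spearman as Pearson on ranks; multiplicity is handled by
Benjamini–Hochberg FDR.

The nightly models are `outcome ~ sleep predictors + (1 | participant)`
fitted by **maximum likelihood** (not REML) with `glmmTMB`, so Gaussian
and beta-family models are directly comparable on likelihood scale.
Proportion outcomes (commission rate / 100) use a beta response with a
constant zero-inflation probability (`zi = ~1`): days with exactly zero
commissions are carried by the inflation component instead of squeezing
transforms; exact ones (which the beta density cannot represent) fall
back to the `(y(n−1)+0.5)/n` squeeze. Standardized coefficients come
from a refit on z-scaled predictors (and z-scaled outcome for the
Gaussian family); their Wald Z statistics equal the raw ones up to
optimizer tolerance. Type III tests are Wald chi-square
(`car::Anova(type = "III")`); with 1-df numeric predictors the
chi-square is the squared Z.

ICC = between / (between + within) variance. For the zero-inflated
beta model no residual variance exists; the latent ICC substitutes a
fixed latent scale, default 1 (the conventional latent logistic scale),
with π²/3 available as the alternative convention — the two differ
substantially (0.21 between-variance gives 0.174 vs 0.060), which is
why the scale is an explicit argument rather than a constant.

The 95% CI for Gaussian-model ICCs is a parametric bootstrap: simulate
from the fitted model, refit, take 2.5/97.5 percentiles. Refitting uses
`lme4::lmer` (ML) or, for balanced intercept-only designs, a
closed-form one-way ANOVA moment estimator that is orders of magnitude
faster; the two agree on balanced data and the fast engine refuses
covariate or unbalanced models. Percentile intervals for a variance
ratio at ~17 groups undercover mildly (measured ≈ 0.90–0.95 at nominal
0.95 in the package's own coverage simulation); this is a property of
the percentile method at this group count, not a defect of the
implementation, and the coverage test bounds it accordingly.

Power simulation draws participant-day data from the random-intercept
model with a truncated-normal sleep predictor and counts Wald
rejections of the slope. At the 17 × 11 design with between/within
variances 2404.27/1440.80, slopes of −1 to −2 outcome units per
predictor unit land in a 10–50% power band while −5 is detected
essentially always — the regime in which only large nightly
sleep-cognition effects are detectable.

# The synthetic-data generator

**What it emulates.** (i) Hypnograms: a first-order Markov chain over
{W, N1, N2, N3, REM} in 30-s epochs. The default matrix is built from
target stationary fractions (taken from the stage-minute scale of
multi-night recordings in older adults over an 8-h time in bed:
W 0.105, N1 0.074, N2 0.455, N3 0.138, REM 0.228) and per-stage
persistences (wake bouts ≈ 1–3 min, long consolidated N2), through
`P = diag(p) + (1 − p) q′` with `q_j ∝ π_j (1 − p_j)`, which makes the
target exactly stationary. Full simulated nights average ≈ 64–66 min
N3 and ≈ 45–49 min WASO; mean TST is ≈ 430 min, about 3% above the
target scale, because a stationary chain cannot additionally produce a
distinct sleep-onset latency — accepted as a known simplification.
(ii) Background EEG: 1/f (exponent 1) Gaussian noise at 15 µV RMS with
extra 0.5–2 Hz noise (5 µV RMS) during N3. (iii) Events: SOs as
negative + positive half-sine pairs (mean p2p 86.5 µV, SD 6) and
spindles as Hann-windowed sinusoids (12–14 Hz, ~1 s, peak 20 µV,
SD 2), placed uniformly over N2/N3 epochs with rejection sampling, a
0.5-s guard gap and Poisson counts at 4.2/min (SO) and 1.5/min
(spindle). (iv) Behavior: outcomes from the same random-intercept model
the analysis fits, Gaussian or zero-inflated beta.

**Amplitude semantics.** Injected SO amplitudes are defined on the
detection scale — the peak-to-peak the event shows after the
0.3–40 Hz + 0.3–4 Hz chain — and the injector rescales the raw
waveform by the chain's measured attenuation for that template. This
mirrors physiology (a raw SO is larger than its narrowband image) and
keeps "inject an 86.5 µV event" meaning what the detector criteria
mean by 86.5 µV. Sub-threshold probes are built the same way
(`so_template()` is exported).

**What it does not emulate,** hence what passing tests do not show
about real data: no real EEG spectra beyond 1/f plus events (no alpha
intrusions, no arousals, no movement or electrode-pop artifacts beyond
the amplitude rule's reach), no stage-transition spectral dynamics, no
inter-participant differences in event morphology, no circadian
structure within the night, and behavioral outcomes with exactly the
fitted model's structure. Recovery results are therefore statements
about the pipeline's correctness at a realistic SNR (reported with
every recovery figure: 15 µV-RMS background), not about detector
performance on dry-electrode field recordings.

**Seeds.** One master integer fans out to per-night, per-replicate
sub-seeds through a small multiplicative-congruential mixer
(`derive_seed()`), all below 2³¹; identical spec + seed gives
bit-identical hypnograms, signals and outcome tables.

# Problem sizes used by the tests

The suite runs entirely on synthetic data sized for thorough but
proportionate checking: detector recovery uses 10 independent 10-min
nights (~75–90 min of N2+N3, ≈ 350 SOs and ≈ 130 spindles); the
specificity check 6 × 10 min of event-free background; type-I control
60 null cohorts of 17 × 11; large-sample variance recovery 10 cohorts
of 100 × 50; bootstrap coverage 100 outer replications × 200 boots
(fast moment-estimator engine); power 150–300 simulations per slope.

# Known limitations

* The Markov hypnogram has no sleep-onset latency or ultradian cycling;
  WASO and efficiency are realistic on average but not in within-night
  structure.
* Spindle detection thresholds were calibrated on the synthetic
  background; on real dry-electrode data they would need re-tuning (the
  same caveat the underlying algorithm family carries for new
  montages).
* The EDF writer/reader implements the subset of EDF this pipeline
  needs (16-bit, one record/s, µV); it is not a general EDF+ library.
* Bootstrap CIs are unavailable for the zero-inflated beta family, and
  the latent-ICC scale convention materially changes the value — both
  conventions are reported rather than adjudicated.
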