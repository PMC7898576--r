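---
title: "Modelling rhythmic attention and pupillometric entrainment with pupilbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rhythmic attention and pupillometric entrainment with pupilbeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pupilbeat` implements a complete simulation-and-analysis chain for
deviance-detection experiments with looping rhythmic stimuli: a linear
oscillator model that converts audio into a temporal salience prediction, a
forward convolution model of the continuous pupil signal, a ZEST adaptive
threshold procedure with a simulated observer, pupillometry preprocessing
with evoked-response extraction, and a phase-coherence entrainment analysis
with a shuffled-stimulus null. This vignette records the scientific and
numerical decisions behind each stage — what is assumed, what is tunable,
and what the synthetic data do and do not establish.

## The oscillator model

The model embodies dynamic attending theory's central claim: attention
oscillates, and entrains to the periodicities present in the input. Its
front end splits audio into 40 band-pass channels whose centers are spaced
on the ERB (auditory) scale from 141 to 8877 Hz; channels are 2nd-order
Butterworth band-passes between the ERB midpoints of neighbouring centers,
applied forward-backward, followed by 10 ms frame RMS, which fixes the
model rate at 100 Hz. This is a deliberately transparent stand-in for a
full auditory-nerve simulation: the downstream contract is only the
40-band RMS envelope, and a documented filterbank keeps the package
dependency-free and the tests exact. Onsets are the half-wave rectified
first difference of each envelope — an edge detector per band — and the
40 channels are averaged in contiguous groups of 8 into 5 bands.

Each band then drives 99 *reson* filters: two-pole damped resonators

$$y[t] = g\,x[t] + 2r\cos(\omega_0)\,y[t-1] - r^2\,y[t-2]$$

with constant-Q damping $r = \exp(-\pi f / (Q\,r_s))$, $Q = 10$, input gain
$g$ normalized so a sinusoid at the tuned frequency passes at unit
amplitude, and tuned frequencies log-spaced over 0.25–10 Hz. Constant-Q
log spacing gives uniform resolution in musical (ratio) terms; $Q = 10$
means an oscillator rings for roughly ten cycles, long enough to integrate
metrical evidence while still tracking change. Both choices are
configurable (`reson_bank()`); the literature the architecture descends
from does not pin them down, so they are explicit parameters rather than
constants.

A 2 s / 10 ms-hop sliding RMS of the filter outputs forms per-band
periodicity surfaces; the 2 s window covers at least one full cycle of
every periodicity down to 0.5 Hz and about one cycle of the bar at
moderate tempi. Surfaces are averaged across bands and over time into the
mean periodicity profile (MPP). Peak periodicities are strict local maxima
of the 99-point profile exceeding 5% of the profile's amplitude range above
its minimum; plateaus resolve to their lowest-frequency sample, endpoints
are never peaks, and an all-flat profile has no peaks (an empty peak set is
a legitimate result, not an error — only `temporal_salience()` refuses to
mask on it).

One point deserves emphasis because it shapes several tests: an impulse
train at $f$ drives *all* of its harmonics with equal Fourier amplitude,
and each reson filter is unit-gain at its own tuned frequency, so
harmonically rich onset trains ring the 2 Hz, 4 Hz, … filters comparably.
The informative statement about a 2 Hz train is therefore that the peak
*nearest the stimulus rate* falls on the filter nearest 2 Hz — not that
2 Hz dominates the whole profile.

### Resonator amplitude

"Mean resonator amplitude" needs an operational definition. The package
uses the instantaneous amplitude of the analytic signal (FFT-based Hilbert
transform) of each filter output, averaged point-wise over the selected
(band, filter) pairs; full-wave rectification is available as
`amplitude = "rectified"`. Rectification superimposes ripple at twice each
filter frequency on the salience series; the analytic amplitude measures
how strongly the oscillator is ringing without that artifact, and brings
the peak-masked salience into close correspondence with the amplitude
envelope on metrically plain patterns (aligned correlations of roughly
0.7–0.85 on the shipped presets, computed in the test suite). Patterns
whose accents sit off the energy grid — the offbeat- and
double-time-accented presets — correlate more weakly by design: masking to
peak periodicities encodes meter, not instantaneous energy, and that
divergence is precisely the model's scientific content.

### The salience series

The one-loop salience series is cut from the final loop of a run over
`loops` tiled iterations (default 10), so the oscillators are in steady
state; with $Q = 10$ the slowest filters (0.25 Hz, ~4 s ring time) have
settled well before the final loop. The series is nonnegative and has one
sample per model frame (a 2.243 s loop at 100 Hz is 224 frames; loop
durations are not generally integer multiples of the frame, so lengths are
rounded and stated ±1 sample).

## The pupil forward model

The pupillary response function is an Erlang gamma,
$h(t) = t^{n} e^{-n t / t_{max}}$, with the non-motor parameterization
$n = 10.1$ (sequential neural signalling steps) and $t_{max} = 512$ ms
(peak latency without a button press); $dh/dt = 0$ at exactly
$t = t_{max}$, which the tests verify on a 1 ms grid. The kernel is
peak-normalized because its output units are arbitrary — downstream
comparisons z-score everything — and truncated where it decays below 0.1%
of its peak, about 1.36 s at the defaults. The ~1300 ms empirical
return-to-baseline delay is carried as metadata
(`return_to_baseline_ms`); truncating on the decay fraction rather than at
that fixed delay keeps the rule valid for any $(n, t_{max})$, e.g. the
930 ms motor variant.

Prediction tiles the one-loop salience `n_loops` times, convolves linearly
(FFT), discards the first kernel length of output rather than convolving
circularly — the discarded segment is the onset transient that a listener
in continuous audio does not experience — and mean-centers. Mean-centering
makes predictions comparable across variants but means shift-equivariance
holds only up to a constant, a detail the property tests account for.

## The adaptive experiment

Scheduling and inference are deliberately separated: `schedule_run()` owns
the stimulus grammar (80% chance of a deviant after a standard loop,
always a standard after a deviant, four probed positions cycled without
replacement in blocks of four, quota of 20 deviants per position, one
closing standard loop), and `run_experiment()` consumes the schedule with
four independent ZEST trackers. ZEST maintains a discretized density over
threshold on a −10…30 dB grid with 0.1 dB steps, starts from a Gaussian
prior with mean 10 dB (the starting difference limen) and SD 6 dB, presents
each trial at the posterior mean, and multiplies in a likelihood
$P(\mathrm{yes} \mid L,\theta) = \gamma + (1-\gamma-\lambda)\,
\Phi((L-\theta)/\sigma)$ with $\gamma = \lambda = 0.02$ and
$\sigma = 2$ dB. These family parameters are conventional psychophysics
defaults, exposed as arguments because the procedure's source description
does not fix them; the simulated observer uses the same functional form
with its own (independent) parameters, plus a lognormal response time so
that responses slower than the 1000 ms scoring window count as misses.
Presented levels are clipped to 0–30 dB (physical presentation limits) and
flagged when clipping occurs. With a near-step observer the procedure
recovers the true threshold to within one grid step in 20 observations;
with a 2 dB-slope stochastic observer the replicate-mean bias stays within
±1.5 dB (both computed in the test suite).

## Synthetic data: what is emulated, and what is not

The generator ships five deterministic 16-position presets at 107 BPM
(140 ms grid, 2.243 s loops) built from three timbres — snap-like (~2 kHz),
shaker-like (~6 kHz) and conga-like (~200 Hz) noise/tone bursts with
10–80 ms exponential decays — chosen to drive the 5-band front end
differentially. Each preset carries a dynamic accent cycle: onset
velocities wax and wane at one characteristic metrical harmonic (bar,
half-note, dotted, beat, double-time), so the presets' mean periodicity
profiles emphasize different sub-3 Hz peaks. This mirrors a varied battery
of drum loops; it also matters analytically, because magnitude-squared
coherence is scale-invariant per frequency bin — if every stimulus shared
one peak set, the shuffled-stimulus null would equal the true coherence by
construction and the true-vs-null contrast would be meaningless for any
noise level. Rendering is circular (burst tails wrap to the loop start),
which makes a rendered loop the exact steady state of continuous looping:
concatenated copies are seamless, sample for sample, whenever the loop
duration is a whole number of samples.

Synthetic pupil logs are the tiled convolved prediction expressed in
arbitrary eye-tracker units (baseline 1000, gain 30), plus a slow ~0.01 Hz
sinusoidal drift (amplitude 15 units), white noise (SD 4 units), and
Poisson blinks (0.1 Hz) realized as 100–300 ms missing runs flanked by
±60-unit spikes and saccade flags — the artifact morphology the
preprocessing rules are designed to remove. With all three noise sources
at zero the log is exactly the resampled prediction, which closes the loop
with the coherence analysis (self-coherence 1). What the generator does
*not* emulate: luminance responses, gaze-position crosstalk, cognitive
fluctuations, non-stationary entrainment, or any deviation of the
listener's attention dynamics from the model's own prediction. Passing
tests therefore demonstrate that the pipeline is correct and sensitive
under the model's assumptions — not that real pupils behave this way.

## Entrainment statistics

Welch cross-spectra use 4.4 s windows with 75% overlap and a periodic Hann
taper, each segment demeaned, density-scaled by $1/(r_s \sum w^2)$; at
100 Hz the bin resolution is ~0.227 Hz. The pupil is resampled 500 → 100 Hz
(zero-phase anti-alias low-pass at 80% of the target Nyquist, then
decimation) so both signals share a bin grid. Coherence
$C(f) = |P_{xy}|^2 / (P_{xx} P_{yy})$ is clipped to [0, 1] against
floating-point excursions and returned as `NA` where an auto-spectrum is
zero. The estimate is biased upward by ~$1/n_{segments}$ for independent
signals and is identically 1 with a single segment — run lengths should
keep dozens of segments, and the package's own simulations use 60–380 s.

Peak-band summaries average coherence at the Welch bin nearest each MPP
peak below 3 Hz (no interpolation; at 0.227 Hz resolution the nearest-bin
error is below half a bin). For the shuffled-stimulus null, each other
stimulus's prediction is evaluated **at that stimulus's own peak
frequencies** — the null asks "does this pupil cohere with stimulus B the
way a pupil recorded to B should" — with `peaks = "own"` available for the
alternative reading (evaluate every pairing at the recorded stimulus's
peaks). The paired true-vs-null comparison is a standard paired t-test,
generic over the number of runs.

`delta_aic()` rescales a vector of AIC values by subtracting the minimum,
so the preferred model maps to exactly 0; it is the utility used when
comparing threshold predictors fitted externally (mixed-effects model
fitting itself is out of scope — the pipeline exports tidy trial and
feature tables for it).

## Preprocessing details and degenerate inputs

The 20-unit jump threshold refers to the generator's arbitrary pupil
units and is a parameter, as real trackers differ in scale. Leading and
trailing missing runs are filled by nearest-valid-value extension
(interpolation has no second anchor there); the choice is flagged in the
trace metadata. The 0.05 Hz high-pass is applied forward-backward so
event-locked latencies are not shifted; a trace shorter than 60 s triggers
a warning because the filter barely resolves its own cutoff there.
Z-scoring a constant trace is an error (zero variance), as is finalizing a
ZEST track before its quota, inserting a deviant window that would wrap
across the loop boundary, and computing a paired t on zero-variance
differences. PDR velocity is the two-point slope from the onset sample to
the epoch maximum (deterministic, unlike a regression fit) and defined as
0 when the maximum sits at onset. When the scaled MAD is zero but values
differ, only exact-median values are kept, with a warning.

## Problem sizes

The shipped tests and the acceptance script run the audio chain at 20 kHz
with 6–10 loop iterations per stimulus, simulate 10 participants × 3
stimuli × 140 loops for the entrainment recovery study, 200 replicate runs
for ZEST parameter recovery, and a ~12,500-loop schedule for the
scheduling-rate simulation. These sizes give stable statistics (binomial
99% intervals, replicate SDs) while keeping a full run in the low minutes
on one core; all are parameters, not limits.

## Known limitations

The cochlear front end is an envelope filterbank, not a nerve model;
compressive nonlinearities and adaptation are absent. The reson bank is
linear, so it cannot show the subharmonic/mode-locking phenomena nonlinear
oscillator models produce. The 5% peak rule has no hysteresis: peaks near
threshold can enter or leave the set under small stimulus changes, and
downstream peak-masked salience changes discretely when they do.
Scheduling assumes the four probed positions fit the no-wrap deviant
constraint (probe time + 200 ms inside the loop). Null coherence with few
stimuli rests on their peak sets actually differing; with near-identical
stimuli the contrast is structurally near zero, as discussed above.
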