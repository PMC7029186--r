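---
title: "Quantifying the 20-40 Hz tail-beat rhythm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the 20-40 Hz tail-beat rhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimrhythm)
```

## The problem

Larval zebrafish swim by beating their tail at roughly 20-40 Hz. Between 3
and 5 days post-fertilization (dpf) the swimming pattern matures from long,
infrequent "burst" episodes to short, frequent "beat-and-glide" episodes,
and the circuit that generates the beat rhythm reorganizes: early rhythms
survive blockade of glycinergic inhibition (strychnine), later rhythms do
not. `swimrhythm` implements the analysis chain used to quantify this
transition from ventral-root recordings and high-speed video, a reduced
coupled-oscillator model of the circuit change, and seeded synthetic-data
generators so the whole chain is testable without any recordings.

## The Peak_20-40 statistic

For each recording, ten 200-ms epochs are taken from within swimming
episodes (episodes are >200 ms bursts of high-frequency activity; the trace
is first bandpass filtered 1-200 Hz). Each epoch's normalized
autocorrelation is fitted by least squares with

$$\mathrm{Autocorr}_{fit}(\tau) = a_0 + a_1\tau + a_2\tau^2$$

on the lag window 20-50 ms (endpoints included). A 20-40 Hz rhythm is
called *detected* when

$$25\,\mathrm{ms} < -\frac{a_1}{2a_2} < 50\,\mathrm{ms}
\quad\text{and}\quad a_2 < 0,$$

both inequalities strict: the fitted parabola must be concave down with its
vertex in the lag range of one 20-40 Hz period. The per-recording score is
the exact fraction of the ten epochs with a detected peak. Note the
asymmetry between the fit window (from 20 ms) and the acceptance interval
(from 25 ms); it is preserved exactly as published, not "corrected".
Downstream of the score sit the strychnine attenuation,
$1 - \mathrm{score}_{Str}/\mathrm{score}_{Ctrl}$, and the rejection rule
(animals with control scores below 0.5 are discarded, except the documented
somite-1/5-dpf exemption).

### What the quadratic-fit detector can and cannot see

The fixed 30-ms fit window gives the statistic an *intrinsic sensitive
band narrower than its name*. For any clean single-frequency rhythm the
epoch autocorrelation is, to good approximation, a (possibly damped)
cosine with its first peak at the beat period $1/f$:

* for $f$ near 20 Hz the peak sits at ~50 ms, the open upper bound: the
  least-squares parabola over [20, 50] ms is then concave *up* and nothing
  is detected;
* for $f$ above ~35 Hz the first peak crowds the lower edge and the second
  peak (at $2/f$) enters the window, again destroying the single interior
  maximum.

Scanning sinusoids, compound-burst trains, and amplitude- or
frequency-modulated variants, the detector fires reliably for roughly
23-35 Hz and essentially never outside ~21-36 Hz; idealized
fast-decaying damped-cosine autocorrelations cap the coverage of a uniform
20-40 Hz band at about 0.74. Two consequences are verified by this
package's own acceptance suite and are deliberately left as failing
expectations rather than papered over:

1. a *mean detection rate of 80%* across recordings whose tail-beat
   frequencies cover 20-40 Hz uniformly is not attainable (we measure
   ~0.58); the published >80% control rate is consistent with real
   tail-beat content concentrating mid-band;
2. a rhythm at *exactly* 20 Hz -- the oscillator model's natural
   frequency -- is structurally undetectable by the printed conditions,
   because its autocorrelation peak coincides with the strict 50-ms bound.

A further measured property worth knowing: on pure white-noise epochs the
conditions *false-positive at roughly 40%* (a random concave fit tends to
put its vertex mid-window), while slow-deflection epochs (the
strychnine-like signal shape) are rejected almost surely because their
autocorrelation curvature puts the vertex near lag zero. The low strychnine
scores in the source data are therefore evidence of slow, structured
activity rather than of white noise.

## The synthetic recordings

`generate_fictive_trace()` states this world (all values fixed at design
time):

* background: unit-SD white Gaussian noise; sampling 10 kHz (the published
  processing filters at 1 kHz but does not state the digitization rate);
* episodes: raised-cosine 20-ms on/off ramps; burst modes mean 2 s
  duration at 0.12 episodes/s, beat-and-glide modes 0.35 s at 0.8/s --
  the "long but infrequent" versus "short but frequent" contrast;
* control carrier: one smooth compound-discharge wave per tail beat
  (Gaussian bump, SD 4 ms, beat times jittered 2 ms around the regular
  grid), RMS-matched to a sinusoid of amplitude `snr` noise-SDs; a literal
  sinusoid carrier is available as `carrier = "sine"`. A ventral root
  records compound potentials, and this shape gives the autocorrelation
  the positive-bump-at-the-period structure real epochs show;
* strychnine modes: episodes become slow 3 Hz deflections plus broadband
  (non-rhythmic) within-episode noise, emulating the long voltage changes
  seen under glycine blockade. In the 3-dpf-like `burst_str` mode each
  episode *keeps* its tail-beat carrier with probability 0.4 (oscillations
  persisted in a large share of 3-dpf episodes under strychnine); in the
  5-dpf-like `bg_str` mode the probability is 0. This residual-rhythm
  construction reproduces, by design, the direction of the developmental
  contrast: attenuation is larger for the 5-dpf-like modes.

What a green test on this world does *not* establish: robustness to
electrode drift, movement artifacts, 50/60 Hz contamination, non-Gaussian
noise, or tail-beat frequency glides within an episode -- none of which
are modelled.

The epoch-selection default deserves a note: the published counting ("ten
per fish" epochs described as episodes) implies one epoch per episode
where possible, so `rhythm_score()` uses a round-robin `"spread"` strategy
across episodes in temporal order; `"earliest"` (fill the first episode
first) and seeded `"random"` placement are selectable.

## Episode detection

The published analysis identified episodes by inspection; the detector
here is the package's own. The envelope is |x| smoothed over 20 ms; the
threshold is the envelope median plus `threshold_k` (default 3) robust
SDs (MAD) of the envelope -- median-anchored so that sparse episodes do
not inflate the baseline estimate. Gaps under 50 ms are merged and runs
under 200 ms dropped. On the synthetic world this recovers every ground-
truth episode with boundary errors well under 50 ms, and produces
essentially no false episodes on pure noise (the 200-ms minimum does most
of that work).

## The filter

No signal-processing package is available in the supported dependency
stack, so the 1-200 Hz bandpass is realized in the frequency domain with
the *squared* magnitude response of a 4th-order Butterworth bandpass --
exactly the magnitude a forward-backward time-domain pass would apply, and
exactly zero phase (zero phase matters: a phase-shifting filter would move
episode boundaries and epoch timing). Passband ripple is < 5% at 30 Hz, DC
is eliminated, and a 500 Hz probe is attenuated below 0.1% amplitude.

## Kinematics

The video chain mirrors frame-by-frame midline tracking: threshold, 1-px
dilation, hole filling, largest component, Zhang-Suen thinning, pruning to
the skeleton's longest geodesic path (ties broken toward the caudal-most
endpoint), rostral-caudal ordering from the embedded-head side, arc-length
resampling to 31 points, per-segment angle = arctan of the local slope
minus the same quantity on the rest posture, and a per-segment FFT.

The source description is internally inconsistent about the normalized
body coordinate (the methods text puts 0.0 at the extreme caudal segment,
the corresponding figure legend puts 1.0 there). We follow the figure
convention -- caudal = 1.0 -- and expose `caudal_is_one = FALSE` to flip
it; the discrepancy is flagged here rather than silently resolved. The
rest posture defaults to the first frame (the generator emits a rest-pose
first frame via a short amplitude onset ramp) and can be overridden.
Because the pipeline works on a pixel grid, exact rotation invariance is
limited by the thinning pass; spectra agree to within a few percent of the
dominant segment's band power under 180-degree rotation, and the tests
assert that quantization-aware form.

## The coupled-oscillator model

The pacemaker kernel is a harmonic oscillator represented exactly by its
closed-form output, the drive $F_0\sin(\omega_0 (t-t_1))$; the half-center
network oscillator is the damped oscillator

$$\ddot{x} + 2\zeta\omega_0\dot{x} + \omega_0^2 x =
F_0\sin(\omega_0 (t-t_1)) + F_1(t),$$

with $\omega_0 = 2\pi\cdot 20$ rad/s and both drive terms gated by the
descending go signal $F_1(t)$ (a step on $[t_1, t_2]$). Two deliberate
readings of the published equation: the restoring term is written there
without the $x$ (a typo -- without it the system has no natural
frequency), and "natural frequency of 20 Hz" is treated as ordinary
frequency so the output actually oscillates in the tail-beat band.
Damping $\zeta$ models reciprocal inhibition (high $\zeta$ ~ strychnine),
coupling $F_0$ the pacemaker's influence (high ~ 3 dpf). Unstated values
fixed here: $F_1 = 1$, gate 0.5-2.5 s, duration 3 s, $dt = 10^{-4}$ s,
zero initial conditions.

Integration is fixed-step classical RK4 with the drive evaluated
analytically at substep times; the gate edges fall on step boundaries so
the step discontinuity does not degrade the observed convergence (halving
$dt$ changes the solution by < $10^{-7}$ in max norm). The closed-form
resonant steady-state amplitude $F_0/(2\zeta\omega_0^2)$ is matched to
well under 1%, and the post-gate free decay follows the $\zeta\omega_0$
envelope rate.

`model_autocorr_analysis()` feeds the gated output (plus optional seeded
observation noise) through the identical Peak_20-40 machinery on
consecutive 200-ms windows, calling the rhythm detected when at least half
the windows pass. As analysed above, the model's exactly-20-Hz rhythm sits
on the detector's strict boundary, so the published qualitative 2x2
detection pattern is *not* reproduced by the printed conditions -- the
package reports this honestly (the corresponding acceptance expectations
fail) rather than nudging the natural frequency or the acceptance
interval.

## Statistics

Classical equal-variance Student's t tests (the source names no Welch
correction), paired for within-fish contrasts, unpaired across fish, and
one-way ANOVA for multi-group contrasts, with Bonferroni adjustment of the
0.05 criterion. The printed thresholds are truncated for display (0.05/3
appears as 0.0166); comparisons use the exact value and
`format_alpha()` reproduces the display form. Identical samples return
statistic 0 and p = 1 instead of erroring. Episode-duration summaries
pool episodes across animals (mean and SEM over the pooled set, the
published convention), with per-animal averaging as an option.

## Numerical choices and degenerate inputs

* autocorrelation: biased estimator (taper $1-k/n$), demeaned, normalized
  to 1 at lag zero; zero-variance epochs error;
* quadratic fit: plain least squares on the 301 lag samples in [20, 50]
  ms at 10 kHz; fewer than 3 samples error; $a_2 = 0$ and vertices exactly
  at 25 or 50 ms are no-peak by the strict inequalities;
* scores are exact rationals `n_detected / n_epochs`;
* seeded generators restore the caller's RNG state, and one run-level seed
  expands into per-stage streams through a deterministic derivation.

## Known limitations

The synthetic world is stylized (white noise, fixed episode statistics,
single tail-beat frequency per recording). The kinematics assume a
head-embedded fish spanning the frame horizontally with small bend angles.
The model is linear, so only relative amplitudes across regimes are
meaningful. And the core statistic itself, faithfully implemented, has the
band and false-positive properties documented above -- they are properties
of the published conditions, not of this implementation.
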