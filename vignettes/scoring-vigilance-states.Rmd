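---
title: "Scoring vigilance states from fixed frequency profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring vigilance states from fixed frequency profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigiscore)
```

## The scoring model

`vigiscore` assigns one of seven vigilance states — three awake substates
(a1/a2/a3, dominated by delta, theta and alpha band power respectively),
REM, and three non-REM grades — or a noise label to every epoch of a
rodent EEG recording. The model rests on two assumptions:

1. **Frequency profiles are fixed.** The spectral fingerprint of each
   state recurs across animals and datasets, so the rule bands and
   ratio cutoffs are constants, not fitted parameters. Only the noise
   bounds vary between recordings (amplifier gain and electrode
   impedance differ) and are therefore exposed for manual adjustment.
2. **Muscle tone disambiguates wake from sleep.** Theta-dominated
   wakefulness and REM sleep have near-identical spectra; what separates
   them is neck-muscle tone. A change-point segmentation of the summed,
   squared, high-pass-filtered EMG splits the recording into tense and
   relaxed macro-states before any spectral rule is applied. The gate is
   the "semi" in semi-automatic: detected transitions should be checked
   visually, and `apply_manual_overrides()` accepts interval edits
   (`start`, `end`, `state`) recorded with manual provenance.

Per epoch, the decision order is: noise test, then macro gate, then
either the awake band-sum argmax (tense) or the REM comparison followed
by the nREM ratio ladder (relaxed). REM is tested before the ladder
because a theta-dominated sleep epoch can also satisfy a ladder
inequality; this precedence makes the rules total and exclusive, so a
label always exists and `U` (unscored) can never be emitted by the
scorer.

### Boundary conventions

Band membership is half-open, `lo <= f < hi`, so the printed awake bands
(0.2–3, 3.2–6, 6.2–12 Hz) never double-count a bin and the small gaps
between them (3–3.2, 6–6.2 Hz) belong to no band, matching the printed
edges literally. In the nREM ladder the printed "10–20 times" is read as
closed at 20 and open at 10 (`r > 20` slow-wave, `10 < r <= 20` nREM2,
`r <= 10` nREM3): an epoch sitting exactly on a boundary receives the
deeper-sleep label. A tie in the awake argmax goes to the
higher-frequency band (a3 over a2 over a1), consistent with the resting
state requiring dominant alpha. A zero 20–24 Hz denominator is treated
as an infinite ratio (slow-wave sleep). These conventions are exercised
directly against an independently written brute-force transcription of
the rules in the test suite.

### Spectral estimation

Epochs are mean-removed, zero-padded to at least `fs / 0.2` samples and
transformed with a plain (untapered) FFT. Zero-padding to a 5 s
equivalent gives every epoch length in {0.5, 1, 5} s the same 0.2 Hz bin
grid, so the rule-band edges land exactly on bins — the rules compare
summed profile shape, not variance, so no taper is needed. Welch's
method (Hann window, 50% overlap, one-sided density scaling) is used
where a calibrated density is wanted: the aperiodic fit and the
per-state spindle-band PSD. Both estimators locate the same peak for
narrowband signals, which the tests assert.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `epoch_len` | 1 | s | native rule resolution; 0.5 and 5 supported |
| `target_fs` | 256 | Hz | scoring copy rate; anti-aliased, keeps all rule bands below Nyquist (no rate is mandated by the method, this is a choice) |
| `noise_low`, `noise_high` | 1e-3 / 1e3 × median epoch power | a.u. | recording-specific; any value used is reported |
| `nrem_hi_ratio`, `nrem_lo_ratio` | 20, 10 | — | the fixed ladder cutoffs |
| EMG window | 1 | s | aligns the tone envelope with the default epoch grid |
| change-point penalty | 3·log(n)·var(env) | — | scales with envelope variance, so detection is invariant under gain changes |
| minimum macro-segment | 10 | s | the envelope is noise-sensitive; shorter detected segments merge into the neighbor with the closer mean |

Downsampling uses an 8th-order zero-phase Butterworth at 45% of the
target rate followed by spline interpolation onto the exact output grid,
which supports arbitrary (even irrational) rate ratios while preserving
total duration to within one output sample.

The change-point model is an exact penalized least-squares segmentation
(L2 cost, dynamic programming over all segmentations); tense/relaxed
assignment thresholds segment means at the midpoint of their two
clusters from a deterministic 1-D two-means split. With no
within-recording contrast (a single cluster) the envelope carries no
absolute tone scale, and the gate defaults to relaxed unless a
calibrated `tense_floor` is supplied. Without any EMG channel the gate
falls back to per-epoch total spectral power (sleep carries more power
than wake), resolving the REM/a2 ambiguity toward awake — a documented
limitation, since muscle tone is the principled separator.

## The analysis battery

* **Wavelet coherence** (`coherence_profile`): analytic Morlet
  (ω₀ = 6, 12 voices per octave) on a logarithmic 0.5–70 Hz grid;
  cross- and auto-spectra are smoothed in time (Gaussian of the wavelet
  scale) and across scale (boxcar over 0.6 octave) before the magnitude
  ratio, then averaged over time. Coherence is bounded in [0, 1],
  identically 1 for identical inputs, and the cone-of-influence edges
  are trimmed before time-averaging.
* **PACz** (`pacz`): raw coupling is the mean-vector modulation index
  |mean(A·e^{iφ})| with phase from a ±1 Hz band at 1–15 Hz and amplitude
  from a ±8 Hz band at 30–50 Hz (wide enough to pass every modulation
  sideband). The null is 100 seeded circular time-shifts of the phase
  series — preserving both marginals — and PACz is the z-score against
  that null. Fixed seeds give bit-identical output.
* **DFA** (`dfa_alpha`): fluctuation of the integrated, mean-removed
  series over 20 logarithmically spaced window sizes spanning 1–20% of
  the series, linear detrend per window, α from the log–log slope. Log
  spacing gives even leverage in the fit. At the largest scales few
  windows remain and detrending absorbs fluctuation, so α carries a
  small negative finite-size bias (white noise reads ≈ 0.47–0.50 at
  n = 10⁵); this is inherent to the fixed 1–20% range.
* **Banded DFA / fE/I** (`banded_dfa`, `fei`): per center frequency, a
  ±20% relative band (raised-cosine edges — a brick-wall filter's 1/t
  impulse-response tails would masquerade as long-range correlation),
  amplitude envelope via the analytic signal, DFA on the envelope. The
  smallest scale is floored at five envelope correlation times
  (5/(bandwidth)), below which DFA measures the filter, not the signal.
  fE/I is 1 minus the correlation between per-window (5 s,
  non-overlapping) mean amplitude and amplitude-normalized detrended
  fluctuation; it is only interpretable in the presence of long-range
  correlations, so bands with α < 0.6 return an invalid flag and no
  number. The shuffled-amplitude surrogate averages over 200
  permutations (a single permutation's correlation has standard error
  1/√n_windows, far too noisy to certify the expected value of 1).
* **Aperiodic exponent** (`aperiodic_exponent`): robust log–log
  regression of the Welch PSD over 0.5–65 Hz with iterative exclusion of
  points more than 2.5 negative-residual SDs *above* the fit —
  oscillatory peaks ride on top of the 1/f background, so only upward
  outliers are removed. Pure power laws are recovered exactly; one
  additive Gaussian peak perturbs the exponent by less than 0.1.
* **Spindles** (`detect_spindles`): 8–18 Hz FIR band-pass (quarter-second
  kernel, short enough that zero-phase filtering cannot smear a
  sub-criterion burst past the 0.5 s minimum), z-score, Hilbert
  envelope, envelope standardized (a Rayleigh envelope sits above one
  signal-SD most of the time, so thresholds are in envelope SD units).
  Events run from the 1 SD up-crossing to the return below 1 SD and are
  kept when the peak exceeds 3.5 SD and the duration lies in [0.5, 2] s.
  Under a Gaussian background the false-positive rate is at or below
  about 0.2 events/min, asserted in the tests.

Label analytics use the sample (n−1) standard deviation in the
coefficient of variance (animal groups are small), Bonferroni over the
unique off-diagonal cells in the correlogram, and per-frequency Welch
t-intervals Bonferroni-corrected across the evaluated frequencies in the
difference-wave test — a deliberately conservative family-wise
guarantee, verified at ≤ 5% on a 1000-replicate null in the tests.

## The synthetic generator

`synth_recording()` emulates exactly what the scorer consumes: per-state
spectral fingerprints (a 1/f background of state-specific exponent plus
fixed-amplitude oscillatory peaks), an EMG channel whose tone contrasts
5:1 between wake and sleep, spindles injected at 0/2/5 events·min⁻¹ in
nREM1/2/3, and instantaneous transitions at epoch boundaries (rodent
state switches are near-instant). Design choices worth recording:

* Peaks are fixed-amplitude sinusoids at integer or half-integer
  frequencies completing whole cycles within every supported epoch
  length, and the 20–24 Hz floor of the nREM grades is a single 22 Hz
  tone: band powers are then phase-independent and the low/high ratio
  concentrates tightly around the geometric midpoint of each ladder rung
  (≈ 14 for nREM2, ≈ 5 for nREM3), so each recipe satisfies its own rule
  in ≥ 95% of draws — asserted by `recipe_self_check()` for every
  default recipe.
* The a2 (theta awake) peak sits at 5 Hz: the scoring band is half-open
  at 6 Hz, and a peak on the excluded edge would leak half its power out
  of band.
* The default 10-minute schedule uses bout durations that are multiples
  of 5 s so that 0.5, 1 and 5 s epoch grids tile it identically, and
  every wake/sleep bout exceeds the gate's 10 s minimum segment.
* The PAC fixture's modulating rhythm is a narrowband *noise* oscillator,
  not a pure sinusoid: a circularly shifted deterministic phase series
  would remain phase-locked to a periodic amplitude, silently breaking
  the surrogate null.
* Relative wake/sleep power levels follow the qualitative ordering that
  sleep carries more low-frequency power than wake; the exact scaling is
  a choice.

What the generator does **not** emulate: waveform morphology
(K-complexes, epileptiform discharges, movement artifacts beyond
amplitude excursions), non-stationarity within a state, volume
conduction between channels, or realistic inter-animal variability.
Passing the round-trip tests therefore certifies the rule engine, the
gate, and the analytics against their specifications — not scoring
accuracy on real animals, which is bounded by how well real states
respect the fixed profiles.

## Problem sizes and runtime choices

The validation battery runs at desk scale: DFA calibration on 10 seeded
series of 10⁵ samples; the rule-engine oracle on 10,000 random band
configurations; the end-to-end round trip on a 10-minute, 256 Hz,
three-channel recording scored at all three epoch lengths; PACz
calibration on 30 s fixtures with 50 null repeats; and a 1000-replicate
difference-wave null. These sizes keep the full suite under a minute of
compute while leaving every statistical check with comfortable margins.
The O(n²) change-point program is sized for envelopes of a few thousand
windows; day-long recordings at 1 s windows should be gated in chunks
(e.g. per hour) or with a coarser envelope window.

## Known limitations

* The fixed profiles are the model: animals or preparations whose
  spectra violate them (e.g. strong seizure activity inflating
  high-frequency power) will be mis-graded toward a3/nREM3, and
  epileptiform activity is explicitly out of scope.
* Epochs containing a state transition inherit whichever profile
  dominates; sub-second states are invisible at the supported epoch
  lengths.
* The EMG-free fallback cannot separate REM from theta-dominated wake.
* DFA α at the fixed 1–20% scale range carries the finite-size bias
  noted above; comparisons should use matched series lengths.
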