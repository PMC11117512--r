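---
title: "Estimating the ankle-brachial index from pulse wave velocity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the ankle-brachial index from pulse wave velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abipwv)
```

## The measurement model

The ankle-brachial index is classically a ratio of systolic pressures.
`abipwv` instead estimates it as a ratio of pulse wave velocities, which are
themselves ratios of arterial path length to pulse transit time. Three
channels are recorded simultaneously at 200 Hz on one body side: one ECG
lead on the chest, one PPG trace on the index fingertip and one on the
hallux. For each cardiac cycle the ECG R-peak marks the proximal time
reference and the PPG systolic peak (the S-point) the distal one, so the
pulse transit times to hand and foot are

$$\mathrm{PTT}_h = t_{S,\mathrm{hand}} - t_R, \qquad
  \mathrm{PTT}_f = t_{S,\mathrm{foot}} - t_R ,$$

and with height-dependent path lengths $L_\mathrm{hand}(H)$ and
$L_\mathrm{foot}(H)$ the per-beat velocities and index are

$$\mathrm{PWV}_h = \frac{L_\mathrm{hand}(H)}{\mathrm{PTT}_h}, \qquad
  \mathrm{PWV}_f = \frac{L_\mathrm{foot}(H)}{\mathrm{PTT}_f}, \qquad
  \mathrm{ABI} = \frac{\mathrm{PWV}_f}{\mathrm{PWV}_h}
              = \frac{L_\mathrm{foot}\,\mathrm{PTT}_h}
                     {L_\mathrm{hand}\,\mathrm{PTT}_f}.$$

The reported ABI is the arithmetic mean of per-beat ABI values over one
contiguous 30-second window (`abi_summary()`; the window start is
adjustable to emulate an operator choosing an artifact-free interval). The
mean of per-beat ratios was chosen over the ratio of mean velocities
because the per-beat formulation is what the measurement defines at each
R-peak; for the stationary synthetic signals used in testing the two
differ only in the fourth decimal.

Key modelling assumptions: the two acquisition devices are
clock-synchronised (the package offers a per-channel `t0` offset for manual
alignment, but no synchronisation protocol is modelled); the pre-ejection
period is absorbed into the transit times rather than subtracted (it
affects both limbs' PTT from the same R-peak, and partially cancels in the
ratio); and the arterial path lengths depend on height only.

## Arterial path lengths

Five segments are modelled as quadratics in height $H$ (metres):
right/left arm artery (`RA`, `LA`, heart to index fingertip), right/left
leg artery (`AR`, `AL`, heart to heel) and the plantar artery (`PA`, heel
to mid-hallux). The foot paths are composites: `ARf = AR + PA`,
`ALf = AL + PA`. The default coefficients reproduce the published fits to
measurements of 35 adults; since that measurement table is not public, the
refitting routine (`fit_length_model()`) is validated on synthetic data —
it recovers the printed coefficients exactly (to $10^{-9}$) from noiseless
model-generated lengths, which is the strongest check available.

Heights are accepted in $[1.0, 2.5]$ m with a hard error outside: the
quadratics are fitted on adults and are non-physical when extrapolated
(the plantar quadratic, for instance, peaks at $H \approx 1.81$ m and
decreases beyond it, so monotonicity in height cannot be assumed across
segments).

## Denoising

**Powerline stage.** The filtering step's purpose is removing mains
interference, so the default is a 50 Hz IIR notch (quality factor 30)
applied forward-backward for zero phase. A literal 50 Hz *high-pass* mode
is also provided (`mode = "LITERAL_HIGHPASS"`) for fidelity to hardware
descriptions that specify one, but it removes nearly all QRS energy (which
lies below ~40 Hz) and is not the default. Zero-phase application matters:
landmark times must not shift, and the test suite asserts a clean pulse's
argmax moves ≤ 1 sample.

Implementation detail with practical consequences: forward-backward IIR
filtering started from a zero filter state rings a startup transient into
the record edges — for a Q = 30 notch under unit-amplitude mains the
residual is large enough to create spurious R-peak detections in the
beat-free tail of a recording. The package's filtfilt therefore (i) pads
with an odd (anti-symmetric) extension whose oscillatory part fades in
from the edge level over several seconds, so the notch locks onto the
interferent gradually, (ii) starts each pass from steady-state initial
conditions, and (iii) re-pads the backward pass from its own
already-filtered input. A pure 50 Hz tone is suppressed by roughly 106 dB
with no edge artifact, while a 1 Hz tone passes to within $10^{-6}$.

**ECG wavelet stage.** The ECG is reconstructed from detail bands 2 and 4
of a four-level Symlet-4 decomposition: at 200 Hz, level 2 covers
25–50 Hz (the sharp QRS content that makes the R-peak stand out) and level
4 covers 6.3–12.5 Hz (lower-frequency ventricular content that keeps beats
with weak or atypical complexes detectable); discarding the approximation
band removes baseline wander. The package uses the *undecimated*
(maximal-overlap/stationary) transform for this band selection,
implemented as the corresponding zero-phase transfer functions applied in
the frequency domain. This choice is load-bearing: the decimated DWT's
keep-bands projection is shift-variant — the reconstructed peak amplitude
of a QRS kernel varies threefold and its argmax moves by up to 5 samples
depending on where the beat falls relative to the coefficient grid — which
would make sample-accurate R-peak timing impossible. The undecimated band
selection is linear, shift-equivariant and zero-phase (properties the test
suite asserts), its band transfers together with the approximation band
sum to one at every frequency, and output energy never exceeds input
energy. The circular (FFT) boundary is appropriate for records much longer
than the filter cascade; the minimum accepted length is $2^{\text{levels}}$
samples.

**PPG wavelet stage.** The PPG is denoised with the decimated Symlet-4
transform (5 levels, symmetric extension): all detail coefficients are
soft-thresholded at the universal threshold $\sigma\sqrt{2\ln N}$, with
$\sigma$ estimated from the finest detail band as
$\mathrm{median}(|d_1|)/0.6745$. On a clean trace $\hat\sigma \approx 0$
and the signal passes through essentially unchanged; decimation is
unproblematic here because thresholding preserves the broad systolic pulse
rather than selecting bands. The decimated transform itself is validated
against reference coefficient values frozen in the tests.

**Polarity.** Electrode placement can invert the lead. Polarity is
classified by tail-percentile asymmetry of the reconstructed ECG
(`NEGATIVE` iff $|q_{0.005}| > |q_{0.995}|$) and negative leads are
inverted before detection. The extreme percentile pair is deliberate: QRS
main lobes occupy only a few percent of samples after band selection, so
milder percentiles (e.g. 5/95) land in the oscillatory side lobes, whose
asymmetry has the *opposite* sign. The 0.5/99.5 pair classifies all tested
conditions (clean and 10 dB noise, upright and inverted) correctly.

## Landmark detection

**R-peaks** are local maxima exceeding `threshold_frac` (default 0.6) times
a rolling amplitude reference — the 99th percentile of $|x|$ over a 2 s
window, with edge windows shifted inward rather than truncated. Candidates
are accepted in order of decreasing amplitude under a refractory constraint
(default 0.25 s, i.e. ≤ 240 bpm); plateau ties resolve to the earlier
sample. The percentile reference makes the threshold insensitive to slow
amplitude drift; the refractory rule is the only beat-rejection mechanism
(no ectopy classification).

**S-points** are searched per beat in the window from
`min_delay_s` (default 0.05 s, skipping the ECG-coincident artifact region)
after the R-peak to the next R-peak; the last beat's window extends by the
median R-R interval. A beat with no interior local maximum (flat trace, or
maximum pinned to the window edge) is marked missing and excluded from the
PTT series and the ABI mean — dropped, not interpolated. Heart rate is
reported as $60/\overline{RR}$ in beats per minute.

## The synthetic generator

`generate_session()` emulates what the pipeline actually exploits — event
timing — with deliberately simple kernels: a Gaussian QRS spike (SD 0.02 s,
optionally negated; an optional T-wave bump stresses the detector), and a
raised-cosine systolic pulse (width 0.3 s) delayed by the configured
per-limb transit time. R-R intervals are the mean interval plus Gaussian
jitter (SD 0.02 s, truncated at ±3 SD and floored to respect the
refractory bound). Contaminants are additive: 50 Hz mains, sinusoidal
baseline wander (default 0.2 Hz) and white Gaussian noise; ground-truth
landmark times are exact regardless of noise settings, and the generator
is bit-reproducible given its seed (the global RNG stream is left
untouched). Default conditions mirror the nominal protocol: 200 Hz, 90 s
per side, 60 bpm.

The noise level for a stated signal-to-noise ratio is defined against the
mean power of the clean QRS train
($\mathrm{rms} = A\sqrt{\sigma_t\sqrt{\pi}/\overline{RR}}$, helper
`noise_sigma_for_snr()`); for the default settings 10 dB corresponds to
$\sigma \approx 0.059$ for a unit-amplitude QRS.

What the generator does *not* emulate — realistic waveform morphology,
motion artifacts, sensor decoupling, arrhythmia, inter-beat amplitude
variation — bounds what passing tests show: they demonstrate that the
pipeline recovers timing-encoded hemodynamics accurately under additive
stationary contamination, not that it is robust to every bedside artifact.

## Verified performance

The test suite (all values computed at run time) establishes, on seeded
synthetic sessions at 1.70 m height and 60 bpm over the grid
$\mathrm{PTT}_h \in \{0.15, 0.20, 0.25\}$ s ×
$\mathrm{PTT}_f \in \{0.25, 0.30, 0.35\}$ s:

* clean sessions: recovered ABI within 2 % of the closed-form truth in
  every cell (typically within 0.2 %); R-peaks within ±1 sample of
  generator truth for heart rates 40–180 bpm; recovered per-beat PTTs
  within one sample period of the configured values;
* with unit-amplitude 50 Hz interference plus 10 dB noise: ABI within 5 %
  in every cell, R-peaks within ±2 samples with no spurious or missed
  detections;
* exact algebraic identities: $\mathrm{ABI} = L_f\,\mathrm{PTT}_h /
  (L_h\,\mathrm{PTT}_f)$ to $10^{-12}$, and invariance of the ABI under
  common scaling of both PTT series.

## Clinical agreement statistics

The embedded 22-subject cohort (9 female, 13 male, diabetic, at risk of
PAD) pairs the traditional Doppler ABI with the system ABI per side.
`validation_report()` recomputes: MAE overall 0.1056 (from the printed
3-decimal values; female 0.0939, male 0.1137), ±0.1 concordance (left
12/22 = 54.5 %; female right 77.8 %, female left 66.7 %, male left
46.2 %), and Bland–Altman limits $\bar d \pm 1.96\,s_d$ with 21 of 22
differences inside on each side. Two conventions are explicit because the
source analysis left them open: the SD divisor is selectable
(`POPULATION`, divisor $n$, is the default; `SAMPLE` uses $n-1$; the
left-side inside-count is 21 under both), and the tolerance band is the
closed interval $|d| \le 0.1$ (no cohort value sits on the boundary).
Subject 11's traditional readings were incompressible-artery results
reported only as ">1.30"; they enter numerically as 1.30 and carry a
censoring flag — one of the system's motivating cases, since the PWV-based
method still produced quantitative values (1.309/1.348) for this subject.

One reproducibility caveat is documented rather than corrected: from the
printed 3-decimal table the right-side concordance is 16/22 (and male
right 9/13), one less than the published 17/22 (10/13); subject 13's right
difference $|1.18 - 1.066| = 0.114$ is the borderline case, and the
original count evidently used unrounded system values. The right-side
count is therefore asserted in tests at its recomputed value of 16.

## Numerical choices and degenerate inputs

* Sample indices are 1-based (R convention); the time of sample $i$ is
  $t_0 + (i-1)/f_s$. All inter-event quantities are in seconds.
* Wavelet boundary handling: symmetric (edge-replicating) extension for
  the decimated transform; circular for the undecimated band selection.
* An all-zero signal passes every filter stage unchanged (linearity) and
  yields an empty R-peak sequence — an empty detection is a result, not an
  error; downstream summaries then fail with stage-named errors.
* A constant ECG has indeterminate polarity and is rejected.
* Sessions shorter than the averaging window (30 s) are rejected
  (`insufficient duration`), as are signals shorter than one filter length
  or $2^{\text{levels}}$ samples for wavelet stages, heights outside
  $[1.0, 2.5]$ m, and non-positive lengths or transit times.
* Fewer than 10 usable beats in the window flags the result as not
  reportable (`reportable = FALSE`) rather than erroring; mean PWVs
  outside 0.5–30 m/s raise a physiological-range flag.
* Test problem sizes were chosen to exercise the nominal protocol
  (90-second sessions) on the full 3 × 3 transit-time grid in both clean
  and contaminated conditions while keeping the whole suite under a few
  minutes of CPU; shorter sessions (30–45 s) are used where only landmark
  behaviour is at stake.

## Known limitations

* The height-length model is population-level; individual anatomy,
  sex- and side-specific variation beyond the five printed equations, and
  imaging-derived paths are out of scope.
* No blood-pressure estimation from PTT, and no modelling of the
  pre-ejection period; the ABI ratio partially cancels it, but residual
  bias in patients with altered ejection dynamics is plausible.
* The agreement statistics characterise the published cohort table, not
  new recordings; the raw clinical ECG/PPG signals are not public, so the
  signal pipeline is validated on synthetic data only.
* The detector suite has no arrhythmia handling beyond the refractory
  rule; ectopic beats will enter the PTT series if their S-points are
  found.
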