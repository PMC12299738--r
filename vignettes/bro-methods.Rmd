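---
title: "Extracting blink-related oscillations from four-channel frontal EEG"
author: "broeeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting blink-related oscillations from four-channel frontal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous blinks are followed by a stereotyped delta-band brain
response -- the blink-related oscillation (BRO) -- reflecting the brain's
re-evaluation of the visual scene when the eyes re-open. BROs can be
measured from as few as four forehead electrodes (F7, Fp1, Fp2, F8),
which makes them attractive for wearable EEG, but the blink itself
deposits an ocular artifact two orders of magnitude larger than the
response, at exactly the latency of interest. This package implements the
full extraction chain -- blink detection, time-frequency mask denoising,
component and spectral measurement -- and the paired statistics used to
compare two electrode systems (a textile-electrode headband versus dry
Ag/AgCl electrodes) recorded from the same subjects. Because real paired
recordings cannot ship with the package, a ground-truthed synthetic
generator reproduces the statistical structure the analysis assumes, and
every stage is validated against it.

## The synthetic cohort

`synth_config()` / `generate_paired_session()` simulate 3-minute,
256 Hz, four-channel eyes-open recordings containing:

* a 1/f ("pink", power spectral density proportional to 1/f) background,
  scaled to 10 uV standard deviation -- the standard stochastic surrogate
  for resting EEG;
* 10 Hz alpha activity (5 uV) and a 50 Hz mains sinusoid (2 uV), with
  random phases;
* blink artifacts: single-peaked raised-cosine transients (100 ms rise,
  200 ms fall) with peak amplitudes of 150 uV at the prefrontal sites
  (Fp1, Fp2) and 90 uV at the lateral frontal sites (F7, F8), so that the
  artifact topography decreases away from the eyes;
* a biphasic BRO added time-locked to every blink maximum on all four
  channels: a +4 uV Gaussian lobe peaking 100 ms post-blink (C1) and a
  -4 uV lobe at 250 ms (C2), each with a 60 ms half-width at half
  maximum. With that width the kernel keeps more than 95% of its spectral
  energy below 4.5 Hz, so it is representable inside the delta keep-band
  of the denoiser; the half-width-at-half-maximum reading of the width
  parameter is what keeps the two lobes' realized extrema within one
  sample of the nominal latencies despite their overlap.

Blink times follow a renewal process whose inter-blink interval is the
4 s minimum gap plus an exponential excess, calibrated so the *realized*
rate equals the configured 12 blinks/min (about 36 events per recording).
A homogeneous Poisson stream thinned by the 4 s dead time would realize
barely half the nominal rate, so the renewal construction is used
instead. The minimum gap exceeds the analysis' 3 s separation rule by
design: generated events survive temporal thresholding unless jittered on
purpose.

A paired session shares one blink train and one BRO kernel between the
two simulated systems and draws the noise floors independently, with the
textile-like system's noise scaled by 1.3. The generator returns the
ground truth (every blink-maximum sample and all injected parameters),
which the tests use as an oracle for detection and recovery.

What the generator does **not** emulate: ocular dynamics beyond the
stereotyped kernel (no saccades, no eyelid flutter, no amplitude
variability between blinks), inter-subject variability of BRO amplitude
and latency, and non-stationary electrode artifacts. Two consequences
matter when reading the outputs. First, measured C1/C2 amplitudes on
cleaned synthetic data include a contribution from the blink-artifact
tail that survives the mask (see below), so they exceed the injected
4 uV; their *directions* and *latencies* are the meaningful recovery
checks. Second, because all simulated subjects share identical injected
content, permutation nulls that relabel waveforms across subjects are
nearly as concordant as the true pairing -- the ICC permutation p-values
on synthetic cohorts are therefore uninformative even though the ICC
point estimates (about 0.97 in the time domain) are high; the
calibration of the permutation machinery is instead verified on
exchangeable null data, where its type-I error is 0.05 as it should be.

## Preprocessing

Recordings are notch-filtered at 50 Hz (2nd-order Butterworth band-stop,
1 Hz width) and band-passed 0.5-20 Hz with a 4th-order Butterworth
design; both are applied forward-backward, so the net phase is zero and
the effective magnitude response is squared. "4th order" names the
design order, not the doubled effective order -- the common convention.
Edges are padded by odd reflection over roughly three filter time
constants before filtering to suppress start-up transients. Manual
inspection for gross artifacts is replaced by `flag_large_amplitude()`,
which reports (never removes) samples exceeding a configurable 500 uV
threshold, keeping the step reproducible.

## Blink detection

The vEOG is the Fp1 channel band-passed 0.5-16 Hz. A stereotypical blink
serves as template: either a manually delimited span, or (in unattended
runs) +/-0.35 s around the largest excursion exceeding five MADs above
the median. The template, mean-removed and unit-normalized, is slid
along the vEOG and scored by normalized cross-correlation with one
amendment: windows whose mean-removed energy is below the template's are
penalized by their relative RMS. Pure scale-invariant similarity would
accept any low-amplitude noise wiggle shaped like a blink -- on default
synthetic data that costs half the precision, and through the
separation rule most of the recall; the penalized score leaves an exact
match at 1 while keeping sub-threshold energy out. Local maxima above a
configurable fraction (default 0.6) of the best score become candidates,
each anchored at the vEOG maximum within its matched window -- that
anchor defines T0. Anchoring on the band-passed vEOG can move T0 by one
sample relative to the underlying transient peak, which is within the
tolerance of every downstream window. Finally, any event with a
neighbour closer than 3 s is removed -- both members of a close pair,
since a kept first blink would still have a contaminated post-blink
window. A recording in which no template or no event can be found yields
an empty event set and is reported as an excluded subject, never a
crashed run.

## Time-frequency filtering

Each surviving blink anchors a 3 s epoch (-1.5 to +1.5 s, T0 at zero).
Per trial and channel the epoch is transformed with a short-time Fourier
transform using a 128 ms Hamming window; a binary mask multiplies the
coefficients; the masked map is inverse-transformed; and the trials are
baseline-corrected by their (-1500, -500) ms means and averaged.

Three numerical choices deserve emphasis:

* **Frequency grid.** A 33-sample window has a native bin spacing of
  ~7.8 Hz -- the 0.5-4 Hz keep-band cannot be expressed on it. Frames are
  therefore zero-padded to `n_fft = fs` (one second), giving a 1 Hz grid
  on which the band maps to bins 1-4. This interpolation is the only way
  the stated mask is realizable with the stated window.
* **Frame advance.** The 100 ms figure attached to the window is read as
  the *overlap* between successive 128 ms windows, i.e. a 28 ms hop
  (7 samples at 256 Hz). Read as the hop instead, adjacent windows would
  share only 7 of 33 samples; the summed-squared-window normalization of
  the least-squares synthesis then ripples by more than an order of
  magnitude at the 9.85 Hz frame rate, and a masked reconstruction
  acquires spurious extrema pinned to the normalization minima (at
  mid-points between frame centres, wherever the grid is placed) plus
  strong frame-rate modulation sidebands. Under the dense-overlap
  reading the synthesis is smooth and an injected biphasic BRO is
  recovered with its morphology intact; under the sparse reading it is
  not recoverable at all. `stft_params()` exposes `hop_ms` for building
  the sparse variant explicitly.
* **Grid anchoring.** The frame grid is shifted so one window centre
  coincides exactly with T0. The mask's time interval is defined around
  the blink; anchoring makes its realization identical across trials,
  subjects and systems instead of depending on where an epoch's first
  sample happens to fall. A shifted grid can leave up to `hop - 1` edge
  samples covered by no window; they reconstruct as zero and lie outside
  every analysis window.

The mask itself is unity exactly where 0.5 <= f <= 4 Hz (closed) and the
frame centre is outside (-0.5, 0.1) s (open), zero elsewhere -- one mask
for all channels, trials, subjects and systems. Inversion is
least-squares: each frame's inverse FFT is re-weighted by the analysis
window, overlap-added, and normalized by the summed squared window. For
an all-pass mask this reconstructs the interior to machine precision
(relative RMS below 1e-8 in the tests); masking makes it a contraction,
so cleaned-trial energy never exceeds raw-trial energy.

Two intrinsic limitations of the 128 ms window are worth knowing. Its
spectral main lobe is ~31 Hz wide, so out-of-band tones leak into the
1-4 Hz bins: a pure 10 Hz epoch is suppressed to roughly 15% RMS, not to
zero. And hard time-gating at the mask boundary scatters some delta
energy broadband. Both effects are properties of the published parameter
set, and the unit tests assert the measured behaviour (strong, but not
total, out-of-band rejection).

Because the blink artifact's fall lasts ~200 ms, the first kept frames
after the 0.1 s mask edge still contain its tail; its delta-band
projection survives into the cleaned average as a positive bump near
100 ms and a rebound near 250 ms. On synthetic data this residue adds to
the injected BRO rather than obscuring its timing -- recovered grand
average latencies are ~110 ms and ~245 ms -- but it is why cleaned
component amplitudes should be compared against baseline and between
systems, not read as absolute response sizes.

## Feature measurement

* **OCI** (ocular contamination index): |amplitude at 0 ms| /
  |amplitude at -1000 ms| of a trial-averaged waveform, computed on raw
  and cleaned averages; the percent drop quantifies artifact removal.
  Absolute values keep the index positive and finite when the baseline
  sample crosses zero. Under the default synthetic conditions the mean
  reduction is about 97% per system (recomputed by
  `scripts/acceptance.R`), not more: the zero-phase 0.5 Hz high-pass
  gives each 150 uV blink a coherent slow undershoot, which both
  inflates the raw baseline amplitude at -1000 ms (capping the raw OCI)
  and, through the baseline correction, leaves a ~1 uV offset at T0 in
  the cleaned average. Larger blink-to-background ratios push the
  reduction arbitrarily close to 100%.
* **C1/C2 components**: C1 is the largest positive peak in 0-190 ms, C2
  the largest negative peak in 210-450 ms; amplitudes are means over a
  20 ms window centred on each peak (truncated at epoch edges), the
  baseline is the (-1300, -1100) ms mean, and ties break to the earliest
  latency.
* **Spectral power**: 6-cycle complex Morlet wavelets on a 0.5-20 Hz
  grid in 0.5 Hz steps (covering every analysis band; the grid is a
  package choice). Log power is `log(|coefficient|^2 + floor)` with a
  floor of 1e-12 of the map maximum so silent segments stay finite.
  Baseline correction subtracts each frequency row's (-1500, -500) ms
  mean, per trial, before averaging -- and the baseline-corrected log
  power is what feeds the band series, keeping one object flowing
  through the frequency-domain chain.
* **Delta sub-bands**: low 0.5-1.5, mid 1.5-3.5, high 3.5-4.5 Hz,
  membership closed on the left and open on the right so shared edges
  are never double-counted; coefficients are summed across in-band
  frequencies over the 0-1000 ms post-blink window.

## Statistics

Paired t (two-sided), Wilcoxon signed-rank (zeros dropped; exact
signed-rank distribution for n <= 25 without ties, tie-corrected normal
approximation otherwise; V = sum of positive-difference ranks), and
Pearson correlation with the t-based test on n-2 degrees of freedom are
standard. The intraclass correlation treats time points as targets and
the two systems as raters and defaults to ICC(2,1) -- two-way random
effects, absolute agreement, single measurement -- because the question
is whether the two systems *agree*, not merely co-vary; a consistency
variant ICC(3,1) is a switch.

Both permutation tests use the add-one convention
p = (1 + #{null >= observed}) / (n_perm + 1) and a dedicated seed, so
statistical randomness never shares a stream with data generation. The
time-frequency test compares per-cell paired t-statistics against a null
built by flipping each subject's difference-map sign (equivalently,
swapping the system labels within a subject -- the
exchangeability-respecting operation for a paired design); cells with
identically zero differences are reported as t = 0, p = 1. No
multiple-comparison correction is applied to the point-wise p-map. The
ICC null instead reassigns the pooled waveforms freely across subject-
by-system slots before recomputing per-subject ICCs and averaging. Type-I
error of both tests is verified by simulation on exchangeable nulls
(200 null datasets, 199 permutations each) to be 0.05 within Monte-Carlo
tolerance.

## Problem sizes and determinism

The validation suite runs 9-subject paired cohorts at the full 180 s
recording length for the artifact-removal surface, 20 independent
sessions for component recovery, and reduced grids (for example 4 x 5
cells, 8 subjects) for the permutation calibration -- sizes chosen to
give stable Monte-Carlo estimates while keeping a full run in minutes on
one core. Every stage is deterministic given the configuration seed:
per-subject, per-test and per-channel seeds are derived offsets, a
repeated `run_pipeline()` is byte-identical after serialization, and
rendered outputs contain no timestamps.

## Known limitations

* The cleaned signal between roughly -0.45 s and +0.04 s is identically
  its baseline offset: every frame covering it is masked. Measures
  inside that region (such as the cleaned T0 amplitude) reflect the
  baseline-correction offset, not brain signal.
* The 128 ms window's leakage and the hard mask edges set a floor on
  out-of-band rejection (see above); a longer window would sharpen
  frequency selectivity at the cost of the time resolution the blink
  interval demands.
* Synthetic cohorts carry no between-subject variability, so
  cross-subject permutation nulls are degenerate there (ICC p-values
  near 1); real cohorts do not share this property.
* EDF support covers continuous, equal-rate, 16-bit recordings -- the
  subset this workflow produces and consumes -- not annotated EDF+.
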