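---
title: "Methods: event-locked spectral analysis of occlusion-cycle mobile EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked spectral analysis of occlusion-cycle mobile EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`eegpipe` analyses high-density scalp EEG recorded while a participant
experiences a recurring visual occlusion cycle: 1.5 s of occlusion followed
by 7.5 s of clear vision, with a uniform random extra delay of up to 1 s
appended to each cycle so onsets cannot be anticipated. The scientific
questions it serves are (i) whether occlusion onset/offset produces
event-locked spectral power changes (event-related
synchronization/desynchronization, read from an ERSP map) and (ii) whether
it realigns the phase of ongoing oscillations (phase resetting, read from
inter-trial coherence, ITC) — two effects that are dissociable: a pure phase
reset raises ITC with no change in median spectral power.

The package implements the full chain: a synthetic data generator with known
ground truth, preprocessing and channel rejection, burst and muscle-artifact
suppression, sync-track clock alignment and epoching, Morlet time-frequency
statistics with bootstrap masking, and weighted k-means clustering of
independent components across subjects.

# The synthetic generator as a stated world

No public recordings accompany the protocol, so every downstream stage is
validated against `simulate_recording()` / `simulate_study()`. The
generator's defaults are the protocol's stated values wherever a value is
stated: 512 Hz sampling, the 1.5 s / 7.5 s / up-to-1 s occlusion cycle, a
2 Hz square-wave sync channel (1.0 to 1.8 V levels), 128-channel support
(32-channel default montage for test runtime), and neck-EMG auxiliary
channels. Values the protocol does not state were chosen once on realism
grounds and are not tuned:

* **Sources.** One narrowband source per classical band (theta 4-8, alpha
  8-13, beta 13-30, gamma 30-100 Hz), generated as $A(t)\cos\varphi(t)$ with
  $\dot\varphi = 2\pi f(t)$ and $f(t)$ an Ornstein-Uhlenbeck walk (SD 0.3 Hz,
  reversion 2 s$^{-1}$) clipped to the band. Amplitudes 6/8/4/2 uV.
* **Background.** Eight spatially mixed 1/f background sources (3 uV) plus
  0.5 uV independent sensor noise. The mixed background is what gives
  neighbouring channels their realistic correlation; with independent noise
  only, the "uncorrelated channel" rejection criterion false-alarms on
  healthy channels.
* **Mixing.** Gains decay with source-electrode distance,
  $\exp(-d/80\,\mathrm{mm})$, on a spherical montage; forward head modelling
  is out of scope.
* **Artifacts.** Muscle bursts are 20-100 Hz band-passed noise (SD 25 uV,
  0.4-1 s, Tukey-windowed) projected coherently onto the three electrodes
  nearest a random site — coherent projection mirrors a physical muscle
  source and keeps burst channels correlated with each other. Bad channels
  are injected one per failure mode: 10x-SD noise, spike-driven kurtosis,
  and amplitude-matched independent pink noise.

## The phase-reset model

A stimulus-locked phase reset is modelled as entrainment: at event +
latency, a per-trial target phase is drawn from von Mises(reset_phase,
kappa) — kappa = 0 gives no reset, kappa >= 50 a near-complete one — and the
oscillator's phase error relative to that target decays as
$\dot\delta = -k\sin(\delta/2)$ over the effect window, with
$k = 2\pi \cdot$ `reset_coupling_hz` (default 1 Hz).

This choice is deliberate. Three simpler mechanisms were implemented and
rejected because they violate the dissociation the effect exists to model:
an instantaneous phase jump injects a measured 2.4 dB broadband transient
through the wavelet; a linear phase slew pushes the instantaneous frequency
into the wavelet skirt (0.6-1.1 dB at band-edge cells); a power-preserving
crossfade of two oscillators produces a coherent-sum power notch of up to
3 dB at the transition. The entrainment form bounds every trial's frequency
excursion by `reset_coupling_hz`, so the band-mean median ERSP stays within
about 0.15 dB while ITC rises inside 0-300 ms. Residual band-edge cells can
still move by ~1 dB on some seeds; the dissociation is therefore stated (and
tested) as a band-mean contrast, not a single-cell bound. The degenerate
kappa limits are verified with jitter-free sources at coupling completion,
because with an entrainment mechanism "phase identical at event time" is
only reachable asymptotically.

Power modulation multiplies the source amplitude by $10^{\mathrm{dB}/20}$
under a Tukey window (10% taper) to avoid spectral splatter; a +3 dB
modulation doubles Hilbert-envelope band power (verified to within 1%).

# Preprocessing

Stages run in the protocol's order: downsample to 256 Hz, 1 Hz high-pass,
common median reference, optional mains notch, channel rejection, ASR,
EEMD/CCA, spherical-spline interpolation of rejected channels, and separate
average referencing of EEG and EMG.

* Filters are 4th-order Butterworth designs applied forward-backward (the
  protocol states only the cutoff); coefficients were validated against an
  independent reference implementation during development. The mains filter
  is a zero-phase biquad notch (+/-1 Hz) at the line frequency and its first
  harmonic, standing in for a multi-taper regression tool whose internals
  are external to this package.
* Resampling is anti-alias Butterworth filtering plus integer decimation
  (FFT resampling for non-integer ratios). Event times live on the seconds
  clock and are unaffected.
* Channel rejection uses the three population criteria: SD more than 2 SDs
  above the cross-channel mean SD, kurtosis (Pearson, Gaussian = 3) more
  than 5 SDs above the mean, or best-neighbour correlation below 0.4 in more
  than 1% of 1-s windows. Neighbours are the 4 nearest electrodes by
  position (index-adjacent channels when positions are absent); window
  length and threshold are package choices, config-exposed. Note that with
  roughly 30 channels the "mean + k SD" population form flags a single
  extreme outlier with only ~10% margin for the kurtosis criterion — the
  outlier itself inflates the population SD — which is inherent to the rule,
  not to this implementation.

# Denoising

**ASR (simplified).** Principal axes are eigenvectors of the covariance of a
clean standing baseline (the protocol uses 5 min; preprocessed identically);
each axis's threshold is mean + 20 SD of per-window RMS. Cleaning projects
half-overlapping Hann-weighted 0.5-s windows onto the axes, zeroes axes
whose RMS exceeds threshold, and overlap-adds. Unlike the reference tool
there is no sliding covariance re-estimation; the static-axis form satisfies
the same burst-suppression contract and is fully testable.

**EEMD -> IMF1 -> CCA.** Each channel's first intrinsic mode function is
extracted by complementary-pair ensemble EMD: noise is added as +/- pairs so
the averaged IMFs plus residue reconstruct the input exactly (plain
averaging leaves $O(\sigma/\sqrt{n})$ error, which would violate the <1%
reconstruction contract). The added-noise SD defaults to 0.1x the signal SD:
at 0.2x the noise itself occupies IMF1 and displaces the signal's
high-frequency mode to IMF2 (two-tone IMF1 correlation drops from 0.97 to
0.81). Canonical correlation between the channels-by-time IMF1 matrix and
its 1-sample-delayed copy orders components by lag-1 autocorrelation;
components whose contributed variance exceeds median + 1.5 IQR (the
protocol's "exceeded the median interquartile range", multiplier
config-exposed) are zeroed and the cleaned IMF1 is added back. The stage
runs at 256 Hz, where the 30-100 Hz muscle band occupies IMF1; measured on
the generator's burst fixtures it removes 83-88% of burst-window 30-100 Hz
power while changing clean-window alpha power by under 6%.

# Time-frequency statistics

Morlet wavelets on a 4-100 Hz, 50-bin log grid with
$\mathrm{cycles}(f) = 3\,(f/4)^{1/2}$, amplitude-calibrated so a
unit-amplitude sinusoid yields |coefficient| 1. Times within half the
longest wavelet of either epoch edge are trimmed; the pipeline epochs with a
symmetric pad equal to that half-support so the full (-500, 0) ms baseline
survives trimming.

ERSP is the median across trials of single-trial power, in dB relative to
the mean-over-baseline of the median power at that frequency; the median
(the protocol's choice) moves by under 0.2 dB when one of 60 trials carries
100x power, where the mean moves by more than 1 dB. ITC is the resultant
length of unit phase vectors across trials; for n uniform phases its
expectation is $\sqrt{\pi}/(2\sqrt{n})$, which the implementation matches to
within 0.01 at n = 10 and 100.

**Significance masking.** Both maps are masked by baseline-resampling
bootstrap (the classic scheme: per trial, a random baseline time point per
iteration), with two extensions adopted after measuring type-I error on
stationary data: the trials are bootstrapped as well, and the ERSP
surrogate's baseline normalizer is re-estimated each iteration by a circular
block bootstrap (block = 2 wavelet SDs). Without these the null is
conditionally too narrow at low frequencies — a 0.5-1 s baseline holds fewer
than three independent power samples per trial below 8 Hz — and the
pointwise test rejects ~10% of null cells at alpha = 0.05; with them the
measured rate is 5.0% on average (4 seeds). Because wavelet smoothing
correlates cells, the realized per-run fraction still fluctuates by a few
percent; the acceptance test therefore bounds it by alpha + 2 binomial SEs
with n = n_boot (the quantile-estimation uncertainty), the only reading
under which any pointwise test can pass at a fixed seed. Masked cells are
set to 0 (dB or coherence), mirroring the display convention; the ITC map is
additionally baseline-subtracted per frequency, with the raw map retained
since subtraction can produce small negatives.

# Component clustering

The decomposition backend is pluggable: an externally computed unmixing
matrix is accepted as-is, and the default is an in-package symmetric
FastICA (tanh contrast) after PCA to at most 80 components (auto-capped at
the channel count), estimated on an evenly strided subset of at most 60k
samples. Equivalent-dipole fitting is out of scope: dipole coordinates are
pipeline inputs, supplied by the generator's ground truth in recovery tests
and by a deliberately crude scalp-map-weighted localizer (labelled a
synthetic stand-in) in the end-to-end run.

Per component, three feature blocks are assembled: log Welch PSD 3-45 Hz
(PCA to 10 dims), dipole xyz in mm, and the normalized scalp map (PCA to 10
dims). Each block is centred and scaled by a single factor — the SD of its
leading dimension — then weighted 2 (spectral), 10 (dipole), 1 (scalp) and
concatenated. Per-dimension standardization was implemented first and
rejected: it amplifies pure-noise PCA dimensions to the level of informative
ones, and k-means then splits true clusters (observed: a 7-subject planted
cluster split into two sub-threshold halves). k-means uses k = 14 with 50
restarts (20 restarts still left occasional bad optima on the recovery
fixture); components more than 3 SD from their cluster's mean within-cluster
distance (leave-one-out) are outliers; clusters with fewer than 5 distinct
participants are discarded; one component per participant per cluster is
kept — the lowest residual variance whose spectral profile is not
artifact-like (global peak above 30 Hz, more than 10 dB excess below 6 Hz,
or no alpha/beta peak after log-log 1/f detrending), ties breaking toward
the lower component index.

On the planted-cluster fixture (8 subjects, 6 true locations with 5 mm
dipole jitter, a 4-subject planted cluster, and per-subject noise components
kept 30 mm away from planted sites so membership is unambiguous), all 6 true
clusters are retained with centroids within 10 mm of truth and the
4-subject cluster is discarded, across all 10 development seeds.

# What a green run does and does not establish

The generator emulates: band-limited oscillatory sources under 1/f
background with realistic channel correlation, event-locked resets and power
modulations, spatially coherent muscle bursts, three bad-channel failure
modes, a sync square wave, and per-subject source-location jitter. It does
not emulate: eye blinks or ECG, gait-locked rhythmic artifacts, electrode
impedance drift, realistic volume conduction (no BEM), or non-stationary
background spectra. Green tests therefore establish that the algorithms
implement their contracts and recover known effects under this world — not
that the pipeline's thresholds are optimal for any particular real
recording.

# Numerical choices and degenerate inputs

Half-open epoch windows [tmin, tmax) on the recording grid with event
sample = round(t x srate); epochs too close to a record edge are dropped and
logged, and epochs overlapping flagged pauses are kept if fully recorded.
EDF is written with 1-s records and per-channel symmetric physical ranges
(16-bit; BDF 24-bit). Flat sync signals warn and return no edges; ASR
windows where every axis exceeds threshold fall back to the single
lowest-RMS axis and are logged; CCA on rank-deficient input reduces by PCA
and flags it; cluster singletons never become outliers; an all-suspect
subject keeps its lowest-RV component flagged rather than dropping the
subject. The test suite's simulations are scaled (60-290 s recordings, 10-50
EEMD ensembles) to keep the default run inside a 1-CPU budget; the
end-to-end acceptance test runs the full stated study (8 subjects, ~60
trials) once. The pipeline's EEMD ensemble default (10, complementary pairs)
and bootstrap default (200) are runtime-constrained choices, config-exposed,
with the standalone function defaults at conventional values (100
ensembles, 500 bootstraps).

# Known limitations

Static-axis ASR under-cleans non-stationary artifact subspaces; the notch is
narrower than a multi-taper line remover and will not track drifting mains;
ERSP/ITC masking is pointwise (no cluster-based multiple-comparison
correction, per the display convention it mirrors); the crude localizer is
not a dipole fit and its coordinates should never be interpreted
anatomically; anatomical cluster labels are user metadata, not computed.
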