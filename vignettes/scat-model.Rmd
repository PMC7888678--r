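---
title: "The SCAT receiver: spectrogram correlation and transformation of biosonar echoes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SCAT receiver: spectrogram correlation and transformation of biosonar echoes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatr)
```

## The model

Echolocating bats and dolphins perceive targets through two delay
quantities extracted from each returning echo: the **range delay** `t`
(broadcast-to-echo travel time, about 5.8 ms per metre in air and 1.4 ms
per metre in water, two-way) and the **glint delay** `Δt` (the time
separation between reflections from a target's discrete reflecting
points, or glints). When two glints are closer than the ear's
integration time (~250 µs for dolphin clicks, ~300 µs for bat chirps),
their reflections overlap and interfere, carving periodic nulls into the
echo spectrum at a frequency spacing `Δf = 1/Δt`. The Spectrogram
Correlation and Transformation (SCAT) receiver recovers `t` directly
from timing and recovers `Δt` indirectly, by detecting the nulls and
inverting their spacing.

Everything downstream of the filterbank operates on *threshold-crossing
times*, not on amplitudes. The processing stages, each an exported
function, are:

1. **Gammatone filterbank** (`run_filterbank()`): 4th-order gammatone
   filters, equivalent rectangular bandwidth (ERB) 4 kHz, unit gain at
   each center frequency. Bat preset: 161 channels, 20–100 kHz at
   0.5 kHz; dolphin preset: 121 channels, 30–150 kHz at 1 kHz. The
   grids deliberately oversample frequency — adjacent passbands overlap
   by ~90% — because later stages read spectral shape out of timing
   differences between neighbouring channels.
2. **Transduction** (`transduce()`): half-wave rectification followed by
   a causal 2nd-order Butterworth lowpass at 10 kHz. The high cutoff
   preserves cycle-by-cycle structure in channels below ~20 kHz while
   high channels emerge as smooth envelopes. Causality matters: latency
   is the computational currency, and zero-phase filtering would destroy
   the quantity being computed.
3. **Gain normalization** (`normalize_gain()`): the broadcast's maximum
   is pinned at 1.0 full scale, mimicking the middle-ear gain control
   that squeezes the self-heard broadcast into the receiver's dynamic
   range. Echoes are scaled by the same factor and normally sit at no
   more than half of full scale.
4. **Threshold crossings** (`detect_crossings()`): ten equally spaced
   levels from 3% to 98% of full scale
   (`fraction_k = 0.03 + (k−1)(0.98−0.03)/9`); per event, channel and
   level, the first upward crossing, linearly interpolated. A level
   never crossed is missing (`NA`) — the raw material of null detection.
5. **Dechirping** (`dechirp()`): each echo crossing is re-referenced to
   the broadcast crossing in the same channel at the same level. This
   removes the FM sweep's time-frequency slope using the self-heard
   broadcast as the stored template, so any broadcast waveform works
   without reconfiguring the receiver.
6. **Amplitude-latency trading** (`apply_alt()`): 25 µs of added latency
   per decibel of per-channel attenuation (Table-convention `−25 µs/dB`),
   added on top of the natural threshold-crossing retardation. ALT
   transposes the across-frequency amplitude profile into an
   across-frequency timing profile, which is what makes nulls visible to
   a purely time-based reader.
7. **Range delay** (`estimate_range_delay()`): all non-missing dechirped
   delays accumulate into a histogram (bin width one sample period, 2 µs
   at 500 kHz); `t` is the histogram's *leading edge* — the left boundary
   of the earliest contiguous bin cluster at which the cumulative count
   reaches 10% of the mass — because ALT drags the tail rightward.
8. **Null detection and the triangular network** (`find_nulls()`,
   `run_triangular_network()`, `invert_spacing()`): nulls are located
   from latency bumps and crossing voids (below), entered on the base of
   a triangular coincidence network spanning the analyzed bandwidth
   (80 kHz bat, 120 kHz dolphin), and adjacent-null spacings are read
   from the apex points. The aggregate `Δf` is the mode of the
   grid-quantized spacings; `Δt = 1/Δf` tops out at the reciprocal of
   the base (12.5 µs for the bat).
9. **Clutter fill-in and energy normalization**
   (`fill_lowpass_void()`, `normalize_image_energy()`): a
   lowpass-filtered region (the signature of off-axis or distant
   clutter) is too wide to register as one null and is instead tiled by
   every candidate spacing from ~3 kHz up to the maximum registrable
   null width (~15 kHz), producing a broad plateau of spurious glint
   delays. Normalizing each glint-delay histogram by its area spreads
   the clutter's mass thin, so a focused echo's peak at the true `Δt`
   protrudes above its cluttered twin — blurring as clutter rejection.

`scat_run()` chains all stages and returns a `scat_image` whose
`tidy()` method gives one row per echo with `t_ms`, `delta_t_us`,
`delta_f_khz`, null counts and gating/split flags.

## What the generator emulates

The synthesis module is first-class, tested code; its defaults are the
study conditions:

* bat broadcast: 3-ms two-harmonic logarithmic downsweep, FM1 55→25 kHz,
  FM2 90→50 kHz (`bat_chirp_spec()`), phase integrated analytically so
  instantaneous-frequency tests are exact;
* dolphin broadcast: ~50-µs Gabor-like transient spanning 40–150 kHz
  with spectral centroid 95 kHz (`dolphin_click_spec()`); the source
  does not give the click's analytic form, so a Gaussian-envelope cosine
  shaped to the stated band is used;
* multi-glint echoes: sums of exact frequency-domain fractional-delay
  replicas, positive reflection sign by default (a per-glint sign flag
  exists), glint gains 0.5 each in the standard fixtures so echoes stay
  at no more than half the broadcast amplitude;
* lowpass clutter: a zero-phase FFT-domain gain ramp (cutoff, dB/kHz
  slope, cap), so coloration in dB is exactly controllable;
* sequences: broadcast at 0.5 ms, echoes at ≥5 ms separation, sampling
  rate 500 kHz; annotations round-trip exactly through the plain-text +
  YAML container (`write_echo_sequence()`).

Not emulated (out of scope by design): atmospheric absorption,
spreading loss, beam patterns, Doppler, receiver noise, and overlapping
echo streams from rapid emission. Passing tests therefore demonstrate
the receiver's behaviour under clean, fully segregated conditions, not
its noise robustness.

## Numerical choices and open-design decisions

**Causal, equal-delay filterbank.** The gammatone FIR (truncated at
1.2 ms, decay parameter `b = 1.019·ERB`) has the same envelope-peak
group delay (~0.12 ms) in every channel because the ERB is constant, so
the common latency cancels exactly in dechirping. Outputs are *not*
advanced to compensate it: advancing makes click responses acausal and
pushes first crossings out of their event windows.

**Oversampled rectification.** Half-wave rectification generates
carrier harmonics; at 500 kHz sampling the 4th harmonic of a 125-kHz
carrier aliases to DC and leaks through the 10-kHz smoother. Each
channel is therefore rectified and smoothed at twice the rate and
decimated back. A small residual remains detectable within ±1 channel
of fs/4.

**Attenuation reference.** The ALT reference is the peak of a
doubly-smoothed amplitude envelope: the raw envelope maximum of a
few-cycle click varies by whole decibels with carrier-crest alignment.
A second, integrated statistic (channel energy) is kept alongside,
because when two click reflections are separated by nearly the
integration time the envelope peak no longer carries the interference
ripple but the integrated response still does. For a uniformly
attenuated echo both statistics equal the attenuation in dB, so the
25 µs/dB calibration is unchanged.

**Null evidence.** A null must show (a) a *topographic* latency bump:
a local peak of the ALT-augmented level-1 delay curve with prominence
≥ 25 µs (one decibel of local depth at the trading coefficient, far
above the ~2 µs interpolation jitter), and (b) an amplitude deficit of
≥ 1 dB that recovers on *both* flanks. Prominence is used instead of a
deviation-from-median rule because the median absolute deviation of the
delay field is dominated by the null scallop itself exactly when many
nulls are present; and topographic prominence is immune to the convex
band-edge ramps that fool running-median baselines. Deep drop-outs
(echo failing to reach level 4 where the broadcast does) are a second,
independent cue that also captures lowpass regions, which shift the
whole latency baseline rather than forming a local bump. Null centers
are taken from the attenuation apex after removing the linear background
between the flanks, refined by a parabolic fit; the apex is used rather
than a cluster centroid because the half-prominence span is skewed by
the sweep direction while the apex is stable to a fraction of a channel.

**Wide voids and fill-in.** Clusters wider than the maximum registrable
null width (15 kHz) are voids. Only voids attached to the top of the
analyzed band, with only the lowest levels crossed across their span,
qualify as lowpass regions and are tiled with fill-in spacings
(3 kHz … min(width, 15 kHz) on the channel grid). An *interior* wide
null — e.g. the single ~20-kHz-wide null of a 9-µs click echo — is
simply too broad to register and contributes nothing, which is why that
echo yields no glint estimate.

**Separate-glint resolution.** A channel votes for a second onset when
its envelope, after reaching at least half its event maximum, falls
back below the lowest threshold for at least 50 µs (longer than any
rectification-ripple dip at the lowest channel frequency) and then
crosses level 1 upward again, no earlier than the integration time
after the first crossing. Channels whose *broadcast* response shows the
same double-onset pattern (harmonic-seam channels receiving both FM1
and FM2 energy) are excluded. The echo splits when at least 15% of
responding channels (and at least 5) vote, using the tight cluster
around the modal onset delay. Under the standard conditions this splits
the click series at 300/500/700 µs and the chirp series at 500/700 µs,
and never splits rippled echoes.

**Harmonic handling (bat mode).** FM1 (≤50 kHz) and FM2 (>50 kHz) are
processed as separate band segments; null lists concatenate but a
spacing never straddles the seam. The low-frequency gate requires
level-1 crossings across at least half of the 25–30 kHz channels — a
single crossing is not enough, because the uppermost gate channel's
4-kHz skirt still responds to energy just above the band. The gate band
is a named configuration key (override to 23–30 kHz where wanted).

**Aggregation and ties.** The aggregate `Δf` is the mode of
grid-quantized apex spacings (the vertically aligned apex column); the
mode rather than the mean, because fill-in apexes would bias a mean.
Ties resolve to the smallest spacing. The glint-delay histogram keeps
*all* apexes, so fill-in structure appears as histogram mass.

## Known limitations

* A threshold receiver measures onsets at fixed absolute levels, so a
  half-amplitude echo's level-1 crossings are naturally retarded by a
  few tens of microseconds (crossing at 6% of the channel peak instead
  of 3%), and ALT adds its floor on top. The leading-edge range delay
  of the standard worked example is therefore ~0.05 ms to the right of
  the constructed delay — invisible at display resolution and well
  inside a 2% band, but not within one 2-µs histogram bin. Enabling or
  disabling ALT moves the leading edge by under 50 µs.
* The level-1→top crossing stretch at spectral peaks is ~0.7 ms for the
  two-harmonic chirp (channel dwell 0.3–0.6 ms with a 3% first
  threshold), larger than the ~0.2 ms sometimes quoted for the fast
  upper harmonic alone.
* Bat-chirp glint recovery degrades once the null spacing approaches
  the minimum resolvable 3 kHz: at `Δt = 300 µs` (`Δf ≈ 3.3 kHz`) the
  ERB-4 channels retain under 1 dB of ripple contrast and no reliable
  estimate emerges, although the dolphin click series resolves 200 µs
  (`Δf = 5 kHz`) cleanly through the integrated-energy cue.
* The model is monaural and deterministic; binaural extensions, neural
  spiking, and sub-microsecond phase hyperacuity are outside its scope.

## Problem sizes

All standard analyses run at the native 500-kHz rate: the worked
single-echo fixtures are ~12 ms of signal (≈6,000 samples × 161 or 121
channels), the ten-echo click series ~58 ms (≈29,000 samples × 121
channels), and the seven-echo clutter series ~42 ms × 161 channels.
Each full pipeline completes in seconds on one CPU; these sizes are the
paper-scale worked examples themselves, not reductions.
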