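# scatr

An R implementation of the **Spectrogram Correlation and Transformation
(SCAT)** receiver — a computational model of how wideband echolocators
(big brown bats, bottlenose dolphins) turn biosonar echoes into
perceptions of target *range* and *shape*.

## The problem and the model

A biosonar echo from a real target is a stack of overlapping
mini-replicas of the broadcast, one per reflecting point ("glint"). Two
quantities characterize the target:

* **range delay** `t` — broadcast-to-echo travel time (≈5.8 ms/m in
  air, 1.4 ms/m in water, two-way), encoding distance;
* **glint delay** `Δt` — the separation between glint reflections,
  encoding the target's profile depth (100 µs ↔ 1.7 cm in air).

When `Δt` is shorter than the ear's integration time the reflections
merge and interfere, leaving periodic nulls in the echo spectrum spaced
`Δf = 1/Δt` apart. SCAT recovers both quantities from *timing alone*:

1. a bank of 4th-order gammatone filters (bat: 161 channels, 20–100 kHz;
   dolphin: 121 channels, 30–150 kHz; ERB 4 kHz) with half-wave
   rectification and 10-kHz lowpass smoothing forms an auditory
   spectrogram;
2. ten amplitude thresholds (3%–98% of the gain-normalized broadcast)
   convert each channel into first-crossing times;
3. echo crossings are **dechirped** against the broadcast's crossings,
   removing the FM sweep's slope; **amplitude-latency trading** (25 µs
   per dB of channel attenuation) transposes the amplitude spectrum into
   a latency profile;
4. `t` is the **leading edge** of the cross-frequency delay histogram;
   `Δt` comes from detecting the spectral nulls (latency bumps and
   crossing voids), registering adjacent-null spacings on a triangular
   coincidence network, and inverting the dominant spacing
   (`Δt = 1/Δf`);
5. lowpass-filtered clutter echoes flood the network with fill-in nulls,
   blurring their glint image; normalizing glint histograms by image
   energy turns that blurring into clutter rejection.

Every study condition — bat two-harmonic chirps (FM1 55→25 kHz, FM2
90→50 kHz), ~50-µs dolphin clicks (40–150 kHz), multi-glint echoes,
lowpass clutter series — is generated synthetically by the package, so
the full pipeline is testable without any external recording.

## Worked example

The canonical worked example: a bat chirp followed 6 ms later by a
two-glint echo whose reflections are 100 µs apart.

```r
library(scatr)

seq <- two_glint_fixture(delay_ms = 6, delta_t_us = 100)
img <- scat_run(seq, scat_config("bat"))
tidy(img)
#> # A tibble: 1 × 11
#>   event rejected  t_ms t2_ms split delta_t_us delta_f_khz n_channels reliable
#>   <dbl> <lgl>    <dbl> <dbl> <lgl>      <dbl>       <dbl>      <int> <lgl>
#> 1     1 FALSE     6.05    NA FALSE        100          10        154 TRUE
```

The receiver reads the echo at a range delay of ~6 ms (the leading edge
sits a few hundredths of a millisecond late — the natural threshold
retardation of a half-amplitude echo) and recovers the 100-µs glint
delay from the 10-kHz null spacing. The detected nulls sit at the odd
5-kHz multiples, as interference of two equal in-phase reflections
demands:

```r
img$nulls[["1"]]$nulls
#> # A tibble: 7 × 6
#>   center_khz width_khz n_channels max_level dev_us segment
#>        <dbl>     <dbl>      <int>     <int>  <dbl>   <int>
#> 1       23           7         14         9   312.       1
#> 2       35.3         6         12         8   304.       1
#> 3       45.3         3          6         6   220.       1
#> # ... 55.3, 65.5, 75.4, 85.6 follow in segment 2
```

Converted to spatial terms: `delay_to_range(6, "air")` ≈ 1.03 m of
range, `glint_delay_to_spacing(100)` ≈ 1.7 cm of profile depth.

`autoplot(img, "dechirped")`, `autoplot(img, "range")`,
`autoplot(img, "glint")` and `autoplot(img, "network")` draw the
dechirped threshold-crossing spectrogram, the range-delay histograms,
the glint-delay histograms (raw or energy-normalized) and the triangular
network's zig-zag trace. `scat_demo()` regenerates the four standard
end-to-end scenarios (`bat2HFM`, `dolClick`, `clutterRejection`,
`clutterRejection-dolClick`), and `inst/cli/scat.R` exposes
synthesis/run/demo from a shell.

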