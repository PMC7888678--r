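# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; no data files.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# full front-end + delay traces for a sequence, reused across modules
run_frontend <- function(seq, cfg) {
  coch <- normalize_gain(
    transduce(run_filterbank(seq, cfg$filterbank, seq$fs)),
    c(seq$broadcast_start, seq$broadcast_start + seq$broadcast_duration + 1.8e-3)
  )
  events <- scat_events(seq)
  cm <- detect_crossings(coch, events)
  dech <- dechirp(cm)
  alt <- apply_alt(dech, channel_attenuation(cm), cfg$alt_us_per_db)
  list(seq = seq, cfg = cfg, coch = coch, events = events, cm = cm,
       dech = dech, alt = alt)
}

# worked example: bat two-harmonic chirp, 100-us two-glint echo at 6 ms
fx_bat <- function() {
  fixture("bat", function() {
    cfg <- scat_config("bat")
    fx <- run_frontend(two_glint_fixture(), cfg)
    fx$img <- scat_run(fx$seq, cfg)
    fx
  })
}

# flat single-glint echo (exact delayed replica, gain 1) at 6 ms
fx_bat_single <- function() {
  fixture("bat_single", function() {
    cfg <- scat_config("bat")
    seq <- assemble_sequence(
      make_fm_chirp(bat_chirp_spec()),
      list(glint_target(6, 0, 1))
    )
    fx <- run_frontend(seq, cfg)
    fx$img <- scat_run(seq, cfg)
    fx
  })
}

# bat chirp pair: two glints separated by 700 us (beyond integration time)
fx_bat700 <- function() {
  fixture("bat700", function() {
    cfg <- scat_config("bat")
    seq <- assemble_sequence(
      make_fm_chirp(bat_chirp_spec()),
      list(glint_target(6, c(0, 700), c(0.5, 0.5)))
    )
    fx <- run_frontend(seq, cfg)
    fx$resolved <- resolve_separate_glints(
      fx$coch, fx$cm, fx$events,
      min_sep = cfg$second_min_sep, silence_gap = cfg$silence_gap,
      qualify_frac = cfg$qualify_frac, split_frac = cfg$split_frac
    )
    fx
  })
}

# full dolphin click series 9-700 us
fx_dol_series <- function() {
  fixture("dol_series", function() {
    cfg <- scat_config("dolphin")
    seq <- two_glint_series_sequence("dolphin")
    list(
      seq = seq, cfg = cfg,
      img = scat_run(seq, cfg),
      true_dt = c(9, 18, 26, 35, 70, 100, 200, 300, 500, 700)
    )
  })
}

# single dolphin 100-us echo (small, fast; used for determinism etc.)
fx_dol_single <- function(delay_ms = 5) {
  fixture(paste0("dol_single_", delay_ms), function() {
    cfg <- scat_config("dolphin")
    seq <- assemble_sequence(
      make_click(dolphin_click_spec()),
      list(glint_target(delay_ms, c(0, 100), c(0.5, 0.5)))
    )
    list(seq = seq, cfg = cfg, img = scat_run(seq, cfg))
  })
}

# focused vs lowpass-filtered 100-us click echo (clutter suppression demo)
fx_dol_clutter <- function() {
  fixture("dol_clutter", function() {
    scat_demo("clutterRejection-dolClick")
  })
}

# seven-echo lowpass FM clutter series
fx_clutter <- function() {
  fixture("clutter", function() {
    scat_run(lowpass_series_sequence(), scat_config("bat", gate_band_khz = c(23, 30)))
  })
}

# bat batch: 50/100/200-us glints at 5/12/18 ms
fx_bat_batch <- function() {
  fixture("bat_batch", function() scat_demo("bat2HFM"))
}

# synthetic cochleagram with known envelopes, for closed-form tests
make_test_cochleagram <- function(env, fs, cf_khz, full_scale = 1) {
  structure(
    env,
    cf = cf_khz * 1e3, fs = fs, config = NULL, amp = env,
    full_scale = full_scale, class = "cochleagram"
  )
}

# instantaneous frequency of a real waveform via its analytic signal
instantaneous_frequency <- function(w, fs) {
  n <- length(w)
  W <- fft(w)
  h <- c(1, rep(2, ceiling(n / 2) - 1), rep(0, floor(n / 2)))
  if (n %% 2 == 0) h[n / 2 + 1] <- 1
  z <- fft(W * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  c(dph, dph[length(dph)]) * fs / (2 * pi)
}

# magnitude spectrum on a frequency grid
mag_spectrum <- function(w, fs, pad = 2^16) {
  n <- max(pad, length(w))
  S <- abs(fft(c(w, numeric(n - length(w)))))[1:(n / 2)]
  tibble::tibble(f = (0:(n / 2 - 1)) * fs / n, mag = S)
}

# symmetric raised-cosine window of length n
raised_cosine_ramp <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}
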