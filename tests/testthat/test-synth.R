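fs <- 500e3

test_that("log-sweep instantaneous frequency follows the closed form", {
  spec <- chirp_spec(3, list(c(55, 25)), sweep = "logarithmic", envelope = "flat")
  w <- make_fm_chirp(spec, fs)
  f_inst <- instantaneous_frequency(w, fs)
  n <- length(w)
  # closed form for a log sweep: f(t) = f1 (f2/f1)^(t/T)
  t_probe <- c(0.25, 0.5, 0.75)
  for (tp in t_probe) {
    expected <- 55e3 * (25 / 55)^tp
    measured <- median(f_inst[round(n * tp) + (-20:20)])
    expect_equal(measured, expected, tolerance = 0.01)
  }
  # midpoint equals the geometric mean of the endpoints
  expect_equal(
    median(f_inst[round(n / 2) + (-20:20)]), sqrt(55e3 * 25e3),
    tolerance = 0.01
  )
})

test_that("hyperbolic and linear sweeps follow their closed-form trajectories", {
  trajectories <- list(
    hyperbolic = function(u) 1 / (1 / 55e3 + u * (1 / 25e3 - 1 / 55e3)),
    linear = function(u) 55e3 + u * (25e3 - 55e3)
  )
  for (shape in names(trajectories)) {
    w <- make_fm_chirp(
      chirp_spec(3, list(c(55, 25)), sweep = shape, envelope = "flat"), fs
    )
    f_inst <- instantaneous_frequency(w, fs)
    n <- length(w)
    for (u in c(0.25, 0.5, 0.75)) {
      expect_equal(
        median(f_inst[round(n * u) + (-20:20)]), trajectories[[shape]](u),
        tolerance = 0.01
      )
    }
  }
})

test_that("zero-bandwidth sweep degenerates to a pure tone", {
  w <- make_fm_chirp(chirp_spec(1, list(c(50, 50)), envelope = "flat"), fs)
  sp <- mag_spectrum(w, fs)
  expect_equal(sp$f[which.max(sp$mag)], 50e3, tolerance = 1e-3)
})

test_that("harmonic-locked chirps carry k times the fundamental phase", {
  spec <- chirp_spec(3, list(c(50, 25), c(100, 50)),
    envelope = "flat", harmonic_locked = TRUE
  )
  w <- make_fm_chirp(spec, fs)
  # isolate each harmonic by FFT masking, compare instantaneous frequencies
  n <- length(w)
  W <- fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  band <- function(lo, hi) {
    Wk <- W
    Wk[f < lo | f > hi] <- 0
    Re(fft(Wk, inverse = TRUE)) / n
  }
  f1 <- instantaneous_frequency(band(20e3, 55e3), fs)
  f2 <- instantaneous_frequency(band(60e3, 110e3), fs)
  idx <- round(n * 0.3):round(n * 0.7)
  expect_equal(median(f2[idx] / f1[idx]), 2, tolerance = 0.01)
  # declaring a non-multiple pair as locked is rejected
  expect_error(
    chirp_spec(3, list(c(55, 25), c(90, 50)), harmonic_locked = TRUE),
    "harmonic"
  )
})

test_that("sub-Nyquist sampling is rejected with the Nyquist bound named", {
  expect_error(make_fm_chirp(bat_chirp_spec(), fs = 150e3), "Nyquist")
  expect_error(make_click(dolphin_click_spec(), fs = 250e3), "Nyquist")
})

test_that("click spectrum is confined to its declared band", {
  w <- make_click(click_spec(50, c(40, 150), 95), fs)
  sp <- mag_spectrum(w, fs)
  peak <- max(sp$mag)
  # -20 dB points inside [40, 150] kHz
  loud <- sp$f[sp$mag > peak * 10^(-20 / 20)]
  expect_gte(min(loud), 40e3)
  expect_lte(max(loud), 150e3)
  # at least 95% of spectral energy inside the band
  e_in <- sum(sp$mag[sp$f >= 40e3 & sp$f <= 150e3]^2)
  expect_gte(e_in / sum(sp$mag^2), 0.95)
  # FFT centroid oracle: spectral centroid within 5% of 95 kHz
  centroid <- sum(sp$f * sp$mag) / sum(sp$mag)
  expect_equal(centroid, 95e3, tolerance = 0.05)
})

test_that("single unit glint returns an exact delayed copy with a flat ratio spectrum", {
  b <- make_click(dolphin_click_spec(), fs)
  e <- make_multiglint_echo(b, glint_target(6, 0, 1), fs)
  expect_equal(as.numeric(e[seq_along(b)]), as.numeric(b), tolerance = 1e-10)
  expect_lt(max(abs(e[-seq_along(b)])), 1e-10)
})

test_that("two-glint ratio spectra have nulls at the reciprocal spacing", {
  b <- make_click(dolphin_click_spec(), fs)
  # 50-us separation: minima at 10, 30, 50, 70, 90 kHz (zeros of |1+e^{-i2pi f dt}|)
  e <- make_multiglint_echo(b, glint_target(6, c(0, 50), c(1, 1)), fs)
  n <- 2^16
  ratio <- abs(fft(c(e, numeric(n - length(e)))) / fft(c(b, numeric(n - length(b)))))[1:(n / 2)]
  f <- (0:(n / 2 - 1)) * fs / n
  df_bin <- fs / n
  for (fn in c(10e3, 30e3, 50e3, 70e3, 90e3)) {
    win <- which(abs(f - fn) < 4e3)
    expect_lt(abs(f[win[which.min(ratio[win])]] - fn), 2 * df_bin + 1)
  }
})

test_that("null spacing times glint delay is one across the two-glint family", {
  b <- make_click(dolphin_click_spec(), fs)
  n <- 2^17
  f <- (0:(n / 2 - 1)) * fs / n
  for (dt_us in c(26, 35, 70, 100, 200)) {
    e <- make_multiglint_echo(b, glint_target(6, c(0, dt_us), c(1, 1)), fs)
    ratio <- abs(fft(c(e, numeric(n - length(e)))) / fft(c(b, numeric(n - length(b)))))[1:(n / 2)]
    inband <- f > 50e3 & f < 140e3
    # local minima of the ratio spectrum
    r <- ratio
    is_min <- inband & r < dplyr::lag(r, default = Inf) & r < dplyr::lead(r, default = Inf) &
      r < 0.2 * stats::median(r[inband])
    spacings <- diff(f[which(is_min)])
    spacings <- spacings[spacings > 2e3]
    measured <- stats::median(spacings)
    expect_equal(measured * dt_us * 1e-6, 1, tolerance = 0.02)
  }
})

test_that("echo RMS scales linearly with single-glint gain", {
  b <- make_fm_chirp(bat_chirp_spec(), fs)
  rms <- function(x) sqrt(mean(x^2))
  e1 <- make_multiglint_echo(b, glint_target(6, 0, 1), fs)
  e2 <- make_multiglint_echo(b, glint_target(6, 0, 0.25), fs)
  expect_equal(rms(e2) / rms(e1), 0.25, tolerance = 1e-10)
})

test_that("glint spec validation rejects malformed targets", {
  expect_error(glint_target(6, c(0, 100, 50)), "increasing")
  expect_error(glint_target(6, c(10, 20)), "First glint offset")
  expect_error(glint_target(-1, 0), "positive")
  expect_error(glint_target(6, c(0, 50), gains = c(1, -1)), "gains")
})

test_that("lowpass clutter follows the designed dB ramp and spares the passband", {
  b <- make_fm_chirp(bat_single_harmonic_spec(), fs)
  e <- make_multiglint_echo(b, glint_target(6, 0, 1), fs)
  prof <- lowpass_profile(60, ramp_db_per_khz = 1, max_db = 30)
  ef <- apply_lowpass_clutter(e, prof, fs)
  n <- 2^16
  gain_at <- function(sig, ref, fr) {
    G <- abs(fft(c(sig, numeric(n - length(sig)))) / fft(c(ref, numeric(n - length(ref)))))
    idx <- round(fr / fs * n) + 1
    20 * log10(G[idx])
  }
  # FFT gain oracle: ramp within 1 dB of design
  expect_equal(gain_at(ef, e, 70e3), -10, tolerance = 1)
  expect_equal(gain_at(ef, e, 80e3), -20, tolerance = 1)
  expect_equal(gain_at(ef, e, 95e3), -30, tolerance = 1)  # capped
  # below the cutoff unchanged within 0.5 dB
  expect_lt(abs(gain_at(ef, e, 40e3)), 0.5)
  # null filter is the identity
  e0 <- apply_lowpass_clutter(e, lowpass_profile(60, 1, 0), fs)
  expect_equal(as.numeric(e0), as.numeric(e), tolerance = 1e-12)
})

test_that("assembled sequences round-trip their annotations exactly", {
  set.seed(42)
  targets <- list(
    glint_target(5, c(0, 50), c(0.5, 0.5)),
    glint_target(12, c(0, 100), c(0.6, 0.4),
      lowpass = lowpass_profile(80, 2, 40)
    ),
    glint_target(18, c(0, 70, 200), c(0.5, 0.3, 0.2),
      signs = c(1, -1, 1), attenuation_db = 3
    )
  )
  seq <- assemble_sequence(make_fm_chirp(bat_chirp_spec(), fs), targets, fs)
  path <- file.path(tempdir(), "seq-roundtrip")
  write_echo_sequence(seq, path)
  back <- read_echo_sequence(path)
  expect_equal(back$samples, seq$samples, tolerance = 1e-12)
  expect_equal(back$fs, seq$fs)
  expect_equal(as_tibble(back), as_tibble(seq))
  for (i in seq_along(targets)) {
    expect_equal(back$targets[[i]]$offsets, targets[[i]]$offsets)
    expect_equal(back$targets[[i]]$gains, targets[[i]]$gains)
    expect_equal(back$targets[[i]]$signs, targets[[i]]$signs)
  }
})

test_that("overlapping echo windows are rejected; empty target list is the broadcast alone", {
  b <- make_fm_chirp(bat_chirp_spec(), fs)
  expect_error(
    assemble_sequence(b, list(glint_target(5, 0), glint_target(7, 0)), fs),
    "Overlapping"
  )
  seq <- assemble_sequence(b, list(), fs)
  i0 <- round(seq$broadcast_start * fs)
  expect_equal(seq$samples[i0 + seq_along(b)], b, tolerance = 1e-9)
  expect_lt(max(abs(seq$samples[1:(i0 - 10)])), 1e-9)
})

test_that("synthesis is deterministic: identical specs give bit-identical waveforms", {
  s1 <- two_glint_fixture()
  s2 <- two_glint_fixture()
  expect_identical(s1$samples, s2$samples)
})
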