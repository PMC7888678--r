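#' @keywords internal
#' Exact fractional-sample delay of a zero-padded buffer.
#'
#' Works in the frequency domain, so a band-limited waveform is shifted
#' without interpolation error.  The buffer must carry at least
#' `shift_samples` trailing zeros to avoid circular wrap-around.
shift_fractional <- function(x, shift_samples) {
  n <- length(x)
  if (shift_samples == 0) return(x)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  Re(fft(fft(x) * exp(-2i * pi * k * shift_samples), inverse = TRUE)) / n
}

chirp_phase <- function(f1, f2, duration, sweep, t) {
  if (abs(f2 - f1) < 1e-9) {
    return(2 * pi * f1 * t)
  }
  switch(sweep,
    logarithmic = {
      r <- f2 / f1
      2 * pi * f1 * duration / log(r) * (r^(t / duration) - 1)
    },
    hyperbolic = {
      q <- (1 / f2 - 1 / f1) / duration
      2 * pi * log(1 + f1 * q * t) / q
    },
    linear = {
      2 * pi * (f1 * t + (f2 - f1) * t^2 / (2 * duration))
    }
  )
}

raised_cosine_edges <- function(n, edge_fraction) {
  env <- rep(1, n)
  ne <- floor(n * edge_fraction)
  if (ne > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = ne)))
    env[seq_len(ne)] <- ramp
    env[n + 1 - seq_len(ne)] <- ramp
  }
  env
}

#' Synthesize a multi-harmonic FM chirp
#'
#' Generates a downsweeping FM broadcast from a [chirp_spec()].  The phase
#' of each harmonic is integrated analytically (not by cumulative sum), so
#' the instantaneous frequency follows the declared sweep law exactly; when
#' the spec is harmonic-locked, harmonic k carries exactly k times the
#' phase of harmonic 1.
#'
#' @param spec A [chirp_spec()].
#' @param fs Sampling rate in Hz (default 500 kHz).
#' @return Numeric waveform of `round(duration * fs)` samples, peak
#'   amplitude normalized to 1.
#' @examples
#' w <- make_fm_chirp(chirp_spec(3, list(c(55, 25), c(90, 50))), fs = 500e3)
#' @export
make_fm_chirp <- function(spec, fs = 500e3) {
  stopifnot(inherits(spec, "chirp_spec"))
  check_nyquist(max_frequency(spec), fs)
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (spec$harmonic_locked) {
    h1 <- spec$harmonics[[1]]
    phi1 <- chirp_phase(h1[1], h1[2], spec$duration, spec$sweep, t)
    w <- Reduce(`+`, lapply(seq_along(spec$harmonics), function(k) cos(k * phi1)))
  } else {
    w <- Reduce(`+`, lapply(spec$harmonics, function(h) {
      cos(chirp_phase(h[1], h[2], spec$duration, spec$sweep, t))
    }))
  }
  if (spec$envelope == "raised-cosine") {
    w <- w * raised_cosine_edges(n, spec$edge_fraction)
  }
  w / max(abs(w))
}

#' Synthesize a wideband biosonar click
#'
#' Generates a few-cycle Gabor-like transient: a cosine carrier at the
#' spec's center frequency under a Gaussian envelope whose width is chosen
#' so that the magnitude spectrum is about 20 dB down at the declared band
#' edges and at least 95% of the spectral energy stays inside the band.
#'
#' @param spec A [click_spec()].
#' @param fs Sampling rate in Hz.
#' @return Numeric waveform of `round(duration * fs)` samples, peak 1.
#' @examples
#' w <- make_click(click_spec(50, c(40, 150), 95), fs = 500e3)
#' @export
make_click <- function(spec, fs = 500e3) {
  stopifnot(inherits(spec, "click_spec"))
  check_nyquist(spec$band[2], fs)
  n <- max(round(spec$duration * fs), 3)
  t <- (seq_len(n) - 1) / fs
  t0 <- spec$duration / 2
  sigma_t <- spec$duration / 8
  w <- exp(-(t - t0)^2 / (2 * sigma_t^2)) * cos(2 * pi * spec$center * (t - t0))
  w / max(abs(w))
}

check_nyquist <- function(fmax, fs) {
  if (fs < 2 * fmax) {
    abort(sprintf(
      "Sampling rate %.0f Hz is below the Nyquist bound %.0f Hz for a %.0f Hz signal.",
      fs, 2 * fmax, fmax
    ))
  }
  invisible(TRUE)
}

#' Form a multi-glint echo from a broadcast
#'
#' The echo is the sum of delayed mini-replicas of the broadcast, one per
#' glint, at the target's glint offsets and gains (optionally with a sign
#' flip per reflection), followed by the overall attenuation and optional
#' lowpass clutter coloration.  Delays are applied with exact
#' frequency-domain fractional shifts.  The returned waveform starts at
#' the first reflection; the target annotation travels along as the
#' `"target"` attribute.
#'
#' @param broadcast Numeric broadcast waveform.
#' @param target A [glint_target()].
#' @param fs Sampling rate in Hz.
#' @return Echo waveform with attribute `target`.
#' @examples
#' b <- make_click(click_spec(), fs = 500e3)
#' e <- make_multiglint_echo(b, glint_target(6, c(0, 100), c(0.5, 0.5)), 500e3)
#' @export
make_multiglint_echo <- function(broadcast, target, fs = 500e3) {
  stopifnot(inherits(target, "glint_target"))
  if (!all(is.finite(broadcast))) abort("`broadcast` must be finite.")
  max_shift <- ceiling(max(target$offsets) * fs)
  n <- length(broadcast) + max_shift + 64L
  echo <- numeric(n)
  for (i in seq_along(target$offsets)) {
    buf <- c(broadcast, numeric(n - length(broadcast)))
    echo <- echo +
      target$signs[i] * target$gains[i] *
        shift_fractional(buf, target$offsets[i] * fs)
  }
  echo <- echo * 10^(-target$attenuation_db / 20)
  if (!is.null(target$lowpass)) {
    echo <- apply_lowpass_clutter(echo, target$lowpass, fs)
  }
  attr(echo, "target") <- target
  echo
}

#' Apply lowpass clutter coloration
#'
#' Echoes from off-axis or distant objects are lowpass filtered relative
#' to on-axis echoes.  The coloration is applied as a zero-phase
#' frequency-domain gain ramp: frequencies below the cutoff are untouched,
#' attenuation grows linearly (in dB per kHz) above it, capped at the
#' profile's maximum.  A zero-dB maximum is the identity.
#'
#' @param echo Numeric waveform.
#' @param profile A [lowpass_profile()].
#' @param fs Sampling rate in Hz.
#' @return Filtered waveform of the same length.
#' @export
apply_lowpass_clutter <- function(echo, profile, fs) {
  stopifnot(inherits(profile, "lowpass_profile"))
  if (profile$cutoff >= fs / 2) {
    abort("Lowpass cutoff must lie below the Nyquist frequency.")
  }
  target_attr <- attr(echo, "target")
  n <- length(echo)
  f <- abs(c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)) * fs / n
  excess_khz <- pmax(f - profile$cutoff, 0) / 1e3
  atten_db <- pmin(excess_khz * profile$ramp_db_per_khz, profile$max_db)
  out <- Re(fft(fft(echo) * 10^(-atten_db / 20), inverse = TRUE)) / n
  attr(out, "target") <- target_attr
  out
}

#' Assemble a broadcast-plus-echoes sequence
#'
#' Places one broadcast at `broadcast_start` and one multi-glint echo per
#' target at its annotated range delay (measured from the broadcast
#' onset), producing the single-channel waveform the receiver processes.
#' Successive range delays must be separated by at least the declared
#' inter-echo separation so that processing epochs never overlap; the
#' model assumes each broadcast's echo stream is fully segregated.
#'
#' @param broadcast Numeric broadcast waveform.
#' @param targets List of [glint_target()] (may be empty).
#' @param fs Sampling rate in Hz.
#' @param window Window/timing parameters from [scat_windows()].
#' @return An `echo_sequence` object.
#' @examples
#' b <- make_fm_chirp(bat_chirp_spec())
#' seq <- assemble_sequence(b, list(glint_target(6, c(0, 100), c(.5, .5))))
#' @export
assemble_sequence <- function(broadcast,
                              targets = list(),
                              fs = 500e3,
                              window = scat_windows()) {
  for (tg in targets) stopifnot(inherits(tg, "glint_target"))
  delays <- vapply(targets, function(tg) tg$delay, numeric(1))
  if (length(delays) > 1) {
    if (is.unsorted(delays, strictly = TRUE)) {
      abort("Targets must be given in order of strictly increasing range delay.")
    }
    if (any(diff(delays) < window$separation - 1e-9)) {
      abort(sprintf(
        "Overlapping echo windows: successive range delays must be >= %.3f ms apart.",
        window$separation * 1e3
      ))
    }
  }
  dur <- length(broadcast) / fs
  if (length(delays) && min(delays) < dur + 0) {
    # echoes may overlap the broadcast tail for short delays; forbid outright
    # overlap of the broadcast epoch
    if (min(delays) < window$separation) {
      abort("First echo delay must be >= the broadcast/echo separation.")
    }
  }
  echoes <- lapply(targets, make_multiglint_echo, broadcast = broadcast, fs = fs)
  tail_s <- 2e-3
  total <- window$broadcast_start + dur + tail_s +
    if (length(delays)) max(delays + vapply(echoes, length, 1L) / fs) else 0
  n <- ceiling(total * fs)
  samples <- numeric(n)
  add_at <- function(samples, w, at_s) {
    buf <- c(as.numeric(w), numeric(n - length(w)))
    samples + shift_fractional(buf, at_s * fs)
  }
  samples <- add_at(samples, broadcast, window$broadcast_start)
  for (i in seq_along(echoes)) {
    samples <- add_at(samples, echoes[[i]], window$broadcast_start + delays[i])
  }
  structure(
    list(
      samples = samples,
      fs = fs,
      broadcast_start = window$broadcast_start,
      broadcast_duration = dur,
      targets = targets,
      window = window
    ),
    class = "echo_sequence"
  )
}

#' Timing/window parameters of a broadcast-echo sequence
#'
#' Mirrors the parameter set used to describe an example signal:
#' per-frequency signal widths (`callLenForMostFreq`, `callLenForHighFreq`,
#' `callLenSpecial`), the broadcast start time (`whenBrStart`) and the
#' separation between the broadcast and successive echoes
#' (`SepbwBRand1stEchoinSmpls`).  All values in seconds.
#'
#' @param call_len Signal width at most frequencies (s).
#' @param call_len_high Signal width at the highest frequencies (s).
#' @param call_len_special Signal width at the lowest frequencies (s).
#' @param broadcast_start Time at which the broadcast begins (s).
#' @param separation Minimum separation between broadcast and successive
#'   echoes (s).
#' @return A list of window parameters.
#' @export
scat_windows <- function(call_len = 1.5e-3,
                         call_len_high = 1.5e-3,
                         call_len_special = 1.8e-3,
                         broadcast_start = 0.5e-3,
                         separation = 5e-3) {
  list(
    call_len = call_len,
    call_len_high = call_len_high,
    call_len_special = call_len_special,
    broadcast_start = broadcast_start,
    separation = separation
  )
}

#' @export
print.echo_sequence <- function(x, ...) {
  cat(sprintf(
    "<echo_sequence> %d samples @ %.0f kHz (%.2f ms), broadcast %.2f ms at %.2f ms, %d echo(es)\n",
    length(x$samples), x$fs / 1e3, length(x$samples) / x$fs * 1e3,
    x$broadcast_duration * 1e3, x$broadcast_start * 1e3, length(x$targets)
  ))
  invisible(x)
}

#' @export
as_tibble.echo_sequence <- function(x, ...) {
  if (length(x$targets) == 0) {
    return(tibble(
      event = integer(), delay_ms = numeric(), n_glints = integer(),
      delta_t_us = numeric(), attenuation_db = numeric(), lowpass_cutoff_khz = numeric()
    ))
  }
  purrr::imap_dfr(x$targets, function(tg, i) {
    tibble(
      event = i,
      delay_ms = tg$delay * 1e3,
      n_glints = length(tg$offsets),
      delta_t_us = if (length(tg$offsets) > 1) tg$offsets[2] * 1e6 else NA_real_,
      attenuation_db = tg$attenuation_db,
      lowpass_cutoff_khz = if (is.null(tg$lowpass)) NA_real_ else tg$lowpass$cutoff / 1e3
    )
  })
}
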