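#' Standard broadcast presets
#'
#' `bat_chirp_spec()` is the big brown bat two-harmonic FM chirp: 3 ms
#' long, FM1 sweeping 55 to 25 kHz and FM2 90 to 50 kHz, logarithmic
#' downsweeps.  `bat_single_harmonic_spec()` is the one-harmonic 100 to
#' 20 kHz sweep used for the clutter-rejection demonstrations.
#' `dolphin_click_spec()` is the bottlenose dolphin click: a ~50 us
#' transient spanning 40-150 kHz.
#'
#' @param duration_ms Chirp duration in ms.
#' @return A [chirp_spec()] or [click_spec()].
#' @name scat-presets
NULL

#' @rdname scat-presets
#' @export
bat_chirp_spec <- function(duration_ms = 3) {
  chirp_spec(duration_ms, list(c(55, 25), c(90, 50)), sweep = "logarithmic")
}

#' @rdname scat-presets
#' @export
bat_single_harmonic_spec <- function(duration_ms = 3) {
  chirp_spec(duration_ms, list(c(100, 20)), sweep = "logarithmic")
}

#' @rdname scat-presets
#' @export
dolphin_click_spec <- function() {
  click_spec(50, c(40, 150), 95)
}

#' Canonical two-glint study sequences
#'
#' `two_glint_fixture()` builds the worked single-echo example: the bat
#' two-harmonic chirp followed 6 ms later by a two-glint echo with 100 us
#' glint separation (each glint at half the broadcast amplitude).
#' `two_glint_series_sequence()` builds the batch series of two-glint
#' echoes with glint separations 9, 18, 26, 35, 70, 100, 200, 300, 500,
#' 700 us, for either the bat chirp or the dolphin click.
#' `lowpass_series_sequence()` builds the clutter series: a one-harmonic
#' 100-20 kHz FM broadcast followed by seven 100-us two-glint echoes with
#' progressively deeper lowpass filtering.
#'
#' @param delay_ms Range delay of the fixture echo (ms).
#' @param delta_t_us Glint separation(s) in microseconds.
#' @param kind `"bat"` or `"dolphin"` broadcast.
#' @param delta_ts_us Glint separations for the series (us).
#' @param first_delay_ms Range delay of the first echo in a series (ms).
#' @param spacing_ms Spacing between successive echoes in a series (ms).
#' @param glint_gain Linear gain of each of the two glints (default 0.5,
#'   keeping echoes at no more than half the broadcast amplitude).
#' @param cutoffs_khz Lowpass cutoff per clutter echo (kHz).
#' @param ramp_db_per_khz,max_db Lowpass ramp steepness and cap.
#' @param fs Sampling rate (Hz).
#' @return An `echo_sequence`.
#' @examples
#' seq <- two_glint_fixture()
#' @name scat-sequences
NULL

#' @rdname scat-sequences
#' @export
two_glint_fixture <- function(delay_ms = 6, delta_t_us = 100,
                              kind = c("bat", "dolphin"),
                              glint_gain = 0.5, fs = 500e3) {
  kind <- match.arg(kind)
  b <- switch(kind,
    bat = make_fm_chirp(bat_chirp_spec(), fs),
    dolphin = make_click(dolphin_click_spec(), fs)
  )
  assemble_sequence(
    b,
    list(glint_target(delay_ms, c(0, delta_t_us), rep(glint_gain, 2))),
    fs = fs
  )
}

#' @rdname scat-sequences
#' @export
two_glint_series_sequence <- function(kind = c("bat", "dolphin"),
                                      delta_ts_us = c(9, 18, 26, 35, 70, 100, 200, 300, 500, 700),
                                      first_delay_ms = 5,
                                      spacing_ms = 5,
                                      glint_gain = 0.5,
                                      fs = 500e3) {
  kind <- match.arg(kind)
  b <- switch(kind,
    bat = make_fm_chirp(bat_chirp_spec(), fs),
    dolphin = make_click(dolphin_click_spec(), fs)
  )
  targets <- purrr::imap(delta_ts_us, function(dt, i) {
    glint_target(
      first_delay_ms + (i - 1) * spacing_ms,
      c(0, dt), rep(glint_gain, 2)
    )
  })
  assemble_sequence(b, targets, fs = fs)
}

#' @rdname scat-sequences
#' @export
lowpass_series_sequence <- function(delta_t_us = 100,
                                    cutoffs_khz = c(95, 90, 83, 76, 69, 62, 55),
                                    ramp_db_per_khz = 2,
                                    max_db = 40,
                                    first_delay_ms = 5,
                                    spacing_ms = 5,
                                    glint_gain = 0.5,
                                    fs = 500e3) {
  b <- make_fm_chirp(bat_single_harmonic_spec(), fs)
  targets <- purrr::imap(cutoffs_khz, function(cut, i) {
    glint_target(
      first_delay_ms + (i - 1) * spacing_ms,
      c(0, delta_t_us), rep(glint_gain, 2),
      lowpass = lowpass_profile(cut, ramp_db_per_khz, max_db)
    )
  })
  assemble_sequence(b, targets, fs = fs)
}

#' Read and write echo sequences as plain text
#'
#' A sequence is stored as two files: `<path>.txt` holding one sample per
#' line and `<path>.yml` holding the sampling rate, broadcast timing,
#' window parameters and the full ground-truth target annotations.  The
#' round trip is exact to the printed precision (17 significant digits,
#' i.e. lossless for doubles).
#'
#' @param x An `echo_sequence`.
#' @param path Base path (without extension).
#' @return `write_echo_sequence()` returns `path` invisibly;
#'   `read_echo_sequence()` returns the reconstructed `echo_sequence`.
#' @export
write_echo_sequence <- function(x, path) {
  stopifnot(inherits(x, "echo_sequence"))
  writeLines(formatC(x$samples, format = "g", digits = 17), paste0(path, ".txt"))
  meta <- list(
    fs = x$fs,
    broadcast_start = x$broadcast_start,
    broadcast_duration = x$broadcast_duration,
    window = x$window,
    targets = lapply(x$targets, function(tg) {
      list(
        delay = tg$delay,
        offsets = as.list(tg$offsets),
        gains = as.list(tg$gains),
        signs = as.list(tg$signs),
        attenuation_db = tg$attenuation_db,
        lowpass = if (is.null(tg$lowpass)) NULL else unclass(tg$lowpass)
      )
    })
  )
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 17)
  invisible(path)
}

#' @rdname write_echo_sequence
#' @export
read_echo_sequence <- function(path) {
  samples <- as.numeric(readLines(paste0(path, ".txt")))
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  targets <- lapply(meta$targets, function(tg) {
    glint_target(
      delay_ms = tg$delay * 1e3,
      offsets_us = unlist(tg$offsets) * 1e6,
      gains = unlist(tg$gains),
      signs = unlist(tg$signs),
      lowpass = if (is.null(tg$lowpass)) {
        NULL
      } else {
        lowpass_profile(
          tg$lowpass$cutoff / 1e3, tg$lowpass$ramp_db_per_khz, tg$lowpass$max_db
        )
      },
      attenuation_db = tg$attenuation_db
    )
  })
  structure(
    list(
      samples = samples,
      fs = meta$fs,
      broadcast_start = meta$broadcast_start,
      broadcast_duration = meta$broadcast_duration,
      targets = targets,
      window = meta$window
    ),
    class = "echo_sequence"
  )
}
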