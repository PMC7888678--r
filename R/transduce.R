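#' Auditory transduction of filterbank outputs
#'
#' Converts band signals into a cochleagram: each channel is half-wave
#' rectified and smoothed with a causal 2nd-order Butterworth lowpass at
#' 10 kHz.  The cutoff is deliberately high: channels tuned near or below
#' the cutoff keep visible cycle-by-cycle structure (the model's access to
#' fine timing at the low end of the chirp), while channels well above it
#' come out as smooth envelopes.  The smoother is applied forward only -
#' latency carries the model's information, so zero-phase filtering would
#' destroy the quantity being computed.
#'
#' Rectification is a nonlinearity: it creates harmonics of the carrier
#' (2f, 4f, ...) that can alias through the sampling rate into the
#' passband of the smoother for carriers near integer fractions of the
#' sampling rate.  To keep those artifacts out of the envelope, each
#' channel is rectified and smoothed at twice the sampling rate
#' (band-limited interpolation) and decimated back afterwards.
#'
#' @param bands A `scat_bands` object from [run_filterbank()].
#' @param lowpass_cutoff Smoothing cutoff in Hz (default 10 kHz).
#' @param lowpass_order Butterworth order (default 2).
#' @return A `cochleagram` object (channels x samples, all values >= 0).
#' @export
transduce <- function(bands, lowpass_cutoff = 10e3, lowpass_order = 2) {
  stopifnot(inherits(bands, "scat_bands"))
  fs <- attr(bands, "fs")
  bf <- signal::butter(lowpass_order, lowpass_cutoff / fs, type = "low")
  out <- unclass(bands)
  n <- ncol(out)
  amp <- out
  for (i in seq_len(nrow(out))) {
    x2 <- upsample2(out[i, ])
    y2 <- signal::filter(bf, pmax(x2, 0))
    out[i, ] <- y2[seq(1L, 2L * n, by = 2L)]
    # second smoothing pass: amplitude reference envelope, free of the
    # residual carrier ripple that shifts raw envelope maxima of
    # few-cycle transients
    amp[i, ] <- signal::filter(bf, y2)[seq(1L, 2L * n, by = 2L)]
  }
  out <- pmax(out, 0)
  amp <- pmax(amp, 0)
  structure(out,
    cf = attr(bands, "cf"), fs = fs, config = attr(bands, "config"),
    amp = amp, full_scale = NA_real_, class = "cochleagram"
  )
}

# Exact band-limited 2x upsampling by spectral zero-insertion.
upsample2 <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- floor(n / 2)
  X2 <- complex(2L * n)
  X2[1:(h + 1)] <- X[1:(h + 1)]
  X2[(2L * n - (n - h - 2)):(2L * n)] <- X[(h + 2):n]
  2 * Re(fft(X2, inverse = TRUE)) / (2L * n)
}

#' Broadcast-referenced gain normalization
#'
#' Scales the whole cochleagram so that the global maximum inside the
#' broadcast window equals 1.0 full scale.  This mimics the animal's gain
#' control: the self-heard broadcast is squeezed to occupy the full
#' dynamic range of the ten threshold levels, and echoes (normally no more
#' than about half the broadcast amplitude) sit lower on the same scale.
#'
#' @param coch A `cochleagram`.
#' @param broadcast_window `c(start, end)` of the broadcast epoch in
#'   seconds.
#' @return The rescaled `cochleagram` with `attr(, "full_scale") = 1`.
#' @export
normalize_gain <- function(coch, broadcast_window) {
  stopifnot(inherits(coch, "cochleagram"))
  fs <- attr(coch, "fs")
  i0 <- max(1L, floor(broadcast_window[1] * fs) + 1L)
  i1 <- min(ncol(coch), ceiling(broadcast_window[2] * fs))
  if (i1 <= i0) abort("Broadcast window is empty.")
  peak <- max(coch[, i0:i1])
  if (peak <= 0 || peak < 1e-9 * max(coch)) {
    abort("Silent broadcast window: cannot normalize gain.")
  }
  out <- unclass(coch) / peak
  amp <- attr(coch, "amp")
  structure(out,
    cf = attr(coch, "cf"), fs = fs, config = attr(coch, "config"),
    amp = if (is.null(amp)) NULL else amp / peak,
    full_scale = 1, class = "cochleagram"
  )
}
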