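#' Threshold levels of the crossing detector
#'
#' Ten equally spaced amplitude thresholds from 3% to 98% of full scale:
#' `fraction_k = 0.03 + (k - 1) * (0.98 - 0.03) / 9`.
#'
#' @param n_levels Number of levels (default 10).
#' @param start,end Lowest and highest level as fractions of full scale.
#' @return Numeric vector of level fractions, strictly increasing.
#' @examples
#' threshold_levels()   # 0.03 ... 0.98
#' @export
threshold_levels <- function(n_levels = 10, start = 0.03, end = 0.98) {
  if (n_levels < 2 || start >= end) abort("Invalid threshold configuration.")
  start + (seq_len(n_levels) - 1) * (end - start) / (n_levels - 1)
}

#' Event windows of a broadcast-echo sequence
#'
#' Partitions a sequence into one processing epoch per sound: event 0 is
#' the broadcast, events 1..K the echoes, each window running from the
#' sound's onset to its onset plus the broadcast duration plus the
#' per-frequency signal width.  Overlapping windows are rejected; the
#' model requires echo streams to be fully segregated.
#'
#' @param seq An `echo_sequence`.
#' @param call_len Signal width appended to each sound's duration (s);
#'   defaults to the sequence's `call_len_special`.
#' @return Tibble with columns `event`, `kind`, `start`, `end` (seconds).
#' @export
scat_events <- function(seq, call_len = NULL) {
  stopifnot(inherits(seq, "echo_sequence"))
  call_len <- call_len %||% seq$window$call_len_special
  dur <- seq$broadcast_duration
  delays <- vapply(seq$targets, function(tg) tg$delay, numeric(1))
  ev <- tibble(
    event = c(0L, seq_along(seq$targets)),
    kind = c("broadcast", rep("echo", length(seq$targets))),
    start = seq$broadcast_start + c(0, delays),
    end = seq$broadcast_start + c(0, delays) + dur + call_len
  )
  if (nrow(ev) > 1) {
    if (any(diff(ev$start) <= 0)) abort("Overlapping event windows.")
    # a window may not run into the next event's onset
    ev$end[-nrow(ev)] <- pmin(ev$end[-nrow(ev)], ev$start[-1])
  }
  ev
}

#' Detect threshold crossings
#'
#' For every event, channel and threshold level, finds the first upward
#' crossing of the smoothed envelope within the event window, linearly
#' interpolated between samples.  A threshold that is never crossed is
#' recorded as missing (`NA`), and because envelopes start from zero the
#' crossing times are non-decreasing in level.  The per-event, per-channel
#' envelope peak and energy (the amplitude references for
#' amplitude-latency trading) are attached as the `"peaks"` attribute.
#'
#' @param coch A gain-normalized `cochleagram`.
#' @param events Event window tibble from [scat_events()].
#' @param levels Threshold level fractions from [threshold_levels()].
#' @return A tibble of class `scat_crossings` with columns `event`,
#'   `kind`, `channel`, `cf_khz`, `level`, `time` (seconds, `NA` when the
#'   level is never crossed), plus attributes `peaks` and `levels`.
#' @export
detect_crossings <- function(coch, events, levels = threshold_levels()) {
  stopifnot(inherits(coch, "cochleagram"))
  if (is.na(attr(coch, "full_scale"))) {
    abort("Cochleagram must be gain-normalized before crossing detection.")
  }
  fs <- attr(coch, "fs")
  cf <- attr(coch, "cf")
  amp <- attr(coch, "amp")
  if (is.null(amp)) amp <- unclass(coch)
  n_lev <- length(levels)
  n_ch <- nrow(coch)
  res <- vector("list", nrow(events) * n_ch)
  peaks <- vector("list", nrow(events))
  k <- 0L
  for (e in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$start[e] * fs) + 1L)
    i1 <- min(ncol(coch), ceiling(events$end[e] * fs))
    seg_t0 <- (i0 - 1) / fs
    pk <- numeric(n_ch)
    en <- numeric(n_ch)
    for (ch in seq_len(n_ch)) {
      env <- coch[ch, i0:i1]
      pk[ch] <- max(amp[ch, i0:i1])
      en[ch] <- sum(env^2) / fs
      times <- first_crossings(env, levels, fs, seg_t0)
      k <- k + 1L
      res[[k]] <- tibble(
        event = events$event[e],
        kind = events$kind[e],
        channel = ch,
        cf_khz = cf[ch] / 1e3,
        level = seq_len(n_lev),
        time = times
      )
    }
    peaks[[e]] <- tibble(
      event = events$event[e], kind = events$kind[e],
      channel = seq_len(n_ch), cf_khz = cf / 1e3, peak = pk, energy = en
    )
  }
  out <- dplyr::bind_rows(res)
  structure(out,
    peaks = dplyr::bind_rows(peaks),
    levels = levels,
    fs = fs,
    class = c("scat_crossings", class(out))
  )
}

# First upward crossing of each level in an envelope segment, linearly
# interpolated; NA where never crossed.  A crossing requires a rising
# transition env[i-1] < L <= env[i], so a segment that starts above a
# level does not count as crossing it.
first_crossings <- function(env, levels, fs, t0) {
  vapply(levels, function(L) {
    above <- env >= L
    i <- which(above & !dplyr::lag(above, default = FALSE))[1]
    if (is.na(i) || i == 1L) return(NA_real_)
    frac <- (L - env[i - 1]) / (env[i] - env[i - 1])
    t0 + (i - 2 + frac) / fs
  }, numeric(1))
}

#' @export
print.scat_crossings <- function(x, ...) {
  cat(sprintf(
    "<scat_crossings> %d events x %d channels x %d levels (%.1f%% crossed)\n",
    dplyr::n_distinct(x$event), dplyr::n_distinct(x$channel),
    length(attr(x, "levels")), 100 * mean(!is.na(x$time))
  ))
  NextMethod()
}
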