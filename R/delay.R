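#' Low-frequency gate on echo processing
#'
#' Big brown bats require the lowest broadcast frequencies (about
#' 25-30 kHz) to be present in an echo before any delay processing is
#' started; echoes missing them are rejected outright.  An echo passes
#' the gate when first-level threshold crossings are present across the
#' gate band - by default in at least half of its channels.  A single
#' crossing does not suffice: with 4-kHz ERBs the skirt of the uppermost
#' gate channel still responds to energy just above the band, so an echo
#' stripped of its low frequencies can leak one spurious crossing.
#'
#' @param crossings A `scat_crossings` map.
#' @param gate_band_khz `c(lo, hi)` gate band in kHz (default 25-30).
#' @param min_fraction Fraction of gate-band channels that must carry a
#'   level-1 crossing.
#' @return Tibble with one row per echo event: `event`, `accepted`,
#'   `n_gate_channels` (gate-band channels with a level-1 crossing).
#' @export
low_frequency_gate <- function(crossings, gate_band_khz = c(25, 30),
                               min_fraction = 0.5) {
  in_band <- crossings$cf_khz >= gate_band_khz[1] &
    crossings$cf_khz <= gate_band_khz[2]
  n_band <- dplyr::n_distinct(crossings$channel[in_band])
  crossings |>
    dplyr::filter(.data$kind == "echo", .data$level == 1L) |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      n_gate_channels = sum(
        !is.na(.data$time) &
          .data$cf_khz >= gate_band_khz[1] & .data$cf_khz <= gate_band_khz[2]
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(accepted = .data$n_gate_channels >= ceiling(min_fraction * n_band)) |>
    dplyr::select("event", "accepted", "n_gate_channels")
}

#' Dechirp crossing times against the broadcast
#'
#' Re-references every echo crossing time to the broadcast crossing time
#' in the same channel at the same threshold level.  This removes the
#' time-frequency slope of the FM sweep: the broadcast maps onto a
#' vertical line at zero delay and a flat single-glint echo onto a
#' vertical line at its true range delay.  A cell is missing whenever the
#' echo or the broadcast lacks the corresponding crossing.
#'
#' @param crossings A `scat_crossings` map containing the broadcast event.
#' @return Tibble of class `scat_dechirped` with columns `event`,
#'   `channel`, `cf_khz`, `level`, `delay` (seconds, `NA` when missing).
#'   Channels are ordered from lowest to highest frequency.
#' @export
dechirp <- function(crossings) {
  br <- crossings |>
    dplyr::filter(.data$kind == "broadcast") |>
    dplyr::select("channel", "level", br_time = "time")
  out <- crossings |>
    dplyr::filter(.data$kind == "echo") |>
    dplyr::left_join(br, by = c("channel", "level")) |>
    dplyr::mutate(delay = .data$time - .data$br_time) |>
    dplyr::arrange(.data$event, .data$cf_khz, .data$level) |>
    dplyr::select("event", "channel", "cf_khz", "level", "delay")
  structure(out,
    levels = attr(crossings, "levels"),
    fs = attr(crossings, "fs"),
    alt_applied = FALSE,
    class = c("scat_dechirped", class(out))
  )
}

#' Per-channel echo attenuation relative to the broadcast
#'
#' Attenuation is measured inside the event windows from the peaks of
#' the doubly-smoothed amplitude envelope:
#' `20 * log10(broadcast peak / echo peak)` per channel, floored at 0 dB
#' (an echo louder than the broadcast in a channel trades no latency)
#' and capped at 80 dB.  The doubly-smoothed envelope is used because
#' the raw envelope maximum of a few-cycle transient depends on
#' carrier-phase alignment, which would inject decibel-scale jitter into
#' the attenuation profile.  With `statistic = "energy"` the integrated
#' response `10 * log10(broadcast energy / echo energy)` is returned
#' instead - the cue that remains sensitive when the two reflections
#' only partly overlap in time (click echoes near the integration
#' limit).  For a uniformly attenuated echo both statistics equal the
#' attenuation in dB.
#'
#' @param crossings A `scat_crossings` map (uses its `"peaks"` attribute).
#' @param statistic `"peak"` (default) or `"energy"`.
#' @return Tibble `event`, `channel`, `cf_khz`, `attenuation_db`.
#' @export
channel_attenuation <- function(crossings, statistic = c("peak", "energy")) {
  statistic <- match.arg(statistic)
  peaks <- attr(crossings, "peaks")
  br <- peaks |>
    dplyr::filter(.data$kind == "broadcast") |>
    dplyr::select("channel", br_peak = "peak", br_energy = "energy")
  peaks |>
    dplyr::filter(.data$kind == "echo") |>
    dplyr::left_join(br, by = "channel") |>
    dplyr::mutate(
      attenuation_db = if (statistic == "peak") {
        20 * log10(.data$br_peak / pmax(.data$peak, 1e-12))
      } else {
        10 * log10(.data$br_energy / pmax(.data$energy, 1e-24))
      },
      attenuation_db = pmin(pmax(.data$attenuation_db, 0), 80)
    ) |>
    dplyr::select("event", "channel", "cf_khz", "attenuation_db")
}

#' Apply amplitude-latency trading
#'
#' Auditory latency lengthens as stimulus amplitude drops; the model uses
#' 25 us of added latency per decibel of attenuation.  Each dechirped
#' delay cell is augmented by `coefficient x attenuation(channel)` on top
#' of the natural threshold-crossing retardation; missing cells stay
#' missing.  Negative attenuations have already been clamped to zero.
#'
#' @param dechirped A `scat_dechirped` table.
#' @param attenuation Per-channel attenuation from [channel_attenuation()]
#'   (columns `event`, `channel`, `attenuation_db`).
#' @param alt_us_per_db Trading coefficient, us per dB (magnitude;
#'   default 25).
#' @return The augmented `scat_dechirped` table.
#' @examples
#' # 1 dB of attenuation lengthens every delay in that channel by 25 us
#' @export
apply_alt <- function(dechirped, attenuation, alt_us_per_db = 25) {
  if (alt_us_per_db < 0) abort("`alt_us_per_db` is a magnitude; it must be >= 0.")
  out <- dechirped |>
    dplyr::left_join(
      dplyr::select(attenuation, "event", "channel", "attenuation_db"),
      by = c("event", "channel")
    ) |>
    dplyr::mutate(
      delay = .data$delay + alt_us_per_db * 1e-6 * pmax(.data$attenuation_db, 0)
    ) |>
    dplyr::select("event", "channel", "cf_khz", "level", "delay")
  structure(out,
    levels = attr(dechirped, "levels"),
    fs = attr(dechirped, "fs"),
    alt_applied = TRUE,
    class = class(dechirped)
  )
}

# Leading edge of a delay histogram: left boundary of the earliest
# contiguous run of occupied bins at which the cumulative count first
# reaches `lead_frac` of the total mass.
leading_edge <- function(counts, edges, lead_frac) {
  occ <- counts > 0
  run_id <- cumsum(occ & !dplyr::lag(occ, default = FALSE))
  run_id[!occ] <- NA
  cum <- cumsum(counts)
  total <- sum(counts)
  first_bin <- which(occ & cum >= lead_frac * total)[1]
  edges[which(run_id == run_id[first_bin])[1]]
}

#' Estimate range delay from the dechirped histogram
#'
#' Accumulates all non-missing dechirped delays of an echo into a
#' histogram (default bin width one sample period, 2 us at 500 kHz) and
#' takes the target's range delay from the histogram's leading edge: the
#' left boundary of the earliest contiguous bin cluster at which the
#' cumulative count reaches a configurable fraction (default 10%) of the
#' total mass.  The leading edge is used because amplitude-latency
#' trading drags the tail of the histogram to longer delays; the long
#' threshold marks are discounted by the leading-edge rule rather than
#' deleted.
#'
#' @param dechirped A `scat_dechirped` table (normally ALT-applied).
#' @param event Echo event id.
#' @param levels Which threshold levels feed the histogram: `"first"`
#'   (level 1 only, least ALT-biased; the default) or `"all"` (pooled,
#'   skewed) or an integer vector.
#' @param bin_s Histogram bin width in seconds.
#' @param lead_frac Leading-edge mass fraction.
#' @param min_channels Minimum contributing channels for a reliable
#'   estimate.
#' @return List of class `range_delay_estimate`: `t` (seconds), `t_ms`,
#'   `histogram` (tibble `delay`, `count`), `n`, `reliable`.
#' @export
estimate_range_delay <- function(dechirped, event,
                                 levels = c("first", "all"),
                                 bin_s = 2e-6,
                                 lead_frac = 0.1,
                                 min_channels = 5) {
  lev <- if (is.numeric(levels)) {
    as.integer(levels)
  } else {
    switch(match.arg(levels), first = 1L, all = seq_along(attr(dechirped, "levels")))
  }
  d <- dechirped$delay[dechirped$event == event & dechirped$level %in% lev]
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    return(structure(
      list(
        t = NA_real_, t_ms = NA_real_,
        histogram = tibble(delay = numeric(), count = integer()),
        n = 0L, reliable = FALSE
      ),
      class = "range_delay_estimate"
    ))
  }
  idx <- floor(d / bin_s)
  rng <- range(idx)
  counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  edges <- (rng[1]:rng[2]) * bin_s
  t <- leading_edge(counts, edges, lead_frac)
  structure(
    list(
      t = t,
      t_ms = t * 1e3,
      histogram = tibble(delay = edges, count = counts),
      n = length(d),
      reliable = length(unique(
        dechirped$channel[dechirped$event == event &
          dechirped$level %in% lev & !is.na(dechirped$delay)]
      )) >= min_channels
    ),
    class = "range_delay_estimate"
  )
}

#' @export
print.range_delay_estimate <- function(x, ...) {
  cat(sprintf(
    "<range_delay_estimate> t = %.3f ms (%d entries%s)\n",
    x$t_ms, x$n, if (x$reliable) "" else ", unreliable"
  ))
  invisible(x)
}

#' Resolve widely separated glints as separate range delays
#'
#' When two glint reflections are farther apart than the receiver's
#' integration time they no longer interfere: each produces its own
#' envelope rise in every channel and the pair registers as two range
#' delays rather than one rippled echo.  A channel reports a second
#' onset when, after its envelope has risen to a substantial peak
#' (`qualify_frac` of the channel's event maximum), the envelope falls
#' back below the lowest threshold for at least `silence_gap` seconds -
#' genuine silence between two separate sounds, longer than any
#' half-wave-rectification ripple dip - and then crosses the lowest
#' threshold upward again, no earlier than `min_sep` (about the
#' integration time of echo reception) after the first crossing.
#' Channels whose broadcast response itself shows such a second onset
#' (harmonic seam channels receiving both FM1 and FM2 energy) are
#' excluded.  A second range-delay estimate is emitted when second
#' onsets appear in at least `split_frac` of the responding channels
#' (and at least `min_channels`), using only the tight cluster around
#' the modal onset delay.
#'
#' @param coch Gain-normalized `cochleagram`.
#' @param crossings `scat_crossings` for the same sequence.
#' @param events Event windows from [scat_events()].
#' @param min_sep Minimum separation between onsets (s); about the
#'   integration time of echo reception (250 us dolphin, 300 us bat).
#' @param silence_gap Minimum below-threshold gap before a second onset
#'   (s); must exceed the rectification ripple period of the lowest
#'   channel.
#' @param qualify_frac Fraction of the channel's event maximum the first
#'   sound must reach before a silence gap counts.
#' @param split_frac Minimum fraction of responding channels that must
#'   report a second onset.
#' @param levels Threshold level fractions.
#' @param bin_s,lead_frac,min_channels Leading-edge histogram parameters
#'   for both estimates.
#' @return Tibble: `event`, `glint` (1 or 2), `t` (s), `t_ms`, `n`.
#' @export
resolve_separate_glints <- function(coch, crossings, events,
                                    min_sep = 250e-6,
                                    silence_gap = 50e-6,
                                    qualify_frac = 0.5,
                                    split_frac = 0.15,
                                    levels = threshold_levels(),
                                    bin_s = 2e-6,
                                    lead_frac = 0.1,
                                    min_channels = 5) {
  stopifnot(inherits(coch, "cochleagram"))
  fs <- attr(coch, "fs")
  lev1 <- levels[1] * attr(coch, "full_scale")
  gap_n <- max(1L, round(silence_gap * fs))
  # interpolated second level-1 upward crossing after a qualified
  # silence gap; NA when the channel holds a single sound
  second_onset <- function(env, t1, seg_t0) {
    j1 <- max(1L, floor((t1 - seg_t0) * fs) + 1L)
    if (j1 >= length(env)) return(NA_real_)
    te <- env[j1:length(env)]
    n <- length(te)
    t_rel <- (seq_along(te) - 1) / fs
    jq <- which(te >= qualify_frac * max(te))[1]
    below <- te < lev1
    r <- rle(below)
    runlen <- rep(r$lengths, r$lengths)
    prev_gap <- c(0, runlen[-n]) * c(FALSE, below[-n])
    rec <- which(
      te >= lev1 & c(FALSE, below[-n]) &
        prev_gap >= gap_n & t_rel >= min_sep & seq_along(te) > jq
    )[1]
    if (is.na(rec)) return(NA_real_)
    frac <- (lev1 - te[rec - 1]) / (te[rec] - te[rec - 1])
    seg_t0 + (j1 - 1 + rec - 2 + frac) / fs
  }
  brev <- events[events$kind == "broadcast", ]
  bi0 <- max(1L, floor(brev$start * fs) + 1L)
  bi1 <- min(ncol(coch), ceiling(brev$end * fs))
  br_c1 <- crossings |>
    dplyr::filter(.data$kind == "broadcast", .data$level == 1L) |>
    dplyr::select("channel", br_time = "time")
  eligible <- vapply(seq_len(nrow(coch)), function(ch) {
    t1 <- br_c1$br_time[br_c1$channel == ch]
    if (length(t1) == 0 || is.na(t1)) return(FALSE)
    is.na(second_onset(coch[ch, bi0:bi1], t1, (bi0 - 1) / fs))
  }, logical(1))
  out <- list()
  for (e in events$event[events$kind == "echo"]) {
    ev <- events[events$event == e, ]
    i0 <- max(1L, floor(ev$start * fs) + 1L)
    i1 <- min(ncol(coch), ceiling(ev$end * fs))
    seg_t0 <- (i0 - 1) / fs
    c1 <- crossings |>
      dplyr::filter(.data$event == e, .data$level == 1L) |>
      dplyr::select("channel", c1 = "time") |>
      dplyr::left_join(br_c1, by = "channel")
    d1 <- (c1$c1 - c1$br_time)[!is.na(c1$c1) & !is.na(c1$br_time) & eligible[c1$channel]]
    n1 <- length(d1)
    d2 <- numeric()
    for (ch in which(eligible)) {
      t1 <- c1$c1[c1$channel == ch]
      b1 <- c1$br_time[c1$channel == ch]
      if (length(t1) == 0 || is.na(t1) || is.na(b1)) next
      c2 <- second_onset(coch[ch, i0:i1], t1, seg_t0)
      if (!is.na(c2)) d2 <- c(d2, c2 - b1)
    }
    # keep only the tight cluster around the modal second-onset delay
    if (length(d2)) {
      coarse <- floor(d2 / (2 * min_sep / 5))
      m <- as.numeric(names(sort(table(coarse), decreasing = TRUE))[1])
      d2 <- d2[abs(coarse - m) <= 1]
    }
    split <- length(d2) >= max(min_channels, split_frac * n1)
    mk <- function(d, g) {
      if (length(d) < min_channels) return(NULL)
      idx <- floor(d / bin_s)
      rng <- range(idx)
      counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
      t <- leading_edge(counts, (rng[1]:rng[2]) * bin_s, lead_frac)
      tibble(event = e, glint = g, t = t, t_ms = t * 1e3, n = length(d))
    }
    out[[length(out) + 1L]] <- dplyr::bind_rows(
      mk(d1, 1L),
      if (split) mk(d2, 2L)
    )
  }
  dplyr::bind_rows(out)
}
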