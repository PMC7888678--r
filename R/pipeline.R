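#' Receiver configuration
#'
#' Bundles every tunable parameter of the receiver, preset per species.
#' The core timing parameters mirror the conventional names used to
#' describe a broadcast-echo sequence (`Fs`, `callLenForMostFreq`,
#' `callLenForHighFreq`, `callLenSpecial`, `whenBrStart`,
#' `startingThPercent`, `SepbwBRand1stEchoinSmpls`, `NT`, `ALT`) and can
#' be round-tripped through YAML with [write_scat_config()].
#'
#' @param mode `"bat"` or `"dolphin"`.
#' @param fs Sampling rate (Hz).
#' @param windows Timing parameters from [scat_windows()].
#' @param n_levels,th_start,th_end Threshold ladder (see
#'   [threshold_levels()]).
#' @param alt_us_per_db Amplitude-latency trading coefficient
#'   (magnitude, us/dB; stored with negative sign in YAML by the
#'   `-25 us/dB` convention).
#' @param lowpass_cutoff,lowpass_order Transduction smoother.
#' @param gate_band_khz Low-frequency gate band (bat mode; `NULL`
#'   disables the gate).
#' @param bin_s,lead_frac,min_channels,hist_levels Range-delay histogram
#'   parameters (see [estimate_range_delay()]).
#' @param second_min_sep,silence_gap,qualify_frac,split_frac
#'   Separate-glint resolution (see [resolve_separate_glints()]).
#' @param support_level,void_level,min_prominence_us Null-detection
#'   evidence thresholds (see [find_nulls()]).
#' @param filterbank A [filterbank_config()].
#' @param network A [triangular_network()].
#' @param ... Unused.
#' @return A `scat_config` list.
#' @examples
#' cfg <- scat_config("bat")
#' @export
scat_config <- function(mode = c("bat", "dolphin"),
                        fs = 500e3,
                        windows = scat_windows(),
                        n_levels = 10,
                        th_start = 0.03,
                        th_end = 0.98,
                        alt_us_per_db = 25,
                        lowpass_cutoff = 10e3,
                        lowpass_order = 2,
                        gate_band_khz = NULL,
                        bin_s = 2e-6,
                        lead_frac = 0.1,
                        min_channels = 5,
                        hist_levels = "first",
                        second_min_sep = NULL,
                        silence_gap = 50e-6,
                        qualify_frac = 0.5,
                        split_frac = 0.15,
                        support_level = 2,
                        void_level = 4,
                        min_prominence_us = 25,
                        filterbank = NULL,
                        network = NULL,
                        ...) {
  mode <- match.arg(mode)
  structure(
    list(
      mode = mode,
      fs = fs,
      windows = windows,
      n_levels = n_levels,
      th_start = th_start,
      th_end = th_end,
      alt_us_per_db = alt_us_per_db,
      lowpass_cutoff = lowpass_cutoff,
      lowpass_order = lowpass_order,
      gate_band_khz = if (mode == "bat") gate_band_khz %||% c(25, 30) else gate_band_khz,
      bin_s = bin_s,
      lead_frac = lead_frac,
      min_channels = min_channels,
      hist_levels = hist_levels,
      second_min_sep = second_min_sep %||% switch(mode, bat = 300e-6, dolphin = 250e-6),
      silence_gap = silence_gap,
      qualify_frac = qualify_frac,
      split_frac = split_frac,
      support_level = support_level,
      void_level = void_level,
      min_prominence_us = min_prominence_us,
      filterbank = filterbank %||% filterbank_config(mode),
      network = network %||% triangular_network(mode)
    ),
    class = "scat_config"
  )
}

#' Write or read a receiver configuration as YAML
#'
#' The YAML uses the conventional sequence-description keys (`Fs`,
#' `callLenForMostFreq`, `callLenForHighFreq`, `callLenSpecial`,
#' `whenBrStart`, `startingThPercent`, `SepbwBRand1stEchoinSmpls`, `NT`,
#' `ALT`) plus the receiver's own keys.  `ALT` is written with the
#' negative sign convention (latency added per dB of attenuation).
#'
#' @param config A `scat_config`.
#' @param path YAML file path.
#' @export
write_scat_config <- function(config, path) {
  stopifnot(inherits(config, "scat_config"))
  yaml::write_yaml(list(
    mode = config$mode,
    Fs = config$fs,
    callLenForMostFreq = config$windows$call_len,
    callLenForHighFreq = config$windows$call_len_high,
    callLenSpecial = config$windows$call_len_special,
    whenBrStart = config$windows$broadcast_start,
    SepbwBRand1stEchoinSmpls = config$windows$separation,
    NT = config$n_levels,
    startingThPercent = config$th_start,
    endingThPercent = config$th_end,
    ALT = -config$alt_us_per_db,
    lowpassCutoff = config$lowpass_cutoff,
    lowpassOrder = config$lowpass_order,
    gateBandkHz = config$gate_band_khz,
    binSeconds = config$bin_s,
    leadFraction = config$lead_frac,
    minChannels = config$min_channels,
    histLevels = config$hist_levels,
    secondMinSep = config$second_min_sep,
    silenceGap = config$silence_gap,
    qualifyFraction = config$qualify_frac,
    splitFraction = config$split_frac,
    supportLevel = config$support_level,
    voidLevel = config$void_level,
    minProminenceUs = config$min_prominence_us
  ), path, precision = 17)
  invisible(path)
}

#' @rdname write_scat_config
#' @export
read_scat_config <- function(path) {
  y <- yaml::read_yaml(path)
  scat_config(
    mode = y$mode,
    fs = y$Fs,
    windows = scat_windows(
      call_len = y$callLenForMostFreq,
      call_len_high = y$callLenForHighFreq,
      call_len_special = y$callLenSpecial,
      broadcast_start = y$whenBrStart,
      separation = y$SepbwBRand1stEchoinSmpls
    ),
    n_levels = y$NT,
    th_start = y$startingThPercent,
    th_end = y$endingThPercent,
    alt_us_per_db = abs(y$ALT),
    lowpass_cutoff = y$lowpassCutoff,
    lowpass_order = y$lowpassOrder,
    gate_band_khz = unlist(y$gateBandkHz),
    bin_s = y$binSeconds,
    lead_frac = y$leadFraction,
    min_channels = y$minChannels,
    hist_levels = y$histLevels,
    second_min_sep = y$secondMinSep,
    silence_gap = y$silenceGap,
    qualify_frac = y$qualifyFraction,
    split_frac = y$splitFraction,
    support_level = y$supportLevel,
    void_level = y$voidLevel,
    min_prominence_us = y$minProminenceUs
  )
}

#' Run the full receiver on a sequence
#'
#' End-to-end processing of a broadcast-echo sequence: gammatone
#' filterbank, transduction, broadcast-referenced gain normalization,
#' threshold-crossing detection, the low-frequency gate (bat mode),
#' dechirping with amplitude-latency trading, leading-edge range-delay
#' estimation, separate-glint resolution, spectral-null detection,
#' the triangular coincidence network with lowpass fill-in, and
#' image-energy normalization.  Echoes rejected by the gate carry no
#' image; echoes resolved into two separate range delays carry no
#' interference-based glint estimate.
#'
#' @param seq An `echo_sequence`.
#' @param config A [scat_config()].
#' @return A `scat_image` object; see [tidy.scat_image()].
#' @examples
#' \donttest{
#' img <- scat_run(two_glint_fixture(), scat_config("bat"))
#' tidy(img)
#' }
#' @export
scat_run <- function(seq, config = scat_config("bat")) {
  stopifnot(inherits(seq, "echo_sequence"), inherits(config, "scat_config"))
  fs <- seq$fs
  levels <- threshold_levels(config$n_levels, config$th_start, config$th_end)
  bands <- run_filterbank(seq, config$filterbank, fs)
  coch <- transduce(bands, config$lowpass_cutoff, config$lowpass_order)
  events <- scat_events(seq)
  coch <- normalize_gain(
    coch,
    c(events$start[events$kind == "broadcast"], events$end[events$kind == "broadcast"])
  )
  crossings <- detect_crossings(coch, events, levels)
  gate <- if (!is.null(config$gate_band_khz)) {
    low_frequency_gate(crossings, config$gate_band_khz)
  } else {
    tibble(
      event = events$event[events$kind == "echo"],
      accepted = TRUE, n_gate_channels = NA_integer_
    )
  }
  resolved <- resolve_separate_glints(
    coch, crossings, events,
    min_sep = config$second_min_sep,
    silence_gap = config$silence_gap,
    qualify_frac = config$qualify_frac,
    split_frac = config$split_frac,
    levels = levels,
    bin_s = config$bin_s,
    lead_frac = config$lead_frac,
    min_channels = config$min_channels
  )
  dech <- dechirp(crossings)
  alt <- apply_alt(dech, channel_attenuation(crossings), config$alt_us_per_db)
  range_list <- list()
  glint_list <- list()
  null_list <- list()
  for (e in events$event[events$kind == "echo"]) {
    key <- as.character(e)
    if (!gate$accepted[gate$event == e]) next
    range_list[[key]] <- estimate_range_delay(
      alt, e,
      levels = config$hist_levels, bin_s = config$bin_s,
      lead_frac = config$lead_frac, min_channels = config$min_channels
    )
    split <- any(resolved$event == e & resolved$glint == 2L)
    if (split) next
    ns <- find_nulls(
      alt, crossings, e,
      network = config$network,
      support_level = config$support_level,
      void_level = config$void_level,
      min_prominence_us = config$min_prominence_us
    )
    null_list[[key]] <- ns
    ap <- run_triangular_network(ns, config$network)
    all_apexes <- dplyr::bind_rows(ap$apexes, fill_lowpass_void(ns, config$network))
    est <- invert_spacing(all_apexes, config$network)
    if (sum(est$histogram$count) > 0) est <- normalize_image_energy(est)
    glint_list[[key]] <- est
  }
  assemble_image(
    range_estimates = range_list,
    glint_estimates = glint_list,
    nullsets = null_list,
    resolved = resolved,
    gate = gate,
    dechirped = alt,
    seq = seq,
    config = config
  )
}

#' Assemble the joint range-delay and glint-delay image
#'
#' Merges the two parallel delay estimates into the model's composite
#' output: per echo, a range delay `t` (two when separate-glint
#' resolution fired, in which case there is no interference-based glint
#' delay) and a glint delay `delta_t` attached to it.
#'
#' @param range_estimates Named list (by event id) of
#'   [estimate_range_delay()] results.
#' @param glint_estimates Named list (by event id) of
#'   [invert_spacing()] results; ids must be a subset of the range ids.
#' @param nullsets,resolved,gate,dechirped,seq,config Optional supporting
#'   traces carried along for plotting and tidying.
#' @return A `scat_image` object.
#' @export
assemble_image <- function(range_estimates,
                           glint_estimates = list(),
                           nullsets = list(),
                           resolved = NULL,
                           gate = NULL,
                           dechirped = NULL,
                           seq = NULL,
                           config = NULL) {
  if (length(setdiff(names(glint_estimates), names(range_estimates)))) {
    abort("Glint-delay estimates carry event ids with no range-delay estimate.")
  }
  all_ids <- union(
    names(range_estimates),
    as.character(gate$event %||% integer())
  )
  all_ids <- all_ids[order(as.numeric(all_ids))]
  events <- purrr::map_dfr(all_ids, function(key) {
    e <- as.numeric(key)
    rejected <- !is.null(gate) && !gate$accepted[gate$event == e]
    rd <- range_estimates[[key]]
    ge <- glint_estimates[[key]]
    second <- if (!is.null(resolved)) {
      resolved$t_ms[resolved$event == e & resolved$glint == 2L]
    } else {
      numeric()
    }
    first_onset <- if (!is.null(resolved)) {
      resolved$t_ms[resolved$event == e & resolved$glint == 1L]
    } else {
      numeric()
    }
    tibble(
      event = e,
      rejected = rejected,
      # for an echo resolved into two glints both delays come from the
      # same onset-crossing path, so their difference is the glint
      # separation
      t_ms = if (length(second) && length(first_onset)) {
        first_onset[1]
      } else if (is.null(rd)) {
        NA_real_
      } else {
        rd$t_ms
      },
      t2_ms = if (length(second)) second[1] else NA_real_,
      split = length(second) > 0,
      delta_t_us = if (is.null(ge)) NA_real_ else ge$delta_t_us,
      delta_f_khz = if (is.null(ge)) NA_real_ else ge$delta_f_khz,
      n_channels = if (is.null(rd)) 0L else rd$n,
      reliable = if (is.null(rd)) FALSE else rd$reliable,
      n_nulls = if (is.null(nullsets[[key]])) NA_integer_ else nrow(nullsets[[key]]$nulls),
      fill_mass = if (is.null(ge)) NA_integer_ else sum(ge$histogram$fill_count)
    )
  })
  structure(
    list(
      events = events,
      range = range_estimates,
      glint = glint_estimates,
      nulls = nullsets,
      resolved = resolved,
      gate = gate,
      dechirped = dechirped,
      annotations = if (is.null(seq)) NULL else as_tibble(seq),
      config = config
    ),
    class = "scat_image"
  )
}

#' @export
print.scat_image <- function(x, ...) {
  cat(sprintf("<scat_image> %d echo event(s)\n", nrow(x$events)))
  print(x$events)
  invisible(x)
}

#' Tidy and summarize a receiver image
#'
#' `tidy()` returns one row per echo event with the estimated range
#' delay(s), glint delay, null count and gating/split flags.  `glance()`
#' returns a one-row summary of the run.
#'
#' @param x A `scat_image`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scat_image <- function(x, ...) {
  x$events
}

#' @rdname tidy.scat_image
#' @export
glance.scat_image <- function(x, ...) {
  ev <- x$events
  tibble(
    n_events = nrow(ev),
    n_rejected = sum(ev$rejected),
    n_split = sum(ev$split, na.rm = TRUE),
    n_glint_estimates = sum(!is.na(ev$delta_t_us)),
    mode = x$config$mode %||% NA_character_
  )
}

#' Serialize a receiver image to JSON
#'
#' Writes the tidy event table together with the per-event range and
#' glint histograms, null lists and the dechirped trace, and reads them
#' back into a `scat_image`.  Numeric round-trip is at JSON text
#' precision.
#'
#' @param x A `scat_image`.
#' @param path JSON file path.
#' @export
write_scat_image <- function(x, path) {
  stopifnot(inherits(x, "scat_image"))
  payload <- list(
    events = x$events,
    range = purrr::map(x$range, function(r) {
      list(t = r$t, n = r$n, reliable = r$reliable, histogram = r$histogram)
    }),
    glint = purrr::map(x$glint, function(g) {
      list(
        delta_t_us = g$delta_t_us, delta_f_khz = g$delta_f_khz,
        n_apexes = g$n_apexes, n_dropped = g$n_dropped,
        histogram = g$histogram, normalized = g$normalized
      )
    }),
    nulls = purrr::map(x$nulls, function(n) list(nulls = n$nulls, voids = n$voids)),
    dechirped = if (is.null(x$dechirped)) NULL else as.data.frame(x$dechirped)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_scat_image
#' @export
read_scat_image <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  range <- purrr::map(y$range, function(r) {
    structure(
      list(
        t = r$t, t_ms = r$t * 1e3, histogram = as_tibble(r$histogram),
        n = r$n, reliable = r$reliable
      ),
      class = "range_delay_estimate"
    )
  })
  glint <- purrr::map(y$glint, function(g) {
    structure(
      list(
        delta_t_us = g$delta_t_us %||% NA_real_,
        delta_f_khz = g$delta_f_khz %||% NA_real_,
        histogram = as_tibble(g$histogram),
        normalized = if (is.null(g$normalized)) NULL else as_tibble(g$normalized),
        n_apexes = g$n_apexes, n_dropped = g$n_dropped
      ),
      class = "glint_delay_estimate"
    )
  })
  nulls <- purrr::map(y$nulls, function(n) {
    structure(
      list(nulls = as_tibble(n$nulls), voids = as_tibble(n$voids)),
      class = "scat_nullset"
    )
  })
  events <- as_tibble(y$events)
  # columns that were all-missing are dropped by the JSON round trip
  num_cols <- c(
    "t_ms", "t2_ms", "delta_t_us", "delta_f_khz", "n_nulls", "fill_mass"
  )
  for (col in num_cols) {
    if (!col %in% names(events)) events[[col]] <- NA_real_
    events[[col]] <- as.numeric(events[[col]])
  }
  if (!"split" %in% names(events)) events$split <- FALSE
  events <- events[, c(
    "event", "rejected", "t_ms", "t2_ms", "split", "delta_t_us",
    "delta_f_khz", "n_channels", "reliable", "n_nulls", "fill_mass"
  )]
  structure(
    list(
      events = events,
      range = range,
      glint = glint,
      nulls = nulls,
      resolved = NULL,
      gate = NULL,
      dechirped = if (is.null(y$dechirped)) NULL else as_tibble(y$dechirped),
      annotations = NULL,
      config = NULL
    ),
    class = "scat_image"
  )
}
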