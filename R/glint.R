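#' Triangular coincidence network configuration
#'
#' The glint-delay pathway registers spectral interference nulls on the
#' base of a triangular network of coincidence nodes whose depth encodes
#' the frequency spacing of adjacent nulls.  The base spans the analyzed
#' bandwidth (80 kHz for the bat's 20-100 kHz band, 120 kHz for the
#' dolphin's 30-150 kHz band), so the registrable spacing runs from the
#' minimum resolvable spacing (about 3 kHz) up to the base width, and the
#' glint-delay axis tops out at the reciprocal of the base (12.5 us for
#' the bat).
#'
#' @param species `"bat"` or `"dolphin"` preset, or `NULL` with explicit
#'   arguments.
#' @param base_khz Base width = analyzed bandwidth (kHz).
#' @param min_resolvable_khz Minimum resolvable null spacing (kHz).
#' @param max_null_width_khz Widest single null registrable by one
#'   frequency-tuned channel population (kHz); broader voids are treated
#'   as lowpass regions and tiled with fill-in nulls.
#' @param grid_khz Channel grid step used to quantize null spacings.
#' @param band_split_khz Optional harmonic seam (bat: 50 kHz); nulls are
#'   collected separately below and above it and a spacing never
#'   straddles the seam.
#' @return A `triangular_network` list, including `axis_top_us` and
#'   `axis_bottom_us`, the limits of the glint-delay axis.
#' @examples
#' triangular_network("bat")$axis_top_us   # 12.5
#' @export
triangular_network <- function(species = c("bat", "dolphin"),
                               base_khz = NULL,
                               min_resolvable_khz = 3,
                               max_null_width_khz = 15,
                               grid_khz = NULL,
                               band_split_khz = NULL) {
  if (is.null(base_khz)) {
    species <- match.arg(species)
    base_khz <- switch(species, bat = 80, dolphin = 120)
    grid_khz <- grid_khz %||% switch(species, bat = 0.5, dolphin = 1)
    band_split_khz <- band_split_khz %||% switch(species, bat = 50, dolphin = NULL)
  } else {
    species <- if (is.character(species)) species[1] else "custom"
    grid_khz <- grid_khz %||% 0.5
  }
  structure(
    list(
      species = species,
      base_khz = base_khz,
      min_resolvable_khz = min_resolvable_khz,
      max_null_width_khz = max_null_width_khz,
      grid_khz = grid_khz,
      band_split_khz = band_split_khz,
      axis_top_us = 1e3 / base_khz,
      axis_bottom_us = 300
    ),
    class = "triangular_network"
  )
}

# Topographic prominent-peak finder on a per-channel evidence curve.
# Returns one row per local maximum whose prominence (height above the
# higher of the two flanking key cols) reaches min_prom, with the span of
# contiguous channels above half prominence.  Peaks sitting on the
# segment boundary are ignored: a monotone ramp (e.g. a band-edge or
# lowpass attenuation slope) has no interior peak and so never
# registers.
find_prominent_peaks <- function(v, min_prom) {
  r <- rle(v)
  vals <- r$values
  n <- length(vals)
  out <- list()
  if (n >= 3) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in 2:(n - 1)) {
      if (vals[i] <= vals[i - 1] || vals[i] <= vals[i + 1]) next
      lmin <- Inf
      for (j in (i - 1):1) {
        if (vals[j] > vals[i]) break
        lmin <- min(lmin, vals[j])
      }
      rmin <- Inf
      for (j in (i + 1):n) {
        if (vals[j] > vals[i]) break
        rmin <- min(rmin, vals[j])
      }
      prom <- vals[i] - max(min(lmin, vals[i]), min(rmin, vals[i]))
      if (!is.finite(prom)) prom <- vals[i] - min(lmin, rmin)
      if (prom < min_prom) next
      half <- vals[i] - prom / 2
      lo <- starts[i]
      while (lo > 1 && v[lo - 1] >= half) lo <- lo - 1L
      hi <- ends[i]
      while (hi < length(v) && v[hi + 1] >= half) hi <- hi + 1L
      out[[length(out) + 1L]] <- c(
        peak = floor((starts[i] + ends[i]) / 2), prom = prom, lo = lo, hi = hi
      )
    }
  }
  if (!length(out)) {
    return(tibble(peak = integer(), prom = numeric(), lo = integer(), hi = integer()))
  }
  m <- do.call(rbind, out)
  tibble(
    peak = as.integer(m[, "peak"]), prom = m[, "prom"],
    lo = as.integer(m[, "lo"]), hi = as.integer(m[, "hi"])
  )
}

#' Detect spectral interference nulls
#'
#' Overlapping glint reflections carve periodic nulls into the echo
#' spectrum.  In the threshold-crossing representation a null shows up as
#' two cues.  First, a latency bump: amplitude-latency trading transposes
#' the locally lower amplitude into later level-1 crossing times, so the
#' ALT-augmented dechirped delay traces a bump over the flanking channels
#' (channels whose lowest threshold is never crossed sit later than every
#' crossing in the band).  Bumps are found as topographic peaks of the
#' per-channel delay curve with prominence of at least
#' `min_prominence_us`; the spanning cluster runs to half prominence.
#' Second, a void: a run of channels where the echo fails to reach the
#' `void_level` threshold although the broadcast does - the cue that also
#' captures broad lowpass-filtered regions, which shift the whole latency
#' baseline instead of forming a local bump.  Narrow clusters become
#' nulls with a deviation-weighted centroid; clusters wider than the
#' maximum registrable null width are recorded as voids, flagged
#' `at_edge` when they hug the top of the analyzed band (the signature of
#' lowpass clutter, and the precondition for [fill_lowpass_void()]).
#'
#' @param dechirped ALT-applied `scat_dechirped` table.
#' @param crossings The `scat_crossings` map for the same sequence.
#' @param event Echo event id.
#' @param network A [triangular_network()].
#' @param support_level Minimum broadcast level for a channel to be
#'   analyzed at all.
#' @param void_level Void cue: echo fails to reach this level in a
#'   channel where the broadcast does.
#' @param min_prominence_us Minimum latency prominence of a null bump
#'   (default 25 us, i.e. one decibel of local depth at the standard
#'   trading coefficient - well above the interpolation jitter of
#'   crossing times).
#' @return A `scat_nullset` list: `nulls` (tibble `center_khz`,
#'   `width_khz`, `n_channels`, `max_level`, `dev_us`, `segment`),
#'   `voids` (tibble `lo_khz`, `hi_khz`, `width_khz`, `segment`,
#'   `at_edge`), and the per-channel evidence table `channels`.
#' @export
find_nulls <- function(dechirped, crossings, event,
                       network = triangular_network("bat"),
                       support_level = 2,
                       void_level = 4,
                       min_prominence_us = 25) {
  if (!isTRUE(attr(dechirped, "alt_applied"))) {
    warn("Null detection normally runs on the ALT-applied representation.")
  }
  e <- event
  br_max <- crossings |>
    dplyr::filter(.data$kind == "broadcast") |>
    dplyr::group_by(.data$channel, .data$cf_khz) |>
    dplyr::summarise(br_max = max(c(0L, .data$level[!is.na(.data$time)])), .groups = "drop")
  echo_max <- crossings |>
    dplyr::filter(.data$kind == "echo", .data$event == e) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(echo_max = max(c(0L, .data$level[!is.na(.data$time)])), .groups = "drop")
  atten <- channel_attenuation(crossings) |>
    dplyr::filter(.data$event == e) |>
    dplyr::select("channel", "attenuation_db")
  atten_en <- channel_attenuation(crossings, "energy") |>
    dplyr::filter(.data$event == e) |>
    dplyr::select("channel", atten_energy_db = "attenuation_db")
  d1 <- dechirped |>
    dplyr::filter(.data$event == e, .data$level == 1L) |>
    dplyr::select("channel", delay1 = "delay")
  ch <- br_max |>
    dplyr::left_join(echo_max, by = "channel") |>
    dplyr::left_join(atten, by = "channel") |>
    dplyr::left_join(atten_en, by = "channel") |>
    dplyr::left_join(d1, by = "channel") |>
    dplyr::arrange(.data$cf_khz) |>
    dplyr::mutate(
      support = .data$br_max >= support_level,
      segment = if (is.null(network$band_split_khz)) {
        1L
      } else {
        1L + (.data$cf_khz > network$band_split_khz)
      }
    )
  # latency evidence curve: ALT-augmented level-1 delay; a channel whose
  # lowest threshold is never crossed is later than every crossing
  v_all <- ch$delay1 * 1e6
  if (any(is.finite(v_all))) {
    v_all[!is.finite(v_all)] <- max(v_all[is.finite(v_all)]) + 2 * min_prominence_us
  }
  nulls <- list()
  voids <- list()
  for (seg in unique(ch$segment)) {
    sel <- which(ch$segment == seg & ch$support)
    if (length(sel) < 3) next
    s <- ch[sel, ]
    v <- v_all[sel]
    covered <- rep(FALSE, nrow(s))
    att <- s$attenuation_db
    # excess attenuation over the cluster's flanks: a genuine null must
    # show an amplitude deficit that recovers on BOTH sides (a latency
    # bump without one is crossing jitter; a one-sided deficit is the
    # slope of a neighbouring null or a band edge)
    atten_excess <- function(span) {
      side_min <- function(idx) {
        idx <- idx[idx >= 1 & idx <= nrow(s)]
        if (!length(idx)) return(-Inf)
        min(att[idx])
      }
      lo_fl <- side_min((min(span) - 2L):(min(span) - 1L))
      hi_fl <- side_min((max(span) + 1L):(max(span) + 2L))
      max(att[span]) - max(lo_fl, hi_fl)
    }
    # null center: attenuation apex within the cluster after removing the
    # linear background interpolated between the two flanks (a broadcast
    # spectrum slope, e.g. the click's Gaussian skirt, would otherwise
    # drag the apex downhill), refined by a parabolic fit through the
    # apex and its two neighbours
    apex_center <- function(span) {
      lo <- min(span)
      hi <- max(span)
      fl_lo <- (lo - 2L):(lo - 1L)
      fl_lo <- fl_lo[fl_lo >= 1]
      fl_hi <- (hi + 1L):(hi + 2L)
      fl_hi <- fl_hi[fl_hi <= nrow(s)]
      idx <- lo:hi
      d <- att[idx]
      if (length(fl_lo) && length(fl_hi)) {
        x0 <- mean(fl_lo)
        x1 <- mean(fl_hi)
        y0 <- mean(att[fl_lo])
        y1 <- mean(att[fl_hi])
        d <- d - (y0 + (idx - x0) / (x1 - x0) * (y1 - y0))
      }
      j <- which.max(d)
      i0 <- idx[j]
      if (j > 1 && j < length(idx)) {
        denom <- d[j - 1] - 2 * d[j] + d[j + 1]
        delta <- if (denom < 0) min(max(0.5 * (d[j - 1] - d[j + 1]) / denom, -0.5), 0.5) else 0
        s$cf_khz[i0] + delta * network$grid_khz
      } else {
        s$cf_khz[i0]
      }
    }
    peaks <- find_prominent_peaks(v, min_prominence_us)
    if (nrow(peaks)) {
      peaks <- peaks[order(-peaks$prom), ]
      for (p in seq_len(nrow(peaks))) {
        span <- peaks$lo[p]:peaks$hi[p]
        width <- length(span) * network$grid_khz
        if (width > network$max_null_width_khz) next  # handled by the void cue
        if (length(span) < 2 || any(covered[span])) next
        if (atten_excess(span) < min_prominence_us / 25) next
        covered[span] <- TRUE
        nulls[[length(nulls) + 1L]] <- tibble(
          center_khz = apex_center(span),
          width_khz = width,
          n_channels = length(span),
          max_level = max(s$echo_max[span]),
          dev_us = peaks$prom[p],
          segment = seg
        )
      }
    }
    # integrated-response cue: when the two reflections only partly
    # overlap in time (click echoes approaching the integration limit)
    # the envelope peak no longer carries the interference ripple, but
    # the channel's integrated energy still does; run the same
    # prominence detector on the energy-attenuation curve (in dB, one
    # decibel of prominence corresponding to the latency threshold at
    # the trading coefficient)
    aen <- s$atten_energy_db
    en_peaks <- find_prominent_peaks(aen, min_prominence_us / 25)
    if (nrow(en_peaks)) {
      en_peaks <- en_peaks[order(-en_peaks$prom), ]
      en_excess <- function(span) {
        side_min <- function(idx) {
          idx <- idx[idx >= 1 & idx <= nrow(s)]
          if (!length(idx)) return(-Inf)
          min(aen[idx])
        }
        lo_fl <- side_min((min(span) - 2L):(min(span) - 1L))
        hi_fl <- side_min((max(span) + 1L):(max(span) + 2L))
        max(aen[span]) - max(lo_fl, hi_fl)
      }
      en_center <- function(span) {
        j <- which.max(aen[span])
        i0 <- span[j]
        if (i0 > 1 && i0 < nrow(s) && j > 1 && j < length(span)) {
          yl <- aen[i0 - 1]
          y0 <- aen[i0]
          yr <- aen[i0 + 1]
          denom <- yl - 2 * y0 + yr
          delta <- if (denom < 0) min(max(0.5 * (yl - yr) / denom, -0.5), 0.5) else 0
          s$cf_khz[i0] + delta * network$grid_khz
        } else {
          s$cf_khz[i0]
        }
      }
      for (p in seq_len(nrow(en_peaks))) {
        span <- en_peaks$lo[p]:en_peaks$hi[p]
        width <- length(span) * network$grid_khz
        if (width > network$max_null_width_khz) next
        if (length(span) < 2 || any(covered[span])) next
        if (en_excess(span) < min_prominence_us / 25) next
        covered[span] <- TRUE
        nulls[[length(nulls) + 1L]] <- tibble(
          center_khz = en_center(span),
          width_khz = width,
          n_channels = length(span),
          max_level = max(s$echo_max[span]),
          dev_us = en_peaks$prom[p] * 25,
          segment = seg
        )
      }
    }
    # void cue: deep drop-outs relative to the broadcast; wide runs are
    # lowpass regions, narrow uncovered runs are nulls in their own right
    flag <- s$echo_max < void_level & s$br_max >= void_level
    eligible_top <- max(c(-Inf, s$cf_khz[s$br_max >= void_level]))
    r <- rle(as.vector(flag))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- starts[j]:ends[j]
      width <- length(span) * network$grid_khz
      if (width <= network$max_null_width_khz) {
        if (any(covered[span]) || length(span) < 2) next
        if (atten_excess(span) < min_prominence_us / 25) next
        nulls[[length(nulls) + 1L]] <- tibble(
          center_khz = apex_center(span),
          width_khz = width,
          n_channels = length(span),
          max_level = max(s$echo_max[span]),
          dev_us = max(v[span]) - min(v[span]),
          segment = seg
        )
      } else {
        # a genuine lowpass region leaves only the lowest levels crossed
        # over most of its span; a wide but moderate ripple/taper stretch
        # does not qualify
        if (median(s$echo_max[span]) > 2) next
        voids[[length(voids) + 1L]] <- tibble(
          lo_khz = min(s$cf_khz[span]), hi_khz = max(s$cf_khz[span]),
          width_khz = width, segment = seg,
          at_edge = max(s$cf_khz[span]) >= eligible_top - 2 * network$grid_khz
        )
      }
    }
  }
  nulls_df <- dplyr::bind_rows(nulls)
  if (nrow(nulls_df)) nulls_df <- dplyr::arrange(nulls_df, .data$center_khz)
  structure(
    list(
      event = e,
      nulls = nulls_df,
      voids = dplyr::bind_rows(voids),
      channels = ch
    ),
    class = "scat_nullset"
  )
}

#' @export
print.scat_nullset <- function(x, ...) {
  cat(sprintf(
    "<scat_nullset> event %s: %d null(s)%s\n", x$event, nrow(x$nulls),
    if (nrow(x$voids)) sprintf(", %d lowpass void(s)", nrow(x$voids)) else ""
  ))
  if (nrow(x$nulls)) print(x$nulls)
  invisible(x)
}

#' Run the triangular coincidence network
#'
#' Connects adjacent detected nulls: each consecutive pair within a band
#' segment forms one coincidence apex whose depth is the pair's frequency
#' difference, quantized to the channel grid.  The aggregate spacing
#' estimate is the mode of the apex spacings (the vertically aligned apex
#' column); ties resolve to the smallest spacing.  Spacings outside the
#' resolvable range are dropped, a single null yields no apex and no
#' estimate, and a spacing never straddles the harmonic seam.
#'
#' @param nullset A `scat_nullset` (or a tibble with `center_khz` and
#'   optionally `segment`).
#' @param network A [triangular_network()].
#' @return List of class `scat_apexes`: `apexes` (tibble `f_lo_khz`,
#'   `f_hi_khz`, `delta_f_khz`, `fill`), `delta_f_khz` (aggregate mode,
#'   `NA` if fewer than two nulls), `n_dropped`.
#' @export
run_triangular_network <- function(nullset, network = triangular_network("bat")) {
  nulls <- if (inherits(nullset, "scat_nullset")) nullset$nulls else as_tibble(nullset)
  if (!nrow(nulls)) {
    return(structure(
      list(
        apexes = tibble(
          f_lo_khz = numeric(), f_hi_khz = numeric(),
          delta_f_khz = numeric(), fill = logical()
        ),
        delta_f_khz = NA_real_, n_dropped = 0L
      ),
      class = "scat_apexes"
    ))
  }
  if (!"segment" %in% names(nulls)) nulls$segment <- 1L
  apexes <- nulls |>
    dplyr::group_by(.data$segment) |>
    dplyr::arrange(.data$center_khz, .by_group = TRUE) |>
    dplyr::reframe(
      f_lo_khz = .data$center_khz[-dplyr::n()],
      f_hi_khz = .data$center_khz[-1]
    ) |>
    dplyr::mutate(
      delta_f_khz = round((.data$f_hi_khz - .data$f_lo_khz) / network$grid_khz) *
        network$grid_khz,
      fill = FALSE
    ) |>
    dplyr::select("f_lo_khz", "f_hi_khz", "delta_f_khz", "fill")
  keep <- apexes$delta_f_khz >= network$min_resolvable_khz &
    apexes$delta_f_khz <= network$base_khz
  n_dropped <- sum(!keep)
  apexes <- apexes[keep, ]
  agg <- if (nrow(apexes)) {
    tab <- table(apexes$delta_f_khz)
    as.numeric(names(tab)[which.max(tab)])
  } else {
    NA_real_
  }
  structure(
    list(apexes = apexes, delta_f_khz = agg, n_dropped = n_dropped),
    class = "scat_apexes"
  )
}

#' Tile a lowpass void with fill-in nulls
#'
#' A lowpass-filtered region of the spectrum acts like a single null far
#' wider than any frequency-tuned channel can register, so the network
#' approximates it as a multiplicity of narrower nulls: every candidate
#' spacing on the channel grid from the minimum resolvable spacing up to
#' the widest spacing that fits the void (capped at the maximum
#' registrable null width) contributes one apex.  After inversion these
#' produce the broad plateau of spurious glint delays that blurs clutter
#' images.  Only voids attached to the top of the analyzed band are
#' tiled - that is the signature of lowpass filtering; a wide interior
#' interference null (e.g. from a very small glint separation) is simply
#' too broad to register and contributes nothing.
#'
#' @param nullset A `scat_nullset` whose `voids` table lists lowpass
#'   regions, or that table itself.
#' @param network A [triangular_network()].
#' @return Tibble of fill-in apexes (`f_lo_khz`, `f_hi_khz`,
#'   `delta_f_khz`, `fill = TRUE`), empty when there is no void.
#' @export
fill_lowpass_void <- function(nullset, network = triangular_network("bat")) {
  voids <- if (inherits(nullset, "scat_nullset")) nullset$voids else as_tibble(nullset)
  empty <- tibble(
    f_lo_khz = numeric(), f_hi_khz = numeric(),
    delta_f_khz = numeric(), fill = logical()
  )
  if (!nrow(voids)) return(empty)
  if ("at_edge" %in% names(voids)) voids <- voids[voids$at_edge, ]
  if (!nrow(voids)) return(empty)
  purrr::pmap_dfr(voids, function(lo_khz, hi_khz, width_khz, ...) {
    top <- min(width_khz, network$max_null_width_khz)
    if (top < network$min_resolvable_khz) return(empty)
    spacings <- seq(
      ceiling(network$min_resolvable_khz / network$grid_khz) * network$grid_khz,
      top,
      by = network$grid_khz
    )
    tibble(
      f_lo_khz = lo_khz, f_hi_khz = lo_khz + spacings,
      delta_f_khz = spacings, fill = TRUE
    )
  })
}

#' Invert null spacings into glint delays
#'
#' Each apex spacing is transposed into a glint delay `delta_t = 1 /
#' delta_f`.  All apexes (not only the dominant column) accumulate into a
#' histogram whose bins are the reciprocals of the grid spacings between
#' `1/base` and `1/min_resolvable`, so secondary structure such as
#' clutter fill-in appears as histogram mass.  The primary glint delay is
#' the mode of the raw histogram.
#'
#' @param apexes A `scat_apexes` result (or a tibble with `delta_f_khz`
#'   and optionally `fill`).
#' @param network A [triangular_network()].
#' @return List of class `glint_delay_estimate`: `delta_t_us` (primary,
#'   `NA` if no apex), `delta_f_khz`, `histogram` (tibble
#'   `delta_f_khz`, `delta_t_us`, `bin_width_us`, `count`, `fill_count`),
#'   `normalized` (`NULL` until [normalize_image_energy()]), `n_apexes`,
#'   `n_dropped`.
#' @examples
#' # a 10 kHz spacing inverts to a 100 us glint delay
#' @export
invert_spacing <- function(apexes, network = triangular_network("bat")) {
  ap <- if (inherits(apexes, "scat_apexes")) apexes$apexes else as_tibble(apexes)
  if (!"fill" %in% names(ap)) ap$fill <- FALSE
  grid <- seq(
    ceiling(network$min_resolvable_khz / network$grid_khz) * network$grid_khz,
    network$base_khz,
    by = network$grid_khz
  )
  in_range <- ap$delta_f_khz >= network$min_resolvable_khz &
    ap$delta_f_khz <= network$base_khz
  n_dropped <- sum(!in_range)
  ap <- ap[in_range, ]
  idx <- round((ap$delta_f_khz - grid[1]) / network$grid_khz) + 1L
  counts <- tabulate(idx, nbins = length(grid))
  fill_counts <- tabulate(idx[ap$fill], nbins = length(grid))
  s <- network$grid_khz
  hist <- tibble(
    delta_f_khz = grid,
    delta_t_us = 1e3 / grid,
    bin_width_us = 1e3 / (grid - s / 2) - 1e3 / (grid + s / 2),
    count = counts,
    fill_count = fill_counts
  )
  primary_f <- if (sum(counts) > 0) grid[which.max(counts)] else NA_real_
  structure(
    list(
      delta_t_us = if (is.na(primary_f)) NA_real_ else 1e3 / primary_f,
      delta_f_khz = primary_f,
      histogram = hist,
      normalized = NULL,
      n_apexes = nrow(ap),
      n_dropped = n_dropped
    ),
    class = "glint_delay_estimate"
  )
}

#' @export
print.glint_delay_estimate <- function(x, ...) {
  if (is.na(x$delta_t_us)) {
    cat("<glint_delay_estimate> no spacing estimate (fewer than two nulls)\n")
  } else {
    cat(sprintf(
      "<glint_delay_estimate> delta_t = %.1f us (delta_f = %.1f kHz, %d apexes)\n",
      x$delta_t_us, x$delta_f_khz, x$n_apexes
    ))
  }
  invisible(x)
}

#' Normalize a glint-delay histogram by image energy
#'
#' Divides the histogram by its total area (count times bin width summed
#' over bins) so it integrates to one.  Because clutter fill-in spreads
#' its mass over a wide span of glint delays, normalization scales the
#' cluttered image down everywhere, and a focused echo's peak at the true
#' glint delay protrudes above the cluttered echo's value at the same
#' delay - the model's anticorrelation mechanism for clutter rejection.
#'
#' @param estimate A `glint_delay_estimate`.
#' @return The estimate with its `normalized` field set to a tibble of
#'   densities (`delta_t_us`, `density`, integrating to 1).
#' @export
normalize_image_energy <- function(estimate) {
  stopifnot(inherits(estimate, "glint_delay_estimate"))
  h <- estimate$histogram
  area <- sum(h$count * h$bin_width_us)
  if (!is.finite(area) || area <= 0) {
    warn("Empty glint-delay histogram; nothing to normalize.")
    return(estimate)
  }
  estimate$normalized <- tibble(
    delta_f_khz = h$delta_f_khz,
    delta_t_us = h$delta_t_us,
    density = h$count / area
  )
  estimate
}
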