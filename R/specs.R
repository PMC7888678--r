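#' Broadcast and target specifications
#'
#' Constructors for the small specification objects the synthesis module
#' consumes.  `chirp_spec()` describes a multi-harmonic downsweeping FM
#' chirp of the kind emitted by big brown bats, `click_spec()` a short
#' wideband transient of the kind emitted by bottlenose dolphins, and
#' `glint_target()` a point-glint target that turns a broadcast into a
#' multi-glint echo at a given range delay.
#'
#' Times are given in the units conventional at each scale (chirp duration
#' in ms, click duration and glint offsets in us); everything is converted
#' to seconds internally.
#'
#' @param duration_ms,duration_us Signal duration.
#' @param harmonics List of `c(f_start, f_end)` pairs in kHz, each a
#'   downsweep (`f_start >= f_end`).
#' @param sweep One of `"logarithmic"`, `"hyperbolic"`, `"linear"`.
#' @param envelope `"flat"` or `"raised-cosine"` onset/offset shaping.
#' @param edge_fraction Fraction of the duration devoted to each
#'   raised-cosine edge.
#' @param harmonic_locked If `TRUE`, harmonic k is generated with exactly
#'   k times the phase trajectory of harmonic 1 (requires the declared
#'   frequency pairs to be k-multiples of the first pair).
#' @param band `c(f_low, f_high)` in kHz for a click.
#' @param center_khz Click spectral centroid in kHz
#'   (`f_low < center < f_high`).
#' @param delay_ms Range delay of the first glint, in ms after the
#'   broadcast onset.
#' @param offsets_us Glint delays relative to the first reflection, in us;
#'   strictly increasing with first element 0.
#' @param gains Linear amplitude gain per glint (all > 0).
#' @param signs Optional +1/-1 reflection sign per glint (default all +1).
#' @param lowpass Optional lowpass coloration profile from
#'   [lowpass_profile()].
#' @param attenuation_db Overall echo attenuation in dB (>= 0).
#' @param cutoff_khz Frequency above which clutter attenuation begins.
#' @param ramp_db_per_khz Attenuation slope above the cutoff.
#' @param max_db Cap on the attenuation ramp.
#'
#' @return A classed list describing the signal or target.
#' @seealso [make_fm_chirp()], [make_click()], [make_multiglint_echo()]
#' @examples
#' chirp_spec(3, list(c(55, 25), c(90, 50)))
#' click_spec(50, c(40, 150), 95)
#' glint_target(6, offsets_us = c(0, 100), gains = c(0.5, 0.5))
#' @name scat-specs
NULL

#' @rdname scat-specs
#' @export
chirp_spec <- function(duration_ms,
                       harmonics,
                       sweep = c("logarithmic", "hyperbolic", "linear"),
                       envelope = c("raised-cosine", "flat"),
                       edge_fraction = 0.05,
                       harmonic_locked = FALSE) {
  sweep <- match.arg(sweep)
  envelope <- match.arg(envelope)
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L || duration_ms <= 0) {
    abort("`duration_ms` must be a single positive number.")
  }
  if (!is.list(harmonics) || length(harmonics) == 0L) {
    abort("`harmonics` must be a non-empty list of c(f_start, f_end) kHz pairs.")
  }
  for (h in harmonics) {
    if (length(h) != 2L || any(h <= 0)) {
      abort("Each harmonic must be a pair of positive frequencies (kHz).")
    }
    if (h[1] < h[2]) {
      abort("Harmonics must be downsweeps: f_start >= f_end.")
    }
  }
  if (harmonic_locked && length(harmonics) > 1L) {
    f1 <- harmonics[[1]]
    for (k in seq_along(harmonics)) {
      if (max(abs(harmonics[[k]] - k * f1)) > 1e-9) {
        abort("harmonic_locked requires harmonic k to sweep k x harmonic 1.")
      }
    }
  }
  if (edge_fraction < 0 || edge_fraction > 0.5) {
    abort("`edge_fraction` must lie in [0, 0.5].")
  }
  structure(
    list(
      duration = duration_ms * 1e-3,
      harmonics = lapply(harmonics, function(h) h * 1e3),
      sweep = sweep,
      envelope = envelope,
      edge_fraction = edge_fraction,
      harmonic_locked = harmonic_locked
    ),
    class = "chirp_spec"
  )
}

#' @rdname scat-specs
#' @export
click_spec <- function(duration_us = 50, band = c(40, 150), center_khz = 95) {
  if (duration_us <= 0) abort("`duration_us` must be positive.")
  if (length(band) != 2L || band[1] >= band[2]) {
    abort("`band` must be c(f_low, f_high) with f_low < f_high (kHz).")
  }
  if (center_khz <= band[1] || center_khz >= band[2]) {
    abort("`center_khz` must lie strictly inside `band`.")
  }
  structure(
    list(
      duration = duration_us * 1e-6,
      band = band * 1e3,
      center = center_khz * 1e3
    ),
    class = "click_spec"
  )
}

#' @rdname scat-specs
#' @export
glint_target <- function(delay_ms,
                         offsets_us = 0,
                         gains = rep(1, length(offsets_us)),
                         signs = rep(1, length(offsets_us)),
                         lowpass = NULL,
                         attenuation_db = 0) {
  if (delay_ms <= 0) abort("Range delay `delay_ms` must be positive.")
  if (offsets_us[1] != 0) abort("First glint offset must be 0.")
  if (is.unsorted(offsets_us, strictly = TRUE)) {
    abort("Glint offsets must be strictly increasing.")
  }
  if (length(gains) != length(offsets_us) || any(gains <= 0)) {
    abort("`gains` must be positive and match `offsets_us` in length.")
  }
  if (length(signs) != length(offsets_us) || !all(signs %in% c(-1, 1))) {
    abort("`signs` must be +1 or -1 per glint.")
  }
  if (!is.null(lowpass) && !inherits(lowpass, "lowpass_profile")) {
    abort("`lowpass` must come from lowpass_profile().")
  }
  if (attenuation_db < 0) abort("`attenuation_db` must be >= 0.")
  structure(
    list(
      delay = delay_ms * 1e-3,
      offsets = offsets_us * 1e-6,
      gains = gains,
      signs = signs,
      lowpass = lowpass,
      attenuation_db = attenuation_db
    ),
    class = "glint_target"
  )
}

#' @rdname scat-specs
#' @export
lowpass_profile <- function(cutoff_khz, ramp_db_per_khz = 2, max_db = 40) {
  if (cutoff_khz <= 0) abort("`cutoff_khz` must be positive.")
  if (ramp_db_per_khz < 0 || max_db < 0) {
    abort("`ramp_db_per_khz` and `max_db` must be >= 0.")
  }
  structure(
    list(
      cutoff = cutoff_khz * 1e3,
      ramp_db_per_khz = ramp_db_per_khz,
      max_db = max_db
    ),
    class = "lowpass_profile"
  )
}

max_frequency <- function(spec) {
  if (inherits(spec, "chirp_spec")) {
    max(vapply(spec$harmonics, max, numeric(1)))
  } else if (inherits(spec, "click_spec")) {
    spec$band[2]
  } else {
    abort("Unknown spec type.")
  }
}
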