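#' Acoustic geometry of wideband echolocation
#'
#' Helpers that convert between the timing quantities the receiver measures
#' and the spatial quantities an echolocating animal perceives.  Range delay
#' is two-way travel time, so one metre of target range corresponds to
#' `2 / c` seconds of delay: about 5.8 ms/m in air and 1.4 ms/m in water.
#' A glint delay (the time separation between two reflections from the same
#' target) maps onto a glint profile depth of `c * delta_t / 2`, e.g. a
#' 100 us glint delay in air is a 1.7 cm deep target profile.
#'
#' @param medium `"air"` (c = 343 m/s) or `"water"` (c = 1480 m/s).
#' @param range_m Target range in metres.
#' @param delay_ms Two-way echo delay in milliseconds.
#' @param delta_t_us Glint delay in microseconds.
#' @param spacing_cm Glint profile depth in centimetres.
#'
#' @return A numeric scalar or vector in the units named by the function.
#' @examples
#' delay_per_range("air")        # ~5.8 ms per metre of range
#' glint_delay_to_spacing(100)   # 100 us <-> 1.7 cm in air
#' @name biosonar-geometry
NULL

sound_speed <- function(medium = c("air", "water")) {
  medium <- match.arg(medium)
  c(air = 343, water = 1480)[[medium]]
}

#' @rdname biosonar-geometry
#' @export
delay_per_range <- function(medium = c("air", "water")) {
  2 / sound_speed(medium) * 1e3   # ms per metre, two-way
}

#' @rdname biosonar-geometry
#' @export
range_to_delay <- function(range_m, medium = c("air", "water")) {
  range_m * delay_per_range(medium)
}

#' @rdname biosonar-geometry
#' @export
delay_to_range <- function(delay_ms, medium = c("air", "water")) {
  delay_ms / delay_per_range(medium)
}

#' @rdname biosonar-geometry
#' @export
glint_delay_to_spacing <- function(delta_t_us, medium = c("air", "water")) {
  delta_t_us * 1e-6 * sound_speed(medium) / 2 * 100   # cm
}

#' @rdname biosonar-geometry
#' @export
glint_spacing_to_delay <- function(spacing_cm, medium = c("air", "water")) {
  spacing_cm / 100 * 2 / sound_speed(medium) * 1e6    # us
}
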