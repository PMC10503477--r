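#' Dimensionless gait variables (dynamic similarity)
#'
#' Walking animals of different size move dynamically similarly when their
#' dimensionless gait variables coincide. Using midstance hip height `h`
#' as the functional limb length and `g` the gravitational acceleration:
#' speed is normalized as \eqn{V/\sqrt{hg}} (a Froude-style number),
#' lengths as \eqn{L/h}, frequencies as \eqn{F/\sqrt{g/h}}, and forces in
#' body weights \eqn{F/(m g)}. Duty factors and relative limb phases are
#' dimensionless as recorded.
#'
#' @param V Absolute walking speed (m/s, >= 0).
#' @param h Midstance hip height (m, > 0).
#' @param g Gravitational acceleration (m/s^2, > 0); default 9.81.
#' @return Dimensionless speed \eqn{V/\sqrt{hg}}.
#' @examples
#' dimensionless_speed(0.5, 0.25)   # 0.3193
#' @export
dimensionless_speed <- function(V, h, g = 9.81) {
  check_nonnegative(V, "V")
  check_positive(h, "h"); check_positive(g, "g")
  V / sqrt(h * g)
}

#' @rdname dimensionless_speed
#' @param L Stride or step length (m).
#' @return `dimensionless_length()`: \eqn{L/h}.
#' @export
dimensionless_length <- function(L, h) {
  check_positive(h, "h")
  L / h
}

#' @rdname dimensionless_speed
#' @param F_hz Stride frequency (Hz).
#' @return `dimensionless_frequency()`: \eqn{F\sqrt{h/g}}.
#' @export
dimensionless_frequency <- function(F_hz, h, g = 9.81) {
  check_positive(h, "h"); check_positive(g, "g")
  F_hz * sqrt(h / g)
}

#' Duty factor
#'
#' Stance time divided by stride time, in (0, 1].
#'
#' @param stance_time,stride_time Durations in seconds; requires
#'   `0 < stance_time <= stride_time`.
#' @export
duty_factor <- function(stance_time, stride_time) {
  check_positive(stance_time, "stance_time")
  check_positive(stride_time, "stride_time")
  if (any(stance_time > stride_time)) {
    stop("stance_time exceeds stride_time", call. = FALSE)
  }
  stance_time / stride_time
}

#' Relative limb phase
#'
#' Footfall timing offset relative to the reference limb, expressed as a
#' fraction of stride time and wrapped into `[0, 1)`.
#'
#' @param footfall_time_offset Offset in seconds (may be negative or
#'   exceed one stride).
#' @param stride_time Stride duration in seconds (> 0).
#' @export
relative_phase <- function(footfall_time_offset, stride_time) {
  check_positive(stride_time, "stride_time")
  wrap_unit(footfall_time_offset / stride_time)
}

#' Normalize a force to body weights
#'
#' @param F_n Force in newtons (sign preserved, e.g. braking fore-aft
#'   forces stay negative).
#' @param BM Body mass (kg, > 0).
#' @param g Gravitational acceleration (m/s^2).
#' @return Force in body weights (BW).
#' @export
normalize_force <- function(F_n, BM, g = 9.81) {
  check_positive(BM, "BM"); check_positive(g, "g")
  F_n / (BM * g)
}

#' Normalize a stride table according to dynamic similarity
#'
#' Appends dimensionless columns to a stride table: `froude_speed`,
#' `rel_stride_length`, `rel_step_length_fore`, `rel_step_length_hind`,
#' `rel_frequency`. Duty factors and phases are carried through unchanged.
#' Rows with a missing or non-positive `hip_height_m` cannot be normalized
#' and are dropped with a warning naming how many were skipped.
#'
#' @param strides Data frame with at least `speed_ms`, `stride_length_m`,
#'   `stride_frequency_hz` and `hip_height_m`; step-length columns are
#'   normalized when present.
#' @param g Gravitational acceleration (m/s^2).
#' @return The stride table with dimensionless columns appended (absolute
#'   columns preserved alongside). Empty input gives an empty result.
#' @export
normalize_stride_table <- function(strides, g = 9.81) {
  stopifnot(is.data.frame(strides))
  if (nrow(strides) == 0L) {
    strides$froude_speed <- numeric(0)
    strides$rel_stride_length <- numeric(0)
    strides$rel_frequency <- numeric(0)
    return(strides)
  }
  h <- strides$hip_height_m
  bad <- is.na(h) | h <= 0
  if (any(bad)) {
    warning(sprintf("skipping %d stride(s) with missing/non-positive hip height",
                    sum(bad)), call. = FALSE)
    strides <- strides[!bad, , drop = FALSE]
    h <- strides$hip_height_m
  }
  strides$froude_speed <- dimensionless_speed(strides$speed_ms, h, g)
  strides$rel_stride_length <- dimensionless_length(strides$stride_length_m, h)
  if (!is.null(strides$step_length_fore_m)) {
    strides$rel_step_length_fore <-
      dimensionless_length(strides$step_length_fore_m, h)
  }
  if (!is.null(strides$step_length_hind_m)) {
    strides$rel_step_length_hind <-
      dimensionless_length(strides$step_length_hind_m, h)
  }
  strides$rel_frequency <-
    dimensionless_frequency(strides$stride_frequency_hz, h, g)
  strides
}
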