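#' Saturating postural-maturation profile
#'
#' Newborn piglets walk with flexed limbs and extend them over the first
#' hours of life, which raises the midstance hip height without any change
#' in body mass. The profile is a saturating exponential
#' \deqn{M(t) = p \, (1 - e^{-t/\tau})}
#' with plateau `plateau_fraction` (`p`, the asymptotic relative hip-height
#' gain over the value at birth) and time constant `time_constant` (hours).
#' The default time constant, `8 / log(10)` (about 3.47 h), places 90% of
#' the plateau at 8 hours postpartum, matching the observation that most of
#' the postural change is complete by then.
#'
#' An optional `stall_age` freezes the profile at its value at that age for
#' all later ages. This models a behaviourally stalled animal (e.g. an
#' energy-depleted low-birth-weight piglet) whose limb posture stops
#' maturing while the clock keeps running.
#'
#' @param plateau_fraction Non-negative asymptotic relative increase
#'   (dimensionless, e.g. 0.28 for 28%).
#' @param time_constant Time constant in hours (> 0).
#' @param stall_age Age in hours beyond which the profile is frozen, or
#'   `NULL` (default) for no stall.
#' @return An object of class `"maturation_profile"`.
#' @seealso [maturation_value()], [calibrate_maturation()]
#' @export
maturation_profile <- function(plateau_fraction,
                               time_constant = 8 / log(10),
                               stall_age = NULL) {
  check_nonnegative(plateau_fraction, "plateau_fraction")
  check_positive(time_constant, "time_constant")
  if (!is.null(stall_age)) check_nonnegative(stall_age, "stall_age")
  structure(
    list(plateau_fraction = plateau_fraction,
         time_constant = time_constant,
         stall_age = stall_age),
    class = "maturation_profile"
  )
}

#' Calibrate the maturation plateau to a measured window increase
#'
#' Reported postural maturation is a percent increase in category-mean
#' midstance hip height between two observation ages (by default 1 h and
#' 28 h postpartum; the earliest reliable gait recordings are at about 1 h).
#' Since hip height is \eqn{h(t) = h_0 (1 + M(t))}, a target relative
#' increase \eqn{g} over the window \eqn{[t_1, t_2]} requires
#' \deqn{p = g / \left[m(t_2) - (1+g)\, m(t_1)\right], \quad
#'       m(t) = 1 - e^{-t/\tau}.}
#' With the default window and time constant, a 28% measured increase needs
#' a plateau of about 0.412.
#'
#' @param target_increase Relative hip-height increase measured across the
#'   window (default 0.28).
#' @param window Length-2 ages (hours) between which the increase is
#'   measured.
#' @inheritParams maturation_profile
#' @return A `"maturation_profile"` whose modelled window increase equals
#'   `target_increase`.
#' @export
calibrate_maturation <- function(target_increase = 0.28,
                                 window = c(1, 28),
                                 time_constant = 8 / log(10),
                                 stall_age = NULL) {
  check_nonnegative(target_increase, "target_increase")
  stopifnot(length(window) == 2L, window[2] > window[1], window[1] >= 0)
  m <- 1 - exp(-window / time_constant)
  denom <- m[2] - (1 + target_increase) * m[1]
  if (denom <= 0) {
    stop("target increase unattainable for this window/time constant",
         call. = FALSE)
  }
  maturation_profile(target_increase / denom, time_constant, stall_age)
}

#' Evaluate a maturation profile
#'
#' @param age Age(s) in hours postpartum (>= 0); vectorized.
#' @param profile A [maturation_profile()].
#' @return Dimensionless extension factor(s) in `[0, plateau_fraction]`,
#'   non-decreasing in age, zero at birth.
#' @examples
#' pr <- maturation_profile(0.28)            # 90% of plateau by 8 h
#' maturation_value(8, pr)                   # 0.252
#' @export
maturation_value <- function(age, profile) {
  stopifnot(inherits(profile, "maturation_profile"))
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be non-negative and finite", call. = FALSE)
  }
  t_eff <- if (is.null(profile$stall_age)) age else pmin(age, profile$stall_age)
  profile$plateau_fraction * (1 - exp(-t_eff / profile$time_constant))
}
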