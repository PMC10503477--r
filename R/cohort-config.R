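#' Configuration for the synthetic piglet cohort generator
#'
#' Bundles every tunable of [generate_cohort()] with defaults chosen to
#' emulate the neonatal-pig study design this package targets: 14 normal
#' (AGA) and 11 low-birth-weight (SGA) piglets followed longitudinally at
#' 0, 1, 2, 6, 8, 24, 26, 28 and 96 hours postpartum, a roughly 50%
#' body-mass gap between categories (AGA around 1.4 kg, SGA below 0.8 kg),
#' isometric segment scaling (lengths proportional to body mass^(1/3)),
#' a saturating postural-maturation profile calibrated to a 28% midstance
#' hip-height increase between 1 h and 28 h, and SGA knee/tarsal mean-angle
#' offsets of -11 and -6 degrees.
#'
#' @param n_aga,n_sga Piglets per category (positive integers).
#' @param ages Observation ages in hours postpartum.
#' @param strides_per_age Strides recorded per piglet per age.
#' @param mass_aga_mean,mass_aga_sd,mass_sga_mean,mass_sga_sd Birth-mass
#'   distributions (kg). SGA masses are truncated below the `sga_threshold`,
#'   AGA masses above it, mirroring the <0.8 kg category criterion.
#' @param sga_threshold Birth-mass cut (kg) separating the categories.
#' @param hip_height_coef Hip height at midstance for a fully flexed
#'   (newborn-posture) animal is `hip_height_coef * BM^(1/3)` metres.
#' @param flexion_penalty_sga Persistent extra limb flexion of SGA animals
#'   as a relative hip-height deficit (dimensionless; 0 disables).
#' @param maturation A [maturation_profile()] applied to both categories.
#' @param sga_stall_age If non-`NULL`, SGA maturation (and the maturation-
#'   coupled gait/posture signal) is frozen at this age (hours), modelling
#'   an energy-deficit behavioural stall; AGA animals are unaffected.
#' @param froude_speed Mature dimensionless (Froude) self-selected walking
#'   speed \eqn{V/\sqrt{hg}}.
#' @param speed_floor Fraction of `froude_speed` expressed at birth; the
#'   dimensionless speed rises with maturation from
#'   `speed_floor * froude_speed` to `froude_speed`.
#' @param rel_stride_length Mature dimensionless stride length \eqn{L/h}.
#' @param duty Hind-limb duty factor (stance time / stride time).
#' @param duty_fore_ratio Fore over hind duty-factor ratio.
#' @param phases Mean relative phases of (right hind, left fore, right
#'   fore) limbs, referenced to left-hind touchdown, fractions of stride.
#' @param posture_offsets_sga Named radian offsets added to SGA joint mean
#'   angles (defaults: knee -11 deg, tarsal -6 deg).
#' @param extension_gain Radians by which hindlimb joint mean angles
#'   (hip/knee/tarsal) extend from birth posture to full maturation;
#'   forelimb joints extend by 1/3 of this.
#' @param templates Joint-angle Fourier template bank, see
#'   [joint_template_bank()].
#' @param n_cycle_samples Samples per generated joint-angle cycle (>= 17).
#' @param n_stance_nodes Nodes of generated stance GRF curves (intervals+1).
#' @param fore_share Fraction of body weight carried by the two forelimbs.
#' @param noise Named list of noise scales: `gait_cv` (multiplicative CV on
#'   dimensionless gait draws), `hip_cv` (hip height), `phase_sd` (absolute,
#'   stride fractions), `angle_sd` (radians, joint mean angle),
#'   `amplitude_cv` (joint oscillation amplitude), `grf_sd` (relative GRF
#'   shape perturbation), `part_mass_sigma` (lognormal sigma of body-part
#'   masses), `muscle_cv` (muscle morphometrics). All must be >= 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return A classed list (`"cohort_config"`).
#' @export
cohort_config <- function(n_aga = 14L, n_sga = 11L,
                          ages = c(0, 1, 2, 6, 8, 24, 26, 28, 96),
                          strides_per_age = 2L,
                          mass_aga_mean = 1.4, mass_aga_sd = 0.15,
                          mass_sga_mean = 0.7, mass_sga_sd = 0.08,
                          sga_threshold = 0.8,
                          hip_height_coef = 0.10,
                          flexion_penalty_sga = 0.06,
                          maturation = calibrate_maturation(),
                          sga_stall_age = NULL,
                          froude_speed = 0.35,
                          speed_floor = 0.75,
                          rel_stride_length = 1.15,
                          duty = 0.65,
                          duty_fore_ratio = 1.03,
                          phases = c(rh = 0.5, lf = 0.25, rf = 0.75),
                          posture_offsets_sga = c(knee = -11 * pi / 180,
                                                  tarsal = -6 * pi / 180),
                          extension_gain = 0.12,
                          templates = joint_template_bank(),
                          n_cycle_samples = 100L,
                          n_stance_nodes = 51L,
                          fore_share = 0.6,
                          noise = list(),
                          g = 9.81) {
  noise_default <- list(gait_cv = 0.06, hip_cv = 0.02, phase_sd = 0.01,
                        angle_sd = 0.03, amplitude_cv = 0.05, grf_sd = 0.04,
                        part_mass_sigma = 0.05, muscle_cv = 0.05)
  unknown <- setdiff(names(noise), names(noise_default))
  if (length(unknown)) {
    stop("unknown noise component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  noise <- utils::modifyList(noise_default, noise)
  if (any(vapply(noise, function(x) !is.finite(x) || x < 0, logical(1)))) {
    stop("noise scales must be non-negative and finite", call. = FALSE)
  }
  if (n_aga < 1 || n_sga < 0 || strides_per_age < 1) {
    stop("piglet and stride counts must be positive", call. = FALSE)
  }
  check_nonnegative(ages, "ages")
  check_positive(c(mass_aga_mean, mass_sga_mean, hip_height_coef,
                   froude_speed, rel_stride_length, g, n_cycle_samples,
                   n_stance_nodes),
                 "size/speed parameters")
  stopifnot(inherits(maturation, "maturation_profile"),
            duty > 0, duty <= 1, fore_share > 0, fore_share < 1,
            speed_floor > 0, speed_floor <= 1,
            n_cycle_samples >= 17, n_stance_nodes >= 3,
            length(phases) == 3L)
  validate_template_bank(templates)
  structure(
    list(n_aga = as.integer(n_aga), n_sga = as.integer(n_sga),
         ages = sort(unique(ages)), strides_per_age = as.integer(strides_per_age),
         mass_aga_mean = mass_aga_mean, mass_aga_sd = mass_aga_sd,
         mass_sga_mean = mass_sga_mean, mass_sga_sd = mass_sga_sd,
         sga_threshold = sga_threshold,
         hip_height_coef = hip_height_coef,
         flexion_penalty_sga = flexion_penalty_sga,
         maturation = maturation, sga_stall_age = sga_stall_age,
         froude_speed = froude_speed, speed_floor = speed_floor,
         rel_stride_length = rel_stride_length,
         duty = duty, duty_fore_ratio = duty_fore_ratio,
         phases = phases,
         posture_offsets_sga = posture_offsets_sga,
         extension_gain = extension_gain,
         templates = templates,
         n_cycle_samples = as.integer(n_cycle_samples),
         n_stance_nodes = as.integer(n_stance_nodes),
         fore_share = fore_share, noise = noise, g = g),
    class = "cohort_config"
  )
}

#' Fourier template bank for limb joint-angle cycles
#'
#' Band-limited (at most 8 harmonics) walking-shaped templates for the six
#' sagittal limb joints (shoulder, elbow, carpal, hip, knee, tarsal), in the
#' interior-angle convention: radians, pi = fully extended, 0 = fully
#' flexed, cycle anchored at limb touchdown. The curves are plausible
#' quadruped walking profiles constructed for simulation; they are not
#' digitized from any experimental recording.
#'
#' @return Named list; each element has `mean` (radians) and `harmonics`
#'   (complex length-8 vector of one-sided Fourier coefficients
#'   \eqn{c_1..c_8}).
#' @export
joint_template_bank <- function() {
  h <- function(...) {
    z <- c(...)
    c(z, rep(0 + 0i, 8 - length(z)))
  }
  list(
    shoulder = list(mean = 1.65,
                    harmonics = h(0.10 + 0.03i, 0.020 - 0.010i, 0.008 + 0i,
                                  0.003 + 0i)),
    elbow    = list(mean = 2.00,
                    harmonics = h(0.14 - 0.05i, 0.040 + 0.020i, 0.012 + 0i,
                                  0.004 + 0i)),
    carpal   = list(mean = 2.35,
                    harmonics = h(0.22 + 0.08i, 0.060 - 0.030i, 0.020 + 0i,
                                  0.006 + 0i)),
    hip      = list(mean = 1.90,
                    harmonics = h(0.12 + 0.02i, 0.020 + 0i, 0.006 + 0i)),
    knee     = list(mean = 1.75,
                    harmonics = h(0.15 - 0.06i, 0.050 + 0.020i, 0.015 + 0i,
                                  0.005 + 0i)),
    tarsal   = list(mean = 2.00,
                    harmonics = h(0.16 + 0.05i, 0.050 - 0.020i, 0.020 + 0i,
                                  0.007 + 0i))
  )
}

validate_template_bank <- function(templates) {
  if (!is.list(templates) || is.null(names(templates))) {
    stop("templates must be a named list", call. = FALSE)
  }
  for (nm in names(templates)) {
    tp <- templates[[nm]]
    if (is.null(tp$mean) || is.null(tp$harmonics)) {
      stop("template `", nm, "` needs `mean` and `harmonics`", call. = FALSE)
    }
    if (length(tp$harmonics) > 8 && any(tp$harmonics[-(1:8)] != 0)) {
      stop("template `", nm, "` has more than 8 nonzero harmonics",
           call. = FALSE)
    }
  }
  invisible(templates)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic piglet cohort configuration\n")
  cat(sprintf("  piglets: %d AGA + %d SGA\n", x$n_aga, x$n_sga))
  cat(sprintf("  ages (h pp): %s\n", paste(x$ages, collapse = ", ")))
  cat(sprintf("  strides per piglet per age: %d\n", x$strides_per_age))
  cat(sprintf("  maturation plateau %.3f, tau %.2f h%s\n",
              x$maturation$plateau_fraction, x$maturation$time_constant,
              if (!is.null(x$sga_stall_age))
                sprintf(", SGA stall at %g h", x$sga_stall_age) else ""))
  invisible(x)
}
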