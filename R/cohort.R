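#' Generate a synthetic piglet cohort with strides, kinematics, forces
#'
#' Draws a cohort of SGA (small-for-gestational-age) and AGA (appropriate-
#' for-gestational-age) piglets and simulates, for each piglet and
#' observation age, voluntary-walking strides with spatiotemporal
#' variables, six sagittal joint-angle cycles, single-limb ground reaction
#' force (GRF) curves, extensor-muscle morphometrics and a simple
#' energy-status table. The generator embodies the statistical structure
#' the downstream analyses assume:
#' \itemize{
#'   \item a category body-mass gap (SGA roughly half of AGA mass);
#'   \item isometric size scaling (segment lengths proportional to
#'     body mass to the 1/3);
#'   \item a saturating postural-maturation profile raising midstance hip
#'     height, identical for both categories unless an SGA stall is set;
#'   \item strides constructed in dimensionless (dynamic-similarity) form
#'     and mapped to absolute units through hip height, so that with zero
#'     noise animals of different size walk dynamically similarly;
#'   \item band-limited (8-harmonic) joint-angle cycles with configurable
#'     SGA knee/tarsal mean-angle offsets;
#'   \item double-hump vertical GRFs in body weights whose per-limb
#'     stance-time-weighted means sum to one body weight.
#' }
#'
#' Randomness is fully determined by `seed`: each data block (piglets,
#' strides, joint traces, GRFs, muscles, energetics) draws from its own
#' named substream so that adding a block never perturbs earlier ones.
#'
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @return An object of class `"piglet_cohort"`: a list with data frames
#'   `piglets`, `strides`, `joint_traces` (long: stride_id, joint,
#'   cycle_fraction, angle_rad), `grf_traces` (long: stride_id, limb,
#'   component, stance_fraction, force_bw), `muscles`, `energetics`, plus
#'   the `config` and `seed` used.
#' @seealso [write_cohort()], [apply_scaling()], [normalize_stride_table()]
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  piglets <- generate_piglets(config, seed)
  strides <- generate_strides(piglets, config, seed)
  joint_traces <- generate_cohort_traces(strides, config, seed)
  grf_traces <- generate_cohort_grfs(strides, config, seed)
  muscles <- generate_muscles(piglets, config, seed)
  energetics <- generate_energetics(piglets, config, seed)
  structure(
    list(piglets = piglets, strides = strides, joint_traces = joint_traces,
         grf_traces = grf_traces, muscles = muscles, energetics = energetics,
         config = config, seed = as.integer(seed)),
    class = "piglet_cohort"
  )
}

# reference segment lengths (m) of a 1.4 kg neonate; scaled isometrically
ref_segments <- function() {
  c(scapula = 0.065, humerus = 0.060, radius_ulna = 0.055,
    metacarpus = 0.035, femur = 0.060, tibia_fibula = 0.065,
    metatarsus = 0.045)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) break
    }
    out[i] <- x
  }
  out
}

generate_piglets <- function(config, seed) {
  set.seed(substream_seed(seed, "piglets"))
  n <- config$n_aga + config$n_sga
  category <- rep(c("AGA", "SGA"), c(config$n_aga, config$n_sga))
  bm <- c(
    rnorm_trunc(config$n_aga, config$mass_aga_mean, config$mass_aga_sd,
                lower = config$sga_threshold),
    rnorm_trunc(config$n_sga, config$mass_sga_mean, config$mass_sga_sd,
                lower = 0.25, upper = config$sga_threshold)
  )
  sex <- sample(c("F", "M"), n, replace = TRUE)
  segs <- outer((bm / 1.4)^(1 / 3), ref_segments())
  colnames(segs) <- paste0("seg_", names(ref_segments()))
  sig <- config$noise$part_mass_sigma
  data.frame(
    piglet_id = sprintf("P%02d", seq_len(n)),
    category = category, sex = sex, birth_mass_kg = bm,
    segs,
    limb_length_m = rowSums(segs[, c("seg_femur", "seg_tibia_fibula",
                                     "seg_metatarsus"), drop = FALSE]),
    front_part_mass_kg = 0.41 * bm^1.02 * exp(stats::rnorm(n, 0, sig)),
    hind_part_mass_kg = 0.38 * bm^1.16 * exp(stats::rnorm(n, 0, sig)),
    stringsAsFactors = FALSE
  )
}

# maturation fraction in [0,1): profile value / plateau, with SGA stall
maturation_state <- function(age, category, config) {
  prof <- config$maturation
  if (identical(category, "SGA") && !is.null(config$sga_stall_age)) {
    prof <- maturation_profile(prof$plateau_fraction, prof$time_constant,
                               stall_age = config$sga_stall_age)
  }
  m <- maturation_value(age, prof)
  list(value = m, fraction = m / prof$plateau_fraction)
}

generate_strides <- function(piglets, config, seed) {
  set.seed(substream_seed(seed, "strides"))
  nz <- config$noise
  grid <- expand.grid(pig = seq_len(nrow(piglets)),
                      age = config$ages,
                      rep = seq_len(config$strides_per_age),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$pig, grid$age, grid$rep), ]
  n <- nrow(grid)
  pg <- piglets[grid$pig, ]
  mst <- mapply(function(a, cat) {
    s <- maturation_state(a, cat, config)
    c(s$value, s$fraction)
  }, grid$age, pg$category)
  m_val <- mst[1, ]; m_frac <- mst[2, ]

  vhat <- config$froude_speed *
    (config$speed_floor + (1 - config$speed_floor) * m_frac) *
    exp(stats::rnorm(n, 0, nz$gait_cv))
  lhat <- config$rel_stride_length * exp(stats::rnorm(n, 0, nz$gait_cv))
  duty_h <- pmin(config$duty * exp(stats::rnorm(n, 0, nz$gait_cv * 0.3)), 0.95)
  duty_f <- pmin(duty_h * config$duty_fore_ratio, 0.95)
  flex <- ifelse(pg$category == "SGA", config$flexion_penalty_sga, 0)
  h <- config$hip_height_coef * pg$birth_mass_kg^(1 / 3) * (1 + m_val) *
    (1 - flex) * exp(stats::rnorm(n, 0, nz$hip_cv))

  V <- vhat * sqrt(h * config$g)
  L <- lhat * h
  Fq <- V / L                       # so that V = L * Fq holds exactly
  Tt <- 1 / Fq
  step_h <- 0.5 * L * exp(stats::rnorm(n, 0, nz$gait_cv * 0.5))
  step_f <- 0.5 * L * exp(stats::rnorm(n, 0, nz$gait_cv * 0.5))
  ph <- wrap_unit(matrix(config$phases, n, 3, byrow = TRUE) +
                    matrix(stats::rnorm(3 * n, 0, nz$phase_sd), n, 3))

  data.frame(
    stride_id = sprintf("S%05d", seq_len(n)),
    piglet_id = pg$piglet_id, category = pg$category, sex = pg$sex,
    age_h = grid$age, birth_mass_kg = pg$birth_mass_kg,
    speed_ms = V, stride_length_m = L,
    step_length_fore_m = step_f, step_length_hind_m = step_h,
    stride_frequency_hz = Fq, stride_time_s = Tt,
    stance_time_s = duty_h * Tt,
    duty_factor = duty_h, duty_factor_fore = duty_f,
    phase_rh = ph[, 1], phase_lf = ph[, 2], phase_rf = ph[, 3],
    hip_height_m = h, maturation_fraction = m_frac,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Generate one stride's six band-limited joint-angle traces
#'
#' Builds the six joint cycles of a single stride from a Fourier template
#' bank, in the coefficient domain, so every generated trace is exactly
#' band-limited to 8 harmonics: the mean angle is shifted by posture
#' offsets, maturation shifts and Gaussian noise; the oscillatory part is
#' scaled by `amplitude_scale` and a multiplicative amplitude jitter. The
#' cycle starts at limb touchdown (cycle fraction 0).
#'
#' @param templates Template bank, see [joint_template_bank()].
#' @param posture_offsets Named radians added to specific joints' mean
#'   angles (e.g. `c(knee = -0.192)`); unnamed joints are unshifted.
#' @param amplitude_scale Multiplier of all harmonic coefficients; 0 gives
#'   constant traces at the mean angle.
#' @param noise_sd Gaussian sd (radians) of the per-joint mean-angle noise.
#' @param n_samples Samples per cycle (>= 17 so 8 harmonics round-trip).
#' @param mean_shifts Named radians added to joint mean angles (used for
#'   the maturation-driven limb extension); recycled default 0.
#' @param amplitude_cv Lognormal sd of the per-joint amplitude jitter.
#' @param stride_id Identifier copied into the output.
#' @return Long data frame: stride_id, joint, cycle_fraction, angle_rad.
#' @export
generate_joint_traces <- function(templates = joint_template_bank(),
                                  posture_offsets = numeric(),
                                  amplitude_scale = 1,
                                  noise_sd = 0,
                                  n_samples = 100L,
                                  mean_shifts = numeric(),
                                  amplitude_cv = 0,
                                  stride_id = "S00001") {
  validate_template_bank(templates)
  if (n_samples < 17) stop("n_samples must be >= 17", call. = FALSE)
  check_nonnegative(c(noise_sd, amplitude_cv), "noise scales")
  tt <- seq(0, 1, length.out = n_samples + 1L)[seq_len(n_samples)]
  joints <- names(templates)
  out <- vector("list", length(joints))
  for (j in seq_along(joints)) {
    tp <- templates[[joints[j]]]
    c0 <- tp$mean +
      (posture_offsets[joints[j]] %0% 0) +
      (mean_shifts[joints[j]] %0% 0) +
      stats::rnorm(1, 0, noise_sd)
    amp <- amplitude_scale * exp(stats::rnorm(1, 0, amplitude_cv))
    cn <- tp$harmonics * amp
    ang <- Re(c0) + 2 * Re(exp(2i * pi * outer(tt, seq_along(cn))) %*% cn)
    out[[j]] <- data.frame(stride_id = stride_id, joint = joints[j],
                           cycle_fraction = tt, angle_rad = as.numeric(ang),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# named-subset-or-zero lookup (missing / NA names give 0)
`%0%` <- function(x, default) {
  if (length(x) != 1 || is.na(x)) default else as.numeric(x)
}

generate_cohort_traces <- function(strides, config, seed) {
  set.seed(substream_seed(seed, "joint_traces"))
  nz <- config$noise
  joints <- names(config$templates)
  hind <- intersect(joints, c("hip", "knee", "tarsal"))
  fore <- setdiff(joints, hind)
  out <- vector("list", nrow(strides))
  for (i in seq_len(nrow(strides))) {
    mf <- strides$maturation_fraction[i]
    shifts <- c(stats::setNames(rep(config$extension_gain * mf,
                                    length(hind)), hind),
                stats::setNames(rep(config$extension_gain * mf / 3,
                                    length(fore)), fore))
    offs <- if (strides$category[i] == "SGA") config$posture_offsets_sga
            else numeric()
    out[[i]] <- generate_joint_traces(
      templates = config$templates, posture_offsets = offs,
      amplitude_scale = 1, noise_sd = nz$angle_sd,
      n_samples = config$n_cycle_samples, mean_shifts = shifts,
      amplitude_cv = nz$amplitude_cv, stride_id = strides$stride_id[i]
    )
  }
  do.call(rbind, out)
}

#' Generate one limb's stance GRF curves (vertical and fore-aft)
#'
#' Produces a double-hump vertical force curve and a braking-then-
#' propulsion fore-aft curve on a uniform stance-fraction grid, expressed
#' in body weights (BW). The vertical curve is normalized on the discrete
#' grid so that its trapezoid stance mean equals `mass_share /
#' duty_factor`; summed over the four limbs of a steady walk this closes
#' the whole-body support balance at 1 BW. The fore-aft curve integrates
#' to zero over stance (steady-state walking).
#'
#' @param limb `"fore"` or `"hind"`.
#' @param duty_factor Stance time over stride time, in (0, 1].
#' @param mass_share Fraction of body weight supported by this limb over
#'   a stride, in (0, 1).
#' @param noise_sd Relative noise scale (amplitude jitter plus smooth
#'   low-order shape perturbation); 0 for deterministic curves.
#' @param n_nodes Number of grid nodes over stance fractions `[0, 1]`.
#' @param stride_id Identifier copied into the output.
#' @return Long data frame: stride_id, limb, component
#'   (`"vertical"`/`"fore_aft"`), stance_fraction, force_bw.
#' @export
generate_grf_trace <- function(limb = c("fore", "hind"),
                               duty_factor, mass_share,
                               noise_sd = 0, n_nodes = 51L,
                               stride_id = "S00001") {
  limb <- match.arg(limb)
  if (duty_factor <= 0 || duty_factor > 1) {
    stop("duty_factor must lie in (0, 1]", call. = FALSE)
  }
  if (mass_share <= 0 || mass_share >= 1) {
    stop("mass_share must lie in (0, 1)", call. = FALSE)
  }
  check_nonnegative(noise_sd, "noise_sd")
  u <- seq(0, 1, length.out = n_nodes)
  s <- sin(pi * u) * (1 - 0.6 * sin(pi * u)^2)   # double-hump support shape
  trap_mean <- function(y) sum((y[-1] + y[-length(y)]) / 2) / (length(y) - 1)
  vert <- s * (mass_share / duty_factor) / trap_mean(s)
  fa <- -0.2 * (mass_share / duty_factor) * sin(2 * pi * u)
  if (noise_sd > 0) {
    z <- stats::rnorm(4)
    pert <- 1 + noise_sd * (z[1] * sin(pi * u) + z[2] * sin(2 * pi * u) +
                              z[3] * sin(3 * pi * u))
    vert <- pmax(vert * exp(stats::rnorm(1, 0, noise_sd)) * pert, 0)
    fa <- fa + noise_sd * 0.2 * (mass_share / duty_factor) * z[4] * sin(pi * u)
  }
  data.frame(
    stride_id = stride_id,
    limb = limb,
    component = rep(c("vertical", "fore_aft"), each = n_nodes),
    stance_fraction = c(u, u),
    force_bw = c(vert, fa),
    stringsAsFactors = FALSE
  )
}

generate_cohort_grfs <- function(strides, config, seed) {
  set.seed(substream_seed(seed, "grf"))
  out <- vector("list", 2L * nrow(strides))
  share_f <- config$fore_share / 2
  share_h <- (1 - config$fore_share) / 2
  for (i in seq_len(nrow(strides))) {
    out[[2 * i - 1]] <- generate_grf_trace(
      "fore", strides$duty_factor_fore[i], share_f,
      noise_sd = config$noise$grf_sd, n_nodes = config$n_stance_nodes,
      stride_id = strides$stride_id[i])
    out[[2 * i]] <- generate_grf_trace(
      "hind", strides$duty_factor[i], share_h,
      noise_sd = config$noise$grf_sd, n_nodes = config$n_stance_nodes,
      stride_id = strides$stride_id[i])
  }
  do.call(rbind, out)
}

# extensor muscle reference morphometrics at 1.4 kg body mass
ref_muscles <- function() {
  data.frame(
    limb = rep(c("fore", "hind"), each = 4L),
    muscle_id = c("triceps_brachii", "supraspinatus", "ext_carpi_radialis",
                  "biceps_brachii",
                  "gluteus_medius", "vastus_lateralis", "gastrocnemius",
                  "ext_digitorum_longus"),
    mass_frac = c(0.0060, 0.0030, 0.0012, 0.0015,
                  0.0050, 0.0060, 0.0035, 0.0010),
    fibre_ref_m = c(0.025, 0.020, 0.018, 0.015,
                    0.030, 0.028, 0.022, 0.016),
    stringsAsFactors = FALSE
  )
}

generate_muscles <- function(piglets, config, seed) {
  set.seed(substream_seed(seed, "muscles"))
  cv <- config$noise$muscle_cv
  rm <- ref_muscles()
  out <- vector("list", nrow(piglets))
  for (i in seq_len(nrow(piglets))) {
    bm <- piglets$birth_mass_kg[i]
    k <- nrow(rm)
    out[[i]] <- data.frame(
      piglet_id = piglets$piglet_id[i],
      limb = rm$limb, muscle_id = rm$muscle_id,
      mass_kg = rm$mass_frac * bm * exp(stats::rnorm(k, 0, cv)),
      fibre_length_m = rm$fibre_ref_m * (bm / 1.4)^(1 / 3) *
        exp(stats::rnorm(k, 0, cv)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

generate_energetics <- function(piglets, config, seed) {
  set.seed(substream_seed(seed, "energetics"))
  grid <- expand.grid(pig = seq_len(nrow(piglets)), age = config$ages,
                      KEEP.OUT.ATTRS = FALSE)
  aga <- piglets$category[grid$pig] == "AGA"
  glucose <- ifelse(aga, 35 * (1 + 1.3 * (1 - exp(-grid$age / 2.5))), 35) +
    stats::rnorm(nrow(grid), 0, 3)
  glycogen <- ifelse(aga, 5.5 * exp(-grid$age / 40), 3.5) +
    stats::rnorm(nrow(grid), 0, 0.3)
  data.frame(
    piglet_id = piglets$piglet_id[grid$pig],
    category = piglets$category[grid$pig],
    age_h = grid$age,
    glucose_mg_dl = pmax(glucose, 5),
    glycogen_pct = pmax(glycogen, 0.2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.piglet_cohort <- function(x, ...) {
  cat("Synthetic piglet cohort (seed", x$seed, ")\n")
  cat(sprintf("  %d piglets (%d AGA, %d SGA), %d strides\n",
              nrow(x$piglets), sum(x$piglets$category == "AGA"),
              sum(x$piglets$category == "SGA"), nrow(x$strides)))
  cat(sprintf("  joint-trace rows: %d; GRF rows: %d; muscles: %d\n",
              nrow(x$joint_traces), nrow(x$grf_traces), nrow(x$muscles)))
  invisible(x)
}

#' @export
summary.piglet_cohort <- function(object, ...) {
  bm <- tapply(object$piglets$birth_mass_kg, object$piglets$category, mean)
  cat("Birth mass (kg), category means:\n")
  print(round(bm, 3))
  cat("Strides per category:\n")
  print(table(object$strides$category))
  invisible(object)
}

#' Write the cohort tables to CSV files
#'
#' Writes `piglets.csv`, `strides.csv`, `joint_traces.csv`,
#' `grf_traces.csv`, `muscles.csv` and `energetics.csv` into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "piglet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("piglets", "strides", "joint_traces", "grf_traces",
            "muscles", "energetics")
  paths <- stats::setNames(file.path(dir, paste0(tabs, ".csv")), tabs)
  for (tb in tabs) {
    utils::write.csv(cohort[[tb]], paths[[tb]], row.names = FALSE)
  }
  invisible(paths)
}

#' Dynamic-similarity scaling transform
#'
#' A triple of positive factors: `alpha` for lengths, `beta` for times,
#' `gamma` for forces (and, under constant gravity, masses). The transform
#' is dynamic-similarity-consistent when `beta = sqrt(alpha)` and
#' `gamma = alpha^3`, in which case all dimensionless gait variables are
#' invariant under [apply_scaling()].
#'
#' @param alpha,beta,gamma Positive scale factors.
#' @return Classed list `"scaling_transform"`.
#' @export
scaling_transform <- function(alpha, beta = sqrt(alpha), gamma = alpha^3) {
  check_positive(alpha, "scaling factors")
  check_positive(c(beta, gamma), "scaling factors")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "scaling_transform")
}

#' Apply a scaling transform to a cohort
#'
#' Multiplies all lengths by `alpha`, all times by `beta` (frequencies by
#' `1/beta`, speeds by `alpha/beta`) and all forces/masses by `gamma`.
#' Joint angles and BW-normalized GRFs are dimensionless and unchanged.
#'
#' @param cohort A `"piglet_cohort"`.
#' @param transform A [scaling_transform()].
#' @return The scaled cohort (same class).
#' @export
apply_scaling <- function(cohort, transform) {
  stopifnot(inherits(cohort, "piglet_cohort"),
            inherits(transform, "scaling_transform"))
  a <- transform$alpha; b <- transform$beta; g <- transform$gamma
  p <- cohort$piglets
  seg_cols <- grep("^seg_", names(p), value = TRUE)
  p[seg_cols] <- p[seg_cols] * a
  p$limb_length_m <- p$limb_length_m * a
  p$birth_mass_kg <- p$birth_mass_kg * g
  p$front_part_mass_kg <- p$front_part_mass_kg * g
  p$hind_part_mass_kg <- p$hind_part_mass_kg * g
  s <- cohort$strides
  s$speed_ms <- s$speed_ms * a / b
  for (cl in c("stride_length_m", "step_length_fore_m",
               "step_length_hind_m", "hip_height_m")) s[[cl]] <- s[[cl]] * a
  for (cl in c("stride_time_s", "stance_time_s")) s[[cl]] <- s[[cl]] * b
  s$stride_frequency_hz <- s$stride_frequency_hz / b
  s$birth_mass_kg <- s$birth_mass_kg * g
  m <- cohort$muscles
  m$mass_kg <- m$mass_kg * g
  m$fibre_length_m <- m$fibre_length_m * a
  cohort$piglets <- p; cohort$strides <- s; cohort$muscles <- m
  cohort
}
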