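test_that("cohort generation is deterministic and CSV output byte-identical", {
  cfg <- tiny_config()
  c1 <- generate_cohort(cfg, seed = 7)
  c2 <- generate_cohort(cfg, seed = 7)
  expect_identical(c1$strides, c2$strides)
  expect_identical(c1$joint_traces, c2$joint_traces)
  expect_identical(c1$grf_traces, c2$grf_traces)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(c1, d1); p2 <- write_cohort(c2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  c3 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(c1$strides$speed_ms, c3$strides$speed_ms))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(n_aga = 0), "positive")
  expect_error(cohort_config(noise = list(gait_cv = -1)), "non-negative")
  expect_error(cohort_config(noise = list(bogus = 1)), "unknown")
  expect_error(cohort_config(duty = 1.2))
})

test_that("maturation profile has the stated boundary and saturation behavior", {
  pr <- maturation_profile(0.28)          # tau = 8/log(10): 90% by 8 h
  expect_equal(maturation_value(0, pr), 0)
  expect_equal(maturation_value(8, pr), 0.252, tolerance = 1e-9)
  expect_equal(maturation_value(96, pr), 0.28, tolerance = 1e-3)
  ages <- seq(0, 48, by = 0.5)
  expect_true(all(diff(maturation_value(ages, pr)) >= 0))
  expect_error(maturation_value(-1, pr), "non-negative")
  st <- maturation_profile(0.28, stall_age = 4)
  expect_equal(maturation_value(10, st), maturation_value(4, st))
})

test_that("calibrated profile yields the target hip-height increase over its window", {
  pr <- calibrate_maturation(0.28, window = c(1, 28))
  g <- (1 + maturation_value(28, pr)) / (1 + maturation_value(1, pr)) - 1
  expect_equal(g, 0.28, tolerance = 1e-10)
  expect_gt(maturation_value(8, pr) / pr$plateau_fraction, 0.9)
})

test_that("piglet table honors the category mass gap and isometric scaling", {
  co <- generate_cohort(cohort_config(), seed = 3)
  p <- co$piglets
  expect_true(all(p$birth_mass_kg > 0))
  expect_true(all(p$birth_mass_kg[p$category == "SGA"] < 0.8))
  expect_lt(mean(p$birth_mass_kg[p$category == "SGA"]),
            0.65 * mean(p$birth_mass_kg[p$category == "AGA"]))
  # isometry: every segment column proportional to BM^(1/3)
  for (cl in grep("^seg_", names(p), value = TRUE)) {
    ratio <- p[[cl]] / p$birth_mass_kg^(1 / 3)
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  }
})

test_that("stride table satisfies its internal-consistency invariants", {
  co <- generate_cohort(cohort_config(), seed = 5)
  s <- co$strides
  expect_true(all(s$duty_factor > 0 & s$duty_factor <= 1))
  expect_true(all(s$stance_time_s <= s$stride_time_s + 1e-12))
  expect_true(all(abs(s$speed_ms -
                        s$stride_length_m * s$stride_frequency_hz) < 1e-9))
  expect_true(all(s$hip_height_m > 0))
  ph <- as.matrix(s[grep("^phase_", names(s))])
  expect_true(all(ph >= 0 & ph < 1))
})

test_that("zero-noise cohorts are dynamically similar across body sizes", {
  cfg <- cohort_config(n_aga = 6, n_sga = 4, ages = c(1, 8),
                       strides_per_age = 1, noise = zero_noise())
  co <- generate_cohort(cfg, seed = 11)
  s <- normalize_stride_table(co$strides)
  for (grp in split(s, interaction(s$category, s$age_h))) {
    expect_lt(diff(range(grp$froude_speed)), 1e-10)
    expect_lt(diff(range(grp$rel_stride_length)), 1e-10)
    expect_lt(diff(range(grp$rel_frequency)), 1e-10)
    expect_lt(diff(range(grp$duty_factor)), 1e-10)
  }
})

test_that("hip height is non-decreasing with age within piglet (zero noise)", {
  cfg <- cohort_config(n_aga = 3, n_sga = 2, ages = c(0, 1, 4, 8, 24),
                       strides_per_age = 1, noise = zero_noise())
  co <- generate_cohort(cfg, seed = 2)
  for (pg in split(co$strides, co$strides$piglet_id)) {
    pg <- pg[order(pg$age_h), ]
    expect_true(all(diff(pg$hip_height_m) >= -1e-12))
  }
})

test_that("scaling transform acts on lengths/times/forces and preserves similarity", {
  cfg <- tiny_config(noise = zero_noise())
  co <- generate_cohort(cfg, seed = 9)
  expect_error(scaling_transform(-1), "positive")
  # identity leaves the dataset unchanged
  id <- apply_scaling(co, scaling_transform(1))
  expect_equal(id$strides, co$strides)
  # dynamic-similarity transform: dimensionless outputs invariant
  sc <- apply_scaling(co, scaling_transform(2, sqrt(2), 8))
  a <- normalize_stride_table(co$strides)
  b <- normalize_stride_table(sc$strides)
  for (cl in c("froude_speed", "rel_stride_length", "rel_frequency")) {
    expect_equal(a[[cl]], b[[cl]], tolerance = 1e-10)
  }
  # alpha = 2 with beta = 1 changes dimensionless frequency by sqrt(2)
  sc2 <- apply_scaling(co, scaling_transform(2, beta = 1))
  b2 <- normalize_stride_table(sc2$strides)
  expect_equal(b2$rel_frequency, a$rel_frequency * sqrt(2), tolerance = 1e-10)
})

test_that("generated joint traces are band-limited and respect offsets", {
  tb <- joint_template_bank()
  set.seed(1)
  # zero noise, zero offsets: trace equals the template reconstruction
  tr <- generate_joint_traces(tb, noise_sd = 0, n_samples = 100)
  knee <- tr[tr$joint == "knee", ]
  ref <- fourier_reconstruct(c(complex(real = tb$knee$mean),
                               tb$knee$harmonics), 100)
  expect_equal(knee$angle_rad, ref$angle_rad, tolerance = 1e-12)
  # amplitude 0: constant at the mean angle
  flat <- generate_joint_traces(tb, amplitude_scale = 0, noise_sd = 0)
  expect_equal(var(flat$angle_rad[flat$joint == "hip"]), 0)
  # knee offset shifts the time-averaged knee angle by the offset
  off <- generate_joint_traces(tb, posture_offsets = c(knee = -0.192),
                               noise_sd = 0)
  expect_equal(mean(off$angle_rad[off$joint == "knee"]) -
                 mean(tr$angle_rad[tr$joint == "knee"]),
               -0.192, tolerance = 1e-10)
  # angles stay inside (0, pi); exact 8-harmonic round trip even with noise
  nz <- generate_joint_traces(tb, noise_sd = 0.05, amplitude_cv = 0.1)
  expect_true(all(nz$angle_rad > 0 & nz$angle_rad < pi))
  for (j in unique(nz$joint)) {
    tr_j <- nz[nz$joint == j, c("cycle_fraction", "angle_rad")]
    rec <- fourier_reconstruct(fourier_decompose(tr_j, 8), nrow(tr_j))
    expect_lt(max(abs(rec$angle_rad - tr_j$angle_rad)), 1e-9)
  }
  bad <- list(knee = list(mean = 1.7, harmonics = rep(0.1 + 0i, 9)))
  expect_error(generate_joint_traces(bad), "8")
  expect_error(generate_joint_traces(tb, n_samples = 10), "17")
})

test_that("GRF curves close the support balance and have the stated shape", {
  g1 <- generate_grf_trace("fore", duty_factor = 0.67, mass_share = 0.3,
                           noise_sd = 0)
  g2 <- generate_grf_trace("hind", duty_factor = 0.65, mass_share = 0.2,
                           noise_sd = 0)
  trap <- function(y, x) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  vf <- g1[g1$component == "vertical", ]
  vh <- g2[g2$component == "vertical", ]
  # per-limb stance-mean vertical force x duty factor sums to 1 BW
  closure <- 2 * (0.67 * trap(vf$force_bw, vf$stance_fraction) +
                    0.65 * trap(vh$force_bw, vh$stance_fraction))
  expect_equal(closure, 1, tolerance = 0.02)
  # forelimb peak exceeds hindlimb peak
  expect_gt(max(vf$force_bw), max(vh$force_bw))
  # two-peak (double hump): local minimum at midstance between two maxima
  mid <- vf$force_bw[vf$stance_fraction == 0.5]
  expect_lt(mid, max(vf$force_bw[vf$stance_fraction < 0.5]))
  expect_lt(mid, max(vf$force_bw[vf$stance_fraction > 0.5]))
  expect_true(all(vf$force_bw >= 0))
  # fore-aft: one zero crossing, braking then propulsion, zero net impulse
  fa <- g1[g1$component == "fore_aft", ]
  inner <- fa$force_bw[fa$stance_fraction > 0 & fa$stance_fraction < 1]
  expect_equal(sum(diff(sign(inner)) != 0), 1)
  expect_lt(inner[1], 0)
  expect_lt(abs(trap(fa$force_bw, fa$stance_fraction)), 1e-12)
  expect_error(generate_grf_trace("fore", 1.2, 0.3), "duty_factor")
  expect_error(generate_grf_trace("fore", 0.6, 1.3), "mass_share")
})

test_that("whole-body vertical impulse per stride equals 1 BW x stride time", {
  cfg <- tiny_config(noise = zero_noise())
  co <- generate_cohort(cfg, seed = 4)
  s <- co$strides[1, ]
  g <- co$grf_traces[co$grf_traces$stride_id == s$stride_id &
                       co$grf_traces$component == "vertical", ]
  trap <- function(y, x) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  impulse <- 0
  for (lb in c("fore", "hind")) {
    gl <- g[g$limb == lb, ]
    duty <- if (lb == "fore") s$duty_factor_fore else s$duty_factor
    stance_t <- duty * s$stride_time_s
    impulse <- impulse + 2 * trap(gl$force_bw, gl$stance_fraction) * stance_t
  }
  expect_equal(impulse, s$stride_time_s, tolerance = 0.02)
})
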