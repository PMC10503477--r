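# Shared fixtures: all data is generated in code at test time.

zero_noise <- function() {
  list(gait_cv = 0, hip_cv = 0, phase_sd = 0, angle_sd = 0,
       amplitude_cv = 0, grf_sd = 0, part_mass_sigma = 0, muscle_cv = 0)
}

tiny_config <- function(...) {
  cohort_config(n_aga = 4L, n_sga = 3L, ages = c(1, 4, 8),
                strides_per_age = 1L, ...)
}

# fabricate a Fourier-descriptor table with plausible structure
make_descriptors <- function(n_strides, seed = 1, mean_shift = c(),
                             prefix = "S") {
  set.seed(seed)
  joints <- c("carpal", "elbow", "hip", "knee", "shoulder", "tarsal")
  base_mean <- c(carpal = 2.35, elbow = 2.0, hip = 1.9, knee = 1.75,
                 shoulder = 1.65, tarsal = 2.0)
  rows <- list()
  for (i in seq_len(n_strides)) {
    for (j in joints) {
      sh <- complex(real = stats::rnorm(8, 0, 0.3),
                    imaginary = stats::rnorm(8, 0, 0.3))
      sh <- sh / sqrt(2 * sum(Mod(sh)^2))   # two-sided unit norm
      mu <- base_mean[[j]] + (if (j %in% names(mean_shift))
        mean_shift[[j]] else 0) + stats::rnorm(1, 0, 0.05)
      row <- data.frame(stride_id = sprintf("%s%05d", prefix, i), joint = j,
                        mean_angle = mu, amplitude = abs(stats::rnorm(1, 0.25, 0.03)),
                        rom = abs(stats::rnorm(1, 0.5, 0.05)))
      for (k in 1:8) row[[paste0("shape_re_", k)]] <- Re(sh[k])
      for (k in 1:8) row[[paste0("shape_im_", k)]] <- Im(sh[k])
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

# band-limited test trace on a uniform n-point grid
cosine_trace <- function(n = 100, mean = 1.5, amp = 0.3, harmonic = 1,
                         phase = 0) {
  tt <- seq(0, 1, length.out = n + 1)[seq_len(n)]
  data.frame(cycle_fraction = tt,
             angle_rad = mean + amp * cos(2 * pi * harmonic * tt + phase))
}
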