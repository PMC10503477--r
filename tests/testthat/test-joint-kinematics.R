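test_that("cycle resampling is periodic linear interpolation", {
  tr <- cosine_trace(100)
  expect_equal(resample_cycle(tr, 100), tr, tolerance = 1e-12)
  const <- data.frame(cycle_fraction = c(0, 0.3, 0.7), angle_rad = 1.2)
  rc <- resample_cycle(const, 40)
  expect_true(all(rc$angle_rad == 1.2))
  expect_error(resample_cycle(data.frame(cycle_fraction = c(0, 0.5, 0.2),
                                         angle_rad = 1:3), 10),
               "increasing")
  # downsampling a single-harmonic trace preserves c1 to interpolation order
  c1 <- fourier_decompose(resample_cycle(cosine_trace(100), 64))["h1"]
  expect_equal(unname(Mod(c1)), 0.15, tolerance = 1e-3)
})

test_that("Fourier decomposition matches analytic coefficients", {
  const <- data.frame(cycle_fraction = seq(0, 1, length.out = 33)[1:32],
                      angle_rad = 1.2)
  cf <- fourier_decompose(const)
  expect_equal(Re(cf[["h0"]]), 1.2)
  expect_equal(Im(cf[["h0"]]), 0)
  expect_true(all(Mod(cf[-1]) < 1e-12))
  cf2 <- fourier_decompose(cosine_trace(64))
  expect_equal(Re(cf2[["h0"]]), 1.5, tolerance = 1e-12)
  expect_equal(cf2[["h1"]], 0.15 + 0i, tolerance = 1e-12)
  expect_true(all(Mod(cf2[c("h2", "h3", "h4")]) < 1e-12))
  expect_error(fourier_decompose(cosine_trace(16)), "aliasing")
  expect_error(fourier_decompose(
    data.frame(cycle_fraction = sort(runif(40)), angle_rad = rnorm(40))),
    "uniform")
})

test_that("Parseval identity holds against a quadrature oracle", {
  set.seed(3)
  for (rep in 1:5) {
    cn <- complex(real = rnorm(8, 0, 0.1), imaginary = rnorm(8, 0, 0.1))
    c0 <- runif(1, 1, 2)
    theta <- function(t) c0 + 2 * Re(exp(2i * pi * outer(t, 1:8)) %*% cn)
    # oracle: mean square by dense trapezoid quadrature, independent of fft
    tfine <- seq(0, 1, length.out = 20001)
    yf <- theta(tfine)^2
    mean_sq <- sum(diff(tfine) * (head(yf, -1) + tail(yf, -1)) / 2)
    tr <- data.frame(cycle_fraction = seq(0, 1, length.out = 101)[1:100],
                     angle_rad = as.numeric(theta(
                       seq(0, 1, length.out = 101)[1:100])))
    cf <- fourier_decompose(tr)
    expect_equal(Re(cf[["h0"]])^2 + 2 * sum(Mod(cf[-1])^2), mean_sq,
                 tolerance = 1e-8)
  }
})

test_that("decompose-reconstruct round trip is exact on band-limited traces", {
  set.seed(5)
  cn <- complex(real = rnorm(8, 0, 0.05), imaginary = rnorm(8, 0, 0.05))
  cf0 <- c(complex(real = 1.8), cn)
  tr <- fourier_reconstruct(cf0, 100)
  cf <- fourier_decompose(tr)
  expect_lt(max(Mod(cf - cf0)), 1e-12)
  rec <- fourier_reconstruct(cf, 100)
  expect_lt(max(abs(rec$angle_rad - tr$angle_rad)), 1e-9)
  # zero coefficients reconstruct the zero trace
  z <- fourier_reconstruct(rep(0 + 0i, 9), 50)
  expect_true(all(z$angle_rad == 0))
  # single harmonic reconstructs a pure cosine (closed form)
  one <- fourier_reconstruct(c(0 + 0i, 0.15 + 0i), 64)
  tt <- one$cycle_fraction
  expect_equal(one$angle_rad, 0.3 * cos(2 * pi * tt), tolerance = 1e-12)
})

test_that("affine split separates posture from unit-norm shape", {
  cf <- fourier_decompose(cosine_trace(64))
  d <- affine_split(cf)
  expect_equal(d$mean_angle, 1.5, tolerance = 1e-12)
  expect_equal(d$amplitude, 0.3 / sqrt(2), tolerance = 1e-12)
  expect_equal(d$shape[[1]], complex(real = 1 / sqrt(2)), tolerance = 1e-12)
  # two-sided spectrum norm is 1
  expect_equal(2 * sum(Mod(d$shape)^2), 1, tolerance = 1e-12)
  # shape invariant under affine transforms of the trace
  tr <- fourier_reconstruct(c(1.8 + 0i,
                              complex(real = rnorm(8, 0, 0.05),
                                      imaginary = rnorm(8, 0, 0.05))), 100)
  tr2 <- tr; tr2$angle_rad <- 2.5 * (tr$angle_rad - mean(tr$angle_rad)) + 0.9
  d1 <- affine_split(fourier_decompose(tr))
  d2 <- affine_split(fourier_decompose(tr2))
  expect_equal(d1$shape, d2$shape, tolerance = 1e-10)
  # constant trace: zero amplitude, all-zero shape
  dc <- affine_split(fourier_decompose(rep(1.2, 33)))
  expect_equal(dc$amplitude, 0)
  expect_true(all(Mod(dc$shape) == 0))
})

test_that("a cyclic shift rotates shape coefficients by exp(-i2pi n delta)", {
  set.seed(7)
  cn <- complex(real = rnorm(8, 0, 0.05), imaginary = rnorm(8, 0, 0.05))
  cf0 <- c(1.8 + 0i, cn)
  delta <- 0.23
  tr <- fourier_reconstruct(cf0, 100)
  shifted <- tr
  shifted$angle_rad <- fourier_reconstruct(
    c(cf0[1], cf0[-1] * exp(-2i * pi * (1:8) * delta)), 100)$angle_rad
  d0 <- affine_split(fourier_decompose(tr))
  d1 <- affine_split(fourier_decompose(shifted))
  expect_equal(d1$shape, d0$shape * exp(-2i * pi * (1:8) * delta),
               tolerance = 1e-10)
})

test_that("range of motion follows the closed form", {
  expect_equal(range_of_motion(rep(1.2, 10)), 0)
  tr <- cosine_trace(200, mean = 1.5, amp = 0.3)
  expect_equal(range_of_motion(tr), 0.6, tolerance = 1e-3)
  tr2 <- tr; tr2$angle_rad <- tr$angle_rad + 0.4
  expect_equal(range_of_motion(tr2), range_of_motion(tr))
})

test_that("descriptor table pools 96 shape coefficients per stride", {
  co <- generate_cohort(tiny_config(), seed = 10)
  desc <- fourier_descriptors(co$joint_traces)
  expect_equal(nrow(desc), 6 * nrow(co$strides))
  sm <- shape_matrix(desc)
  expect_equal(ncol(sm), 96)
  expect_equal(nrow(sm), nrow(co$strides))
  # posture block is 6 means + 6 amplitudes = 12 values per stride
  expect_equal(sum(grepl("^(mean|amplitude)", names(desc))), 2)
})

test_that("coordination PCA has orthonormal loadings and consistent variance", {
  set.seed(12)
  X <- matrix(rnorm(120 * 96), 120, 96)
  pc <- coordination_pca(X, n_pcs = 12)
  G <- crossprod(pc$loadings)
  expect_equal(G, diag(12), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1)
  expect_equal(sum(pc$explained_variance_all), 1, tolerance = 1e-12)
  # full-rank reconstruction returns the input
  pc_all <- coordination_pca(X, n_pcs = 96)
  rec <- sweep(pc_all$scores %*% t(pc_all$loadings), 2, -pc_all$center)
  expect_equal(rec, X, tolerance = 1e-8, ignore_attr = TRUE)
  # degenerate inputs
  same <- matrix(1, 30, 96) * rep(rnorm(96), each = 30)
  expect_true(all(abs(coordination_pca(same, 5)$scores) < 1e-12))
  r1 <- outer(rnorm(40), rnorm(96))
  expect_equal(coordination_pca(r1, 5)$explained_variance[1], 1,
               tolerance = 1e-10)
  expect_error(coordination_pca(X[1:10, ], 12), "more strides")
  # projection of the training data reproduces the scores
  expect_equal(predict(pc, X), pc$scores, tolerance = 1e-10)
})

test_that("posture comparison is null-calibrated and recovers injected offsets", {
  da <- make_descriptors(40, seed = 21)
  db <- make_descriptors(40, seed = 22, prefix = "T")
  cmp <- compare_posture(da, db, seed = 1)
  expect_equal(nrow(cmp), 24)  # 6 means + 6 RoMs + 12 PCs
  expect_lte(sum(cmp$excludes_zero), 3)   # ~5% false positives over 24 vars
  expect_true(all(abs(cmp$post_mean[cmp$type == "mean_angle"]) < 0.05))
  # injected knee offset recovered
  db2 <- make_descriptors(40, seed = 23, prefix = "U",
                          mean_shift = c(knee = -0.192))
  cmp2 <- compare_posture(da, db2, seed = 1)
  knee <- cmp2[cmp2$variable == "mean_knee", ]
  expect_lt(abs(knee$post_mean - (-0.192)), 0.03)
  expect_true(knee$excludes_zero)
  # doubling the group sizes shrinks the interval roughly by 1/sqrt(2)
  da_big <- make_descriptors(80, seed = 24)
  db_big <- make_descriptors(80, seed = 25, prefix = "V")
  cmp_big <- compare_posture(da_big, db_big, seed = 1)
  w_small <- cmp$hi[cmp$variable == "mean_knee"] -
    cmp$lo[cmp$variable == "mean_knee"]
  w_big <- cmp_big$hi[cmp_big$variable == "mean_knee"] -
    cmp_big$lo[cmp_big$variable == "mean_knee"]
  expect_equal(w_big / w_small, 1 / sqrt(2), tolerance = 0.25)
  # degenerate variable: zero variance collapses and is flagged
  dz <- make_descriptors(10, seed = 26); dz$rom[dz$joint == "hip"] <- 0.5
  ez <- make_descriptors(10, seed = 27, prefix = "W")
  ez$rom[ez$joint == "hip"] <- 0.5
  cmpz <- compare_posture(dz, ez, seed = 1)
  expect_true(cmpz$degenerate[cmpz$variable == "rom_hip"])
  expect_error(compare_posture(da[da$stride_id == "S00001", ], db),
               ">= 2 strides")
})
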