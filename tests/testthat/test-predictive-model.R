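test_that("size score tracks body size under isometry", {
  co <- generate_cohort(cohort_config(n_aga = 10, n_sga = 8, ages = 1,
                                      strides_per_age = 1,
                                      noise = zero_noise()), seed = 18)
  segs <- as.matrix(co$piglets[grep("^seg_", names(co$piglets))])
  sc <- size_score(segs)
  expect_equal(cor(sc, co$piglets$birth_mass_kg, method = "spearman"), 1)
  # identical animals score zero
  same <- matrix(0.05, 6, 4)
  expect_warning(sc0 <- size_score(same), "zero-variance")
  expect_true(all(sc0 == 0))
  # enlarging one animal raises its score to the top
  segs2 <- segs; segs2[3, ] <- segs2[3, ] * 2
  expect_equal(which.max(size_score(segs2)), 3)
  expect_error(size_score(segs[, 1, drop = FALSE]), ">= 2")
})

test_that("feature assembly yields the fixed-order 34-vector", {
  sp <- stats::setNames(runif(9), pigletgait:::spatiotemporal_feature_names())
  fv <- assemble_features(sp, runif(12), runif(12), "M")
  expect_length(fv, 34)
  expect_equal(names(fv)[1], "sex")
  expect_equal(fv[["sex"]], 1)
  # named spatiotemporal input is order-independent
  fv2 <- assemble_features(sp[sample(9)], runif(12), runif(12), "M")
  expect_equal(names(fv2), names(fv))
  expect_error(assemble_features(sp, NULL, runif(12), "F"), "postural")
  expect_error(assemble_features(sp[1:5], runif(12), runif(12), "F"),
               "lengths")
  bad <- runif(12); bad[3] <- NaN
  expect_error(assemble_features(sp, bad, runif(12), "F"), "non-finite")
})

test_that("cohort feature tables are 34 wide and consistent with assembly", {
  co <- generate_cohort(tiny_config(), seed = 19)
  ft <- feature_table(co)
  expect_equal(ncol(ft$features), 34)
  expect_equal(nrow(ft$features), nrow(co$strides))
  expect_false(any(!is.finite(ft$features)))
  # row-wise assembly reproduces the matrix construction
  i <- 5
  sn <- normalize_stride_table(co$strides)
  st <- sn[sn$stride_id == rownames(ft$features)[i], ]
  fv <- assemble_features(
    c(froude_speed = st$froude_speed, rel_stride_length = st$rel_stride_length,
      rel_step_length_fore = st$rel_step_length_fore,
      rel_step_length_hind = st$rel_step_length_hind,
      rel_frequency = st$rel_frequency, duty_factor = st$duty_factor,
      duty_factor_fore = st$duty_factor_fore, phase_lf = st$phase_lf,
      phase_rf = st$phase_rf),
    ft$features[i, 11:22], ft$features[i, 23:34], st$sex)
  expect_equal(fv, ft$features[i, ], tolerance = 1e-12)
})

test_that("conjugate training recovers a known linear signal", {
  set.seed(41)
  n <- 300; p <- 34
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  beta <- numeric(p); beta[c(1, 5, 20)] <- c(2, -1, 0.5)
  y <- drop(X %*% beta)
  m <- train_trait_model(X, y, "mass",
                         prior = prior_config(coef_sd = 1e4))
  cm <- m$coef_mean[-1] * m$y_scale / m$x_scale   # back to raw scale
  expect_true(all(abs(cm[c(1, 5, 20)] - beta[c(1, 5, 20)]) <
                    2 * pmax(m$coef_sd[-1][c(1, 5, 20)], 1e-6)))
  expect_true(all(abs(cm[-c(1, 5, 20)]) < 1e-6))
  # interpolation of an exact fit
  pr <- predict(m, X)
  expect_lt(max(abs(pr$fit - y)), 1e-6)
  expect_error(train_trait_model(X, rep(1, n), "mass"), "constant")
  expect_error(train_trait_model(X, c(y[-1], NA), "mass"), "non-finite")
})

test_that("null targets give calibrated coefficient intervals", {
  set.seed(43)
  X <- matrix(rnorm(400 * 10), 400, 10)
  y <- rnorm(400)
  m <- train_trait_model(X, y, "age")
  z <- abs(m$coef_mean[-1]) / m$coef_sd[-1]
  expect_lt(mean(z > 2), 0.3)   # most coefficients consistent with zero
})

test_that("posterior uncertainty shrinks ~1/sqrt(2) when data are doubled", {
  set.seed(44)
  X <- matrix(rnorm(150 * 6), 150, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(150)
  m1 <- train_trait_model(X, y, "size")
  m2 <- train_trait_model(rbind(X, X), c(y, y), "size")
  expect_equal(mean(m2$coef_sd[-1] / m1$coef_sd[-1]), 1 / sqrt(2),
               tolerance = 0.05)
})

test_that("predictive intervals are ordered, centered and affine-invariant", {
  set.seed(45)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(200, sd = 0.5)
  m <- train_trait_model(X, y, "mass")
  Xn <- matrix(rnorm(20 * 8), 20, 8)
  p90 <- predict(m, Xn, level = 0.9)
  p50 <- predict(m, Xn, level = 0.5)
  expect_true(all(p50$hi - p50$lo < p90$hi - p90$lo))
  expect_true(all(p90$lo <= p90$fit & p90$fit <= p90$hi))
  # mean-feature stride predicts the intercept (the target mean region)
  pm <- predict(m, matrix(colMeans(X), 1))
  expect_equal(pm$fit, m$y_center + m$y_scale * m$mn[1], tolerance = 1e-10)
  # affine rescaling of a raw feature column leaves predictions unchanged
  X2 <- X; X2[, 3] <- X2[, 3] * 100 + 7
  Xn2 <- Xn; Xn2[, 3] <- Xn2[, 3] * 100 + 7
  m2 <- train_trait_model(X2, y, "mass")
  expect_equal(predict(m2, Xn2)$fit, predict(m, Xn)$fit, tolerance = 1e-8)
  expect_error(predict(m, Xn[, 1:5]), "mismatch")
  # reproducibility: retraining gives identical posterior summaries
  m3 <- train_trait_model(X, y, "mass")
  expect_identical(m$coef_mean, m3$coef_mean)
  expect_identical(m$bn, m3$bn)
})

test_that("validation reports coverage, bias and error honestly", {
  set.seed(46)
  X <- matrix(rnorm(300 * 6), 300, 6)
  beta <- rnorm(6)
  y <- drop(X %*% beta)
  m <- train_trait_model(X, y, "size", prior = prior_config(coef_sd = 1e4))
  Xh <- matrix(rnorm(100 * 6), 100, 6)
  yh <- drop(Xh %*% beta)
  v <- validate_trait_model(m, Xh, yh)
  expect_lt(v$rmse, 1e-6)   # zero-noise target
  # shuffled actuals destroy coverage
  yn <- drop(X %*% beta) + rnorm(300)
  mn <- train_trait_model(X, yn, "size")
  vh <- validate_trait_model(mn, Xh, drop(Xh %*% beta) + rnorm(100))
  vs <- validate_trait_model(mn, Xh, sample(yn, 100))
  expect_gt(vh$coverage, vs$coverage - 0.05)
})

test_that("per-group prediction differences expose AGA-like bias on SGA strides", {
  co <- generate_cohort(cohort_config(n_aga = 12, n_sga = 6,
                                      ages = c(1, 4, 8),
                                      strides_per_age = 2), seed = 20)
  ft <- feature_table(co)
  aga <- ft$meta$category == "AGA"
  m <- train_trait_model(ft$features[aga, ], ft$meta$mass[aga], "mass")
  pr <- predict(m, ft$features)
  cmp <- compare_predictions(pr$fit, ft$meta$mass, ft$meta$category)
  expect_equal(sort(cmp$group), c("AGA", "SGA"))
  # trained-on bias is small; SGA strides predicted systematically heavier
  expect_lt(abs(cmp$mean_diff[cmp$group == "AGA"]), 0.15)
  expect_gt(cmp$mean_diff[cmp$group == "SGA"], 0.3)
  expect_gt(cmp$frac_over[cmp$group == "SGA"], 0.9)
  expect_error(
    compare_predictions(pr$fit[1:5], ft$meta$mass, ft$meta$category),
    "mismatch")
  # id-matched actuals with an unmatched id error out
  acts <- data.frame(stride_id = ft$meta$stride_id, actual = ft$meta$mass)
  rownames(pr) <- ft$meta$stride_id
  ok <- compare_predictions(pr, acts, ft$meta$category)
  expect_equal(ok$mean_diff, cmp$mean_diff)
  acts$stride_id[1] <- "BOGUS"
  expect_error(compare_predictions(pr[1, , drop = FALSE], acts[1, ], "AGA"),
               "unmatched")
})

test_that("a maturation stall reads as systematic age underestimation", {
  cfg <- cohort_config(n_aga = 30, n_sga = 8, ages = c(1, 2, 4, 6, 8, 10),
                       strides_per_age = 1, posture_offsets_sga = numeric())
  ex <- age_stall_experiment(cfg, seed = 4, stall_age = 4)
  expect_gte(ex$fraction_underestimated, 0)
  expect_lte(ex$fraction_underestimated, 1)
  ex0 <- age_stall_experiment(cfg, seed = 4, stall_age = NULL)
  expect_gt(ex$fraction_underestimated, 0.7)
  expect_lt(abs(ex0$fraction_underestimated - 0.5), 0.25)
  expect_gt(ex$mean_underestimate_h, ex0$mean_underestimate_h)
})
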