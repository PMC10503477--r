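#' Linear body-size score from segmental measures
#'
#' First principal component of the column-centered log segment-length
#' matrix, one score per animal, with the sign fixed so that larger
#' animals score higher. Under isometric growth all log lengths move
#' together and the score is a monotone function of body mass.
#'
#' @param segment_lengths Numeric animals-by-segments matrix (m), at least
#'   2 columns and more rows than columns.
#' @return Numeric vector of size scores (arbitrary units, centered).
#' @export
size_score <- function(segment_lengths) {
  segment_lengths <- as.matrix(segment_lengths)
  if (ncol(segment_lengths) < 2) stop("need >= 2 segments", call. = FALSE)
  check_positive(segment_lengths, "segment_lengths")
  lx <- log(segment_lengths)
  v <- apply(lx, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance segment column(s)", sum(v == 0)),
            call. = FALSE)
    lx <- lx[, v > 0, drop = FALSE]
  }
  if (ncol(lx) < 1) return(rep(0, nrow(segment_lengths)))
  pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1]
  if (pc$sdev[1] > 0 && stats::cor(sc, rowMeans(lx)) < 0) sc <- -sc
  unname(sc)
}

# canonical ordering of the 34-entry feature vector
spatiotemporal_feature_names <- function() {
  c("froude_speed", "rel_stride_length", "rel_step_length_fore",
    "rel_step_length_hind", "rel_frequency", "duty_factor",
    "duty_factor_fore", "phase_lf", "phase_rf")
}

feature_vector_names <- function(joints) {
  c("sex", spatiotemporal_feature_names(),
    paste0("mean_", joints), paste0("amp_", joints),
    paste0("PC", 1:12))
}

#' Assemble one stride's 34-entry feature vector
#'
#' Fixed ordering: sex (0 = F, 1 = M), 9 dimensionless spatiotemporal
#' variables, 12 postural variables (6 joint mean angles then 6
#' amplitudes), 12 coordination PC scores. Input block order does not
#' matter; entries are matched by name where names are present.
#'
#' @param spatiotemporal Named (or ordered) numeric length 9.
#' @param postural Numeric length 12 (6 means then 6 amplitudes).
#' @param coordination Numeric length 12 (PC scores).
#' @param sex `"F"`/`"M"`, or 0/1.
#' @param joints Joint names in canonical order (default the six limb
#'   joints, alphabetical).
#' @return Named numeric vector of length 34.
#' @export
assemble_features <- function(spatiotemporal, postural, coordination, sex,
                              joints = c("carpal", "elbow", "hip", "knee",
                                         "shoulder", "tarsal")) {
  blocks <- list(spatiotemporal = spatiotemporal, postural = postural,
                 coordination = coordination, sex = sex)
  for (nm in names(blocks)) {
    if (is.null(blocks[[nm]]) || length(blocks[[nm]]) == 0) {
      stop("missing feature block: ", nm, call. = FALSE)
    }
  }
  sexnum <- if (is.character(sex) || is.factor(sex)) {
    match(as.character(sex), c("F", "M")) - 1
  } else as.numeric(sex)
  if (length(spatiotemporal) != 9 || length(postural) != 12 ||
      length(coordination) != 12 || length(sexnum) != 1) {
    stop("feature blocks have wrong lengths (need 9/12/12/1)", call. = FALSE)
  }
  sp <- if (!is.null(names(spatiotemporal))) {
    spatiotemporal[spatiotemporal_feature_names()]
  } else spatiotemporal
  out <- c(sexnum, as.numeric(sp), as.numeric(postural),
           as.numeric(coordination))
  names(out) <- feature_vector_names(joints)
  if (any(!is.finite(out))) stop("non-finite feature value", call. = FALSE)
  out
}

#' Build the stride feature table of a cohort
#'
#' Runs dynamic-similarity normalization and Fourier decomposition on a
#' synthetic (or schema-compatible) cohort and assembles the 34-entry
#' feature matrix plus a metadata table with the prediction targets
#' (body mass, size score, age). The coordination PCA can be frozen from
#' a training set and passed in via `pca` so held-out or SGA strides are
#' projected into the training coordinate system.
#'
#' @param cohort A `"piglet_cohort"` (or list with `strides`,
#'   `joint_traces`, `piglets`, `config`).
#' @param pca Optional fitted [coordination_pca()]; if `NULL` one is
#'   fitted on these strides.
#' @param stride_ids Optional subset of stride ids to keep.
#' @return List: `features` (n x 34 matrix, rownames = stride ids),
#'   `meta` (data frame: stride_id, piglet_id, category, age, mass,
#'   size), `pca`, `descriptors`.
#' @export
feature_table <- function(cohort, pca = NULL, stride_ids = NULL) {
  cfg <- cohort$config
  strides <- normalize_stride_table(cohort$strides, g = cfg$g)
  traces <- cohort$joint_traces
  if (!is.null(stride_ids)) {
    strides <- strides[strides$stride_id %in% stride_ids, ]
    traces <- traces[traces$stride_id %in% stride_ids, ]
  }
  desc <- fourier_descriptors(traces, n_harmonics = 8L,
                              n_samples = cfg$n_cycle_samples)
  sm <- shape_matrix(desc)
  if (is.null(pca)) pca <- coordination_pca(sm, n_pcs = 12L)
  scores <- predict(pca, sm)

  joints <- sort(unique(desc$joint))
  post <- matrix(NA_real_, nrow(sm), 2L * length(joints),
                 dimnames = list(rownames(sm),
                                 c(paste0("mean_", joints),
                                   paste0("amp_", joints))))
  for (j in joints) {
    dj <- desc[desc$joint == j, ]
    idx <- match(dj$stride_id, rownames(sm))
    post[idx, paste0("mean_", j)] <- dj$mean_angle
    post[idx, paste0("amp_", j)] <- dj$amplitude
  }

  ord <- match(rownames(sm), strides$stride_id)
  st <- strides[ord, ]
  spat <- as.matrix(st[, c("froude_speed", "rel_stride_length",
                           "rel_step_length_fore", "rel_step_length_hind",
                           "rel_frequency", "duty_factor",
                           "duty_factor_fore", "phase_lf", "phase_rf")])
  feats <- cbind(sex = as.numeric(st$sex == "M"), spat, post,
                 scores[, 1:12, drop = FALSE])
  colnames(feats) <- feature_vector_names(joints)
  rownames(feats) <- st$stride_id

  pg <- cohort$piglets
  seg_cols <- grep("^seg_", names(pg), value = TRUE)
  sizes <- size_score(as.matrix(pg[, seg_cols]))
  meta <- data.frame(
    stride_id = st$stride_id, piglet_id = st$piglet_id,
    category = st$category, age = st$age_h,
    mass = st$birth_mass_kg,
    size = sizes[match(st$piglet_id, pg$piglet_id)],
    stringsAsFactors = FALSE
  )
  list(features = feats, meta = meta, pca = pca, descriptors = desc)
}

#' Prior configuration for Bayesian trait models
#'
#' Priors are placed on the standardized scale (predictors z-scored,
#' target centered and scaled by its sd): coefficients
#' `N(0, coef_sd^2 * sigma^2)`, intercept `N(0, intercept_sd^2 * sigma^2)`
#' and residual variance `Inv-Gamma(a0, b0)` — a conjugate
#' normal-inverse-gamma family with closed-form posterior.
#'
#' @param coef_sd Prior sd of standardized coefficients (default 1).
#' @param intercept_sd Prior sd of the standardized intercept (default 2,
#'   i.e. twice the target sd around the target mean).
#' @param a0,b0 Inverse-gamma shape and scale of the residual variance.
#' @return Classed list `"trait_prior"`.
#' @export
prior_config <- function(coef_sd = 1, intercept_sd = 2, a0 = 3, b0 = 2) {
  check_positive(c(coef_sd, intercept_sd, a0, b0), "prior parameters")
  structure(list(coef_sd = coef_sd, intercept_sd = intercept_sd,
                 a0 = a0, b0 = b0), class = "trait_prior")
}

#' Train a Bayesian linear trait model (reverse modelling)
#'
#' Fits an identity-link Gaussian Bayesian linear model of a subject trait
#' (body mass, size score or age) on stride features — the "reverse"
#' direction: the animal's traits are inferred from how it walks.
#' Predictors are standardized internally and the conjugate
#' normal-inverse-gamma posterior is computed in closed form, so results
#' for a given dataset are exact and reproducible.
#'
#' @param features Numeric n x p matrix (typically p = 34).
#' @param y Numeric target vector (length n, non-constant).
#' @param target One of `"mass"`, `"size"`, `"age"` (label only).
#' @param prior A [prior_config()].
#' @param seed Stored for provenance (the closed-form posterior uses no
#'   randomness).
#' @return Object of class `"trait_model"` with posterior summaries
#'   (`coef_mean`, `coef_sd` on the standardized scale), the full
#'   posterior (`mn`, `Vn`, `an`, `bn`) and the standardization constants.
#' @export
train_trait_model <- function(features, y, target = c("mass", "size", "age"),
                              prior = prior_config(), seed = NULL) {
  target <- match.arg(target)
  X <- as.matrix(features)
  stopifnot(inherits(prior, "trait_prior"))
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in features or target", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("length mismatch", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant target", call. = FALSE)
  if (nrow(X) <= ncol(X)) {
    warning("fewer strides than features; posterior driven by the prior",
            call. = FALSE)
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Z <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y); y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  Z1 <- cbind(intercept = 1, Z)
  v0 <- c(prior$intercept_sd^2, rep(prior$coef_sd^2, ncol(Z)))
  V0inv <- diag(1 / v0)
  Vn <- solve(V0inv + crossprod(Z1))
  mn <- Vn %*% crossprod(Z1, ys)
  an <- prior$a0 + length(ys) / 2
  bn <- prior$b0 + 0.5 * (sum(ys^2) - t(mn) %*% (V0inv + crossprod(Z1)) %*% mn)
  bn <- as.numeric(bn)
  coef_sd <- sqrt(bn / an * diag(Vn)) * sqrt((2 * an) / (2 * an - 2))
  structure(
    list(target = target, mn = as.numeric(mn), Vn = Vn, an = an, bn = bn,
         coef_mean = stats::setNames(as.numeric(mn), colnames(Z1)),
         coef_sd = stats::setNames(coef_sd, colnames(Z1)),
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         n = nrow(X), p = ncol(X), prior = prior,
         seed = seed, feature_names = colnames(X)),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("Bayesian trait model: %s ~ %d stride features (n = %d)\n",
              x$target, x$p, x$n))
  cat(sprintf("  residual sd (posterior mean, target units): %.4g\n",
              sqrt(x$bn / (x$an - 1)) * x$y_scale))
  top <- order(abs(x$coef_mean[-1]), decreasing = TRUE)[1:5]
  cat("  largest standardized coefficients:\n")
  print(round(x$coef_mean[-1][top], 3))
  invisible(x)
}

#' @export
coef.trait_model <- function(object, ...) object$coef_mean

#' @export
summary.trait_model <- function(object, ...) {
  print(object)
  cat("\nPosterior coefficient summaries (standardized scale):\n")
  print(data.frame(mean = round(object$coef_mean, 4),
                   sd = round(object$coef_sd, 4)))
  invisible(object)
}

#' Posterior predictive trait estimates for new strides
#'
#' @param object A [train_trait_model()] fit.
#' @param newdata Feature matrix with the training columns.
#' @param level Central credible level of the predictive interval
#'   (default 0.9).
#' @param ... Unused.
#' @return Data frame: `fit` (posterior predictive mean), `lo`, `hi`
#'   (Student-t predictive interval), on the raw target scale.
#' @export
predict.trait_model <- function(object, newdata, level = 0.9, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) {
    stop(sprintf("feature length mismatch: %d vs %d expected", ncol(X),
                 object$p), call. = FALSE)
  }
  Z1 <- cbind(1, sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/"))
  mu <- as.numeric(Z1 %*% object$mn)
  s2 <- object$bn / object$an *
    (1 + rowSums((Z1 %*% object$Vn) * Z1))
  tq <- stats::qt(1 - (1 - level) / 2, df = 2 * object$an)
  data.frame(
    fit = object$y_center + object$y_scale * mu,
    lo = object$y_center + object$y_scale * (mu - tq * sqrt(s2)),
    hi = object$y_center + object$y_scale * (mu + tq * sqrt(s2)),
    row.names = rownames(X)
  )
}

#' Validate a trait model on held-out strides
#'
#' @param model A `"trait_model"`.
#' @param features Held-out feature matrix (>= 1 row).
#' @param actuals Held-out target values.
#' @param level Credible level of the intervals scored for coverage.
#' @return List: `coverage` (fraction of actuals inside their predictive
#'   interval), `mean_error` (predicted minus actual), `rmse`, `n`.
#' @export
validate_trait_model <- function(model, features, actuals, level = 0.9) {
  pr <- predict(model, features, level = level)
  if (length(actuals) != nrow(pr)) stop("length mismatch", call. = FALSE)
  err <- pr$fit - actuals
  list(coverage = mean(actuals >= pr$lo & actuals <= pr$hi),
       mean_error = mean(err),
       rmse = sqrt(mean(err^2)),
       n = length(actuals))
}

#' Per-group predicted-minus-actual differences
#'
#' Summarizes prediction errors by group (e.g. AGA validation strides vs
#' SGA strides): per-group mean difference with a 95% t interval, and the
#' fractions of strides over- and under-predicted. A model that finds
#' nothing unusual about SGA strides predicts them "AGA-like": mass and
#' size differences systematically positive.
#'
#' @param predictions Data frame from [predict.trait_model()] (or numeric
#'   vector of point predictions), with optional `stride_id` rownames.
#' @param actuals Numeric actual values, matched by position (or a data
#'   frame with `stride_id` and `actual`, matched by id).
#' @param groups Group label per stride.
#' @return Data frame: group, n, mean_diff, lo, hi, frac_over, frac_under.
#' @export
compare_predictions <- function(predictions, actuals, groups) {
  fit <- if (is.data.frame(predictions)) predictions$fit
         else as.numeric(predictions)
  if (is.data.frame(actuals)) {
    if (is.null(actuals$stride_id) || is.null(rownames(predictions))) {
      stop("id matching requires stride_id and prediction rownames",
           call. = FALSE)
    }
    idx <- match(rownames(predictions), actuals$stride_id)
    if (anyNA(idx)) stop("unmatched stride id(s)", call. = FALSE)
    actuals <- actuals$actual[idx]
  }
  if (length(actuals) != length(fit) || length(groups) != length(fit)) {
    stop("length mismatch", call. = FALSE)
  }
  diffs <- fit - actuals
  out <- lapply(split(diffs, groups), function(d) {
    n <- length(d)
    se <- if (n > 1) stats::sd(d) / sqrt(n) else 0
    tq <- if (n > 1) stats::qt(0.975, n - 1) else 0
    data.frame(n = n, mean_diff = mean(d),
               lo = mean(d) - tq * se, hi = mean(d) + tq * se,
               frac_over = mean(d > 0), frac_under = mean(d < 0))
  })
  res <- do.call(rbind, out)
  cbind(group = names(out), res, row.names = NULL)
}

#' Age-stall experiment: does stalled maturation read as a younger animal?
#'
#' Generates a cohort in which SGA postural maturation (and its coupled
#' gait signal) freezes at `stall_age` hours while AGA animals mature
#' normally, trains an age model on AGA strides only (with the
#' coordination PCA frozen on the training strides), predicts SGA stride
#' ages, and reports how often strides of SGA animals older than
#' `stall_age` are assigned a younger age than their true one.
#'
#' @param config Cohort configuration; defaults to a cross-sectional
#'   design of 50 AGA + 8 SGA piglets sampled at 1-10 hours postpartum.
#'   The SGA stall is set from `stall_age` regardless.
#' @param seed Root seed.
#' @param stall_age SGA stall age in hours (`NULL` disables the stall,
#'   the null scenario).
#' @param n_validation AGA strides held out from training.
#' @return List: `fraction_underestimated` (among SGA strides older than
#'   `stall_age`, or all SGA strides when the stall is disabled),
#'   `mean_underestimate_h` (actual minus predicted, hours),
#'   `n_evaluated`, `validation` (held-out AGA calibration summary),
#'   `model`, `predictions`.
#' @export
age_stall_experiment <- function(config = NULL, seed = 1L, stall_age = 4,
                                 n_validation = 35L) {
  if (is.null(config)) {
    # static SGA postural offsets are age-independent and would confound the
    # age signal; the default scenario isolates the maturation stall itself
    config <- cohort_config(
      n_aga = 50L, n_sga = 8L, ages = c(1, 2, 4, 6, 8, 10),
      strides_per_age = 1L, posture_offsets_sga = numeric()
    )
  }
  config$sga_stall_age <- stall_age
  cohort <- generate_cohort(config, seed = seed)
  aga_ids <- cohort$strides$stride_id[cohort$strides$category == "AGA"]
  sga_ids <- cohort$strides$stride_id[cohort$strides$category == "SGA"]

  set.seed(substream_seed(seed, "age_stall_split"))
  val_ids <- sample(aga_ids, min(n_validation, length(aga_ids) - 40L))
  train_ids <- setdiff(aga_ids, val_ids)

  ft_train <- feature_table(cohort, stride_ids = train_ids)
  ft_rest <- feature_table(cohort, pca = ft_train$pca)
  X <- ft_rest$features; meta <- ft_rest$meta
  model <- train_trait_model(X[train_ids, , drop = FALSE],
                             meta$age[match(train_ids, meta$stride_id)],
                             target = "age", seed = seed)
  val <- validate_trait_model(
    model, X[val_ids, , drop = FALSE],
    meta$age[match(val_ids, meta$stride_id)])
  pr <- predict(model, X[sga_ids, , drop = FALSE])
  actual <- meta$age[match(sga_ids, meta$stride_id)]
  keep <- if (is.null(stall_age)) rep(TRUE, length(actual))
          else actual > stall_age
  under <- actual[keep] - pr$fit[keep]
  list(
    fraction_underestimated = mean(under > 0),
    mean_underestimate_h = mean(under),
    n_evaluated = sum(keep),
    validation = val,
    model = model,
    predictions = data.frame(stride_id = sga_ids, actual_age = actual,
                             predicted_age = pr$fit, row.names = NULL)
  )
}
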