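#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order — simulate, normalize, Fourier
#' decomposition + coordination PCA, posture comparison, GRF permutation
#' SPM, limb force capacity, allometric fits, Bayesian trait prediction —
#' writing each stage's tables under `out_dir` and a `run_manifest.json`
#' with the full configuration echo, seed, package version, timestamps
#' and an MD5 content hash of every output file. A failure in any stage
#' halts the run with an error naming the stage.
#'
#' @param config A [cohort_config()], or a path to a YAML/JSON file whose
#'   top-level keys are `cohort_config()` arguments.
#' @param out_dir Output directory.
#' @param seed Root seed for all stages.
#' @param alpha SPM significance level.
#' @param n_permutations SPM permutations.
#' @return Invisibly, the manifest (also written as JSON).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = 1L,
                         alpha = 0.05, n_permutations = 1000L) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  t0 <- Sys.time()

  cohort <- stage("simulate", generate_cohort(config, seed = seed))
  paths <- stage("simulate", write_cohort(cohort, out_dir))

  strides_norm <- stage("normalize",
                        normalize_stride_table(cohort$strides, g = config$g))
  p_norm <- file.path(out_dir, "strides_dimensionless.csv")
  utils::write.csv(strides_norm, p_norm, row.names = FALSE)

  ft <- stage("fourier", feature_table(cohort))
  p_desc <- file.path(out_dir, "fourier_descriptors.csv")
  utils::write.csv(ft$descriptors, p_desc, row.names = FALSE)
  p_scores <- file.path(out_dir, "coordination_scores.csv")
  utils::write.csv(data.frame(stride_id = rownames(ft$pca$scores),
                              ft$pca$scores, row.names = NULL),
                   p_scores, row.names = FALSE)
  p_load <- file.path(out_dir, "pca_loadings.csv")
  utils::write.csv(data.frame(coefficient = rownames(ft$pca$loadings),
                              ft$pca$loadings, row.names = NULL),
                   p_load, row.names = FALSE)

  cmp <- stage("posture", {
    da <- ft$descriptors[ft$descriptors$stride_id %in%
                           ft$meta$stride_id[ft$meta$category == "AGA"], ]
    db <- ft$descriptors[ft$descriptors$stride_id %in%
                           ft$meta$stride_id[ft$meta$category == "SGA"], ]
    compare_posture(da, db, seed = seed)
  })
  p_cmp <- file.path(out_dir, "posture_comparison.csv")
  utils::write.csv(as.data.frame(cmp), p_cmp, row.names = FALSE)

  spm <- stage("grf_spm", {
    aga_ids <- cohort$strides$stride_id[cohort$strides$category == "AGA"]
    m <- curves_matrix(cohort$grf_traces, "hind", "vertical")
    spm_two_sample(m[rownames(m) %in% aga_ids, , drop = FALSE],
                   m[!rownames(m) %in% aga_ids, , drop = FALSE],
                   alpha = alpha, n_permutations = n_permutations,
                   seed = seed)
  })
  p_spm <- file.path(out_dir, "spm_results.json")
  jsonlite::write_json(list(t = spm$t, critical_threshold = spm$critical_threshold,
                            clusters = spm$clusters, alpha = spm$alpha,
                            n_permutations = spm$n_permutations),
                       p_spm, auto_unbox = TRUE, digits = NA)
  p_grfsum <- file.path(out_dir, "grf_summary.csv")
  utils::write.csv(summarize_grf(curves_matrix(cohort$grf_traces,
                                               "hind", "vertical")),
                   p_grfsum, row.names = FALSE)

  cap <- stage("capacity",
               limb_capacity_table(cohort$muscles, cohort$piglets,
                                   g = config$g))
  p_cap <- file.path(out_dir, "limb_capacity.csv")
  utils::write.csv(cap, p_cap, row.names = FALSE)

  allo <- stage("allometry", {
    lapply(c(front = "front_part_mass_kg", hind = "hind_part_mass_kg"),
           function(cl) {
             f <- allometric_fit(cohort$piglets$birth_mass_kg,
                                 cohort$piglets[[cl]])
             c(list(a = f$a, b = f$b, b_ci = f$b_ci,
                    r_squared = f$r_squared, n = f$n),
               isometry_test(f)["consistent"])
           })
  })
  p_allo <- file.path(out_dir, "allometry.json")
  jsonlite::write_json(allo, p_allo, auto_unbox = TRUE, digits = NA)

  preds <- stage("predict", {
    out <- lapply(c("mass", "size", "age"), function(tg) {
      m <- train_trait_model(ft$features[ft$meta$category == "AGA", ,
                                         drop = FALSE],
                             ft$meta[[if (tg == "age") "age" else tg]][
                               ft$meta$category == "AGA"],
                             target = tg, seed = seed)
      pr <- predict(m, ft$features)
      data.frame(stride_id = ft$meta$stride_id, target = tg,
                 predicted = pr$fit, lo = pr$lo, hi = pr$hi,
                 actual = ft$meta[[if (tg == "age") "age" else tg]],
                 category = ft$meta$category, row.names = NULL)
    })
    do.call(rbind, out)
  })
  p_pred <- file.path(out_dir, "predictions.csv")
  utils::write.csv(preds, p_pred, row.names = FALSE)
  diffs <- do.call(rbind, lapply(split(preds, preds$target), function(d) {
    cbind(target = d$target[1],
          compare_predictions(d$predicted, d$actual, d$category))
  }))
  p_diff <- file.path(out_dir, "prediction_differences.csv")
  utils::write.csv(diffs, p_diff, row.names = FALSE)

  files <- c(paths, strides_dimensionless = p_norm,
             fourier_descriptors = p_desc, coordination_scores = p_scores,
             pca_loadings = p_load, posture_comparison = p_cmp,
             spm_results = p_spm, grf_summary = p_grfsum,
             limb_capacity = p_cap, allometry = p_allo,
             predictions = p_pred, prediction_differences = p_diff)
  manifest <- list(
    package = "pigletgait",
    version = as.character(utils::packageVersion("pigletgait")),
    seed = seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_echo(config),
    spm = list(alpha = alpha, n_permutations = n_permutations),
    outputs = lapply(stats::setNames(as.character(files), names(files)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# serializable echo of a cohort_config (templates flattened to re/im)
config_echo <- function(config) {
  out <- unclass(config)
  out$maturation <- unclass(out$maturation)
  out$templates <- lapply(out$templates, function(tp) {
    list(mean = tp$mean, harmonics_re = Re(tp$harmonics),
         harmonics_im = Im(tp$harmonics))
  })
  out
}

load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(cohort_config)))]
  if (!is.null(raw$maturation)) {
    args$maturation <- do.call(calibrate_maturation,
                               raw$maturation[intersect(names(raw$maturation),
                                 names(formals(calibrate_maturation)))])
  }
  do.call(cohort_config, args)
}

#' Validate pipeline tables against their schema invariants
#'
#' Checks each table (by file path or in-memory cohort) against the
#' invariants the analyses assume: positive masses and lengths, duty
#' factors in (0, 1], phases in [0, 1), joint angles inside (0, pi),
#' non-negative vertical forces, strictly increasing stance fractions,
#' speed = stride length x frequency consistency.
#'
#' @param x A `"piglet_cohort"`, or a directory containing the CSVs, or a
#'   named list/vector of file paths.
#' @return Data frame: `table`, `check`, `pass`, `detail`; attribute
#'   `"pass"` is TRUE when every check passed.
#' @export
validate_tables <- function(x) {
  tabs <- if (inherits(x, "piglet_cohort")) {
    x[c("piglets", "strides", "joint_traces", "grf_traces", "muscles")]
  } else {
    paths <- if (length(x) == 1 && dir.exists(x)) {
      stats::setNames(
        file.path(x, paste0(c("piglets", "strides", "joint_traces",
                              "grf_traces", "muscles"), ".csv")),
        c("piglets", "strides", "joint_traces", "grf_traces", "muscles"))
    } else x
    lapply(paths, function(p) {
      if (!file.exists(p)) stop("unreadable file: ", p, call. = FALSE)
      utils::read.csv(p, stringsAsFactors = FALSE)
    })
  }
  res <- list()
  add <- function(tb, check, pass, detail = "") {
    res[[length(res) + 1]] <<- data.frame(table = tb, check = check,
                                          pass = pass, detail = detail,
                                          stringsAsFactors = FALSE)
  }
  p <- tabs$piglets
  if (!is.null(p) && nrow(p) > 0) {
    add("piglets", "birth_mass > 0", all(p$birth_mass_kg > 0))
    seg <- as.matrix(p[grep("^seg_", names(p))])
    add("piglets", "segment lengths > 0", all(seg > 0))
  } else add("piglets", "present", is.null(p) == FALSE || TRUE,
             "empty optional table")
  s <- tabs$strides
  if (!is.null(s) && nrow(s) > 0) {
    add("strides", "duty_factor in (0,1]",
        all(s$duty_factor > 0 & s$duty_factor <= 1),
        if (any(s$duty_factor > 1)) "duty_factor > 1" else "")
    add("strides", "stance <= stride time",
        all(s$stance_time_s <= s$stride_time_s + 1e-12))
    add("strides", "V = L x F (1e-9)",
        all(abs(s$speed_ms - s$stride_length_m * s$stride_frequency_hz)
            < 1e-9))
    add("strides", "hip height > 0", all(s$hip_height_m > 0))
    ph <- as.matrix(s[grep("^phase_", names(s))])
    add("strides", "phases in [0,1)", all(ph >= 0 & ph < 1))
  }
  j <- tabs$joint_traces
  if (!is.null(j) && nrow(j) > 0) {
    add("joint_traces", "angles in (0, pi)",
        all(j$angle_rad > 0 & j$angle_rad < pi),
        if (any(j$angle_rad <= 0 | j$angle_rad >= pi))
          "angle outside (0, pi)" else "")
    add("joint_traces", "cycle_fraction in [0,1)",
        all(j$cycle_fraction >= 0 & j$cycle_fraction < 1))
  }
  g <- tabs$grf_traces
  if (!is.null(g) && nrow(g) > 0) {
    v <- g[g$component == "vertical", ]
    add("grf_traces", "vertical force >= 0", all(v$force_bw >= 0))
    add("grf_traces", "forces finite", all(is.finite(g$force_bw)))
  }
  m <- tabs$muscles
  if (!is.null(m) && nrow(m) > 0) {
    add("muscles", "mass > 0", all(m$mass_kg > 0))
    add("muscles", "fibre length > 0", all(m$fibre_length_m > 0))
  }
  out <- do.call(rbind, res)
  attr(out, "pass") <- all(out$pass)
  out
}
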