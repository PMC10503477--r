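#' Resample a stance-phase force trace onto a fixed grid
#'
#' Force-plate recordings come at the acquisition rate (e.g. 1 kHz, so a
#' few hundred samples per stance); for curve-level statistics all stances
#' are linearly interpolated onto a common grid of `n_intervals` intervals
#' (`n_intervals + 1` nodes) over stance fractions `[0, 1]`. Resampling an
#' already-conforming curve is idempotent.
#'
#' @param force_samples Numeric force values over one stance (>= 2).
#' @param n_intervals Number of intervals of the target grid (default 50).
#' @param sample_times Optional sample times (any unit, strictly
#'   increasing); defaults to uniform spacing over the stance.
#' @return Data frame (`stance_fraction`, `force`) with
#'   `n_intervals + 1` rows.
#' @export
resample_stance <- function(force_samples, n_intervals = 50L,
                            sample_times = NULL) {
  y <- as.numeric(force_samples)
  if (length(y) < 2) stop("need at least 2 stance samples", call. = FALSE)
  x <- if (is.null(sample_times)) {
    seq(0, 1, length.out = length(y))
  } else {
    st <- as.numeric(sample_times)
    if (length(st) != length(y) || any(diff(st) <= 0)) {
      stop("sample_times must be strictly increasing and match forces",
           call. = FALSE)
    }
    (st - st[1]) / (st[length(st)] - st[1])
  }
  u <- seq(0, 1, length.out = n_intervals + 1L)
  data.frame(stance_fraction = u, force = stats::approx(x, y, xout = u)$y)
}

#' Split a stance curve into first and last halves
#'
#' Partitions a fixed-grid stance curve at midstance; the midpoint node is
#' assigned to both halves so each half remains a closed interval
#' (`[0, 0.5]` and `[0.5, 1]`) and their concatenation (dropping the
#' duplicated node) reproduces the original curve.
#'
#' @param curve Data frame (`stance_fraction`, `force`).
#' @return List with elements `first` and `last`.
#' @export
split_stance_halves <- function(curve) {
  stopifnot(is.data.frame(curve))
  u <- curve$stance_fraction
  mid <- which.min(abs(u - 0.5))
  list(first = curve[seq_len(mid), , drop = FALSE],
       last = curve[mid:nrow(curve), , drop = FALSE])
}

#' Permutation-based statistical parametric mapping of 1D force curves
#'
#' Compares two ensembles of stance-normalized force curves over the whole
#' stance domain while respecting the dependence between neighbouring
#' nodes. A pooled-variance two-sample t statistic is computed at every
#' node; the critical threshold is the `(1 - alpha)` quantile of the
#' permutation distribution of the maximum absolute t over the curve
#' (group-label permutation). Suprathreshold clusters of `|t|` are
#' reported with permutation cluster p-values based on the maximum
#' suprathreshold cluster extent under relabeling. When the number of
#' distinct relabelings is at most `n_permutations`, all of them are
#' enumerated and the test is exact.
#'
#' @param curves_a,curves_b Numeric matrices (curves in rows) on a common
#'   grid; at least 3 curves per group.
#' @param alpha Cluster-defining significance level.
#' @param n_permutations Permutations drawn (warns if fewer than
#'   `1/alpha`).
#' @param seed Seed for the permutation draws.
#' @param stance_fraction Optional grid (defaults to uniform `[0, 1]`).
#' @return Object of class `"spm_perm"`: `t` (node t statistics),
#'   `critical_threshold`, `clusters` (data frame: start, end, extent,
#'   p_value), `alpha`, `n_permutations`, `stance_fraction`, `exact`.
#' @export
spm_two_sample <- function(curves_a, curves_b, alpha = 0.05,
                           n_permutations = 1000L, seed = 1L,
                           stance_fraction = NULL) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  if (ncol(curves_a) != ncol(curves_b)) {
    stop("curve ensembles must share a common grid", call. = FALSE)
  }
  na <- nrow(curves_a); nb <- nrow(curves_b)
  if (na < 3 || nb < 3) stop("need >= 3 curves per group", call. = FALSE)
  if (n_permutations < 1 / alpha) {
    warning("fewer permutations than 1/alpha; threshold is coarse",
            call. = FALSE)
  }
  K <- ncol(curves_a)
  u <- stance_fraction %||% seq(0, 1, length.out = K)
  X <- rbind(curves_a, curves_b)
  n <- na + nb

  tfield <- function(ia) {
    xa <- X[ia, , drop = FALSE]; xb <- X[-ia, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    ss <- colSums((xa - rep(ma, each = na))^2) +
      colSums((xb - rep(mb, each = nb))^2)
    s2 <- ss / (n - 2L)
    tt <- (ma - mb) / sqrt(pmax(s2, .Machine$double.xmin) * (1 / na + 1 / nb))
    tt[ss == 0 & abs(ma - mb) < .Machine$double.eps] <- 0
    tt
  }
  t_obs <- tfield(seq_len(na))

  # permutation scheme: exact enumeration when feasible
  n_comb <- choose(n, na)
  exact <- is.finite(n_comb) && n_comb <= n_permutations
  set.seed(substream_seed(seed, "spm"))
  perms <- if (exact) {
    utils::combn(n, na, simplify = FALSE)
  } else {
    replicate(n_permutations, sample.int(n, na), simplify = FALSE)
  }

  tmat <- vapply(perms, function(ia) abs(tfield(ia)), numeric(K))
  max_t <- apply(tmat, 2, max)
  thresh <- stats::quantile(max_t, 1 - alpha, names = FALSE, type = 1)

  cluster_extents <- function(abs_tt) {
    r <- rle(abs_tt > thresh)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
  }
  obs_cl <- cluster_extents(abs(t_obs))
  max_ext <- apply(tmat, 2, function(abs_tt) {
    cl <- cluster_extents(abs_tt)
    if (nrow(cl) == 0) 0L else max(cl[, "end"] - cl[, "start"] + 1L)
  })

  clusters <- if (nrow(obs_cl) == 0) {
    data.frame(start = numeric(0), end = numeric(0), extent = integer(0),
               p_value = numeric(0))
  } else {
    ext <- obs_cl[, "end"] - obs_cl[, "start"] + 1L
    data.frame(
      start = u[obs_cl[, "start"]], end = u[obs_cl[, "end"]],
      extent = as.integer(ext),
      p_value = vapply(ext, function(e)
        (1 + sum(max_ext >= e)) / (length(perms) + 1), numeric(1))
    )
  }
  structure(
    list(t = t_obs, critical_threshold = thresh, clusters = clusters,
         alpha = alpha, n_permutations = length(perms),
         stance_fraction = u, exact = exact),
    class = "spm_perm"
  )
}

#' @export
print.spm_perm <- function(x, ...) {
  cat(sprintf("Permutation SPM: %d %spermutations, alpha = %g\n",
              x$n_permutations, if (x$exact) "(exhaustive) " else "",
              x$alpha))
  cat(sprintf("  max |t| = %.2f, critical threshold = %.2f\n",
              max(abs(x$t)), x$critical_threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    cat("  clusters (stance fraction):\n")
    print(x$clusters, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.spm_perm <- function(x, ...) {
  graphics::plot(x$stance_fraction, x$t, type = "l",
                 xlab = "stance fraction", ylab = "t statistic", ...)
  graphics::abline(h = c(-1, 1) * x$critical_threshold, lty = 2)
  if (nrow(x$clusters) > 0) {
    for (i in seq_len(nrow(x$clusters))) {
      graphics::rect(x$clusters$start[i], graphics::par("usr")[3],
                     x$clusters$end[i], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("orange", 0.3), border = NA)
    }
  }
  invisible(x)
}

#' Mean curve and envelope of a GRF ensemble
#'
#' @param curves Numeric matrix (curves in rows) on a common grid.
#' @param stance_fraction Optional grid (defaults to uniform `[0, 1]`).
#' @return Data frame: `stance_fraction`, `mean`, `min`, `max`.
#' @export
summarize_grf <- function(curves, stance_fraction = NULL) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 1) stop("need at least one curve", call. = FALSE)
  u <- stance_fraction %||% seq(0, 1, length.out = ncol(curves))
  data.frame(stance_fraction = u,
             mean = colMeans(curves),
             min = apply(curves, 2, min),
             max = apply(curves, 2, max))
}

#' Extract a curve matrix from a long GRF table
#'
#' @param grf_traces Long data frame (`stride_id`, `limb`, `component`,
#'   `stance_fraction`, `force_bw`).
#' @param limb,component Which traces to extract.
#' @return Matrix with one row per stride (rownames = stride ids), columns
#'   ordered by stance fraction.
#' @export
curves_matrix <- function(grf_traces, limb = "hind", component = "vertical") {
  d <- grf_traces[grf_traces$limb == limb & grf_traces$component == component, ]
  if (nrow(d) == 0) stop("no matching GRF traces", call. = FALSE)
  d <- d[order(d$stride_id, d$stance_fraction), ]
  ids <- unique(d$stride_id)
  K <- nrow(d) / length(ids)
  if (K != round(K)) stop("ragged GRF grids across strides", call. = FALSE)
  matrix(d$force_bw, nrow = length(ids), ncol = K, byrow = TRUE,
         dimnames = list(ids, NULL))
}
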