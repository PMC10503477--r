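#' Resample a cyclic joint-angle trace onto a uniform grid
#'
#' Periodic linear interpolation of an angle-versus-cycle-fraction trace
#' onto `n_samples` uniformly spaced fractions `0, 1/n, ..., (n-1)/n`.
#' The wrap across the cycle end uses periodicity (the first sample is
#' reused at fraction 1).
#'
#' @param trace Data frame with strictly increasing `cycle_fraction` in
#'   `[0, 1)` and `angle_rad` columns, at least 3 samples.
#' @param n_samples Target number of uniform samples.
#' @return A data frame with columns `cycle_fraction`, `angle_rad`.
#' @export
resample_cycle <- function(trace, n_samples) {
  stopifnot(is.data.frame(trace), n_samples >= 3)
  x <- trace$cycle_fraction
  y <- trace$angle_rad
  if (length(x) < 3) stop("trace needs at least 3 samples", call. = FALSE)
  if (any(diff(x) <= 0)) {
    stop("cycle_fraction must be strictly increasing", call. = FALSE)
  }
  if (min(x) < 0 || max(x) >= 1) {
    stop("cycle_fraction must lie in [0, 1)", call. = FALSE)
  }
  tt <- seq(0, 1, length.out = n_samples + 1L)[seq_len(n_samples)]
  # periodic extension: one period before and after covers all query points
  xx <- c(x - 1, x, x + 1)
  yy <- c(y, y, y)
  data.frame(cycle_fraction = tt,
             angle_rad = stats::approx(xx, yy, xout = tt)$y)
}

#' Fourier series decomposition of a cyclic trace
#'
#' Transforms a uniformly sampled periodic joint-angle cycle to the
#' frequency domain (exponential form):
#' \deqn{c_n = \frac{1}{N}\sum_{k=0}^{N-1} \theta(t_k)\, e^{-i 2\pi n k/N}}
#' returning the mean \eqn{c_0} and the first `n_harmonics` one-sided
#' complex coefficients. Eight harmonics (the default) suffice to describe
#' walking joint-angle profiles; the sampling grid must satisfy the
#' Nyquist condition `N >= 2*n_harmonics + 1` or an aliasing error is
#' raised.
#'
#' @param trace Data frame (`cycle_fraction`, `angle_rad`) on a uniform
#'   grid starting at 0, or a plain numeric vector of angles.
#' @param n_harmonics Number of harmonics retained (default 8).
#' @return Complex vector `c0, c1, ..., c{n_harmonics}` (names `h0..`);
#'   `c0` has zero imaginary part.
#' @seealso [fourier_reconstruct()], [affine_split()]
#' @export
fourier_decompose <- function(trace, n_harmonics = 8L) {
  y <- if (is.data.frame(trace)) {
    dx <- diff(trace$cycle_fraction)
    if (any(abs(dx - dx[1]) > 1e-8)) {
      stop("trace must be on a uniform grid; use resample_cycle()",
           call. = FALSE)
    }
    trace$angle_rad
  } else {
    as.numeric(trace)
  }
  n <- length(y)
  if (n < 2 * n_harmonics + 1) {
    stop(sprintf("aliasing: %d samples cannot support %d harmonics", n,
                 n_harmonics), call. = FALSE)
  }
  cf <- stats::fft(y) / n
  out <- cf[seq_len(n_harmonics + 1L)]
  out[1] <- complex(real = Re(out[1]), imaginary = 0)
  names(out) <- paste0("h", 0:n_harmonics)
  out
}

#' Reconstruct a cyclic trace from Fourier coefficients
#'
#' Inverse of [fourier_decompose()]:
#' \deqn{\theta(t) = c_0 + 2\sum_{n\ge 1} \mathrm{Re}\left(c_n e^{i 2\pi n t}\right).}
#' The round trip decompose-reconstruct is exact (to floating point) for
#' band-limited traces.
#'
#' @param coeffs Complex coefficients `c0..cH` from [fourier_decompose()].
#' @param n_samples Number of uniform output samples.
#' @return Data frame (`cycle_fraction`, `angle_rad`).
#' @export
fourier_reconstruct <- function(coeffs, n_samples) {
  stopifnot(length(coeffs) >= 1, n_samples >= 1)
  tt <- seq(0, 1, length.out = n_samples + 1L)[seq_len(n_samples)]
  nh <- length(coeffs) - 1L
  ang <- rep(Re(coeffs[1]), n_samples)
  if (nh > 0) {
    ang <- ang +
      2 * Re(exp(2i * pi * outer(tt, seq_len(nh))) %*% coeffs[-1])
  }
  data.frame(cycle_fraction = tt, angle_rad = as.numeric(ang))
}

#' Split Fourier coefficients into posture and shape descriptors
#'
#' Separates a joint cycle's coefficients into general postural
#' information — the mean angle \eqn{c_0} and the RMS oscillation
#' amplitude \eqn{A = \sqrt{2\sum_{n\ge1} |c_n|^2}} — and unit-amplitude
#' "shape" information \eqn{s_n = c_n / A}. For a real signal the shape
#' spectrum is two-sided with \eqn{s_{-n} = \bar{s}_n}, so the stored
#' one-sided vector satisfies \eqn{2\sum_n |s_n|^2 = 1} (a pure cosine has
#' \eqn{|s_1| = 1/\sqrt{2}}). A constant trace has `amplitude = 0` and an
#' all-zero shape vector.
#'
#' The shape vector is invariant under any affine transform of the trace
#' \eqn{\theta \to s(\theta - \bar\theta) + m} with `s > 0`; a cyclic time
#' shift by \eqn{\Delta} rotates each harmonic by \eqn{e^{-i2\pi n\Delta}}.
#'
#' @param coeffs Complex `c0..cH` from [fourier_decompose()].
#' @param joint Optional joint label carried into the result.
#' @return List of class `"fourier_descriptor"`: `joint`, `mean_angle`,
#'   `amplitude`, `shape` (complex length-H).
#' @export
affine_split <- function(coeffs, joint = NA_character_) {
  stopifnot(length(coeffs) >= 2)
  cn <- coeffs[-1]
  A <- sqrt(2 * sum(Mod(cn)^2))
  # numerically constant traces (A at floating-point noise level) get a
  # zero shape vector rather than noise/noise ratios
  degenerate <- A <= 1e-12 * max(1, abs(Re(coeffs[1])))
  shape <- if (degenerate) cn * 0 else cn / A
  if (degenerate) A <- 0
  structure(list(joint = joint, mean_angle = unname(Re(coeffs[1])),
                 amplitude = A, shape = shape),
            class = "fourier_descriptor")
}

#' Range of motion of a joint-angle trace
#'
#' @param trace Data frame with `angle_rad` (or numeric vector of angles).
#' @return Max minus min angle (radians, >= 0).
#' @export
range_of_motion <- function(trace) {
  y <- if (is.data.frame(trace)) trace$angle_rad else as.numeric(trace)
  if (length(y) == 0) stop("empty trace", call. = FALSE)
  max(y) - min(y)
}

#' Fourier descriptor table for a cohort of joint traces
#'
#' Resamples each stride-by-joint cycle onto a uniform grid, decomposes it
#' into `n_harmonics` harmonics and splits posture from shape. One row per
#' stride and joint.
#'
#' @param joint_traces Long data frame (`stride_id`, `joint`,
#'   `cycle_fraction`, `angle_rad`).
#' @param n_harmonics Harmonics retained (default 8).
#' @param n_samples Uniform resampling grid size.
#' @return Data frame: `stride_id`, `joint`, `mean_angle`, `amplitude`,
#'   `rom`, then `shape_re_1..H` and `shape_im_1..H` (unit two-sided
#'   norm shape coefficients).
#' @export
fourier_descriptors <- function(joint_traces, n_harmonics = 8L,
                                n_samples = 100L) {
  stopifnot(is.data.frame(joint_traces))
  key <- interaction(joint_traces$stride_id, joint_traces$joint, drop = TRUE)
  pieces <- split(joint_traces, key)
  rows <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$cycle_fraction), ]
    rs <- resample_cycle(tr, n_samples)
    cf <- fourier_decompose(rs, n_harmonics)
    d <- affine_split(cf, joint = tr$joint[1])
    fine <- fourier_reconstruct(cf, 256L)
    out <- data.frame(stride_id = tr$stride_id[1], joint = tr$joint[1],
                      mean_angle = d$mean_angle, amplitude = d$amplitude,
                      rom = range_of_motion(fine),
                      stringsAsFactors = FALSE)
    sr <- as.list(stats::setNames(Re(d$shape),
                                  paste0("shape_re_", seq_len(n_harmonics))))
    si <- as.list(stats::setNames(Im(d$shape),
                                  paste0("shape_im_", seq_len(n_harmonics))))
    cbind(out, as.data.frame(sr), as.data.frame(si))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$stride_id, out$joint), ]
}

#' Pooled shape matrix (strides x 96)
#'
#' Arranges the per-joint shape coefficients of a descriptor table into
#' the coordination input matrix: one row per stride, columns ordered by
#' joint then `re_1..H, im_1..H` (6 joints x 16 = 96 columns for the
#' default 8 harmonics).
#'
#' @param descriptors Output of [fourier_descriptors()].
#' @return Numeric matrix with rownames = stride ids.
#' @export
shape_matrix <- function(descriptors) {
  stopifnot(is.data.frame(descriptors))
  joints <- sort(unique(descriptors$joint))
  strides <- unique(descriptors$stride_id)
  shape_cols <- grep("^shape_(re|im)_", names(descriptors), value = TRUE)
  nh <- length(shape_cols) / 2L
  col_order <- c(paste0("shape_re_", seq_len(nh)),
                 paste0("shape_im_", seq_len(nh)))
  mat <- matrix(NA_real_, length(strides), length(joints) * length(col_order),
                dimnames = list(strides, paste(
                  rep(joints, each = length(col_order)),
                  rep(col_order, length(joints)), sep = ".")))
  for (j in joints) {
    dj <- descriptors[descriptors$joint == j, ]
    idx <- match(dj$stride_id, strides)
    mat[idx, paste(j, col_order, sep = ".")] <-
      as.matrix(dj[, col_order, drop = FALSE])
  }
  if (anyNA(mat)) stop("missing joint(s) for some stride(s)", call. = FALSE)
  mat
}
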