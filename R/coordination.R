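#' Coordination PCA on pooled shape coefficients
#'
#' Reduces the pooled Fourier shape coefficients (6 joints x 16 real
#' values = 96 columns) to a small number of principal components, the
#' "coordination variables" describing intra- and interlimb coordination
#' free of posture and amplitude. The matrix is column-centered but not
#' standardized: shape coefficients are already commensurate and
#' unit-free. A deterministic sign convention is applied (the largest-
#' magnitude loading element of each component is positive).
#'
#' @param shape_mat Numeric strides-by-coefficients matrix, see
#'   [shape_matrix()]. Requires more rows than `n_pcs`.
#' @param n_pcs Components retained (default 12).
#' @return Object of class `"coordination_pca"`: `scores` (n x n_pcs),
#'   `loadings` (96 x n_pcs, orthonormal columns), `explained_variance`
#'   (fractions, non-increasing), `center`, `n_pcs`.
#' @export
coordination_pca <- function(shape_mat, n_pcs = 12L) {
  stopifnot(is.matrix(shape_mat))
  if (nrow(shape_mat) <= n_pcs) {
    stop("need more strides than retained components", call. = FALSE)
  }
  pc <- stats::prcomp(shape_mat, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # fix signs: largest-|loading| entry of each PC made positive
  for (i in seq_len(k)) {
    top <- which.max(abs(load[, i]))
    if (load[top, i] < 0) load[, i] <- -load[, i]
  }
  scores <- sweep(shape_mat, 2, pc$center) %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(k))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = scores, loadings = load,
         explained_variance = ev[seq_len(k)],
         explained_variance_all = ev,
         center = pc$center, n_pcs = k),
    class = "coordination_pca"
  )
}

#' Project new shape coefficients onto fitted coordination components
#'
#' @param object A [coordination_pca()] fit (loadings frozen from the
#'   training strides).
#' @param newdata Strides-by-coefficients matrix with the same columns.
#' @param ... Unused.
#' @return Score matrix (n x n_pcs).
#' @export
predict.coordination_pca <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$center))
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' @export
print.coordination_pca <- function(x, ...) {
  cat(sprintf("Coordination PCA: %d PCs over %d shape coefficients\n",
              x$n_pcs, nrow(x$loadings)))
  cat(sprintf("  cumulative variance explained: %.1f%%\n",
              100 * sum(x$explained_variance)))
  invisible(x)
}
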