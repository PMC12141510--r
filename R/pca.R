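#' Principal component analysis of a spectrum set
#'
#' Mean-centred singular value decomposition (no variance scaling, the
#' convention for spectra). Scores are the sample coordinates
#' `centred data %*% t(loadings)`; explained variance fractions are
#' singular values squared over their total. Component signs are fixed
#' deterministically: each loading's largest-magnitude element is made
#' positive, except that when the axis contains the three carotenoid
#' bands PC-1 is oriented so the summed loading at 1006, 1156 and
#' 1533 cm^-1 is positive — carotene-rich samples then score on the
#' positive side of PC-1.
#'
#' @param set A `spectrum_set` (typically preprocessed via the PCA path)
#'   or a samples-by-variables numeric matrix.
#' @param n_components Components to retain.
#' @param axis Axis values for band orientation (taken from the set when
#'   one is given).
#' @return A list of class `pca_model`: `mean_spectrum`, `loadings`
#'   (component x variable), `scores` (sample x component),
#'   `explained_variance_fraction`, `axis`, `metadata`.
#' @export
fit_pca <- function(set, n_components = 2, axis = NULL) {
  if (inherits(set, "spectrum_set")) {
    X <- t(set$intensities)
    axis <- set$axis
    metadata <- set$metadata
  } else {
    X <- as.matrix(set)
    metadata <- NULL
  }
  n <- nrow(X)
  if (n < 2) stop("at least two spectra are required")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  r <- sum(pos)
  if (n_components > r) {
    stop(sprintf("n_components (%d) exceeds the data rank (%d)",
                 n_components, r))
  }
  idx <- seq_len(n_components)
  loadings <- t(sv$v[, idx, drop = FALSE])
  scores <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_components)
  # deterministic sign convention
  for (k in idx) {
    flip <- FALSE
    if (k == 1 && !is.null(axis)) {
      car <- which(axis %in% c(1006, 1156, 1533))
      if (length(car)) flip <- sum(loadings[1, car]) < 0
    }
    if (k > 1 || is.null(axis) ||
        !length(which(axis %in% c(1006, 1156, 1533)))) {
      flip <- loadings[k, which.max(abs(loadings[k, ]))] < 0
    }
    if (flip) {
      loadings[k, ] <- -loadings[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(X)
  structure(list(
    mean_spectrum = mu,
    loadings = loadings,
    scores = scores,
    explained_variance_fraction = (sv$d[idx]^2) / sum(sv$d^2),
    axis = axis,
    metadata = metadata
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, %d samples\n",
              nrow(x$loadings), nrow(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.2f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project new spectra onto a fitted PCA model
#' @param object A `pca_model`.
#' @param newdata Samples-by-variables matrix or `spectrum_set`.
#' @param ... Unused.
#' @return Scores matrix for the new samples.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectrum_set")) t(newdata$intensities)
       else as.matrix(newdata)
  sweep(X, 2, object$mean_spectrum) %*% t(object$loadings)
}

#' Local maxima of the PC-1 loading
#'
#' Identifies band positions driving PC-1 by locating interior local
#' maxima of the loading trace above a relative prominence floor; used
#' to check that the carotenoid bands (1006, 1156, 1533 cm^-1) carry the
#' between-origin variance.
#'
#' @param pca A `pca_model` fitted with an axis.
#' @param component Component to inspect (default 1).
#' @param min_height Minimum loading value relative to the trace maximum.
#' @return Data frame of `axis` position and `loading` at each maximum.
#' @export
loading_peaks <- function(pca, component = 1, min_height = 0.1) {
  stopifnot(inherits(pca, "pca_model"), !is.null(pca$axis))
  l <- pca$loadings[component, ]
  n <- length(l)
  i <- 2:(n - 1)
  is_max <- l[i] > l[i - 1] & l[i] >= l[i + 1] &
    l[i] > min_height * max(l)
  data.frame(axis = pca$axis[i][is_max], loading = l[i][is_max])
}
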