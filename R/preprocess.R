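#' Asymmetric least squares baseline estimate
#'
#' Whittaker-type smoother with asymmetric weights: the baseline z
#' minimises sum_i w_i (y_i - z_i)^2 + lam * sum_i (delta^2 z_i)^2, with
#' weights re-set each iteration to `p` where y > z and `1 - p` where
#' y <= z. With p << 0.5 points above the running baseline (the Raman
#' bands) are almost ignored, so z tracks the smooth fluorescence
#' background under them. Solved by sparse Cholesky factorisation of the
#' banded system.
#'
#' @param y Numeric intensity vector or a `spectrum`.
#' @param lam Smoothness penalty (larger = stiffer baseline).
#' @param p Asymmetry weight in (0, 1); small values press the baseline
#'   under positive peaks.
#' @param n_iter Weight-update iterations.
#' @return Baseline estimate, same type as the input.
#' @export
als_baseline <- function(y, lam = 1e6, p = 0.001, n_iter = 10) {
  if (inherits(y, "spectrum")) {
    return(spectrum(y$axis, als_baseline(y$intensity, lam, p, n_iter),
                    meta = y$meta))
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("at least 3 points are required")
  if (!all(is.finite(y))) stop("intensity contains non-finite values")
  if (lam <= 0) stop("lam must be positive")
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  if (n_iter < 1) stop("n_iter must be at least 1")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- Matrix::crossprod(D)
  # Second differences annihilate affine trends and the asymmetric
  # weights compare y and z, so a shared affine shift commutes with the
  # whole iteration. Detrending first keeps the large-lam system well
  # scaled (a constant or straight-line input is reproduced exactly).
  x <- seq_len(n)
  aff <- stats::lm.fit(cbind(1, x), y)$fitted.values
  yd <- y - aff
  w <- rep(1, n)
  z <- yd
  for (it in seq_len(n_iter)) {
    A <- Matrix::Diagonal(n, w) + lam * DtD
    rhs <- w * yd
    z <- as.numeric(Matrix::solve(A, rhs))
    # one step of iterative refinement for the ill-conditioned solve
    resid <- rhs - as.numeric(A %*% z)
    z <- z + as.numeric(Matrix::solve(A, resid))
    w <- ifelse(yd > z, p, 1 - p)
  }
  z + aff
}

#' Subtract a baseline from a spectrum
#'
#' @param y Spectrum or intensity vector.
#' @param baseline Baseline of the same length (and same axis, when both
#'   are `spectrum` objects).
#' @return Pointwise difference, same type as `y`.
#' @export
subtract_baseline <- function(y, baseline) {
  if (inherits(y, "spectrum")) {
    b <- if (inherits(baseline, "spectrum")) {
      if (!isTRUE(all.equal(y$axis, baseline$axis))) {
        stop("spectrum and baseline axes differ")
      }
      baseline$intensity
    } else baseline
    if (length(b) != length(y$intensity)) stop("length mismatch")
    return(spectrum(y$axis, y$intensity - b, meta = y$meta))
  }
  b <- if (inherits(baseline, "spectrum")) baseline$intensity else baseline
  if (length(b) != length(y)) stop("length mismatch")
  y - b
}

# SG edge handling: at each end the window is truncated to the available
# one-sided points (no padding beyond the acquisition range) and the
# polynomial degree is capped at the truncated window size minus one.
sg_fit_at <- function(y, idx, center, polyorder) {
  offs <- idx - center
  deg <- min(polyorder, length(idx) - 1)
  A <- outer(offs, 0:deg, `^`)
  stats::lm.fit(A, y[idx])$coefficients[1]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of a least-squares polynomial
#' fitted over a sliding window; polynomials up to `polyorder` pass
#' through unchanged. Interior points use a precomputed convolution
#' kernel; edge points are fitted on the truncated window so the output
#' has the input's length.
#'
#' @param y Intensity vector or `spectrum`.
#' @param window Odd window width in points (default 11).
#' @param polyorder Polynomial degree (default 2).
#' @return Smoothed values, same type as the input.
#' @export
savitzky_golay <- function(y, window = 11, polyorder = 2) {
  if (inherits(y, "spectrum")) {
    return(spectrum(y$axis, savitzky_golay(y$intensity, window, polyorder),
                    meta = y$meta))
  }
  y <- as.numeric(y)
  n <- length(y)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (polyorder < 0) stop("polyorder must be non-negative")
  if (n < window) stop("input shorter than the window")
  h <- (window - 1) / 2
  offs <- -h:h
  A <- outer(offs, 0:polyorder, `^`)
  # kernel = first row of (A'A)^-1 A': evaluates the fit at the centre
  kern <- solve(crossprod(A), t(A))[1, ]
  out <- numeric(n)
  core <- (h + 1):(n - h)
  out[core] <- vapply(core, function(i) sum(kern * y[(i - h):(i + h)]),
                      numeric(1))
  for (i in seq_len(h)) {
    out[i] <- sg_fit_at(y, 1:(i + h), i, polyorder)
    j <- n - i + 1
    out[j] <- sg_fit_at(y, (j - h):n, j, polyorder)
  }
  out
}

#' Vector normalization to unit Euclidean norm
#'
#' @param y Intensity vector or `spectrum` with nonzero L2 norm.
#' @return `y / ||y||_2`, same type as input.
#' @export
vector_normalize <- function(y) {
  if (inherits(y, "spectrum")) {
    return(spectrum(y$axis, vector_normalize(y$intensity), meta = y$meta))
  }
  y <- as.numeric(y)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  y / nrm
}

#' Preprocess a spectrum set for PCA or PLS-R
#'
#' Two fixed recipes: `"pca_path"` applies ALS baseline correction, then
#' Savitzky-Golay smoothing (2nd-order polynomial, 11-point window by
#' default), then vector normalization; `"plsr_path"` applies vector
#' normalization only, leaving the raw intensity structure intact for the
#' regression (additional preprocessing before regression risks
#' overfitting). Metadata is passed through untouched.
#'
#' @param set A `spectrum_set`.
#' @param mode `"pca_path"` or `"plsr_path"`.
#' @param als_lam,als_p,als_iter ALS parameters (pca_path only).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters (pca_path only).
#' @return A `spectrum_set` of preprocessed spectra.
#' @export
preprocess_set <- function(set, mode = c("pca_path", "plsr_path"),
                           als_lam = 1e6, als_p = 0.001, als_iter = 10,
                           sg_window = 11, sg_polyorder = 2) {
  stopifnot(inherits(set, "spectrum_set"))
  mode <- match.arg(mode)
  Y <- set$intensities
  if (ncol(Y) == 0) return(set)
  out <- apply(Y, 2, function(col) {
    if (mode == "pca_path") {
      bl <- als_baseline(col, lam = als_lam, p = als_p, n_iter = als_iter)
      col <- savitzky_golay(col - bl, window = sg_window,
                            polyorder = sg_polyorder)
    }
    vector_normalize(col)
  })
  spectrum_set(set$axis, out, set$metadata)
}
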