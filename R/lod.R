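#' Limit of detection from a restricted-range calibration
#'
#' Fits a PLS sub-model on the low-concentration end of the calibration
#' (0.1-0.5 mM by default — widening the range underestimates the LoD,
#' giving an artificially optimistic value), regresses the sub-model's
#' cross-validated predicted concentrations on the true ones, and
#' applies the pseudo-univariate ICH-style rule LoD = 3.3 * s / slope,
#' where s is the residual standard deviation of that regression and
#' slope its gradient. A multivariate calibration reduced to its
#' predicted-vs-true line behaves like a univariate one, for which
#' 3.3 s / slope is the standard detection limit. Cross-validated
#' rather than training predictions are used because with many spectral
#' channels and few restricted-range samples the training residuals
#' collapse towards zero and would understate the detectable level.
#'
#' @param X Spectra matrix (or a `spectrum_set`, in which case the
#'   restriction uses its `true_conc_mM` metadata and `y` is ignored).
#' @param y True concentrations (mM) for a matrix input.
#' @param conc_min,conc_max Restriction window (mM).
#' @param max_lv Largest latent-variable count tried in the sub-model CV.
#' @param groups Optional preparation labels for the sub-model CV.
#' @return A list of class `lod_result`: `lod` (mM), `slope`,
#'   `residual_sd` (mM), `sub_model`, `n_used`.
#' @export
compute_lod <- function(X, y = NULL, conc_min = 0.1, conc_max = 0.5,
                        max_lv = 10, groups = NULL) {
  if (inherits(X, "spectrum_set")) {
    y <- X$metadata$true_conc_mM
    if (is.null(groups)) groups <- X$metadata$sample_id
    X <- t(X$intensities)
  } else {
    X <- as.matrix(X)
  }
  if (is.null(y)) stop("true concentrations are required")
  keep <- y >= conc_min - 1e-9 & y <= conc_max + 1e-9
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (!is.null(groups)) groups <- groups[keep]
  if (length(unique(y)) < 3) {
    stop("at least 3 distinct concentration levels are required")
  }
  model <- calibration_metrics(X, y, groups = groups, max_lv = max_lv)
  predicted <- attr(model, "cv")$cv_predictions
  line <- stats::lm(predicted ~ y)
  slope <- unname(stats::coef(line)[2])
  s <- stats::sigma(line)
  structure(list(lod = 3.3 * s / slope, slope = slope, residual_sd = s,
                 sub_model = model, n_used = length(y)),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> LoD = %.4g mM (slope %.4g, residual sd %.4g mM, n = %d)\n",
              x$lod, x$slope, x$residual_sd, x$n_used))
  invisible(x)
}
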