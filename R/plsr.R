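#' Fit a PLS regression by NIPALS (single response)
#'
#' Latent variables are extracted from the mean-centred data by the
#' NIPALS sequence: weight `w = X'y / ||X'y||`, score `t = X w`,
#' x-loading `p = X't / t't`, y-loading `q = y't / t't`, then deflation
#' `X <- X - t p'`, `y <- y - q t`. The regression vector is composed as
#' `b = W (P'W)^-1 q`, so predictions are
#' `y_mean + (x - x_mean) %*% b`. With as many latent variables as the
#' data rank this reproduces the ordinary least squares fit.
#'
#' @param X Samples-by-variables matrix (for the carotene calibration:
#'   vector-normalized spectra).
#' @param y Response vector (concentration, mM).
#' @param n_lv Number of latent variables.
#' @param check_rank Verify `n_lv` against the rank of the centred data
#'   (an error when exceeded). Skipping the check avoids a QR
#'   factorisation; extraction still stops safely when the score or
#'   response variance is exhausted.
#' @return A list of class `plsr_model` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `TT`, coefficients `b`, centering vectors and
#'   (after [cross_validate()]/[calibration_metrics()]) training metrics.
#' @export
fit_plsr <- function(X, y, n_lv, check_rank = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite input")
  if (n_lv < 1) stop("n_lv must be at least 1")
  if (stats::var(y) == 0) stop("y has no variance to model")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  if (check_rank) {
    r <- qr(E, LAPACK = FALSE)$rank
    if (n_lv > r) {
      stop(sprintf("n_lv (%d) exceeds the rank of the centred data (%d)",
                   n_lv, r))
    }
  }
  p <- ncol(X)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  q <- numeric(n_lv); TT <- matrix(0, nrow(X), n_lv)
  a_done <- 0L
  t2_first <- NULL
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * max(1, sqrt(sum(f^2)))) break  # y-variance exhausted
    w <- w / wn
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    if (is.null(t2_first)) t2_first <- t2
    if (t2 < 1e-24 * t2_first) break  # X-variance along y exhausted
    P[, a] <- drop(crossprod(E, tt)) / t2
    q[a] <- sum(f * tt) / t2
    W[, a] <- w
    TT[, a] <- tt
    E <- E - tcrossprod(tt, P[, a])
    f <- f - q[a] * tt
    a_done <- a
  }
  if (a_done == 0L) {
    stop("response is uncorrelated with every predictor; ",
         "no latent variable can be extracted")
  }
  if (a_done < n_lv) {
    warning(sprintf("response variance exhausted after %d latent variables",
                    a_done))
    W <- W[, seq_len(a_done), drop = FALSE]
    P <- P[, seq_len(a_done), drop = FALSE]
    TT <- TT[, seq_len(a_done), drop = FALSE]
    q <- q[seq_len(a_done)]
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(n_lv = length(q), x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, TT = TT, b = b,
                 metrics = list()),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d variables\n",
              x$n_lv, length(x$b)))
  if (length(x$metrics)) {
    cat(" ", paste(names(x$metrics),
                   vapply(x$metrics, function(v) format(v, digits = 4), ""),
                   sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict concentrations from a PLS model
#'
#' Negative predictions are returned as-is; when the model carries an
#' RMSECV (after cross-validation) predictions with `|yhat| < RMSECV`
#' are marked effectively zero — indistinguishable from a blank at the
#' model's own cross-validated error.
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix or `spectrum_set` preprocessed identically to
#'   the training data.
#' @param flag If TRUE return a data frame with an `effectively_zero`
#'   column instead of a bare vector (requires a stored RMSECV).
#' @param ... Unused.
#' @return Numeric predictions (mM), or a data frame when `flag = TRUE`.
#' @export
predict.plsr_model <- function(object, newdata, flag = FALSE, ...) {
  X <- if (inherits(newdata, "spectrum_set")) t(newdata$intensities)
       else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("newdata axis does not match the training axis")
  }
  yhat <- drop(object$y_mean + sweep(X, 2, object$x_mean) %*% object$b)
  if (!flag) return(yhat)
  rmsecv <- object$metrics$rmsecv
  if (is.null(rmsecv)) stop("flagging requires an RMSECV; run cross_validate")
  data.frame(predicted_mM = yhat,
             effectively_zero = abs(yhat) < rmsecv,
             row.names = rownames(X))
}

# Regression vectors for every nested LV count of one fitted model:
# b_a uses the first a latent variables (P'W is triangular for PLS1,
# so truncation is exact). Returns a p x n_lv matrix.
nested_coefficients <- function(model) {
  vapply(seq_len(model$n_lv), function(a) {
    Wa <- model$W[, seq_len(a), drop = FALSE]
    Pa <- model$P[, seq_len(a), drop = FALSE]
    drop(Wa %*% solve(crossprod(Pa, Wa), model$q[seq_len(a)]))
  }, numeric(length(model$x_mean)))
}

#' Grouped cross-validation of a PLS calibration
#'
#' Leave-one-sample-out over preparation groups: all spectra sharing a
#' group label (replicate measurements of one preparation) are held out
#' together, preventing replicate leakage from inflating the predictive
#' statistics. For each latent-variable count up to `max_lv` the held-out
#' predictions give RMSECV and Q^2 = 1 - PRESS/TSS, with TSS taken about
#' each fold's training mean. The selected count minimises RMSECV, ties
#' going to the smaller model.
#'
#' @param X Samples-by-variables matrix.
#' @param y Response vector (mM).
#' @param groups Preparation labels (replicates share a label); default
#'   one group per row.
#' @param max_lv Largest latent-variable count to try (capped at 10 and
#'   at the smallest training-fold rank).
#' @return A list of class `plsr_cv`: `table` (n_lv, rmsecv, q2),
#'   `selected_lv`, `rmsecv`, `q2`, and `cv_predictions` at the selected
#'   count.
#' @export
cross_validate <- function(X, y, groups = NULL, max_lv = 10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("cross-validation needs at least 3 samples")
  if (is.null(groups)) groups <- seq_len(n)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must label every row")
  folds <- split(seq_len(n), groups)
  max_lv <- min(max_lv, 10)
  press <- NULL; tss <- 0
  cv_pred <- matrix(NA_real_, n, max_lv)
  for (fold in folds) {
    tr <- setdiff(seq_len(n), fold)
    if (stats::var(y[tr]) == 0) stop("a training fold has zero y variance")
    a_max <- min(max_lv, length(tr) - 1, ncol(X))
    m <- suppressWarnings(fit_plsr(X[tr, , drop = FALSE], y[tr], a_max,
                                   check_rank = FALSE))
    B <- nested_coefficients(m)              # p x achieved
    Xc <- sweep(X[fold, , drop = FALSE], 2, m$x_mean)
    pred <- m$y_mean + Xc %*% B              # held-out preds per LV count
    if (ncol(pred) < max_lv) {               # early stop: pad with last
      pred <- cbind(pred, pred[, rep(ncol(pred), max_lv - ncol(pred)),
                               drop = FALSE])
    }
    cv_pred[fold, ] <- pred
    tss <- tss + sum((y[fold] - mean(y[tr]))^2)
  }
  sq_err <- (cv_pred - y)^2
  rmsecv <- sqrt(colMeans(sq_err))
  q2 <- 1 - colSums(sq_err) / tss
  tab <- data.frame(n_lv = seq_len(max_lv), rmsecv = rmsecv, q2 = q2)
  sel <- which(rmsecv <= min(rmsecv) + 1e-12)[1]  # parsimony on ties
  structure(list(table = tab, selected_lv = sel,
                 rmsecv = rmsecv[sel], q2 = q2[sel],
                 cv_predictions = cv_pred[, sel]),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("<plsr_cv> selected %d LV: RMSECV = %.4g, Q2 = %.4g\n",
              x$selected_lv, x$rmsecv, x$q2))
  invisible(x)
}

#' Full calibration workflow with training and prediction metrics
#'
#' Cross-validates on the training set, refits at the selected
#' latent-variable count, and reports training R^2, cross-validated Q^2
#' and RMSECV, and — when a test set is supplied — RMSEP on the held-out
#' spectra. Train and test sample ids must be disjoint.
#'
#' @param X_train,y_train Training spectra and known concentrations.
#' @param X_test,y_test Optional independent test set.
#' @param groups Preparation labels for the CV folds.
#' @param max_lv Largest latent-variable count to consider.
#' @param train_ids,test_ids Optional sample ids used to enforce
#'   disjointness.
#' @return The fitted `plsr_model` with `metrics` filled in: `r2`, `q2`,
#'   `rmsecv`, `rmsep` (NA without a test set), `n_lv`, and the CV table
#'   as attribute `cv`.
#' @export
calibration_metrics <- function(X_train, y_train, X_test = NULL,
                                y_test = NULL, groups = NULL, max_lv = 10,
                                train_ids = NULL, test_ids = NULL) {
  if (!is.null(train_ids) && !is.null(test_ids) &&
      length(intersect(train_ids, test_ids))) {
    stop("training and test sample ids overlap")
  }
  cv <- cross_validate(X_train, y_train, groups = groups, max_lv = max_lv)
  model <- fit_plsr(X_train, y_train, cv$selected_lv)
  fitted <- predict(model, X_train)
  r2 <- 1 - sum((y_train - fitted)^2) / sum((y_train - mean(y_train))^2)
  rmsep <- NA_real_
  if (!is.null(X_test)) {
    pred <- predict(model, X_test)
    rmsep <- sqrt(mean((pred - y_test)^2))
  }
  model$metrics <- list(r2 = r2, q2 = cv$q2, rmsecv = cv$rmsecv,
                        rmsep = rmsep, n_lv = cv$selected_lv)
  attr(model, "cv") <- cv
  model
}
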