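#' Rank oils by predicted beta-carotene against their PC-1 position
#'
#' Replicate predictions and replicate PC-1 scores are averaged per
#' sample; samples are then sorted by predicted carotene concentration
#' (highest first) and the ordering is compared with the PC-1 ordering
#' by Spearman rank correlation. With PC-1 sign-aligned to the
#' carotenoid bands (see [fit_pca()]), carotene-rich oils sit on the
#' positive side of PC-1 and the correlation is positive when the
#' ranking reflects PC-1 position.
#'
#' @param sample_id Per-spectrum sample labels.
#' @param predicted Per-spectrum predicted concentrations (mM).
#' @param pc1_scores Per-spectrum PC-1 scores for the same spectra.
#' @return A data frame (one row per sample, sorted by mean prediction,
#'   descending) with columns `sample_id`, `predicted_mM`, `pc1_score`,
#'   `rank`, plus attributes `spearman_rho` (NA when the ranking is
#'   degenerate) and `ties` (TRUE when tied predictions occur).
#' @export
rank_by_carotene <- function(sample_id, predicted, pc1_scores) {
  if (length(sample_id) != length(predicted) ||
      length(sample_id) != length(pc1_scores)) {
    stop("sample_id, predicted and pc1_scores must have equal length")
  }
  pred <- tapply(predicted, sample_id, mean)
  pc1 <- tapply(pc1_scores, sample_id, mean)
  pc1 <- pc1[names(pred)]
  ord <- order(pred, decreasing = TRUE)
  out <- data.frame(sample_id = names(pred)[ord],
                    predicted_mM = as.numeric(pred)[ord],
                    pc1_score = as.numeric(pc1)[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  ties <- anyDuplicated(out$predicted_mM) > 0
  rho <- if (length(pred) < 2 || stats::sd(pred) == 0 ||
             stats::sd(pc1) == 0) {
    NA_real_  # ranking undefined: no spread to correlate
  } else {
    stats::cor(pred, pc1, method = "spearman")
  }
  attr(out, "spearman_rho") <- rho
  attr(out, "ties") <- ties
  out
}
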