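# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form and never call the code paths
# they check.

# Per-window least-squares polynomial fit, evaluated at the window
# centre; windows truncated at the ends.
sg_oracle <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    deg <- min(polyorder, length(idx) - 1)
    A <- outer(idx - i, 0:deg, `^`)
    unname(stats::lm.fit(A, y[idx])$coefficients[1])
  }, numeric(1))
}

# Direct evaluation of the simulated noise-free spectrum from its
# configuration: Lorentzian sum plus polynomial baseline, written out
# without reusing the package's evaluators.
analytic_spectrum <- function(config, conc = config$carotene_conc) {
  axis <- seq(config$axis_start, config$axis_end, by = config$axis_step)
  u <- (axis - config$axis_start) / (config$axis_end - config$axis_start)
  y <- rep(0, length(axis))
  for (d in seq_along(config$baseline_coeffs)) {
    y <- y + config$baseline_coeffs[d] * u^(d - 1)
  }
  b <- config$bands
  for (k in seq_len(nrow(b))) {
    amp <- if (b$carotene_linked[k]) {
      b$amplitude[k] * config$carotene_gain * conc
    } else b$amplitude[k]
    y <- y + amp / (1 + ((axis - b$center[k]) / (b$fwhm[k] / 2))^2)
  }
  y
}

# Uniform draws on the 3-part percentage simplex.
random_simplex <- function(n) {
  g <- matrix(stats::rexp(3 * n), ncol = 3)
  100 * g / rowSums(g)
}

# Fatty-acid rows of the 15-sample NMR comparison table
# (oleic, linoleic, saturated percentages).
nmr_table_samples <- function() {
  m <- rbind(
    "197" = c(39.4, 13.3, 47.3),
    "200" = c(41.2, 14.0, 44.8),
    "159" = c(44.4, 12.5, 43.1),
    "47"  = c(35.1, 11.3, 53.6),
    "168" = c(43.3, 12.2, 44.5),
    "423" = c(36.4, 12.1, 51.5),
    "441" = c(36.3, 10.7, 53.0),
    "209" = c(37.5, 12.2, 50.3),
    "400" = c(36.2, 11.3, 52.4),
    "64"  = c(35.8, 10.9, 53.2),
    "392" = c(38.0, 12.0, 50.0),
    "434" = c(35.8, 10.4, 53.8),
    "187" = c(41.1, 11.7, 47.2),
    "229" = c(39.7, 12.1, 48.2),
    "430" = c(40.5, 11.7, 47.7))
  colnames(m) <- c("oleic", "linoleic", "saturated")
  m
}
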