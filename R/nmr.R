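#' Three diagnostic 1H-NMR lipid integrals
#'
#' Signal i: all olefinic (C=C) protons — 2 per oleic chain, 4 per
#' linoleic chain. Signal ii: the bis-allylic CH2 between the double
#' bonds at positions 9 and 12 — 2 protons, linoleic chains only.
#' Signal iii: terminal CH3 of every fatty-acid chain — 3 protons per
#' chain regardless of saturation.
#'
#' @param i_olefinic,i_bis_allylic,i_ch3 Integral values
#'   (proton-equivalent units), all non-negative.
#' @return A list of class `nmr_integrals`.
#' @export
nmr_integrals <- function(i_olefinic, i_bis_allylic, i_ch3) {
  v <- c(i_olefinic, i_bis_allylic, i_ch3)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("integrals must be finite and non-negative")
  }
  structure(list(i_olefinic = i_olefinic, i_bis_allylic = i_bis_allylic,
                 i_ch3 = i_ch3),
            class = "nmr_integrals")
}

#' Fatty-acid chain composition (molar chain percentages)
#'
#' @param oleic_pct,linoleic_pct,saturated_pct Percentages of chains;
#'   each in \[0, 100\], summing to 100.
#' @param tol Tolerance on the sum constraint.
#' @return A list of class `fatty_acid_composition`.
#' @export
fatty_acid_composition <- function(oleic_pct, linoleic_pct, saturated_pct,
                                   tol = 1e-9) {
  v <- c(oleic_pct, linoleic_pct, saturated_pct)
  if (any(v < -tol)) stop("percentages must be non-negative")
  if (abs(sum(v) - 100) > tol) stop("percentages must sum to 100")
  structure(list(oleic_pct = oleic_pct, linoleic_pct = linoleic_pct,
                 saturated_pct = saturated_pct),
            class = "fatty_acid_composition")
}

as_fatty_acid_composition <- function(x, tol = 1e-9) {
  if (inherits(x, "fatty_acid_composition")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3) stop("a composition needs 3 percentages")
  fatty_acid_composition(x[1], x[2], x[3], tol = tol)
}

#' Reference chain compositions of palm and palm kernel oil
#'
#' Typical literature values used for nearest-reference classification:
#' palm (mesocarp) oil around 39.2% oleic / 10.1% linoleic / 49.9%
#' saturated; palm kernel oil far more saturated at about 15.4% / 2.4% /
#' 82.1%. (These literature triples carry rounding and do not sum to
#' exactly 100.)
#'
#' @return Named list of length-3 numeric vectors
#'   (oleic, linoleic, saturated).
#' @export
oil_reference_profiles <- function() {
  list(palm_oil = c(oleic = 39.2, linoleic = 10.1, saturated = 49.9),
       palm_kernel_oil = c(oleic = 15.4, linoleic = 2.4, saturated = 82.1))
}

#' Chain composition from the three NMR integrals
#'
#' Inverts the proton-counting model: N_total = I_iii / 3 (terminal CH3,
#' 3 protons per chain), N_linoleic = I_ii / 2 (bis-allylic CH2),
#' N_oleic = (I_i - 2 I_ii) / 2 (olefinic protons net of the linoleic
#' contribution, 4 per linoleic chain = 2 * I_ii). Percentages are
#' 100 N_x / N_total with the saturated share as the complement, so the
#' three always sum to exactly 100. The result is scale invariant:
#' multiplying all integrals by a positive constant changes nothing.
#'
#' @param integrals An [nmr_integrals()] (or length-3 numeric vector
#'   i, ii, iii).
#' @param tol Relative tolerance for negative-share detection and
#'   boundary clipping.
#' @return A `fatty_acid_composition`.
#' @export
composition_from_integrals <- function(integrals, tol = 1e-8) {
  if (!inherits(integrals, "nmr_integrals")) {
    integrals <- nmr_integrals(integrals[[1]], integrals[[2]], integrals[[3]])
  }
  i1 <- integrals$i_olefinic; i2 <- integrals$i_bis_allylic
  i3 <- integrals$i_ch3
  if (i3 <= 0) stop("terminal CH3 integral must be positive")
  n_tot <- i3 / 3
  n_lin <- i2 / 2
  n_ole <- (i1 - 2 * i2) / 2
  ole <- 100 * n_ole / n_tot
  lin <- 100 * n_lin / n_tot
  sat <- 100 - ole - lin
  scale_tol <- tol * 100
  if (ole < -scale_tol) {
    stop("inconsistent integrals: olefinic signal below the linoleic floor")
  }
  if (sat < -scale_tol) {
    stop("inconsistent integrals: unsaturated shares exceed 100%")
  }
  # clip roundoff-level boundary violations only
  ole <- min(max(ole, 0), 100)
  lin <- min(max(lin, 0), 100)
  sat <- 100 - ole - lin
  fatty_acid_composition(ole, lin, sat, tol = scale_tol)
}

#' Classify an oil as palm or palm kernel by composition
#'
#' Nearest reference in Euclidean distance over the
#' (oleic, linoleic, saturated) triple. Ties (within `tol`) report all
#' tied labels.
#'
#' @param composition A `fatty_acid_composition` or length-3 numeric
#'   vector.
#' @param references Named list of length-3 reference vectors; defaults
#'   to [oil_reference_profiles()].
#' @param tol Absolute distance-tie tolerance.
#' @return A list with `label` (character, >1 element on a tie) and
#'   `distances` (named numeric).
#' @export
classify_oil_type <- function(composition,
                              references = oil_reference_profiles(),
                              tol = 1e-9) {
  if (length(references) == 0) stop("at least one reference is required")
  v <- if (inherits(composition, "fatty_acid_composition")) {
    c(composition$oleic_pct, composition$linoleic_pct,
      composition$saturated_pct)
  } else as.numeric(composition)
  if (length(v) != 3) stop("composition must have 3 components")
  d <- vapply(references, function(ref) sqrt(sum((v - as.numeric(ref))^2)),
              numeric(1))
  list(label = names(d)[d <= min(d) + tol], distances = d)
}

#' Compositions and classifications for a table of integrals
#'
#' Processes each row independently; a row with inconsistent or invalid
#' integrals is reported with its error message and the batch continues.
#'
#' @param table Data frame with columns `sample_id`, `I_olefinic`,
#'   `I_bis_allylic`, `I_ch3`.
#' @param references Reference profiles for classification.
#' @return Data frame with columns `sample_id`, `oleic_pct`,
#'   `linoleic_pct`, `saturated_pct`, `label`, `error` (NA when the row
#'   succeeded).
#' @export
batch_compositions <- function(table,
                               references = oil_reference_profiles()) {
  table <- as.data.frame(table)
  need <- c("sample_id", "I_olefinic", "I_bis_allylic", "I_ch3")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(table)
  out <- data.frame(sample_id = table$sample_id,
                    oleic_pct = rep(NA_real_, n),
                    linoleic_pct = rep(NA_real_, n),
                    saturated_pct = rep(NA_real_, n),
                    label = rep(NA_character_, n),
                    error = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table))) {
    res <- tryCatch({
      comp <- composition_from_integrals(nmr_integrals(
        table$I_olefinic[i], table$I_bis_allylic[i], table$I_ch3[i]))
      cls <- classify_oil_type(comp, references)
      list(comp = comp, label = paste(cls$label, collapse = "|"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$oleic_pct[i] <- res$comp$oleic_pct
      out$linoleic_pct[i] <- res$comp$linoleic_pct
      out$saturated_pct[i] <- res$comp$saturated_pct
      out$label[i] <- res$label
    }
  }
  out
}
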