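#' Construct a single spectrum
#'
#' A `spectrum` couples a strictly monotone axis (Raman shift in cm^-1, or
#' ppm for NMR) with one intensity trace and a free-form metadata list.
#'
#' @param axis Numeric vector, strictly monotone increasing.
#' @param intensity Numeric vector, same length as `axis`, all finite.
#' @param meta Named list of metadata (e.g. `sample_id`, `true_conc_mM`).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(axis, intensity, meta = list()) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have the same length")
  }
  if (length(axis) >= 2 && any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing")
  }
  if (!all(is.finite(intensity))) {
    stop("intensity contains non-finite values")
  }
  structure(list(axis = axis, intensity = intensity, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, axis %.6g..%.6g\n",
              length(x$axis), min(x$axis), max(x$axis)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a set of co-registered spectra
#'
#' Stores spectra column-wise (one column per spectrum, rows follow the
#' shared axis) together with per-spectrum metadata. This mirrors the wide
#' on-disk layout used by [write_spectra()].
#'
#' @param axis Shared axis vector, strictly increasing.
#' @param intensities Numeric matrix, `length(axis)` rows; column names are
#'   spectrum ids.
#' @param metadata Data frame with one row per column of `intensities`;
#'   must contain a `spectrum_id` column matching `colnames(intensities)`.
#'   Conventional columns: `sample_id`, `origin`, `replicate`,
#'   `true_conc_mM`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, intensities, metadata) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(axis)) {
    stop("intensities must have length(axis) rows")
  }
  if (length(axis) >= 2 && any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing")
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("s%03d", seq_len(ncol(intensities)))
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("duplicate spectrum ids in intensity matrix")
  }
  metadata <- as.data.frame(metadata)
  if (!"spectrum_id" %in% names(metadata)) {
    stop("metadata must contain a spectrum_id column")
  }
  if (ncol(intensities) > 0 &&
      !identical(as.character(metadata$spectrum_id), colnames(intensities))) {
    stop("metadata$spectrum_id must match intensity column names in order")
  }
  structure(list(axis = axis, intensities = intensities, metadata = metadata),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points, axis %.6g..%.6g\n",
              ncol(x$intensities), length(x$axis),
              min(x$axis), max(x$axis)))
  extra <- setdiff(names(x$metadata), "spectrum_id")
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectrum_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  ncol(set$intensities)
}

#' Spectra as a samples-by-wavenumber matrix
#'
#' Model-fitting functions ([fit_pca()], [fit_plsr()]) expect samples in
#' rows; this transposes the column-wise storage of a `spectrum_set`.
#'
#' @param set A `spectrum_set`.
#' @return Numeric matrix, one row per spectrum, columns named by axis value.
#' @export
spectra_matrix <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  X <- t(set$intensities)
  colnames(X) <- format(set$axis, trim = TRUE)
  X
}

#' Extract one spectrum from a set
#' @param set A `spectrum_set`.
#' @param i Column index or spectrum id.
#' @return A `spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"))
  spectrum(set$axis, set$intensities[, i],
           meta = as.list(set$metadata[match(
             if (is.character(i)) i else colnames(set$intensities)[i],
             set$metadata$spectrum_id), , drop = FALSE]))
}

# Evaluate a function's randomness under a temporary seed, restoring the
# caller's RNG state afterwards so simulation calls do not perturb scripts.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
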