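#' Read spectra from CSV
#'
#' Wide format: first column the axis (wavenumber or ppm), one named
#' column per spectrum. Long format: columns `axis`, `spectrum_id`,
#' `intensity`. A descending axis is flipped to ascending with a
#' warning; non-numeric or missing cells are reported with their
#' row/column location. A metadata sidecar (columns `spectrum_id`,
#' `sample_id`, `origin`, `replicate`, `true_conc_mM`) is joined when
#' given or when `<path>_meta.csv` exists.
#'
#' @param path CSV file.
#' @param format `"wide_csv"` or `"long_csv"`.
#' @param metadata_path Optional sidecar CSV.
#' @return A `spectrum_set`.
#' @export
read_spectra <- function(path, format = c("wide_csv", "long_csv"),
                         metadata_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate column names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  if (format == "long_csv") {
    need <- c("axis", "spectrum_id", "intensity")
    if (!all(need %in% names(df))) {
      stop("long format needs columns ", paste(need, collapse = ", "))
    }
    ids <- unique(df$spectrum_id)
    ax <- sort(unique(df$axis))
    M <- matrix(NA_real_, length(ax), length(ids),
                dimnames = list(NULL, ids))
    M[cbind(match(df$axis, ax), match(df$spectrum_id, ids))] <- df$intensity
    df <- data.frame(axis = ax, M, check.names = FALSE)
  }
  axis <- suppressWarnings(as.numeric(df[[1]]))
  Y <- as.matrix(df[-1])
  suppressWarnings(storage.mode(Y) <- "double")
  bad <- which(!is.finite(Y), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing intensity at row %d, column '%s'",
                 bad[1, 1] + 1L, colnames(Y)[bad[1, 2]]))
  }
  if (any(!is.finite(axis))) {
    stop(sprintf("non-numeric axis value at row %d",
                 which(!is.finite(axis))[1] + 1L))
  }
  if (length(axis) >= 2 && all(diff(axis) < 0)) {
    warning("descending axis in ", basename(path), "; flipping to ascending")
    axis <- rev(axis)
    Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  }
  if (is.null(metadata_path)) {
    cand <- sub("\\.csv$", "_meta.csv", path)
    if (file.exists(cand)) metadata_path <- cand
  }
  md <- if (!is.null(metadata_path)) {
    m <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    m[match(colnames(Y), m$spectrum_id), , drop = FALSE]
  } else {
    data.frame(spectrum_id = colnames(Y), sample_id = colnames(Y),
               stringsAsFactors = FALSE)
  }
  spectrum_set(axis, Y, md)
}

#' Write spectra to wide CSV (plus metadata sidecar)
#'
#' @param set A `spectrum_set`.
#' @param path Output CSV; first column `wavenumber`, one column per
#'   spectrum.
#' @param metadata_path Sidecar CSV for the metadata; defaults to
#'   `<path>_meta.csv`. NULL suppresses it.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path,
                          metadata_path = sub("\\.csv$", "_meta.csv", path)) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- data.frame(wavenumber = set$axis, set$intensities,
                   check.names = FALSE)
  # %.17g round-trips doubles exactly through the text format
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    md <- set$metadata
    md[] <- lapply(md, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    })
    utils::write.csv(md, metadata_path, row.names = FALSE)
  }
  invisible(path)
}
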