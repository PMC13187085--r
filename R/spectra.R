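#' Spectrum set container
#'
#' A sample-by-wavelength absorbance matrix (log(1/R)) with its wavelength
#' grid. Wavelengths must be strictly increasing and every cell finite;
#' absorbance itself is unconstrained in sign (log(1/R) and derivative spectra
#' may be negative).
#'
#' @param absorbance numeric matrix, one row per sample.
#' @param wavelengths strictly increasing numeric grid (nm), one per column.
#' @param sample_ids character vector, one per row.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(absorbance, wavelengths, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(absorbance)))
  }
  if (length(wavelengths) != ncol(absorbance)) {
    stopf("wavelength grid length (%d) != spectrum length (%d)",
          length(wavelengths), ncol(absorbance))
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stopf("sample_ids length != number of spectra")
  }
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing")
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stopf("absorbance matrix contains missing or non-finite cells")
  }
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(
    list(sample_ids = as.character(sample_ids),
         wavelengths = as.numeric(wavelengths),
         absorbance = absorbance),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$absorbance)

as_spectrum_matrix <- function(x) {
  if (inherits(x, "spectrum_set")) x$absorbance else as.matrix(x)
}

# rebuild a spectrum_set with a new absorbance matrix, keeping metadata
set_absorbance <- function(x, mat) {
  spectrum_set(mat, x$wavelengths, x$sample_ids)
}

check_same_grid <- function(a, b) {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(abs(a$wavelengths - b$wavelengths) > 1e-9)) {
    stopf("wavelength grids differ: [%g, %g] x %d vs [%g, %g] x %d",
          min(a$wavelengths), max(a$wavelengths), length(a$wavelengths),
          min(b$wavelengths), max(b$wavelengths), length(b$wavelengths))
  }
  invisible(TRUE)
}
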