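#' PCA projection of spectra
#'
#' Column-centered (optionally unit-variance scaled) principal component
#' scores, retaining either the smallest number of components whose cumulative
#' explained variance reaches `var_threshold`, or exactly `n_components`.
#'
#' @param spectra a [spectrum_set()] or numeric matrix.
#' @param var_threshold cumulative explained-variance fraction in (0, 1];
#'   ignored when `n_components` is given.
#' @param n_components exact number of components to retain.
#' @param scale. logical; divide columns by their standard deviation
#'   (constant columns are left unscaled).
#' @return score matrix with attributes `explained` (per-component variance
#'   ratios of the retained components) and `sdev`.
#' @export
pca_project <- function(spectra, var_threshold = 0.99, n_components = NULL,
                        scale. = FALSE) {
  X <- as_spectrum_matrix(spectra)
  if (nrow(X) < 2L) stopf("PCA needs at least 2 samples")
  if (is.null(n_components)) {
    if (var_threshold <= 0 || var_threshold > 1) {
      stopf("var_threshold must lie in (0, 1]")
    }
  }
  if (scale.) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(n_components)) {
    min(as.integer(n_components), ncol(pc$x))
  } else {
    which(cumsum(ratio) >= var_threshold - 1e-12)[1]
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "explained") <- ratio[seq_len(k)]
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  scores
}

# Deterministic robust (MCD) location/scatter: MASS::cov.rob under a fixed
# internal seed so flags are reproducible run to run.
robust_mcd <- function(scores, coverage = NULL) {
  n <- nrow(scores)
  k <- ncol(scores)
  if (is.null(coverage)) coverage <- floor((n + k + 1) / 2)
  est <- with_seed(20260101L, {
    MASS::cov.rob(scores, method = "mcd", quantile.used = coverage)
  })
  if (rcond_psd(est$cov) < 1e-12) {
    stopf("robust scatter is (near) singular; retry with fewer score components")
  }
  est
}

rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Flag spectral outliers from PCA scores
#'
#' Robust Mahalanobis distances are computed from a deterministic minimum
#' covariance determinant (MCD) estimate of location and scatter on the first
#' `n_components` score dimensions; samples whose distance exceeds the
#' empirical `percentile` of the distances are flagged.
#'
#' @param scores score matrix from [pca_project()].
#' @param percentile flagging percentile of the distance distribution
#'   (default 99.5); 100 flags nothing.
#' @param n_components score dimensions used (default 5, capped at the
#'   available columns).
#' @return data frame `sample, distance, flagged` with the threshold as an
#'   attribute.
#' @export
flag_spectral_outliers <- function(scores, percentile = 99.5, n_components = 5L) {
  scores <- as.matrix(scores)
  k <- min(as.integer(n_components), ncol(scores))
  S <- scores[, seq_len(k), drop = FALSE]
  if (nrow(S) <= k + 1L) stopf("need more samples than score components + 1")
  est <- robust_mcd(S)
  d2 <- stats::mahalanobis(S, center = est$center, cov = est$cov)
  d <- sqrt(d2)
  thr <- quantile7(d, percentile / 100)
  out <- data.frame(
    sample = if (!is.null(rownames(S))) rownames(S) else seq_len(nrow(S)),
    distance = d,
    flagged = d > thr,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  out
}

#' Consensus over per-pretreatment outlier flags
#'
#' A sample is a global spectral outlier when it was flagged in at least
#' `threshold` (default 75%) of the pretreatments.
#'
#' @param flag_matrix logical matrix, samples x pretreatments.
#' @param threshold consensus fraction in (0, 1].
#' @return logical vector of global flags.
#' @export
consensus_outliers <- function(flag_matrix, threshold = 0.75) {
  flag_matrix <- as.matrix(flag_matrix)
  if (ncol(flag_matrix) < 1L) stopf("need at least one pretreatment column")
  frac <- rowMeans(flag_matrix)
  stats::setNames(frac >= threshold, rownames(flag_matrix))
}

#' IQR cleaning of wet-chemistry reference values
#'
#' Per analyte, values below `Q1 - k*IQR` or above `Q3 + k*IQR` (type-7
#' quantiles) are replaced with `NA`; other analytes of the same sample are
#' retained.
#'
#' @param reference data frame: `sample_id` plus one numeric column per
#'   analyte.
#' @param k fence multiplier (default 1.5).
#' @return the reference table with outlying cells set to `NA`; the count of
#'   removed cells per analyte is attached as attribute `n_removed`.
#' @export
clean_reference_iqr <- function(reference, k = 1.5) {
  stopifnot("sample_id" %in% names(reference))
  analytes <- setdiff(names(reference), "sample_id")
  removed <- stats::setNames(integer(length(analytes)), analytes)
  for (a in analytes) {
    x <- reference[[a]]
    if (all(is.na(x))) stopf("analyte '%s' has no non-missing values", a)
    if (sum(!is.na(x)) < 4L) stopf("analyte '%s' needs >= 4 non-missing values", a)
    q <- quantile7(x, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    bad <- !is.na(x) & (x < q[1] - k * iqr | x > q[2] + k * iqr)
    reference[[a]][bad] <- NA
    removed[a] <- sum(bad)
  }
  attr(reference, "n_removed") <- removed
  reference
}
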