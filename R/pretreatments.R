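#' Spectral pretreatments
#'
#' Constructors for the pretreatment steps evaluated during calibration
#' development: standard normal variate (SNV), multiplicative scatter
#' correction (MSC), polynomial detrending, baseline correction and
#' Savitzky-Golay smoothing/derivatives (SG, SG1, SG2). A pretreatment is an
#' ordered list of steps applied left to right by [apply_pretreatment()].
#'
#' @param steps list of step objects created by `pt_snv()`, `pt_msc()`,
#'   `pt_detrend()`, `pt_baseline()`, `pt_sg()`.
#' @return object of class `pretreatment_spec`.
#' @export
pretreatment <- function(steps = list()) {
  for (s in steps) {
    if (!inherits(s, "pt_step")) stopf("all steps must be pt_* step objects")
  }
  structure(list(steps = steps), class = "pretreatment_spec")
}

#' @rdname pretreatment
#' @export
pt_snv <- function() {
  structure(list(type = "snv"), class = "pt_step")
}

#' @rdname pretreatment
#' @param reference reference spectrum for MSC; `NULL` (default) uses the mean
#'   spectrum of the set the pretreatment is fitted on.
#' @export
pt_msc <- function(reference = NULL) {
  structure(list(type = "msc", reference = reference), class = "pt_step")
}

#' @rdname pretreatment
#' @param degree polynomial degree for detrending (default 2).
#' @export
pt_detrend <- function(degree = 2L) {
  if (!is_count(degree, min = 0L)) stopf("detrend degree must be a nonnegative integer")
  structure(list(type = "detrend", degree = as.integer(degree)), class = "pt_step")
}

#' @rdname pretreatment
#' @param method `"min"` subtracts each spectrum's minimum; `"endpoints"`
#'   subtracts the straight line through the first and last point.
#' @export
pt_baseline <- function(method = c("min", "endpoints")) {
  method <- match.arg(method)
  structure(list(type = "baseline", method = method), class = "pt_step")
}

#' @rdname pretreatment
#' @param window odd filter window length (> polyorder).
#' @param polyorder local polynomial order (>= deriv).
#' @param deriv derivative order: 0 (smoothing), 1 (SG1) or 2 (SG2).
#' @export
pt_sg <- function(window = 11L, polyorder = 2L, deriv = 0L) {
  if (!is_count(window) || window %% 2L == 0L) stopf("SG window must be odd")
  if (!is_count(polyorder, min = 0L) || polyorder >= window) {
    stopf("SG polyorder must satisfy 0 <= polyorder < window")
  }
  if (!deriv %in% 0:2 || deriv > polyorder) {
    stopf("SG deriv must be 0, 1 or 2 and <= polyorder")
  }
  structure(list(type = "sg", window = as.integer(window),
                 polyorder = as.integer(polyorder), deriv = as.integer(deriv)),
            class = "pt_step")
}

#' @export
format.pretreatment_spec <- function(x, ...) {
  if (!length(x$steps)) return("identity")
  paste(vapply(x$steps, function(s) {
    switch(s$type,
      snv = "SNV",
      msc = "MSC",
      detrend = sprintf("detrend(%d)", s$degree),
      baseline = sprintf("baseline(%s)", s$method),
      sg = sprintf("SG%d(%d,%d)", s$deriv, s$window, s$polyorder)
    )
  }, ""), collapse = "+")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("<pretreatment>", format(x), "\n")
  invisible(x)
}

#' Standard normal variate correction
#'
#' Centers and scales each spectrum to mean 0 and sample standard deviation 1,
#' removing per-sample affine scatter.
#'
#' @param spectra a [spectrum_set()] or numeric matrix (rows = spectra).
#' @return same container type as the input.
#' @export
snv <- function(spectra) {
  X <- as_spectrum_matrix(spectra)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  if (any(s == 0)) {
    bad <- which(s == 0)[1]
    id <- if (inherits(spectra, "spectrum_set")) spectra$sample_ids[bad] else bad
    stopf("SNV undefined for constant spectrum (sample %s)", id)
  }
  out <- (X - mu) / s
  if (inherits(spectra, "spectrum_set")) set_absorbance(spectra, out) else out
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum (by default the mean
#' spectrum of the set) and returns `(spectrum - intercept) / slope`.
#'
#' @inheritParams snv
#' @param reference reference spectrum; `NULL` uses the column mean of
#'   `spectra`.
#' @export
msc <- function(spectra, reference = NULL) {
  X <- as_spectrum_matrix(spectra)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X)) stopf("MSC reference length mismatch")
  r <- reference - mean(reference)
  denom <- sum(r^2)
  if (denom == 0) stopf("MSC reference spectrum is constant")
  out <- X
  for (i in seq_len(nrow(X))) {
    b <- sum((X[i, ] - mean(X[i, ])) * r) / denom
    if (abs(b) < 1e-8) stopf("MSC slope ~0 for spectrum %d; correction undefined", i)
    a <- mean(X[i, ]) - b * mean(reference)
    out[i, ] <- (X[i, ] - a) / b
  }
  if (inherits(spectra, "spectrum_set")) set_absorbance(spectra, out) else out
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering on the wavelength grid;
#' derivatives are returned per nm (scaled by the grid step). Delegates to
#' [signal::sgolayfilt()].
#'
#' @inheritParams snv
#' @param window odd window length.
#' @param polyorder polynomial order (< window).
#' @param deriv derivative order 0, 1 or 2.
#' @param step grid step in nm; taken from the `spectrum_set` grid when
#'   available.
#' @export
savitzky_golay <- function(spectra, window = 11L, polyorder = 2L, deriv = 0L,
                           step = NULL) {
  stp <- pt_sg(window, polyorder, deriv)  # validates parameters
  X <- as_spectrum_matrix(spectra)
  if (is.null(step)) {
    step <- if (inherits(spectra, "spectrum_set")) {
      diff(spectra$wavelengths[1:2])
    } else 1
  }
  out <- t(apply(X, 1, function(row) {
    signal::sgolayfilt(row, p = stp$polyorder, n = stp$window, m = stp$deriv,
                       ts = step)
  }))
  if (inherits(spectra, "spectrum_set")) set_absorbance(spectra, out) else out
}

detrend_rows <- function(X, grid, degree) {
  B <- outer(scale_unit(grid), 0:degree, `^`)
  fit <- B %*% qr.solve(B, t(X))
  X - t(fit)
}

scale_unit <- function(g) (g - min(g)) / (max(g) - min(g))

baseline_rows <- function(X, grid, method) {
  if (method == "min") {
    X - apply(X, 1, min)
  } else {
    p <- ncol(X)
    slope <- (X[, p] - X[, 1]) / (grid[p] - grid[1])
    line <- outer(slope, grid - grid[1]) + X[, 1]
    X - line
  }
}

#' Fit a pretreatment to a training spectrum set
#'
#' Resolves data-dependent parameters (currently only the MSC reference, which
#' defaults to the training-set mean spectrum) so the identical transformation
#' can later be applied to new spectra.
#'
#' @param spectra training [spectrum_set()].
#' @param spec a [pretreatment()].
#' @return the spec with all references frozen.
#' @export
fit_pretreatment <- function(spectra, spec) {
  stopifnot(inherits(spec, "pretreatment_spec"))
  cur <- spectra
  spec$steps <- lapply(spec$steps, function(s) {
    if (s$type == "msc" && is.null(s$reference)) {
      s$reference <- colMeans(as_spectrum_matrix(cur))
    }
    cur <<- apply_step(cur, s)
    s
  })
  spec
}

apply_step <- function(spectra, s) {
  X <- as_spectrum_matrix(spectra)
  grid <- if (inherits(spectra, "spectrum_set")) spectra$wavelengths else seq_len(ncol(X))
  out <- switch(s$type,
    snv = return(snv(spectra)),
    msc = return(msc(spectra, reference = s$reference)),
    sg = return(savitzky_golay(spectra, s$window, s$polyorder, s$deriv)),
    detrend = detrend_rows(X, grid, s$degree),
    baseline = baseline_rows(X, grid, s$method)
  )
  if (inherits(spectra, "spectrum_set")) set_absorbance(spectra, out) else out
}

#' Apply a pretreatment pipeline
#'
#' Applies the steps of a [pretreatment()] left to right. An empty step list
#' is the identity. MSC steps without a frozen reference use the mean spectrum
#' of `spectra` itself (fit and apply in one pass); use [fit_pretreatment()]
#' to freeze training references for prediction.
#'
#' @inheritParams fit_pretreatment
#' @return pretreated spectra, same container type and shape as the input.
#' @export
apply_pretreatment <- function(spectra, spec) {
  stopifnot(inherits(spec, "pretreatment_spec"))
  for (s in spec$steps) spectra <- apply_step(spectra, s)
  spectra
}
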