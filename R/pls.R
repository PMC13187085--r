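# PLS1 regression (NIPALS) with coefficient paths, repeated k-fold
# cross-validation, one-sigma component selection and pretreatment comparison.

# NIPALS PLS1 on centered data; returns the regression coefficient path
# B[, k] for k = 1..ncomp components (in centered-X units) plus centers.
# If deflation degenerates before ncomp components the path is truncated and
# the achievable maximum recorded in attr "ncomp".
pls_nipals_path <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  ncomp <- min(ncomp, n - 1L, p)

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  tol <- max(sum(Xc^2), .Machine$double.eps) * 1e-14
  reached <- 0L
  for (h in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw^2 < tol) break
    w <- w / nw
    tvec <- Xc %*% w
    tt <- sum(tvec^2)
    if (tt < tol) break
    pvec <- crossprod(Xc, tvec) / tt
    qh <- sum(yc * tvec) / tt
    Xc <- Xc - tvec %*% t(pvec)
    yc <- yc - qh * tvec
    W[, h] <- w
    P[, h] <- pvec
    Q[h] <- qh
    reached <- h
  }
  if (reached == 0L) stopf("PLS found no usable component (X has no variance?)")
  B <- matrix(0, p, reached)
  for (k in seq_len(reached)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Rk <- crossprod(P[, seq_len(k), drop = FALSE], Wk)
    B[, k] <- Wk %*% solve(Rk, Q[seq_len(k)])
  }
  structure(list(B = B, x_center = x_center, y_center = y_center,
                 ncomp = reached), class = "pls_path")
}

pls_path_predict <- function(path, Xnew, k = path$ncomp) {
  Xc <- sweep(as.matrix(Xnew), 2, path$x_center)
  Xc %*% path$B[, seq_len(k), drop = FALSE] + path$y_center  # columns: 1..k comps
}

#' Fit a PLS1 calibration model
#'
#' Centered partial least squares regression (NIPALS) of one analyte on a
#' (pretreated) spectral matrix.
#'
#' @param X numeric matrix of pretreated spectra, one row per sample.
#' @param y numeric response (no missing values).
#' @param n_components number of latent components (1 ..
#'   `min(n - 1, ncol(X))`, limited by the rank of centered `X`).
#' @param pretreatment optional fitted [pretreatment()] stored with the model
#'   and re-applied by [pls_predict()].
#' @param wavelengths optional wavelength grid stored for grid checking at
#'   prediction time.
#' @return object of class `pls_model` with elements `coefficients`,
#'   `intercept`, `n_components`, `x_center`, `y_center`, `pretreatment`,
#'   `wavelengths` and `training_stats` (RMSEP, Pearson r, n on the training
#'   set).
#' @export
pls_fit <- function(X, y, n_components, pretreatment = NULL, wavelengths = NULL) {
  X <- as.matrix(X)
  if (anyNA(y)) stopf("training response contains missing values")
  if (length(y) != nrow(X)) stopf("X and y sizes differ")
  if (!is_count(n_components)) stopf("n_components must be a positive integer")
  hard_max <- min(nrow(X) - 1L, ncol(X))
  if (n_components > hard_max) {
    stopf("n_components = %d exceeds min(n - 1, p) = %d", n_components, hard_max)
  }
  path <- pls_nipals_path(X, y, n_components)
  if (path$ncomp < n_components) {
    stopf("n_components = %d exceeds the rank of centered X; achievable maximum is %d",
          n_components, path$ncomp)
  }
  b <- path$B[, n_components]
  intercept <- path$y_center - sum(path$x_center * b)
  fitted <- drop(X %*% b) + intercept
  structure(
    list(
      coefficients = b,
      intercept = intercept,
      n_components = as.integer(n_components),
      x_center = path$x_center,
      y_center = path$y_center,
      pretreatment = pretreatment,
      wavelengths = wavelengths,
      training_stats = list(
        rmsep = sqrt(mean((fitted - y)^2)),
        r = if (stats::sd(fitted) > 0) stats::cor(fitted, y) else NA_real_,
        n = length(y)
      )
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d wavelengths; training RMSEP %.4g (n = %d)\n",
              x$n_components, length(x$coefficients),
              x$training_stats$rmsep, x$training_stats$n))
  if (!is.null(x$pretreatment)) cat("  pretreatment:", format(x$pretreatment), "\n")
  invisible(x)
}

#' Predict analyte values from spectra
#'
#' Applies the model's stored pretreatment (if any) and evaluates
#' `intercept + coefficients . spectrum`.
#'
#' @param model a [pls_fit()] model.
#' @param spectra a [spectrum_set()] (grid must match the model's) or an
#'   already-pretreated numeric matrix.
#' @return numeric predictions, one per spectrum.
#' @export
pls_predict <- function(model, spectra) {
  stopifnot(inherits(model, "pls_model"))
  if (inherits(spectra, "spectrum_set")) {
    if (!is.null(model$wavelengths)) {
      check_same_grid(list(wavelengths = model$wavelengths), spectra)
    }
    if (!is.null(model$pretreatment)) {
      spectra <- apply_pretreatment(spectra, model$pretreatment)
    }
  }
  X <- as_spectrum_matrix(spectra)
  if (ncol(X) != length(model$coefficients)) {
    stopf("spectrum length (%d) does not match model (%d)",
          ncol(X), length(model$coefficients))
  }
  drop(X %*% model$coefficients) + model$intercept
}

#' Repeated k-fold cross-validation of a PLS calibration
#'
#' For each iteration, samples are randomly assigned to `folds` folds; the
#' model is fitted on each training split and out-of-fold predictions are
#' collected for every component count 1..`ncomp_max`. RMSEP per component is
#' computed on the pooled out-of-fold predictions; its standard error is the
#' sd of per-fold RMSEPs divided by `sqrt(folds)`.
#'
#' @param X pretreated spectral matrix.
#' @param y response.
#' @param ncomp_max largest component count to evaluate.
#' @param folds folds per iteration (default 5).
#' @param iterations number of random refoldings (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return object of class `cv_curves`: a list with `ncomp` (component grid)
#'   and `iterations`, each holding `rmsep`, `se` (per component) and
#'   `pred` (pooled out-of-fold prediction matrix, one column per component).
#' @export
crossvalidate <- function(X, y, ncomp_max = 10L, folds = 5L, iterations = 5L,
                          seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stopf("need at least as many samples as folds")
  if (floor(n / folds) < 2L) stopf("folds would contain fewer than 2 samples")
  ncomp_max <- min(ncomp_max, n - ceiling(n / folds) - 1L, ncol(X))
  with_seed(seed, {
    iters <- lapply(seq_len(iterations), function(it) {
      assign <- sample(rep(seq_len(folds), length.out = n))
      pred <- matrix(NA_real_, n, ncomp_max)
      fold_rmsep <- matrix(NA_real_, folds, ncomp_max)
      for (f in seq_len(folds)) {
        hold <- assign == f
        path <- pls_nipals_path(X[!hold, , drop = FALSE], y[!hold], ncomp_max)
        ph <- pls_path_predict(path, X[hold, , drop = FALSE])
        kk <- ncol(ph)
        pred[hold, seq_len(kk)] <- ph
        if (kk < ncomp_max) pred[hold, (kk + 1L):ncomp_max] <- ph[, kk]
        fold_rmsep[f, ] <- sqrt(colMeans((pred[hold, , drop = FALSE] - y[hold])^2))
      }
      list(
        rmsep = sqrt(colMeans((pred - y)^2)),
        se = apply(fold_rmsep, 2, stats::sd) / sqrt(folds),
        pred = pred,
        fold = assign
      )
    })
    structure(list(ncomp = seq_len(ncomp_max), iterations = iters, y = y),
              class = "cv_curves")
  })
}

#' One-sigma selection of the number of PLS components
#'
#' Returns the smallest component count whose cross-validated RMSEP is within
#' one standard error of the minimum. An explicit `override` replaces the
#' heuristic (the analogue of adjusting a scree plot by eye) and is recorded
#' on the result.
#'
#' @param curve list with numeric `rmsep` and `se` of equal length (one
#'   iteration of [crossvalidate()]).
#' @param override optional component count taking precedence.
#' @return integer component count; attribute `override` is `TRUE` when the
#'   manual override was used.
#' @export
select_ncomp_one_sigma <- function(curve, override = NULL) {
  if (!is.null(override)) {
    if (!is_count(override)) stopf("override must be a positive integer")
    message(sprintf("ncomp override in effect: using %d components", override))
    return(structure(as.integer(override), override = TRUE))
  }
  rmsep <- curve$rmsep
  se <- curve$se
  if (!length(rmsep)) stopf("empty RMSEP curve")
  if (is.null(se)) se <- rep(0, length(rmsep))
  se[!is.finite(se)] <- 0
  i_min <- which.min(rmsep)
  thr <- rmsep[i_min] + se[i_min]
  structure(which(rmsep <= thr)[1], override = FALSE)
}

#' Compare spectral pretreatments by cross-validated performance
#'
#' For every analyte x candidate pretreatment, runs repeated k-fold
#' cross-validation, picks the component count per iteration with the
#' one-sigma rule, and reports mean/sd RMSEP and Pearson r (computed on the
#' pooled out-of-fold predictions of each iteration, then averaged). The
#' reported `ncomp` is the one chosen in the final iteration. A supplementary
#' Kennard-Stone 80/20 train-test split (test set selected by Mahalanobis
#' max-min on the first two PCs of the pretreated spectra) is evaluated with
#' that `ncomp`.
#'
#' @param spectra a [spectrum_set()].
#' @param reference data frame `sample_id` + one numeric column per analyte
#'   (% units); rows are matched to spectra by `sample_id`.
#' @param specs list of candidate [pretreatment()]s (optionally named).
#' @param folds,iterations,seed cross-validation settings (shared across all
#'   candidates so identical candidates give identical rows).
#' @param ncomp_max largest component count evaluated.
#' @param ks_fraction held-out fraction for the Kennard-Stone check.
#' @return data frame with one row per analyte x pretreatment, sorted by mean
#'   RMSEP within analyte: `analyte, pretreatment, ncomp, mean_rmsep,
#'   sd_rmsep, mean_r, sd_r, ks_rmsep, ks_r`.
#' @export
evaluate_pretreatments <- function(spectra, reference, specs,
                                   folds = 5L, iterations = 5L, seed = 1L,
                                   ncomp_max = 10L, ks_fraction = 0.2) {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (length(specs) == 0L) stopf("need at least one candidate pretreatment")
  if (is.null(names(specs))) names(specs) <- vapply(specs, format, "")
  names(specs)[names(specs) == ""] <- vapply(specs[names(specs) == ""], format, "")
  analytes <- setdiff(names(reference), "sample_id")

  idx <- match(spectra$sample_ids, reference$sample_id)
  rows <- list()
  for (sp_name in names(specs)) {
    fitted_spec <- fit_pretreatment(spectra, specs[[sp_name]])
    Xp <- as_spectrum_matrix(apply_pretreatment(spectra, fitted_spec))
    for (a in analytes) {
      y_all <- reference[[a]][idx]
      keep <- !is.na(y_all)
      if (sum(keep) < 2L * folds) {
        warnf("analyte '%s' skipped: too few reference values", a)
        next
      }
      Xa <- Xp[keep, , drop = FALSE]
      ya <- y_all[keep]
      cv <- crossvalidate(Xa, ya, ncomp_max = ncomp_max, folds = folds,
                          iterations = iterations, seed = seed)
      per_iter <- lapply(cv$iterations, function(it) {
        k <- select_ncomp_one_sigma(it)
        pr <- it$pred[, k]
        c(k = k, rmsep = it$rmsep[k],
          r = if (stats::sd(pr) > 0) stats::cor(pr, ya) else NA_real_)
      })
      per_iter <- do.call(rbind, per_iter)
      ncomp_final <- as.integer(per_iter[nrow(per_iter), "k"])

      # Kennard-Stone 80/20 supplementary check
      pcs <- pca_project(Xa, n_components = 2L)
      n_test <- max(2L, ceiling(ks_fraction * nrow(Xa)))
      test <- kennard_stone_select(pcs, n_test, metric = "mahalanobis")
      train <- setdiff(seq_len(nrow(Xa)), test)
      k_ks <- min(ncomp_final, length(train) - 1L)
      m <- pls_fit(Xa[train, , drop = FALSE], ya[train], k_ks)
      pr_ks <- pls_predict(m, Xa[test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a,
        pretreatment = sp_name,
        ncomp = ncomp_final,
        mean_rmsep = mean(per_iter[, "rmsep"]),
        sd_rmsep = stats::sd(per_iter[, "rmsep"]),
        mean_r = mean(per_iter[, "r"]),
        sd_r = stats::sd(per_iter[, "r"]),
        ks_rmsep = sqrt(mean((pr_ks - ya[test])^2)),
        ks_r = if (stats::sd(pr_ks) > 0) stats::cor(pr_ks, ya[test]) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(analyte = character(), pretreatment = character(),
                      ncomp = integer(), mean_rmsep = numeric(),
                      sd_rmsep = numeric(), mean_r = numeric(),
                      sd_r = numeric(), ks_rmsep = numeric(),
                      ks_r = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte, out$mean_rmsep), ]
  rownames(out) <- NULL
  out
}
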