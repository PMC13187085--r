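test_that("one component captures a rank-1 signal exactly", {
  set.seed(1)
  w <- rnorm(30)
  X <- outer(rnorm(25), w)
  y <- drop(X %*% w) * 0.1 + 3
  m <- pls_fit(X, y, 1)
  expect_lt(m$training_stats$rmsep, 1e-8)
})

test_that("full-rank PLS reproduces OLS predictions", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(12:30, 1)
    p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- pls_fit(X, y, p)
    ols <- stats::lm.fit(cbind(1, X), y)
    expect_lt(max(abs(pls_predict(m, X) - ols$fitted.values)), 1e-6)
  }
})

test_that("training RMSEP is non-increasing in the number of components", {
  set.seed(3)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rnorm(40)
  rmsep <- vapply(1:10, function(k) pls_fit(X, y, k)$training_stats$rmsep, 0)
  expect_true(all(diff(rmsep) <= 1e-10))
})

test_that("coefficients are invariant to training-row permutation", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  perm <- sample(30)
  expect_equal(pls_fit(X, y, 4)$coefficients,
               pls_fit(X[perm, ], y[perm], 4)$coefficients, tolerance = 1e-9)
})

test_that("component count is bounded by the rank of centered X", {
  set.seed(5)
  base <- matrix(rnorm(20 * 3), 20, 3)
  X <- cbind(base, base %*% matrix(rnorm(6), 3, 2))  # rank 3, p = 5
  expect_error(pls_fit(X, rnorm(20), 5), "achievable maximum is 3")
  expect_error(pls_fit(X, rnorm(20), 25), "min\\(n - 1, p\\)")
})

test_that("prediction applies the stored pretreatment and checks the grid", {
  sim <- simulate_spectra(spectra_sim_config(
    seed = 6, n_samples = 40, wavelength_start = 1000, wavelength_stop = 1400,
    wavelength_step = 2, analytes = "protein",
    band_centers = list(protein = 1200), band_widths = list(protein = 40),
    composition_ranges = list(protein = c(5, 25)), noise_sd = 0.001
  ))
  spec <- fit_pretreatment(sim$spectra, pretreatment(list(pt_snv())))
  Xp <- cytonuclear:::as_spectrum_matrix(apply_pretreatment(sim$spectra, spec))
  m <- pls_fit(Xp, sim$reference$protein, 2, pretreatment = spec,
               wavelengths = sim$spectra$wavelengths)
  # training set reproduces stored predictions through the full path
  expect_equal(pls_predict(m, sim$spectra), drop(Xp %*% m$coefficients) + m$intercept)
  # constant raw offset vanishes under an SNV-first spec
  shifted <- spectrum_set(sim$spectra$absorbance + 0.37,
                          sim$spectra$wavelengths, sim$spectra$sample_ids)
  expect_equal(pls_predict(m, shifted), pls_predict(m, sim$spectra),
               tolerance = 1e-8)
  other <- spectrum_set(sim$spectra$absorbance[, 1:100],
                        sim$spectra$wavelengths[1:100])
  expect_error(pls_predict(m, other), "grids differ")
  # zero-coefficient model predicts its intercept everywhere
  m0 <- m
  m0$coefficients[] <- 0
  m0$pretreatment <- NULL
  expect_equal(unique(pls_predict(m0, Xp)), m0$intercept)
})

test_that("cross-validation is seed-reproducible and flat under pure noise", {
  set.seed(8)
  X <- matrix(rnorm(100 * 30), 100, 30)
  y <- rnorm(100)
  cv1 <- crossvalidate(X, y, ncomp_max = 8, seed = 17)
  cv2 <- crossvalidate(X, y, ncomp_max = 8, seed = 17)
  expect_identical(cv1, cv2)
  # pure noise: no component count materially beats sd(y)
  mins <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xs <- matrix(rnorm(100 * 30), 100, 30)
    ys <- rnorm(100)
    cv <- crossvalidate(Xs, ys, ncomp_max = 8, seed = s)
    min(vapply(cv$iterations, function(it) min(it$rmsep), 0)) / sd(ys)
  }, 0)
  expect_true(all(mins >= 0.8))
  expect_error(crossvalidate(X[1:4, ], y[1:4], folds = 5), "folds")
})

test_that("a strong one-component signal is found near ncomp 1", {
  set.seed(9)
  w <- rnorm(30)
  X <- outer(rnorm(80), w) + matrix(rnorm(80 * 30, 0, 0.01), 80, 30)
  y <- drop(X %*% w) * 0.2 + rnorm(80, 0, 0.05)
  cv <- crossvalidate(X, y, ncomp_max = 6, seed = 2)
  for (it in cv$iterations) expect_lte(which.min(it$rmsep), 2)
})

test_that("one-sigma rule picks the most parsimonious near-optimal model", {
  expect_equal(as.integer(select_ncomp_one_sigma(
    list(rmsep = c(1.0, 0.54, 0.50, 0.49), se = c(0.1, 0.05, 0.04, 0.03))
  )), 3L)
  expect_equal(as.integer(select_ncomp_one_sigma(
    list(rmsep = c(0.9, 0.7, 0.5), se = c(0, 0, 0))
  )), 3L)
  expect_message(k <- select_ncomp_one_sigma(list(rmsep = 1, se = 0), override = 7),
                 "override")
  expect_equal(as.integer(k), 7L)
  expect_true(attr(k, "override"))
})

test_that("pretreatment comparison recovers noiseless synthetic analytes", {
  sim <- simulate_spectra(spectra_sim_config(
    seed = 10, n_samples = 80, wavelength_start = 1000, wavelength_stop = 1800,
    wavelength_step = 2, analytes = c("protein", "fat"),
    band_centers = list(protein = c(1200, 1500), fat = c(1350, 1700)),
    band_widths = list(protein = c(30, 40), fat = c(25, 35)),
    composition_ranges = list(protein = c(8, 20), fat = c(1, 4)),
    scatter_multiplicative_sd = 0, scatter_additive_sd = 0, noise_sd = 0
  ))
  tab <- evaluate_pretreatments(sim$spectra, sim$reference,
                                list(pretreatment()), seed = 3, ncomp_max = 6)
  expect_equal(nrow(tab), 2L)  # analytes x candidates
  expect_true(all(tab$mean_r >= 0.99))
  # duplicate candidates give identical rows under a shared seed
  tab2 <- evaluate_pretreatments(sim$spectra, sim$reference,
                                 list(a = pretreatment(), b = pretreatment()),
                                 seed = 3, ncomp_max = 6)
  a <- tab2[tab2$pretreatment == "a", setdiff(names(tab2), "pretreatment")]
  b <- tab2[tab2$pretreatment == "b", setdiff(names(tab2), "pretreatment")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_warning(
    evaluate_pretreatments(
      sim$spectra,
      data.frame(sample_id = sim$reference$sample_id,
                 junk = c(NA, NA, rep(NA, 78))),
      list(pretreatment()), seed = 1),
    "skipped"
  )
})

test_that("PLS model text serialization round-trips", {
  sim <- simulate_spectra(spectra_sim_config(
    seed = 12, n_samples = 30, wavelength_start = 1000, wavelength_stop = 1100,
    wavelength_step = 1, analytes = "protein",
    band_centers = list(protein = 1050), band_widths = list(protein = 20),
    composition_ranges = list(protein = c(5, 25)), noise_sd = 0.001
  ))
  spec <- fit_pretreatment(sim$spectra,
                           pretreatment(list(pt_snv(), pt_sg(7, 2, 1))))
  Xp <- cytonuclear:::as_spectrum_matrix(apply_pretreatment(sim$spectra, spec))
  m <- pls_fit(Xp, sim$reference$protein, 2, pretreatment = spec,
               wavelengths = sim$spectra$wavelengths)
  path <- tempfile(fileext = ".txt")
  write_pls_model(m, path)
  m2 <- read_pls_model(path)
  expect_equal(pls_predict(m2, sim$spectra), pls_predict(m, sim$spectra),
               tolerance = 1e-12)
})
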