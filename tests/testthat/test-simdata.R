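test_that("reciprocal F2 simulation is seed-deterministic and validates its config", {
  cfg <- sim_config(seed = 42, n_plants_per_cytoplasm = 10, n_markers = 4,
                    effect_spec = c(C = 0.2), trait_names = c("t1", "t2"))
  a <- simulate_reciprocal_f2(cfg)
  b <- simulate_reciprocal_f2(cfg)
  expect_identical(a, b)
  # balanced reciprocal halves, maternal cytoplasm labels, one call per plant x marker
  tab <- table(a$traits$cytoplasm_class[a$traits$trait == "t1"],
               a$traits$environment[a$traits$trait == "t1"])
  expect_true(all(tab == 10))
  expect_false(anyDuplicated(a$genotypes[, c("plant_id", "marker_id")]) > 0)

  expect_error(sim_config(effect_spec = c(C = 0.6, GxCxE = 0.5)), "sum to")
  expect_error(sim_config(effect_spec = c(Z = 0.1)), "unknown model term")
  expect_error(sim_config(n_plants_per_cytoplasm = 1), ">= 2")
  expect_error(
    sim_config(segregation_distortion = list(M001 = c(0.5, 0.4, 0.2))),
    "summing to 1"
  )
})

test_that("undistorted markers segregate 1:2:1 at near-nominal chi-square rejection", {
  cfg <- sim_config(seed = 99, n_plants_per_cytoplasm = 50, n_markers = 400,
                    effect_spec = numeric())
  sim <- simulate_reciprocal_f2(cfg)
  flt <- segregation_filter(sim$genotypes, alpha = 0.01)
  tests <- attr(flt, "tests")
  expect_equal(nrow(tests), 400)
  expect_lte(mean(!tests$kept), 0.02)
})

test_that("a distorted marker is reproduced and caught by the segregation filter", {
  cfg <- sim_config(seed = 6, n_plants_per_cytoplasm = 100, n_markers = 2,
                    segregation_distortion = list(M002 = c(0.6, 0.3, 0.1)),
                    effect_spec = numeric())
  sim <- simulate_reciprocal_f2(cfg)
  kept <- segregation_filter(sim$genotypes)
  expect_true("M001" %in% kept)
  expect_false("M002" %in% kept)
})

test_that("null effect spec yields small fitted eta-squared for every term", {
  cfg <- sim_config(seed = 7, n_plants_per_cytoplasm = 100, n_markers = 1,
                    effect_spec = numeric(), trait_names = "y")
  sim <- simulate_reciprocal_f2(cfg)
  rec <- anova_three_way(sim$traits, sim$genotypes, "POP1", "y", "M001")
  expect_true(all(rec$eta2[rec$term != "Residual"] <= 0.05))
})

test_that("a pure cytoplasm effect with zero residual gives two point masses", {
  cfg <- sim_config(seed = 3, n_plants_per_cytoplasm = 6, n_markers = 1,
                    effect_spec = c(C = 0.5), residual_sd = 0, trait_names = "y")
  sim <- simulate_reciprocal_f2(cfg)
  by_cyto <- split(sim$traits$value, sim$traits$cytoplasm_class)
  expect_equal(length(unique(round(by_cyto$wild, 12))), 1L)
  expect_equal(length(unique(round(by_cyto$cultivated, 12))), 1L)
  expect_false(isTRUE(all.equal(by_cyto$wild[1], by_cyto$cultivated[1])))
})

test_that("single active term with vanishing residual drives eta2 toward 1", {
  cfg <- sim_config(seed = 8, n_plants_per_cytoplasm = 30, n_markers = 1,
                    effect_spec = c(C = 0.98), residual_sd = 0.01,
                    trait_names = "y")
  sim <- simulate_reciprocal_f2(cfg)
  rec <- anova_two_way(sim$traits, "POP1", "y")
  expect_gt(rec$eta2[rec$term == "C"], 0.97)
})

test_that("planted three-way interaction share is recovered within tolerance", {
  est <- vapply(1:8, function(s) {
    cfg <- sim_config(seed = s, n_plants_per_cytoplasm = 500, n_markers = 1,
                      effect_spec = c(GxCxE = 0.10), trait_names = "y")
    sim <- simulate_reciprocal_f2(cfg)
    rec <- anova_three_way(sim$traits, sim$genotypes, "POP1", "y", "M001")
    rec$eta2[rec$term == "GxCxE"]
  }, 0)
  expect_lt(abs(mean(est) - 0.10), 0.03)
})

test_that("simulated spectra: monotone band response and SNV scatter removal", {
  # single analyte, one band, no distortions: absorbance at the band center
  # strictly increases with concentration
  cfg <- spectra_sim_config(
    seed = 2, n_samples = 30, wavelength_start = 1000, wavelength_stop = 1200,
    wavelength_step = 1, analytes = "protein",
    band_centers = list(protein = 1100), band_widths = list(protein = 20),
    composition_ranges = list(protein = c(5, 25)),
    scatter_multiplicative_sd = 0, scatter_additive_sd = 0,
    baseline_poly_degree = 0L, noise_sd = 0
  )
  sim <- simulate_spectra(cfg)
  at_center <- sim$spectra$absorbance[, which(sim$spectra$wavelengths == 1100)]
  ord <- order(sim$reference$protein)
  expect_true(all(diff(at_center[ord]) > 0))

  # scatter-only distortion is affine per sample, so SNV equalises samples of
  # equal composition
  cfg2 <- spectra_sim_config(
    seed = 4, n_samples = 2, wavelength_start = 1000, wavelength_stop = 1200,
    wavelength_step = 1, analytes = "protein",
    band_centers = list(protein = 1100), band_widths = list(protein = 20),
    composition_ranges = list(protein = c(10, 10)),
    scatter_multiplicative_sd = 0.2, scatter_additive_sd = 0.1,
    baseline_poly_degree = 1L, noise_sd = 0
  )
  sim2 <- simulate_spectra(cfg2)
  sn <- snv(sim2$spectra)
  expect_equal(sn$absorbance[1, ], sn$absorbance[2, ], tolerance = 1e-10)

  expect_error(
    spectra_sim_config(analytes = "protein", band_centers = list(protein = 1100),
                       band_widths = list(protein = -5),
                       composition_ranges = list(protein = c(0, 10))),
    "widths must be positive"
  )
  expect_identical(simulate_spectra(cfg), sim)
})

test_that("phenomics generator hits its correlation and effect targets", {
  blocks <- list(list(traits = c("t1", "t2"), rho = 0.99),
                 list(traits = "t3", rho = 0))
  tab <- simulate_phenomics(21, 60, 10, blocks, cytoplasm_effect = c(t3 = 1))
  expect_identical(tab, simulate_phenomics(21, 60, 10, blocks,
                                           cytoplasm_effect = c(t3 = 1)))
  # near-collinear pair is pruned to one trait; independent trait survives
  kept <- prune_correlated(tab, 0.95)
  expect_length(intersect(kept, c("t1", "t2")), 1L)
  expect_true("t3" %in% kept)
  # a persistent 1-sd shift gives weighted d close to the plain mean d
  w <- cytonuclear:::weighted_effect_for(tab, "POP1", "t3")
  expect_lt(abs(w - 1), 0.3)
  expect_error(simulate_phenomics(1, 3, 5, blocks), "2 plants per cytoplasm")
  expect_error(
    simulate_phenomics(1, 10, 5, list(list(traits = "x", rho = 1))),
    "\\[0, 1\\)"
  )
})

test_that("null phenomics effects give near-zero weighted effect sizes", {
  blocks <- list(list(traits = sprintf("t%02d", 1:10), rho = 0.2))
  tab <- simulate_phenomics(31, 60, 10, blocks)
  w <- vapply(sprintf("t%02d", 1:10),
              function(tr) cytonuclear:::weighted_effect_for(tab, "POP1", tr), 0)
  expect_lt(mean(abs(w)), 0.1)
})

test_that("simulated bin distributions are valid and median-consistent", {
  d <- simulate_marvin_bins(seed = 1, true_median = 3.1, bin_width = 0.2)
  expect_s3_class(d, "bin_distribution")
  expect_equal(sum(d$pct), 100, tolerance = 1e-9)
  cum <- cumsum(d$pct)
  crossing <- which(cum >= 50)[1]
  expect_gte(3.1, d$bin_lower[crossing] - 0.2)
  expect_lte(3.1, d$bin_upper[crossing] + 0.2)
  # interpolated median lands within one bin width of the target, across seeds
  err <- vapply(1:100, function(s) {
    abs(bin_median(simulate_marvin_bins(s, 3.1, 0.2)) - 3.1)
  }, 0)
  expect_true(all(err <= 0.2))
  expect_error(simulate_marvin_bins(1, 3, bin_width = -1), "invalid bin grid")
})
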