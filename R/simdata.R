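#' Configuration for a synthetic reciprocal F2 population
#'
#' Describes one reciprocal F2 population: plants carrying either the wild
#' (maternal donor) or the cultivated cytoplasm, genotyped at a set of
#' codominant markers and phenotyped in one or more environments. Trait values
#' are generated under the factorial model
#' \deqn{y = \mu + G + C + E + G{\times}C + G{\times}E + C{\times}E +
#'       G{\times}C{\times}E + \epsilon}
#' where G is the (categorical) genotype at a designated causal marker, C the
#' cytoplasm class and E the environment. Each term named in `effect_spec` is
#' rescaled so that its realised variance share of the total equals the target
#' fraction exactly, which makes parameter-recovery tests sharp.
#'
#' @param seed integer seed; identical configurations give identical output.
#' @param n_plants_per_cytoplasm plants per cytoplasm class per environment.
#' @param n_markers number of markers to simulate (ignored when `marker_map`
#'   is supplied).
#' @param marker_map data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`; defaults to `n_markers` markers spread over chromosomes
#'   1H-7H.
#' @param environments character vector of environment labels (default two).
#' @param effect_spec named numeric vector of target variance fractions, names
#'   among `G, C, E, GxC, GxE, CxE, GxCxE`; fractions must sum to < 1.
#' @param residual_sd residual standard deviation in trait units.
#' @param segregation_distortion optional named list mapping marker ids to a
#'   genotype-frequency triple (AA, AB, BB) summing to 1; unlisted markers
#'   segregate 1:2:1.
#' @param trait_names character vector of trait labels to generate.
#' @param population population label attached to all rows.
#' @param causal_marker marker whose genotype enters the trait model (default
#'   the first marker in the map).
#' @param grand_mean trait grand mean.
#' @param genotype_coding `"categorical"` (three-level factor, the default) or
#'   `"additive"` (dosage 0/1/2 entering linearly).
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_reciprocal_f2()]
#' @export
sim_config <- function(seed = 1L,
                       n_plants_per_cytoplasm = 50L,
                       n_markers = 10L,
                       marker_map = NULL,
                       environments = c("E1", "E2"),
                       effect_spec = c(C = 0.05),
                       residual_sd = 1,
                       segregation_distortion = NULL,
                       trait_names = "trait1",
                       population = "POP1",
                       causal_marker = NULL,
                       grand_mean = 50,
                       genotype_coding = c("categorical", "additive")) {
  genotype_coding <- match.arg(genotype_coding)
  if (is.null(marker_map)) {
    stopifnot(is_count(n_markers))
    marker_map <- data.frame(
      marker_id = sprintf("M%03d", seq_len(n_markers)),
      chromosome = paste0(((seq_len(n_markers) - 1L) %% 7L) + 1L, "H"),
      position_bp = seq_len(n_markers) * 1e6,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("marker_id", "chromosome", "position_bp") %in% names(marker_map)))
  if (any(marker_map$position_bp < 0)) stopf("marker positions must be nonnegative")
  if (is.null(causal_marker)) causal_marker <- marker_map$marker_id[1L]
  if (!causal_marker %in% marker_map$marker_id) {
    stopf("causal_marker '%s' is not in the marker map", causal_marker)
  }
  if (!is_count(n_plants_per_cytoplasm, min = 2L)) {
    stopf("n_plants_per_cytoplasm must be an integer >= 2 (per environment)")
  }
  if (length(environments) < 1L) stopf("at least one environment is required")

  valid_terms <- c("G", "C", "E", "GxC", "GxE", "CxE", "GxCxE")
  effect_spec <- effect_spec[effect_spec != 0]
  if (length(effect_spec)) {
    bad <- setdiff(names(effect_spec), valid_terms)
    if (length(bad)) stopf("unknown model term(s) in effect_spec: %s", paste(bad, collapse = ", "))
    if (any(effect_spec < 0)) stopf("effect_spec fractions must be nonnegative")
  }
  if (sum(effect_spec) >= 1) {
    stopf(
      "effect_spec variance fractions sum to %.3f (>= 1): {%s}",
      sum(effect_spec),
      paste(sprintf("%s=%.3g", names(effect_spec), effect_spec), collapse = ", ")
    )
  }
  if (residual_sd < 0) stopf("residual_sd must be nonnegative")
  if (!is.null(segregation_distortion)) {
    for (m in names(segregation_distortion)) {
      tri <- segregation_distortion[[m]]
      if (length(tri) != 3L || any(tri < 0) || abs(sum(tri) - 1) > 1e-8) {
        stopf("segregation_distortion for marker '%s' must be a frequency triple summing to 1", m)
      }
    }
  }

  structure(
    list(
      seed = as.integer(seed),
      n_plants_per_cytoplasm = as.integer(n_plants_per_cytoplasm),
      marker_map = marker_map,
      environments = as.character(environments),
      effect_spec = effect_spec,
      residual_sd = residual_sd,
      segregation_distortion = segregation_distortion,
      trait_names = as.character(trait_names),
      population = population,
      causal_marker = causal_marker,
      grand_mean = grand_mean,
      genotype_coding = genotype_coding
    ),
    class = "sim_config"
  )
}

# Project a k-dimensional effect array onto the interaction-contrast subspace:
# after centering along every axis, the array sums to zero over each level of
# each involved factor, so e.g. a GxCxE pattern contributes nothing to the
# C or GxE margins of a balanced design.
center_all_margins <- function(arr) {
  d <- dim(arr)
  if (is.null(d) || length(d) == 1L) return(arr - mean(arr))
  for (ax in seq_along(d)) {
    m <- apply(arr, setdiff(seq_along(d), ax), mean)
    arr <- sweep(arr, setdiff(seq_along(d), ax), m, "-")
  }
  arr
}

term_factors <- function(term) {
  switch(term,
    G = "G", C = "C", E = "E",
    GxC = c("G", "C"), GxE = c("G", "E"), CxE = c("C", "E"),
    GxCxE = c("G", "C", "E")
  )
}

#' Simulate a reciprocal F2 population with known variance shares
#'
#' Generates a genotype table (independent markers segregating 1:2:1 unless
#' distorted) and a long-format trait table in which each model term's realised
#' variance share matches the configured target. Every plant carries the
#' maternal cytoplasm of its sub-cross; the two reciprocal halves are balanced
#' within each environment.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (plant_id, marker_id, call,
#'   chromosome, position_bp; calls are `"AA"`, `"AB"`, `"BB"`) and `traits`
#'   (unit_id, population, cytoplasm_class, environment, trait, value).
#' @export
simulate_reciprocal_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    envs <- config$environments
    n_cell <- config$n_plants_per_cytoplasm
    design <- expand.grid(
      rep = seq_len(n_cell),
      cytoplasm_class = c("wild", "cultivated"),
      environment = envs,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    n <- nrow(design)
    design$plant_id <- sprintf("%s_P%05d", config$population, seq_len(n))

    # genotypes: markers independent, multinomial calls per plant
    calls <- c("AA", "AB", "BB")
    geno <- lapply(seq_len(nrow(config$marker_map)), function(j) {
      m <- config$marker_map$marker_id[j]
      p <- config$segregation_distortion[[m]]
      if (is.null(p)) p <- c(0.25, 0.5, 0.25)
      data.frame(
        plant_id = design$plant_id,
        marker_id = m,
        call = sample(calls, n, replace = TRUE, prob = p),
        chromosome = config$marker_map$chromosome[j],
        position_bp = config$marker_map$position_bp[j],
        stringsAsFactors = FALSE
      )
    })
    genotypes <- do.call(rbind, geno)

    g_call <- genotypes$call[genotypes$marker_id == config$causal_marker]
    fac <- list(
      G = factor(g_call, levels = calls),
      C = factor(design$cytoplasm_class, levels = c("wild", "cultivated")),
      E = factor(design$environment, levels = envs)
    )

    fr <- config$effect_spec
    f_res <- 1 - sum(fr)
    total_var <- if (config$residual_sd > 0) config$residual_sd^2 / f_res else 1

    traits <- lapply(config$trait_names, function(tr) {
      contrib <- numeric(n)
      for (term in names(fr)) {
        fs <- term_factors(term)
        dims <- vapply(fac[fs], nlevels, 1L)
        raw <- array(stats::rnorm(prod(dims)), dim = dims)
        eff <- center_all_margins(raw)
        idx <- do.call(cbind, lapply(fac[fs], as.integer))
        v <- eff[idx]
        if (term == "G" && config$genotype_coding == "additive") {
          dose <- as.integer(fac$G) - 1L
          v <- dose * stats::rnorm(1)
        }
        v <- v - mean(v)
        s <- sd_pop(v)
        if (s == 0) {
          warnf("term %s has no realised variation for trait '%s'; contribution dropped", term, tr)
          next
        }
        contrib <- contrib + v * sqrt(fr[[term]] * total_var) / s
      }
      eps <- stats::rnorm(n)
      if (config$residual_sd > 0) {
        eps <- eps - mean(eps)
        eps <- eps * config$residual_sd / sd_pop(eps)
      } else {
        eps <- numeric(n)
      }
      data.frame(
        unit_id = design$plant_id,
        population = config$population,
        cytoplasm_class = design$cytoplasm_class,
        environment = design$environment,
        trait = tr,
        value = config$grand_mean + contrib + eps,
        stringsAsFactors = FALSE
      )
    })
    list(genotypes = genotypes, traits = do.call(rbind, traits))
  })
}

#' Configuration for synthetic NIR spectra
#'
#' Spectra are generated as nonnegative mixtures of composition-linked Gaussian
#' absorbance bands on a regular wavelength grid (default 400-2500 nm at 0.5-nm
#' steps, log(1/R) units), plus a fixed polynomial baseline shared by all
#' samples, per-sample multiplicative and additive scatter, and white noise.
#' The true analyte concentrations are returned as the wet-chemistry reference.
#'
#' @param seed integer seed.
#' @param n_samples number of samples.
#' @param wavelength_start,wavelength_stop,wavelength_step grid in nm.
#' @param analytes analyte names.
#' @param band_centers named list, nm positions of each analyte's bands.
#' @param band_widths named list, Gaussian band widths (nm), all > 0.
#' @param composition_ranges named list of `c(min, max)` percentages in
#'   `[0, 100]`.
#' @param band_amplitude absorbance units contributed per 1% concentration at
#'   a band centre.
#' @param scatter_multiplicative_sd,scatter_additive_sd per-sample affine
#'   scatter; set both to 0 for scatter-free spectra.
#' @param baseline_poly_degree degree of the shared polynomial baseline.
#' @param noise_sd white-noise standard deviation (absorbance units).
#' @return an object of class `spectra_sim_config`.
#' @export
spectra_sim_config <- function(seed = 1L,
                               n_samples = 200L,
                               wavelength_start = 400,
                               wavelength_stop = 2500,
                               wavelength_step = 0.5,
                               analytes = c("protein", "fat", "ash", "moisture"),
                               band_centers = list(
                                 protein = c(2054, 2174),
                                 fat = c(1734, 2310),
                                 ash = c(1680, 2100),
                                 moisture = c(1450, 1940)
                               ),
                               band_widths = list(
                                 protein = c(35, 45),
                                 fat = c(30, 40),
                                 ash = c(50, 60),
                                 moisture = c(40, 55)
                               ),
                               composition_ranges = list(
                                 protein = c(8, 20),
                                 fat = c(1, 4),
                                 ash = c(1, 3.5),
                                 moisture = c(8, 14)
                               ),
                               band_amplitude = 0.05,
                               scatter_multiplicative_sd = 0.05,
                               scatter_additive_sd = 0.02,
                               baseline_poly_degree = 2L,
                               noise_sd = 0.001) {
  if (wavelength_stop <= wavelength_start || wavelength_step <= 0) {
    stopf("invalid wavelength grid")
  }
  analytes <- as.character(analytes)
  for (a in analytes) {
    if (is.null(band_centers[[a]]) || is.null(band_widths[[a]]) ||
        is.null(composition_ranges[[a]])) {
      stopf("analyte '%s' needs band_centers, band_widths and composition_ranges", a)
    }
    if (length(band_centers[[a]]) != length(band_widths[[a]])) {
      stopf("analyte '%s': band_centers and band_widths differ in length", a)
    }
    if (any(band_widths[[a]] <= 0)) stopf("analyte '%s': band widths must be positive", a)
    rng <- composition_ranges[[a]]
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 100) {
      stopf("analyte '%s': composition range must lie in [0, 100]", a)
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_samples = as.integer(n_samples),
      wavelength_start = wavelength_start, wavelength_stop = wavelength_stop,
      wavelength_step = wavelength_step, analytes = analytes,
      band_centers = band_centers, band_widths = band_widths,
      composition_ranges = composition_ranges, band_amplitude = band_amplitude,
      scatter_multiplicative_sd = scatter_multiplicative_sd,
      scatter_additive_sd = scatter_additive_sd,
      baseline_poly_degree = as.integer(baseline_poly_degree),
      noise_sd = noise_sd
    ),
    class = "spectra_sim_config"
  )
}

#' Simulate NIR spectra with matching reference chemistry
#'
#' @param config a [spectra_sim_config()].
#' @return list with `spectra` (a [spectrum_set()]) and `reference` (data frame
#'   `sample_id` plus one column of true % per analyte).
#' @export
simulate_spectra <- function(config) {
  stopifnot(inherits(config, "spectra_sim_config"))
  with_seed(config$seed, {
    wl <- seq(config$wavelength_start, config$wavelength_stop,
              by = config$wavelength_step)
    n <- config$n_samples
    p <- length(wl)
    ids <- sprintf("S%04d", seq_len(n))

    conc <- sapply(config$analytes, function(a) {
      rng <- config$composition_ranges[[a]]
      stats::runif(n, rng[1], rng[2])
    })
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, config$analytes))

    pure <- sapply(config$analytes, function(a) {
      ctr <- config$band_centers[[a]]
      wdt <- config$band_widths[[a]]
      rowSums(sapply(seq_along(ctr), function(b) {
        exp(-(wl - ctr[b])^2 / (2 * wdt[b]^2))
      }))
    })
    pure <- matrix(pure, nrow = p)

    signal_mat <- (conc * config$band_amplitude) %*% t(pure)

    u <- (wl - config$wavelength_start) /
      (config$wavelength_stop - config$wavelength_start)
    base_coef <- stats::runif(config$baseline_poly_degree + 1L, 0, 0.2)
    baseline <- drop(outer(u, 0:config$baseline_poly_degree, `^`) %*% base_coef)

    mult <- 1 + stats::rnorm(n, 0, config$scatter_multiplicative_sd)
    addv <- stats::rnorm(n, 0, config$scatter_additive_sd)
    absorb <- sweep(signal_mat, 2, baseline, "+")
    absorb <- absorb * mult + addv
    if (config$noise_sd > 0) {
      absorb <- absorb + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    }
    stopifnot(all(is.finite(absorb)))

    list(
      spectra = spectrum_set(absorb, wl, ids),
      reference = data.frame(sample_id = ids, conc,
                             stringsAsFactors = FALSE, check.names = FALSE)
    )
  })
}

#' Simulate multi-day phenomics traits for one population
#'
#' Daily trait values for plants split between two cytoplasm classes. Traits
#' are organised in correlated blocks (equicorrelated within a block via a
#' shared latent factor per plant-day); cytoplasm effects are constant mean
#' shifts, expressed in residual-sd units, applied to the wild class on every
#' day.
#'
#' @param seed integer seed.
#' @param n_plants total plants (split as evenly as possible between classes;
#'   at least 2 per class).
#' @param n_days number of measurement days (>= 2).
#' @param trait_block_spec list of blocks, each `list(traits = <chr>, rho =
#'   <target within-block correlation in [0, 1)>)`.
#' @param cytoplasm_effect named numeric, mean shift of the wild class per
#'   trait in residual-sd units; traits not named get 0.
#' @param population population label.
#' @param residual_sd residual standard deviation (trait units).
#' @param day_start first day-after-transplanting label.
#' @param growth_per_day deterministic common daily increment (trait units).
#' @return data frame `plant_id, population, cytoplasm_class, day, trait,
#'   value`.
#' @export
simulate_phenomics <- function(seed,
                               n_plants,
                               n_days,
                               trait_block_spec,
                               cytoplasm_effect = numeric(),
                               population = "POP1",
                               residual_sd = 1,
                               day_start = 7L,
                               growth_per_day = 0.1) {
  if (!is_count(n_days, min = 2L)) stopf("n_days must be >= 2")
  n_wild <- floor(n_plants / 2)
  n_cult <- n_plants - n_wild
  if (n_wild < 2L || n_cult < 2L) stopf("need at least 2 plants per cytoplasm class")
  for (blk in trait_block_spec) {
    if (is.null(blk$traits) || is.null(blk$rho)) {
      stopf("each block needs $traits and $rho")
    }
    if (blk$rho < 0 || blk$rho >= 1) stopf("block correlation targets must lie in [0, 1)")
  }
  traits <- unlist(lapply(trait_block_spec, `[[`, "traits"))
  if (anyDuplicated(traits)) stopf("trait names duplicated across blocks")
  shift <- stats::setNames(rep(0, length(traits)), traits)
  shift[names(cytoplasm_effect)] <- cytoplasm_effect

  with_seed(seed, {
    plant_id <- sprintf("%s_PL%04d", population, seq_len(n_plants))
    cyto <- rep(c("wild", "cultivated"), c(n_wild, n_cult))
    days <- day_start + seq_len(n_days) - 1L
    base <- stats::setNames(10 + seq_along(traits), traits)

    rows <- vector("list", length(trait_block_spec))
    grid <- expand.grid(plant = seq_len(n_plants), day = days,
                        KEEP.OUT.ATTRS = FALSE)
    for (b in seq_along(trait_block_spec)) {
      blk <- trait_block_spec[[b]]
      z <- stats::rnorm(nrow(grid))  # latent factor per plant-day
      blk_rows <- lapply(blk$traits, function(tr) {
        eps <- stats::rnorm(nrow(grid))
        noise <- sqrt(blk$rho) * z + sqrt(1 - blk$rho) * eps
        val <- base[[tr]] + growth_per_day * (grid$day - day_start) +
          shift[[tr]] * residual_sd * (cyto[grid$plant] == "wild") +
          residual_sd * noise
        data.frame(
          plant_id = plant_id[grid$plant],
          population = population,
          cytoplasm_class = cyto[grid$plant],
          day = grid$day,
          trait = tr,
          value = val,
          stringsAsFactors = FALSE
        )
      })
      rows[[b]] <- do.call(rbind, blk_rows)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a percentile-bin distribution around a known median
#'
#' Emulates seed-analyzer output that reports each trait as percentage mass in
#' contiguous fractional bins. Mass follows a Gaussian centred on
#' `true_median` (sd of one bin width) discretised to the grid, with mild
#' random per-bin perturbation, then renormalised to 100.
#'
#' @param seed integer seed.
#' @param true_median target median in trait units.
#' @param bin_width bin width in trait units.
#' @param n_bins number of bins; the grid is centred on `true_median`.
#' @return a [bin_distribution()].
#' @export
simulate_marvin_bins <- function(seed, true_median, bin_width, n_bins = 20L) {
  if (!is_count(n_bins) || bin_width <= 0) stopf("invalid bin grid")
  start <- true_median - bin_width * n_bins / 2
  lower <- start + (seq_len(n_bins) - 1L) * bin_width
  upper <- lower + bin_width
  if (true_median < lower[1] || true_median > upper[n_bins]) {
    stopf("true_median %.3f lies outside the bin grid [%.3f, %.3f]",
          true_median, lower[1], upper[n_bins])
  }
  with_seed(seed, {
    mass <- stats::pnorm(upper, true_median, bin_width) -
      stats::pnorm(lower, true_median, bin_width)
    mass <- mass * stats::runif(n_bins, 0.8, 1.2)
    pct <- 100 * mass / sum(mass)
    bin_distribution(lower, upper, pct)
  })
}
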