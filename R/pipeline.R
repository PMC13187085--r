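# Stage dispatcher binding the modules into reproducible runs. Every run
# writes its resolved configuration (with provenance) beside its outputs.

#' Run one pipeline stage
#'
#' Dispatches to one of the analysis stages and writes the stage's artifacts
#' plus a resolved-configuration file (`<stage>_config.txt` carrying package
#' version, timestamp and a hash of the resolved parameters) into `out_dir`.
#'
#' Stages and their parameters:
#' \describe{
#'   \item{`simulate`}{`config` (a [sim_config()]); writes `genotypes.csv`
#'     and `traits.csv`.}
#'   \item{`effects`}{`traits` (path), optional `aggregate`, `outlier_k`;
#'     writes `effects.csv` (see [cytoplasm_effects()]).}
#'   \item{`gcxe`}{`traits`, `genotypes` (paths), optional `alpha`; writes
#'     `gcxe_records.csv` and `gcxe_tally.csv`.}
#'   \item{`phenomics`}{`table` (path), `populations` (length 2), optional
#'     `r_threshold`, `percentile`; writes `divergence.csv`.}
#'   \item{`derive-traits`}{`traits` (path to a wide per-sample CSV with
#'     `TGW`, `GWP`, `moisture` and analyte columns `protein`, `fat`, `ash`);
#'     writes `derived.csv` with the six mass-trait columns appended.}
#'   \item{`calibrate`}{`spectra`, `reference` (paths), `analyte`, optional
#'     `pretreatment` (a [pretreatment()]), `folds`, `iterations`,
#'     `ncomp_max`; writes `model_<analyte>.txt`.}
#'   \item{`predict`}{`model`, `spectra` (paths); writes `predictions.csv`.}
#' }
#'
#' @param stage stage name.
#' @param params named list of stage parameters.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in outputs and used by stochastic
#'   stages.
#' @return (invisibly) character vector of artifact paths.
#' @export
run_pipeline <- function(stage, params = list(), out_dir = ".", seed = 1L) {
  stages <- c("simulate", "effects", "gcxe", "phenomics", "derive-traits",
              "calibrate", "predict")
  if (!stage %in% stages) {
    stopf("unknown stage '%s'; available: %s", stage,
          paste(stages, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character()
  put <- function(name) file.path(out_dir, name)

  if (stage == "simulate") {
    cfg <- params$config
    if (is.null(cfg)) cfg <- sim_config(seed = seed)
    sim <- simulate_reciprocal_f2(cfg)
    write_table_csv(sim$genotypes, put("genotypes.csv"), seed = cfg$seed)
    write_table_csv(sim$traits, put("traits.csv"), seed = cfg$seed)
    art <- c(put("genotypes.csv"), put("traits.csv"))
    message(sprintf("[simulate] seed=%d plants=%d markers=%d traits=%d",
                    cfg$seed, length(unique(sim$traits$unit_id)),
                    length(unique(sim$genotypes$marker_id)),
                    length(unique(sim$traits$trait))))
  } else if (stage == "effects") {
    tab <- read_trait_table(params$traits)
    res <- cytoplasm_effects(
      tab,
      aggregate = if (is.null(params$aggregate)) "line" else params$aggregate,
      outlier_k = if (is.null(params$outlier_k)) 1.5 else params$outlier_k
    )
    write_table_csv(res, put("effects.csv"), seed = seed)
    art <- put("effects.csv")
    message(sprintf("[effects] seed=%d records=%d significant=%d",
                    seed, nrow(res), sum(res$significant, na.rm = TRUE)))
  } else if (stage == "gcxe") {
    tab <- read_trait_table(params$traits)
    gen <- read_genotype_table(params$genotypes)
    alpha <- if (is.null(params$alpha)) 0.01 else params$alpha
    recs <- gcxe_scan(tab, gen, alpha = alpha)
    map <- unique(gen[, intersect(c("marker_id", "chromosome", "position_bp"),
                                  names(gen)), drop = FALSE])
    tl <- tally_terms(recs, map)
    write_table_csv(recs, put("gcxe_records.csv"), seed = seed)
    write_table_csv(tl$counts, put("gcxe_tally.csv"), seed = seed)
    art <- c(put("gcxe_records.csv"), put("gcxe_tally.csv"))
    message(sprintf("[gcxe] seed=%d records=%d significant=%d",
                    seed, nrow(recs), sum(recs$significant, na.rm = TRUE)))
  } else if (stage == "phenomics") {
    tab <- read_phenomics_table(params$table)
    res <- cytoplasmic_divergence(
      tab, params$populations,
      r_threshold = if (is.null(params$r_threshold)) 0.95 else params$r_threshold,
      percentile = if (is.null(params$percentile)) 90 else params$percentile
    )
    write_table_csv(res, put("divergence.csv"), seed = seed)
    art <- put("divergence.csv")
    message(sprintf("[phenomics] seed=%d traits=%d divergent=%d",
                    seed, nrow(res), sum(res$is_divergent)))
  } else if (stage == "derive-traits") {
    df <- read_csv_checked(params$traits,
                           c("TGW", "GWP", "moisture", "protein", "fat", "ash"),
                           "per-sample trait")
    dm <- dry_matter(df$moisture)
    for (a in c("protein", "fat", "ash")) {
      df[[mass_trait_label(a, "1000")]] <- per_grain_mass(df$TGW, dm, df[[a]])
      df[[mass_trait_label(a, "P")]] <- per_plant_mass(df$GWP, dm, df[[a]])
    }
    write_table_csv(df, put("derived.csv"), seed = seed)
    art <- put("derived.csv")
    message(sprintf("[derive-traits] rows=%d", nrow(df)))
  } else if (stage == "calibrate") {
    spectra <- read_spectra_csv(params$spectra)
    reference <- read_reference_table(params$reference)
    analyte <- params$analyte
    if (is.null(analyte) || !analyte %in% names(reference)) {
      stopf("calibrate needs an 'analyte' present in the reference table")
    }
    spec <- if (is.null(params$pretreatment)) pretreatment() else params$pretreatment
    fitted_spec <- fit_pretreatment(spectra, spec)
    Xp <- as_spectrum_matrix(apply_pretreatment(spectra, fitted_spec))
    y <- reference[[analyte]][match(spectra$sample_ids, reference$sample_id)]
    keep <- !is.na(y)
    cv <- crossvalidate(Xp[keep, , drop = FALSE], y[keep],
                        ncomp_max = if (is.null(params$ncomp_max)) 10L else params$ncomp_max,
                        folds = if (is.null(params$folds)) 5L else params$folds,
                        iterations = if (is.null(params$iterations)) 5L else params$iterations,
                        seed = seed)
    k <- select_ncomp_one_sigma(cv$iterations[[length(cv$iterations)]],
                                override = params$ncomp_override)
    model <- pls_fit(Xp[keep, , drop = FALSE], y[keep], as.integer(k),
                     pretreatment = fitted_spec,
                     wavelengths = spectra$wavelengths)
    path <- put(sprintf("model_%s.txt", analyte))
    write_pls_model(model, path)
    art <- path
    message(sprintf("[calibrate] seed=%d analyte=%s ncomp=%d train_rmsep=%.4g",
                    seed, analyte, model$n_components,
                    model$training_stats$rmsep))
  } else if (stage == "predict") {
    model <- read_pls_model(params$model)
    spectra <- read_spectra_csv(params$spectra)
    pred <- pls_predict(model, spectra)
    res <- data.frame(sample_id = spectra$sample_ids, prediction = pred,
                      stringsAsFactors = FALSE)
    write_table_csv(res, put("predictions.csv"), seed = seed)
    art <- put("predictions.csv")
    message(sprintf("[predict] n=%d", nrow(res)))
  }

  resolved <- c(
    sprintf("stage: %s", stage),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("cytonuclear"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("params: %s", paste(deparse(params[setdiff(names(params), "config")]),
                                collapse = " "))
  )
  hash <- sum(utf8ToInt(paste(resolved, collapse = "\n"))) %% 1e9
  resolved <- c(resolved, sprintf("config_hash: %09.0f", hash),
                sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(resolved, put(sprintf("%s_config.txt", stage)))
  invisible(art)
}
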