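# CSV readers/writers. All tables are plain CSV; lines starting with '#' are
# comments (used to record the generating seed). Floating-point values are
# written with 10 significant digits so regression outputs are stable.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- tryCatch(
    suppressWarnings(
      utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE)
    ),
    error = function(e) stopf("failed to parse %s file '%s': %s", what, path,
                              conditionMessage(e))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s file '%s' lacks required column(s): expected {%s}, found {%s}",
          what, path, paste(required, collapse = ", "),
          paste(names(df), collapse = ", "))
  }
  df
}

#' Read a long-format trait table
#'
#' Required columns: `unit_id, population, cytoplasm_class, environment,
#' trait, value`. The value column is parsed as decimal; empty strings and
#' `NA` become missing. Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_trait_table <- function(path) {
  df <- read_csv_checked(path, c("unit_id", "population", "cytoplasm_class",
                                 "environment", "trait", "value"),
                         "trait table")
  df$value <- suppressWarnings(as.numeric(df$value))
  df
}

#' Read a genotype table
#'
#' Required columns: `plant_id, marker_id, call`; `chromosome` and
#' `position_bp` are carried when present.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_genotype_table <- function(path) {
  read_csv_checked(path, c("plant_id", "marker_id", "call"), "genotype table")
}

#' Read a daily phenomics table
#'
#' Required columns: `plant_id, population, cytoplasm_class, day, trait,
#' value`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_phenomics_table <- function(path) {
  df <- read_csv_checked(path, c("plant_id", "population", "cytoplasm_class",
                                 "day", "trait", "value"), "phenomics table")
  df$value <- suppressWarnings(as.numeric(df$value))
  df$day <- as.integer(df$day)
  df
}

#' Read a wet-chemistry reference table
#'
#' `sample_id` plus one numeric column per analyte (% units).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_reference_table <- function(path) {
  df <- read_csv_checked(path, "sample_id", "reference table")
  for (a in setdiff(names(df), "sample_id")) {
    df[[a]] <- suppressWarnings(as.numeric(df[[a]]))
  }
  df
}

#' Read a spectra matrix
#'
#' First column `sample_id`; remaining headers are numeric wavelengths in nm.
#'
#' @param path CSV path.
#' @return a [spectrum_set()].
#' @export
read_spectra_csv <- function(path) {
  df <- read_csv_checked(path, "sample_id", "spectra")
  wl <- suppressWarnings(as.numeric(setdiff(names(df), "sample_id")))
  if (anyNA(wl)) stopf("spectra file '%s': non-numeric wavelength header", path)
  mat <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(mat) <- "numeric"
  spectrum_set(mat, wl, df$sample_id)
}

#' Write a table as CSV with stable numeric formatting
#'
#' Numeric columns are written with 10 significant digits; an optional seed
#' is recorded as a leading comment line.
#'
#' @param df data frame.
#' @param path output CSV path.
#' @param seed optional integer recorded as `# seed: <seed>`.
#' @export
write_table_csv <- function(df, path, seed = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.10g", out[[j]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a spectrum set as CSV
#'
#' @param spectra a [spectrum_set()].
#' @param path output CSV path.
#' @param seed optional seed comment.
#' @export
write_spectra_csv <- function(spectra, path, seed = NULL) {
  df <- data.frame(sample_id = spectra$sample_ids,
                   spectra$absorbance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample_id", sprintf("%.10g", spectra$wavelengths))
  write_table_csv(df, path, seed)
}

#' Serialize a PLS model to a structured text file
#'
#' Single versioned text file holding the pretreatment steps (including any
#' frozen MSC reference), the wavelength grid, centers and coefficients.
#'
#' @param model a [pls_fit()] model.
#' @param path output path.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "cytonuclear_pls_model_version: 1",
    sprintf("n_components: %d", model$n_components),
    sprintf("intercept: %.17g", model$intercept),
    sprintf("y_center: %.17g", model$y_center)
  )
  steps <- if (is.null(model$pretreatment)) list() else model$pretreatment$steps
  lines <- c(lines, sprintf("n_steps: %d", length(steps)))
  for (s in steps) {
    lines <- c(lines, switch(s$type,
      snv = "step: snv",
      msc = c("step: msc", paste0("msc_reference: ", num(s$reference))),
      detrend = sprintf("step: detrend %d", s$degree),
      baseline = sprintf("step: baseline %s", s$method),
      sg = sprintf("step: sg %d %d %d", s$window, s$polyorder, s$deriv)
    ))
  }
  if (!is.null(model$wavelengths)) {
    lines <- c(lines, paste0("wavelengths: ", num(model$wavelengths)))
  }
  lines <- c(lines,
             paste0("x_center: ", num(model$x_center)),
             paste0("coefficients: ", num(model$coefficients)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized PLS model
#'
#' @param path path written by [write_pls_model()].
#' @return a `pls_model`.
#' @export
read_pls_model <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!identical(field("cytonuclear_pls_model_version"), "1")) {
    stopf("unrecognised model file format: %s", path)
  }
  nums <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  step_lines <- grep("^step: ", lines, value = TRUE)
  ref_lines <- grep("^msc_reference: ", lines, value = TRUE)
  ref_i <- 0L
  steps <- lapply(step_lines, function(sl) {
    parts <- strsplit(sub("^step: ", "", sl), " ")[[1]]
    switch(parts[1],
      snv = pt_snv(),
      msc = {
        ref_i <<- ref_i + 1L
        pt_msc(reference = nums(sub("^msc_reference: ", "", ref_lines[ref_i])))
      },
      detrend = pt_detrend(as.integer(parts[2])),
      baseline = pt_baseline(parts[2]),
      sg = pt_sg(as.integer(parts[2]), as.integer(parts[3]), as.integer(parts[4])),
      stopf("unknown step '%s' in model file", parts[1])
    )
  })
  coef <- nums(field("coefficients"))
  wl <- field("wavelengths")
  structure(
    list(
      coefficients = coef,
      intercept = as.numeric(field("intercept")),
      n_components = as.integer(field("n_components")),
      x_center = nums(field("x_center")),
      y_center = as.numeric(field("y_center")),
      pretreatment = if (length(steps)) pretreatment(steps) else NULL,
      wavelengths = if (is.null(wl)) NULL else nums(wl),
      training_stats = NULL
    ),
    class = "pls_model"
  )
}
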