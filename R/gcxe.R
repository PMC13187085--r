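# Marker-based G x C x E analysis: Mendelian segregation filtering, the
# three-way Type III ANOVA per marker x trait x population, and term tallies.

#' Filter markers by Mendelian 1:2:1 segregation
#'
#' Per marker, a chi-square test (2 df) of the non-missing genotype counts
#' against expected n/4 : n/2 : n/4; markers with `p < alpha` are removed.
#' Markers with all calls missing are dropped with a warning (they are not
#' counted as segregation failures).
#'
#' @param genotypes genotype table (`plant_id, marker_id, call, ...`) with
#'   calls in `AA, AB, BB` (anything else is treated as missing).
#' @param alpha rejection threshold (default 0.01).
#' @return character vector of retained marker ids; the per-marker test table
#'   is attached as attribute `tests` (`marker_id, n, chisq, p, kept`).
#' @export
segregation_filter <- function(genotypes, alpha = 0.01) {
  markers <- unique(genotypes$marker_id)
  rows <- lapply(markers, function(m) {
    calls <- genotypes$call[genotypes$marker_id == m]
    calls <- calls[calls %in% c("AA", "AB", "BB")]
    n <- length(calls)
    if (n == 0L) {
      warnf("marker '%s' has no non-missing calls; dropped", m)
      return(NULL)
    }
    obs <- c(sum(calls == "AA"), sum(calls == "AB"), sum(calls == "BB"))
    expc <- n * c(0.25, 0.5, 0.25)
    chisq <- sum((obs - expc)^2 / expc)
    p <- stats::pchisq(chisq, df = 2, lower.tail = FALSE)
    data.frame(marker_id = m, n = n, chisq = chisq, p = p, kept = p >= alpha,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  if (is.null(tests)) stopf("no marker with non-missing calls")
  structure(tests$marker_id[tests$kept], tests = tests)
}

#' Three-way marker x cytoplasm x environment ANOVA
#'
#' Fits `value ~ genotype * cytoplasm * environment` with Type III sums of
#' squares (sum-to-zero contrasts) for one population x trait x marker.
#' Genotype is a categorical factor with up to three levels. Terms made
#' inestimable by empty design cells are reported as undefined with a
#' warning, never silently dropped. Effect sizes, confidence bounds and the
#' significance gate reuse the two-way machinery.
#'
#' @param traits long trait table.
#' @param genotypes genotype table.
#' @param population,trait,marker the analysis cell.
#' @param ci_level,ci_two_sided confidence settings for eta-squared bounds.
#' @return effect-record data frame (terms `G, C, E, GxC, GxE, CxE, GxCxE`
#'   and `Residual`) with a `marker` column.
#' @export
anova_three_way <- function(traits, genotypes, population, trait, marker,
                            ci_level = 0.95, ci_two_sided = FALSE) {
  df <- traits[traits$population == population & traits$trait == trait &
                 !is.na(traits$value), , drop = FALSE]
  g <- genotypes[genotypes$marker_id == marker &
                   genotypes$call %in% c("AA", "AB", "BB"),
                 c("plant_id", "call")]
  if (!nrow(g)) stopf("marker '%s' has no usable calls", marker)
  df$genotype <- g$call[match(df$unit_id, g$plant_id)]
  df <- df[!is.na(df$genotype), , drop = FALSE]
  if (!nrow(df)) stopf("no genotyped observations for this cell")
  if (length(unique(df$genotype)) < 2L) {
    stopf("marker '%s' is monomorphic in population '%s'", marker, population)
  }
  for (marg in c("cytoplasm_class", "environment")) {
    tab <- table(df$genotype, df[[marg]])
    if (any(colSums(tab > 0) < 2L)) {
      stopf("fewer than 2 genotype classes in some %s level for marker '%s'",
            marg, marker)
    }
  }
  fit <- type3_ss(df, c("genotype", "cytoplasm_class", "environment"))
  term_map <- c(
    "genotype" = "G", "cytoplasm_class" = "C", "environment" = "E",
    "genotype:cytoplasm_class" = "GxC", "genotype:environment" = "GxE",
    "cytoplasm_class:environment" = "CxE",
    "genotype:cytoplasm_class:environment" = "GxCxE"
  )
  rec <- build_effect_records(fit, term_map, population, trait,
                              ci_level, ci_two_sided)
  rec$marker <- marker
  rec[, c("population", "trait", "marker", setdiff(names(rec), c("population", "trait", "marker")))]
}

#' Run the full marker scan for one panel
#'
#' Applies [segregation_filter()], then [anova_three_way()] for every
#' population x trait x retained marker, collecting all effect records. The
#' number of model fits is reported so users can judge the (uncorrected)
#' multiplicity of tests.
#'
#' @param traits long trait table.
#' @param genotypes genotype table.
#' @param alpha segregation-filter threshold.
#' @param verbose print the test count.
#' @return effect-record data frame across all cells.
#' @export
gcxe_scan <- function(traits, genotypes, alpha = 0.01, verbose = TRUE) {
  kept <- segregation_filter(genotypes, alpha)
  combos <- unique(traits[, c("population", "trait")])
  out <- list()
  n_tests <- 0L
  for (i in seq_len(nrow(combos))) {
    for (m in kept) {
      rec <- tryCatch(
        anova_three_way(traits, genotypes, combos$population[i],
                        combos$trait[i], m),
        error = function(e) NULL
      )
      if (!is.null(rec)) {
        out[[length(out) + 1L]] <- rec
        n_tests <- n_tests + 1L
      }
    }
  }
  if (verbose) {
    message(sprintf("gcxe_scan: %d marker x trait x population models fitted (no cross-marker multiplicity correction applied)", n_tests))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally gate-passing terms by class, chromosome and population
#'
#' Counts significant records for the marker-involving term classes
#' (G, GxC, GxE, GxCxE) by chromosome and population, and reports, per trait,
#' the marker with the maximum eta squared among significant G terms.
#'
#' @param records effect records from [anova_three_way()]/[gcxe_scan()].
#' @param marker_map data frame `marker_id, chromosome` (positions optional).
#' @return list with `counts` (term, chromosome, population, n) and
#'   `max_g_eta2` (trait, marker_id, eta2).
#' @export
tally_terms <- function(records, marker_map) {
  gterms <- c("G", "GxC", "GxE", "GxCxE")
  sig <- records[!is.na(records$significant) & records$significant &
                   records$term %in% gterms, , drop = FALSE]
  if (!all(sig$marker %in% marker_map$marker_id)) {
    stopf("records carry marker ids missing from the marker map")
  }
  if (nrow(sig) == 0L) {
    return(list(
      counts = data.frame(term = character(), chromosome = character(),
                          population = character(), n = integer()),
      max_g_eta2 = data.frame(trait = character(), marker_id = character(),
                              eta2 = numeric())
    ))
  }
  sig$chromosome <- marker_map$chromosome[match(sig$marker, marker_map$marker_id)]
  counts <- stats::aggregate(
    list(n = rep(1L, nrow(sig))),
    by = list(term = sig$term, chromosome = sig$chromosome,
              population = sig$population),
    FUN = sum
  )
  gsig <- sig[sig$term == "G", , drop = FALSE]
  max_g <- if (nrow(gsig)) {
    do.call(rbind, lapply(split(gsig, gsig$trait), function(d) {
      best <- d[which.max(d$eta2), ]
      data.frame(trait = best$trait, marker_id = best$marker, eta2 = best$eta2,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(trait = character(), marker_id = character(), eta2 = numeric())
  }
  rownames(max_g) <- NULL
  list(counts = counts, max_g_eta2 = max_g)
}
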