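# Phenomics divergence: correlation pruning, per-day Cohen's d, significance
# weighting, cross-population divergence and percentile thresholding.

#' Correlation-based trait pruning
#'
#' Greedy pass in input trait order: a trait is kept iff its absolute
#' pairwise-complete Pearson correlation with every already-kept trait is
#' below `r_threshold`. Per-trait vectors are assembled over all plant x day
#' observations. Zero-variance traits are dropped with a warning before
#' pruning.
#'
#' @param table phenomics table (`plant_id, population, cytoplasm_class, day,
#'   trait, value`).
#' @param r_threshold absolute-correlation threshold (default 0.95).
#' @param trait_order optional explicit ordering; defaults to first
#'   appearance in the table.
#' @return character vector of kept traits.
#' @export
prune_correlated <- function(table, r_threshold = 0.95, trait_order = NULL) {
  traits <- if (is.null(trait_order)) unique(table$trait) else trait_order
  if (length(traits) < 2L) stopf("need at least 2 traits to prune")
  key <- paste(table$plant_id, table$day, sep = "\r")
  obs <- sort(unique(key))
  M <- matrix(NA_real_, length(obs), length(traits),
              dimnames = list(obs, traits))
  M[cbind(match(key, obs), match(table$trait, traits))] <- table$value

  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  degen <- is.na(sds) | sds == 0
  if (any(degen)) {
    warnf("dropping zero-variance trait(s) before pruning: %s",
          paste(traits[degen], collapse = ", "))
    traits <- traits[!degen]
    M <- M[, traits, drop = FALSE]
  }
  kept <- character()
  for (tr in traits) {
    ok <- TRUE
    for (kp in kept) {
      r <- suppressWarnings(
        stats::cor(M[, tr], M[, kp], use = "pairwise.complete.obs")
      )
      if (!is.na(r) && abs(r) >= r_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, tr)
  }
  kept
}

#' Cohen's d between cytoplasm groups
#'
#' `d = (mean_wild - mean_cultivated) / s_pooled`, with the pooled standard
#' deviation weighting the two sample variances by their degrees of freedom.
#'
#' @param group_wild,group_cultivated numeric vectors, each with at least 2
#'   values.
#' @return signed effect size; `NA` with a warning when the pooled sd is 0.
#' @export
cohens_d <- function(group_wild, group_cultivated) {
  x <- group_wild[!is.na(group_wild)]
  y <- group_cultivated[!is.na(group_cultivated)]
  if (length(x) < 2L || length(y) < 2L) stopf("need at least 2 values per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) {
    warnf("pooled standard deviation is zero; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Significance-weighted effect size
#'
#' The per-day effect sizes are averaged (unweighted mean) and multiplied by
#' the fraction of days whose two-sided pooled-variance t-test is significant
#' at `alpha`.
#'
#' @param per_day_d per-day Cohen's d values.
#' @param per_day_p matching per-day t-test p-values.
#' @param alpha per-day significance level (default 0.05).
#' @return weighted effect size.
#' @export
weighted_effect <- function(per_day_d, per_day_p, alpha = 0.05) {
  if (!length(per_day_d) || length(per_day_d) != length(per_day_p)) {
    stopf("per_day_d and per_day_p must be non-empty and of equal length")
  }
  ok <- !is.na(per_day_d) & !is.na(per_day_p)
  if (!any(ok)) stopf("no usable days")
  mean(per_day_d[ok]) * mean(per_day_p[ok] < alpha)
}

#' Divergence between two populations' weighted effects
#'
#' @param w_pop_a,w_pop_b weighted effect sizes of the same trait in two
#'   populations.
#' @return `|w_pop_a - w_pop_b|`.
#' @export
divergence <- function(w_pop_a, w_pop_b) {
  if (is.na(w_pop_a) || is.na(w_pop_b)) stopf("both weighted effects must be defined")
  abs(w_pop_a - w_pop_b)
}

# per-trait, per-population weighted effect from a phenomics table
weighted_effect_for <- function(table, population, trait, alpha = 0.05,
                                wild_class = "wild", cultivated_class = "cultivated") {
  df <- table[table$population == population & table$trait == trait &
                !is.na(table$value), , drop = FALSE]
  days <- sort(unique(df$day))
  d <- p <- rep(NA_real_, length(days))
  for (i in seq_along(days)) {
    w <- df$value[df$day == days[i] & df$cytoplasm_class == wild_class]
    cu <- df$value[df$day == days[i] & df$cytoplasm_class == cultivated_class]
    if (length(w) < 2L || length(cu) < 2L) next
    di <- tryCatch(cohens_d(w, cu), warning = function(cnd) NA_real_)
    if (is.na(di)) {
      warnf("day %s skipped for trait '%s' (%s): degenerate groups",
            days[i], trait, population)
      next
    }
    d[i] <- di
    p[i] <- stats::t.test(w, cu, var.equal = TRUE)$p.value
  }
  weighted_effect(d, p, alpha)
}

#' Flag divergent traits against a percentile threshold
#'
#' The threshold is the empirical `percentile` (type-7 quantile) of all
#' divergences; a trait is divergent iff its divergence strictly exceeds it.
#'
#' @param records data frame with a `divergence` column (>= 2 rows).
#' @param percentile threshold percentile (default 90).
#' @return the records with `threshold` and `is_divergent` columns added.
#' @export
classify_divergent <- function(records, percentile = 90) {
  if (nrow(records) < 2L) stopf("need at least 2 divergence records")
  thr <- quantile7(records$divergence, percentile / 100)
  records$threshold <- thr
  records$is_divergent <- records$divergence > thr
  records
}

#' Cross-population cytoplasmic divergence analysis
#'
#' The full phenomics workflow: correlation pruning over the pooled table,
#' per-day Cohen's d and pooled-variance t-tests within each population,
#' significance weighting, absolute divergence between the two populations,
#' and percentile thresholding.
#'
#' @param table phenomics table covering exactly the two populations to
#'   compare.
#' @param populations character vector of the two population labels.
#' @param r_threshold pruning threshold (default 0.95).
#' @param percentile divergence threshold percentile (default 90).
#' @param alpha per-day t-test level (default 0.05).
#' @return data frame, one row per kept trait, sorted by divergence
#'   descending: `trait, w_<popA>, w_<popB>, divergence, threshold,
#'   is_divergent`.
#' @export
cytoplasmic_divergence <- function(table, populations, r_threshold = 0.95,
                                   percentile = 90, alpha = 0.05) {
  if (length(populations) != 2L) stopf("exactly 2 populations are required")
  sub <- table[table$population %in% populations, , drop = FALSE]
  kept <- prune_correlated(sub, r_threshold)
  recs <- lapply(kept, function(tr) {
    wa <- weighted_effect_for(sub, populations[1], tr, alpha)
    wb <- weighted_effect_for(sub, populations[2], tr, alpha)
    data.frame(trait = tr, w_pop_a = wa, w_pop_b = wb,
               divergence = divergence(wa, wb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  names(out)[2:3] <- paste0("w_", populations)
  out <- classify_divergent(out, percentile)
  out <- out[order(-out$divergence), ]
  rownames(out) <- NULL
  out
}
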