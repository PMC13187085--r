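# Cytoplasm x environment effect models: asymmetric outlier removal,
# aggregation, Type III ANOVA, eta-squared with noncentral-F confidence
# bounds, the three-condition significance gate, and the Delta% summary.

#' Asymmetric boxplot outlier mask
#'
#' Fences are built from median-split semi-interquartile ranges:
#' `lower = Q1 - 2k(Q2 - Q1)` and `upper = Q3 + 2k(Q3 - Q2)` (type-7
#' quantiles), so a skewed tail widens its own fence. With symmetric quartiles
#' this reduces to the ordinary `k * IQR` rule. When the IQR is zero nothing
#' is removed. Missing values are kept (they carry no evidence either way).
#'
#' @param values numeric vector, at least 5 non-missing values.
#' @param k fence multiplier (default 1.5).
#' @return logical keep-mask, same length as `values`.
#' @export
remove_outliers_asymmetric <- function(values, k = 1.5) {
  x <- values[!is.na(values)]
  if (length(x) < 5L) stopf("need at least 5 non-missing values")
  q <- quantile7(x, c(0.25, 0.5, 0.75))
  if (q[3] - q[1] == 0) return(rep(TRUE, length(values)))
  lower <- q[1] - 2 * k * (q[2] - q[1])
  upper <- q[3] + 2 * k * (q[3] - q[2])
  is.na(values) | (values >= lower & values <= upper)
}

#' Outlier removal over a long trait table
#'
#' Applies [remove_outliers_asymmetric()] separately within every
#' environment x population combination, per trait. Groups too small for the
#' rule (< 5 values) are left untouched.
#'
#' @param table long trait table (`unit_id, population, cytoplasm_class,
#'   environment, trait, value`).
#' @param k fence multiplier.
#' @return the table with outlying rows dropped.
#' @export
remove_outliers_table <- function(table, k = 1.5) {
  key <- interaction(table$environment, table$population, table$trait, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(table)), key), function(ix) {
    v <- table$value[ix]
    if (sum(!is.na(v)) < 5L) return(ix)
    ix[remove_outliers_asymmetric(v, k)]
  }), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate replicate observations to line means
#'
#' Line-level panels (fixed lines grown in replicated plots) are reduced to a
#' single mean per unit x environment x trait; plant-level panels (each
#' individual a unique genotype) are used as-is.
#'
#' @param table long trait table.
#' @param level `"line"` (aggregate) or `"plant"` (identity).
#' @return aggregated trait table.
#' @export
aggregate_line_means <- function(table, level = c("line", "plant")) {
  level <- match.arg(level)
  if (level == "plant") return(table)
  agg <- stats::aggregate(
    value ~ unit_id + population + cytoplasm_class + environment + trait,
    data = table, FUN = mean, na.rm = TRUE, na.action = stats::na.pass
  )
  agg[order(agg$trait, agg$environment, agg$unit_id), c(
    "unit_id", "population", "cytoplasm_class", "environment", "trait", "value"
  )] -> out
  rownames(out) <- NULL
  out
}

# ---- Type III engine ------------------------------------------------------

# Type III sums of squares by full-vs-reduced least-squares comparison in the
# sum-to-zero parameterisation: for each term, its columns are removed from
# the full design (all other terms, including higher-order interactions,
# retained) and SS = RSS(reduced) - RSS(full).
type3_ss <- function(df, factors, response = "value") {
  for (fc in factors) df[[fc]] <- droplevels(factor(df[[fc]]))
  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  mm <- stats::model.matrix(form, df, contrasts.arg = contr)
  y <- df[[response]]
  full <- stats::lm.fit(mm, y)
  rss_full <- sum(full$residuals^2)
  rank_full <- full$rank
  df_res <- nrow(df) - rank_full
  aliased <- rank_full < ncol(mm)
  labels <- attr(stats::terms(form), "term.labels")
  asn <- attr(mm, "assign")

  rows <- lapply(seq_along(labels), function(ti) {
    keep <- asn != ti
    ncols <- sum(!keep)
    red <- stats::lm.fit(mm[, keep, drop = FALSE], y)
    df_t <- rank_full - red$rank
    estimable <- !aliased || df_t == ncols
    ss <- sum(red$residuals^2) - rss_full
    if (!estimable) {
      warnf("term %s is not estimable (empty design cell); reported as undefined",
            labels[ti])
      return(data.frame(term = labels[ti], SS = NA_real_, df = df_t,
                        F = NA_real_, p = NA_real_))
    }
    ms_res <- rss_full / df_res
    fval <- if (df_t > 0 && ms_res > 0) (ss / df_t) / ms_res else NA_real_
    pval <- if (is.finite(fval)) stats::pf(fval, df_t, df_res, lower.tail = FALSE) else NA_real_
    data.frame(term = labels[ti], SS = ss, df = df_t, F = fval, p = pval)
  })
  tab <- do.call(rbind, rows)
  list(terms = tab, rss = rss_full, df_res = df_res,
       ss_total = sum((y - mean(y))^2), n = nrow(df))
}

#' Confidence bounds for eta squared
#'
#' Inverts the noncentral-F distribution (pivoting on the noncentrality
#' parameter) at the observed F statistic, then maps the noncentrality bound
#' to the eta-squared scale via `eta2 = ncp / (ncp + df1 + df2 + 1)`. The
#' default is a one-sided interval: only the lower bound is estimated and the
#' upper bound is 1, matching a significance rule that uses the lower bound
#' alone.
#'
#' @param f_value observed F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param level confidence level (default 0.95).
#' @param two_sided if `TRUE`, return a central two-sided interval.
#' @return numeric `c(ci_low, ci_high)`; `c(NA, NA)` for nonfinite F.
#' @export
eta_squared_ci <- function(f_value, df1, df2, level = 0.95, two_sided = FALSE) {
  if (!is.finite(f_value) || f_value < 0 || !is.finite(df1) || !is.finite(df2) ||
      df1 < 1 || df2 < 1) {
    return(c(NA_real_, NA_real_))
  }
  p_low <- if (two_sided) (1 + level) / 2 else level
  lo <- ncp_bound(f_value, df1, df2, p_low)
  hi <- if (two_sided) ncp_bound(f_value, df1, df2, (1 - level) / 2) else Inf
  eta <- function(ncp) if (is.infinite(ncp)) 1 else ncp / (ncp + df1 + df2 + 1)
  c(eta(lo), eta(hi))
}

# largest ncp (0 if none) with P(F_{df1,df2,ncp} <= f_obs) >= prob.
# pf() emits pnbeta convergence warnings at extreme ncp; they only affect
# digits far beyond the bound's use, so they are silenced here.
ncp_bound <- function(f_obs, df1, df2, prob) {
  g <- function(ncp) suppressWarnings(stats::pf(f_obs, df1, df2, ncp = ncp)) - prob
  if (g(0) <= 0) return(0)
  # pnbeta degrades (and slows drastically) for enormous noncentrality; cap
  # the search at 1e6, where the eta2 bound is already ~0.9999
  cap <- 1e6
  if (g(cap) > 0) return(cap)
  hi <- min(max(1, f_obs * df1), cap)
  while (g(hi) > 0) hi <- min(hi * 2, cap)
  stats::uniroot(g, c(0, hi), tol = 1e-8)$root
}

#' Three-condition significance gate
#'
#' A model term is treated as significant only when all of `p <= alpha`,
#' `eta2 >= eta2_min` and `ci_low > 0` hold. Undefined inputs fail the gate.
#'
#' @param p p-value of the term.
#' @param eta2 eta-squared point estimate.
#' @param ci_low lower confidence bound for eta squared.
#' @param alpha p-value threshold (default 0.05).
#' @param eta2_min minimum effect size (default 0.01, i.e. 1%).
#' @return logical.
#' @export
significance_gate <- function(p, eta2, ci_low, alpha = 0.05, eta2_min = 0.01) {
  ok <- !is.na(p) & !is.na(eta2) & !is.na(ci_low) &
    p <= alpha & eta2 >= eta2_min & ci_low > 0
  ok
}

# shared record builder for the two ANOVA engines
build_effect_records <- function(fit, term_map, population, trait,
                                 ci_level = 0.95, ci_two_sided = FALSE) {
  ss_total <- fit$ss_total
  degenerate <- ss_total <= 0
  recs <- lapply(seq_len(nrow(fit$terms)), function(i) {
    row <- fit$terms[i, ]
    eta2 <- if (degenerate || is.na(row$SS)) NA_real_ else max(row$SS, 0) / ss_total
    ci <- if (is.na(row$F)) c(NA_real_, NA_real_) else {
      eta_squared_ci(row$F, row$df, fit$df_res, level = ci_level,
                     two_sided = ci_two_sided)
    }
    data.frame(
      population = population, trait = trait,
      term = unname(term_map[row$term]),
      SS = row$SS, df = row$df, F = row$F, p = row$p,
      eta2 = eta2, eta2_ci_low = ci[1], eta2_ci_high = ci[2],
      significant = significance_gate(row$p, eta2, ci[1]),
      stringsAsFactors = FALSE
    )
  })
  resid <- data.frame(
    population = population, trait = trait, term = "Residual",
    SS = fit$rss, df = fit$df_res, F = NA_real_, p = NA_real_,
    eta2 = if (degenerate) NA_real_ else fit$rss / ss_total,
    eta2_ci_low = NA_real_, eta2_ci_high = NA_real_, significant = NA,
    stringsAsFactors = FALSE
  )
  out <- rbind(do.call(rbind, recs), resid)
  rownames(out) <- NULL
  out
}

#' Two-way cytoplasm x environment ANOVA
#'
#' Fits `value ~ cytoplasm * environment` with Type III sums of squares
#' (sum-to-zero contrasts) for one population x trait and returns one effect
#' record per term (C, E, CxE) plus the residual row. Eta squared is
#' `SS_term / SS_total` (total corrected sum of squares); its lower confidence
#' bound comes from [eta_squared_ci()] and feeds the [significance_gate()].
#'
#' @param table long trait table.
#' @param population,trait the population x trait cell to analyse.
#' @param ci_level,ci_two_sided confidence settings for the eta-squared bound.
#' @return data frame of effect records (`population, trait, term, SS, df, F,
#'   p, eta2, eta2_ci_low, eta2_ci_high, significant`).
#' @export
anova_two_way <- function(table, population, trait,
                          ci_level = 0.95, ci_two_sided = FALSE) {
  df <- table[table$population == population & table$trait == trait &
                !is.na(table$value), , drop = FALSE]
  if (!nrow(df)) stopf("no data for population '%s', trait '%s'", population, trait)
  cy <- unique(df$cytoplasm_class)
  en <- unique(df$environment)
  if (length(cy) != 2L) stopf("expected exactly 2 cytoplasm classes, found %d", length(cy))
  if (length(en) < 2L) stopf("expected at least 2 environments, found %d", length(en))
  counts <- table(df$cytoplasm_class, df$environment)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stopf("empty design cell: cytoplasm '%s' x environment '%s'",
          rownames(counts)[empty[1]], colnames(counts)[empty[2]])
  }
  fit <- type3_ss(df, c("cytoplasm_class", "environment"))
  term_map <- c("cytoplasm_class" = "C", "environment" = "E",
                "cytoplasm_class:environment" = "CxE")
  build_effect_records(fit, term_map, population, trait, ci_level, ci_two_sided)
}

#' Cytoplasmic percentage change
#'
#' `Delta% = mean over environments of 100 * (mu_wild - mu_cultivated) /
#' mu_cultivated`, where the means are per-environment cytoplasm-class trait
#' means.
#'
#' @inheritParams anova_two_way
#' @param wild_class,cultivated_class the two cytoplasm labels.
#' @return numeric Delta% (the per-environment values are attached as
#'   attribute `per_environment`).
#' @export
delta_percent <- function(table, population, trait,
                          wild_class = "wild", cultivated_class = "cultivated") {
  df <- table[table$population == population & table$trait == trait &
                !is.na(table$value), , drop = FALSE]
  if (!nrow(df)) stopf("no data for population '%s', trait '%s'", population, trait)
  envs <- unique(df$environment)
  per_env <- vapply(envs, function(e) {
    mw <- mean(df$value[df$environment == e & df$cytoplasm_class == wild_class])
    mc <- mean(df$value[df$environment == e & df$cytoplasm_class == cultivated_class])
    if (!is.finite(mc) || mc == 0) {
      stopf("cultivated mean is zero or undefined in environment '%s'", e)
    }
    100 * (mw - mc) / mc
  }, 0)
  structure(mean(per_env), per_environment = stats::setNames(per_env, envs))
}

#' Full cytoplasmic-effect analysis for a trait panel
#'
#' The standard pipeline for one panel: per-trait asymmetric outlier removal
#' within environment x population, optional aggregation to line means,
#' Type III two-way ANOVA per population x trait, and the Delta% summary
#' merged onto the cytoplasm rows.
#'
#' @param table long trait table.
#' @param aggregate `"line"` or `"plant"` (see [aggregate_line_means()]).
#' @param outlier_k fence multiplier for [remove_outliers_asymmetric()];
#'   `NULL` skips outlier removal.
#' @param ci_level,ci_two_sided passed to [anova_two_way()].
#' @return effect-record data frame across all populations x traits, with a
#'   `delta_pct` column populated on cytoplasm (C) rows.
#' @export
cytoplasm_effects <- function(table, aggregate = c("line", "plant"),
                              outlier_k = 1.5, ci_level = 0.95,
                              ci_two_sided = FALSE) {
  aggregate <- match.arg(aggregate)
  if (!is.null(outlier_k)) table <- remove_outliers_table(table, outlier_k)
  table <- aggregate_line_means(table, aggregate)
  combos <- unique(table[, c("population", "trait")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    pop <- combos$population[i]
    tr <- combos$trait[i]
    rec <- anova_two_way(table, pop, tr, ci_level, ci_two_sided)
    rec$delta_pct <- NA_real_
    dp <- tryCatch(as.numeric(delta_percent(table, pop, tr)),
                   error = function(e) NA_real_)
    rec$delta_pct[rec$term == "C"] <- dp
    rec
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
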