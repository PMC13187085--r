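# Independent oracles and small data builders used across test files.
# Oracles deliberately avoid the package's own code paths.

# Type III SS oracle: nested least-squares model comparison built directly
# from a sum-to-zero design matrix, one lm() per dropped term.
oracle_type3 <- function(df, factors, response = "value") {
  for (fc in factors) df[[fc]] <- factor(df[[fc]])
  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  mm <- stats::model.matrix(form, df, contrasts.arg = contr)
  y <- df[[response]]
  rss <- function(M) sum(stats::lm(y ~ M - 1)$residuals^2)
  rss_full <- rss(mm)
  asn <- attr(mm, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  vapply(seq_along(labels), function(ti) {
    rss(mm[, asn != ti, drop = FALSE]) - rss_full
  }, 0)
}

# exhaustive greedy Kennard-Stone: same selection rule, brute force over
# candidate distances recomputed from scratch each round
oracle_kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L)
  bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > bestd) {
      bestd <- d(i, j)
      best <- c(i, j)
    }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(c) min(vapply(sel, function(s) d(c, s), 0)), 0)
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# brute-force Savitzky-Golay: fit a local polynomial at every interior point
oracle_sg <- function(y, x, window, polyorder, deriv) {
  half <- (window - 1) / 2
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    fit <- stats::lm(y[idx] ~ poly(x[idx] - x[i], polyorder, raw = TRUE))
    out[i] <- stats::coef(fit)[deriv + 1] * factorial(deriv)
  }
  out
}

# random two-way trait table, optionally balanced
random_twoway_table <- function(n, balanced = FALSE) {
  if (balanced) {
    g <- expand.grid(cytoplasm_class = c("wild", "cultivated"),
                     environment = c("E1", "E2"),
                     rep = seq_len(ceiling(n / 4)), stringsAsFactors = FALSE)
  } else {
    repeat {
      g <- data.frame(
        cytoplasm_class = sample(c("wild", "cultivated"), n, TRUE),
        environment = sample(c("E1", "E2"), n, TRUE)
      )
      if (all(table(g$cytoplasm_class, g$environment) >= 2)) break
    }
  }
  data.frame(
    unit_id = sprintf("u%03d", seq_len(nrow(g))),
    population = "P", trait = "t",
    cytoplasm_class = g$cytoplasm_class, environment = g$environment,
    value = stats::rnorm(nrow(g), mean = 10), stringsAsFactors = FALSE
  )
}

# random three-way instance: trait table plus one genotyped marker
random_threeway_instance <- function(n) {
  repeat {
    df <- random_twoway_table(n)
    geno <- data.frame(
      plant_id = df$unit_id, marker_id = "M1",
      call = sample(c("AA", "AB", "BB"), nrow(df), TRUE, prob = c(.25, .5, .25)),
      chromosome = "1H", position_bp = 1e6, stringsAsFactors = FALSE
    )
    tab <- table(geno$call, df$cytoplasm_class, df$environment)
    if (length(unique(geno$call)) == 3L && all(tab >= 1)) {
      return(list(traits = df, genotypes = geno))
    }
  }
}

# tiny deterministic phenomics table with two populations
tiny_phenomics <- function() {
  rbind(
    simulate_phenomics(11, 20, 4,
                       list(list(traits = c("a", "b"), rho = 0.3)),
                       cytoplasm_effect = c(a = 1), population = "CMPA"),
    simulate_phenomics(12, 20, 4,
                       list(list(traits = c("a", "b"), rho = 0.3)),
                       cytoplasm_effect = c(a = 0.2), population = "CMPB")
  )
}
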