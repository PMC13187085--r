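test_that("asymmetric boxplot fences follow the semi-IQR rule", {
  # symmetric quartiles: rule reduces to the ordinary k*IQR fence; 100 removed
  x <- c(1:9, 100)
  q <- quantile(x, c(.25, .5, .75), type = 7)
  expect_equal(unname(q[2] - q[1]), unname(q[3] - q[2]))  # sample is quartile-symmetric
  keep <- remove_outliers_asymmetric(x)
  expect_identical(which(!keep), 10L)

  expect_true(all(remove_outliers_asymmetric(rep(5, 8))))

  # right-skewed: upper fence exceeds the symmetric-boxplot fence
  y <- c(1, 2, 3, 4, 5, 9, 14, 20, 27, 35)
  qy <- quantile(y, c(.25, .5, .75), type = 7)
  stopifnot(qy[3] - qy[2] > qy[2] - qy[1])
  upper_asym <- qy[3] + 3 * (qy[3] - qy[2])
  upper_sym <- qy[3] + 1.5 * (qy[3] - qy[1])
  expect_gt(upper_asym, upper_sym)
  expect_error(remove_outliers_asymmetric(c(1, 2, 3)), "at least 5")
})

test_that("outlier removal is applied within environment x population, per trait", {
  tab <- rbind(
    data.frame(unit_id = sprintf("a%d", 1:6), population = "P",
               cytoplasm_class = "wild", environment = "E1", trait = "t",
               value = c(10, 11, 12, 13, 14, 500)),
    data.frame(unit_id = sprintf("b%d", 1:6), population = "P",
               cytoplasm_class = "wild", environment = "E2", trait = "t",
               value = c(480, 500, 510, 520, 490, 505))
  )
  out <- remove_outliers_table(tab)
  expect_false(any(out$value == 500 & out$environment == "E1"))
  expect_equal(sum(out$environment == "E2"), 6L)  # 500 is normal in E2
})

test_that("line aggregation averages replicates; plant level is the identity", {
  tab <- data.frame(
    unit_id = rep("L1", 3), population = "P", cytoplasm_class = "wild",
    environment = "E1", trait = "t", value = c(10, 12, 14)
  )
  agg <- aggregate_line_means(tab, "line")
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$value, 12)
  expect_identical(aggregate_line_means(tab, "plant"), tab)
  tab$value[2] <- NA
  expect_equal(aggregate_line_means(tab, "line")$value, 12)
})

test_that("balanced pure cytoplasm contrast gives eta2_C = 1", {
  tab <- expand.grid(rep = 1:3, cytoplasm_class = c("wild", "cultivated"),
                     environment = c("E1", "E2"), stringsAsFactors = FALSE)
  tab$unit_id <- sprintf("u%d", seq_len(nrow(tab)))
  tab$population <- "P"
  tab$trait <- "t"
  tab$value <- ifelse(tab$cytoplasm_class == "wild", 1, 0)
  rec <- anova_two_way(tab, "P", "t")
  expect_equal(rec$eta2[rec$term == "C"], 1)
  expect_equal(rec$eta2[rec$term == "E"], 0)
  expect_equal(rec$eta2[rec$term == "CxE"], 0)
})

test_that("constant response yields undefined eta2 and no significance", {
  tab <- random_twoway_table(24, balanced = TRUE)
  tab$value <- 7
  rec <- anova_two_way(tab, "P", "t")
  expect_true(all(is.na(rec$eta2)))
  expect_false(any(rec$significant[rec$term != "Residual"]))
})

test_that("empty design cells are reported by name", {
  tab <- random_twoway_table(20, balanced = TRUE)
  tab <- tab[!(tab$cytoplasm_class == "wild" & tab$environment == "E2"), ]
  expect_error(anova_two_way(tab, "P", "t"), "wild.*E2|E2.*wild")
})

test_that("Type III SS match the nested least-squares oracle and car::Anova", {
  skip_if_not_installed("car")
  set.seed(20)
  for (i in 1:10) {
    tab <- random_twoway_table(sample(25:60, 1))
    rec <- anova_two_way(tab, "P", "t")
    want <- oracle_type3(tab, c("cytoplasm_class", "environment"))
    expect_equal(rec$SS[1:3], unname(want), tolerance = 1e-8)
    m <- stats::lm(value ~ cytoplasm_class * environment, tab,
                   contrasts = list(cytoplasm_class = "contr.sum",
                                    environment = "contr.sum"))
    A <- car::Anova(m, type = 3)
    expect_equal(rec$SS[1:3], A[["Sum Sq"]][2:4], tolerance = 1e-8)
  }
})

test_that("Type I equals Type III on balanced designs and eta2 sums to 1", {
  set.seed(21)
  for (i in 1:5) {
    tab <- random_twoway_table(32, balanced = TRUE)
    rec <- anova_two_way(tab, "P", "t")
    seq_ss <- stats::anova(stats::lm(value ~ cytoplasm_class * environment, tab))
    expect_equal(rec$SS[1:3], seq_ss[["Sum Sq"]][1:3], tolerance = 1e-8)
    expect_equal(sum(rec$eta2), 1, tolerance = 1e-10)
  }
})

test_that("eta-squared confidence bounds invert the noncentral F correctly", {
  expect_equal(eta_squared_ci(0, 1, 30)[1], 0)
  expect_equal(eta_squared_ci(2, 1, 30)[2], 1)  # one-sided upper bound
  # huge F: lower bound approaches the partial eta2 point estimate
  ci <- eta_squared_ci(1e6, 1, 100)
  point <- 1e6 / (1e6 + 100)
  expect_lt(abs(ci[1] - point), 0.02)
  # bound is nondecreasing in F at fixed dfs
  lows <- vapply(c(0.5, 1, 2, 4, 8, 16, 64), function(f) eta_squared_ci(f, 2, 40)[1], 0)
  expect_true(all(diff(lows) >= 0))
  # the pivot is consistent: at the bound, pf(F; ncp) = level
  f <- 9.3
  lo <- eta_squared_ci(f, 1, 50)[1]
  ncp <- lo / (1 - lo) * (1 + 50 + 1)
  expect_equal(pf(f, 1, 50, ncp = ncp), 0.95, tolerance = 1e-5)
  expect_true(all(is.na(eta_squared_ci(NaN, 1, 10))))
  # two-sided interval brackets the one-sided lower bound
  ci2 <- eta_squared_ci(f, 1, 50, two_sided = TRUE)
  expect_lt(ci2[1], lo)
  expect_lt(ci2[2], 1)
})

test_that("the significance gate is the exact three-condition conjunction", {
  expect_true(significance_gate(0.04, 0.02, 0.001))
  expect_false(significance_gate(0.04, 0.005, 0.001))
  expect_false(significance_gate(0.2, 0.10, 0.02))
  expect_false(significance_gate(0.04, 0.02, 0))
  expect_false(significance_gate(NA, 0.02, 0.01))
})

test_that("gate decisions are monotone in planted effect size", {
  verdict <- vapply(c(0, 0.02, 0.05, 0.10, 0.20), function(share) {
    cfg <- sim_config(seed = 77, n_plants_per_cytoplasm = 60, n_markers = 1,
                      effect_spec = if (share > 0) c(C = share) else numeric(),
                      trait_names = "y")
    rec <- anova_two_way(simulate_reciprocal_f2(cfg)$traits, "POP1", "y")
    rec$significant[rec$term == "C"]
  }, NA)
  expect_true(all(diff(as.integer(verdict)) >= 0))
})

test_that("Delta percent averages per-environment relative differences", {
  tab <- expand.grid(rep = 1:2, cytoplasm_class = c("wild", "cultivated"),
                     environment = c("E1", "E2"), stringsAsFactors = FALSE)
  tab$unit_id <- sprintf("u%d", seq_len(nrow(tab)))
  tab$population <- "P"
  tab$trait <- "t"
  tab$value <- c(52.8, 52.8, 50, 50, 55.6, 55.6, 50, 50)
  dp <- delta_percent(tab, "P", "t")
  expect_equal(as.numeric(dp), 8.4)
  expect_equal(unname(attr(dp, "per_environment")), c(5.6, 11.2))
  tab$value[tab$cytoplasm_class == "wild"] <- 50
  expect_equal(as.numeric(delta_percent(tab, "P", "t")), 0)
  one_env <- tab[tab$environment == "E1", ]
  one_env$value <- c(52.8, 52.8, 50, 50)
  expect_equal(as.numeric(delta_percent(one_env, "P", "t")), 5.6)
  tab$value[tab$cytoplasm_class == "cultivated"] <- 0
  expect_error(delta_percent(tab, "P", "t"), "zero")
})

test_that("cytoplasm_effects runs the full panel workflow end to end", {
  cfg <- sim_config(seed = 30, n_plants_per_cytoplasm = 40, n_markers = 1,
                    effect_spec = c(C = 0.25), trait_names = c("TGW", "GW"))
  sim <- simulate_reciprocal_f2(cfg)
  res <- cytoplasm_effects(sim$traits, aggregate = "plant")
  expect_equal(sort(unique(res$term)), sort(c("C", "E", "CxE", "Residual")))
  expect_true(all(res$significant[res$term == "C"]))
  expect_true(all(!is.na(res$delta_pct[res$term == "C"])))
  expect_true(all(is.na(res$delta_pct[res$term != "C"])))
})
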