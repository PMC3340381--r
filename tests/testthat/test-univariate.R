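test_that("double-entry correlations match direct computation", {
  df <- data.frame(
    pair_id = rep(c("m1", "m2", "d1", "d2"), each = 2),
    zygosity = rep(c("MZ", "MZ", "DZ", "DZ"), each = 2),
    y = c(3, 3, -1, -1, 1, 2, 2, 1)
  )
  zc <- zygosity_correlations(df, "y")
  expect_equal(zc$r_mz, 1)
  # DZ pairs (1,2) and (2,1) double-entered -> r = -1
  expect_equal(zc$r_dz, -1)
  expect_equal(zc$n_mz_pairs, 2L)

  # independent co-twins: correlation near zero
  big <- sim_ace_pairs(5000, 5000, a2 = 0, c2 = 0, e2 = 1, seed = 2)
  zc2 <- zygosity_correlations(big, "y")
  expect_lt(abs(zc2$r_mz), 0.03)
  expect_lt(abs(zc2$r_dz), 0.03)
})

test_that("Falconer estimates follow the closed-form rules", {
  f <- falconer_estimates(list(r_mz = 0.70, r_dz = 0.35))
  expect_equal(unlist(f[c("a2", "c2", "e2")]),
               c(a2 = 0.70, c2 = 0.00, e2 = 0.30))
  f2 <- falconer_estimates(list(r_mz = 0.5, r_dz = 0.5))
  expect_equal(unlist(f2[c("a2", "c2", "e2")]), c(a2 = 0, c2 = 0.5, e2 = 0.5))
  f3 <- falconer_estimates(list(r_mz = 0.6, r_dz = 0.2))
  expect_equal(unlist(f3[c("a2", "c2", "e2")]),
               c(a2 = 0.8, c2 = -0.2, e2 = 0.4))
  expect_false(f3$clipped)
  f4 <- falconer_estimates(list(r_mz = 0.6, r_dz = 0.2), clip = TRUE)
  expect_true(f4$clipped)
  expect_equal(f4$a2 + f4$c2 + f4$e2, 1)
  expect_true(all(unlist(f4[c("a2", "c2", "e2")]) >= 0))
})

test_that("age adjustment is an exact OLS residualization", {
  set.seed(4)
  tab <- data.frame(age = runif(500, 40, 90))
  tab$lin <- 2 * tab$age - 7
  expect_equal(age_adjust(tab, "lin"), rep(0, 500), tolerance = 1e-10)
  tab$y <- tab$age + rnorm(500)
  r <- age_adjust(tab, "y")
  expect_lt(abs(cor(r, tab$age)), 1e-10)
  # residual variance approaches the noise variance
  tab2 <- data.frame(age = runif(1e5, 40, 90))
  tab2$y <- tab2$age + rnorm(1e5)
  expect_equal(var(age_adjust(tab2, "y")), 1, tolerance = 0.02)
  tab$flat_age <- 5
  expect_error(age_adjust(data.frame(age = rep(1, 5), y = 1:5), "y"),
               "constant")
})

test_that("ML and Falconer agree on balanced AE data", {
  df <- sim_ace_pairs(1000, 1000, a2 = 0.6, c2 = 0, e2 = 0.4, seed = 9)
  fal <- falconer_estimates(zygosity_correlations(df, "y"))
  # saturated-covariance ML in the correlation metric: closed-form identity
  fit <- fit_univariate(df, "y", "ACE", ci = FALSE, nonneg = FALSE,
                        standardize = "zygosity")
  expect_lt(abs(fit$components$a2 - fal$a2), 0.02)
  expect_lt(abs(fit$components$e2 - fal$e2), 0.02)
  # the default constrained fit agrees up to boundary/variance-pooling noise
  fit2 <- fit_univariate(df, "y", "ACE", ci = FALSE)
  expect_lt(abs(fit2$components$a2 - fal$a2), 0.08)
})

test_that("component shares are standardized and models are ordered", {
  df <- sim_ace_pairs(300, 300, a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 14,
                      n_singletons = 20)
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(m) {
    fit_univariate(df, "y", m, ci = FALSE)
  })
  names(fits) <- c("ACE", "AE", "CE", "E")
  for (f in fits) {
    expect_equal(f$components$a2 + f$components$c2 + f$components$e2, 1,
                 tolerance = 1e-9)
  }
  # nested models can never beat the saturated model
  for (m in c("AE", "CE", "E")) {
    expect_gte(fits[[m]]$minus2logl - fits$ACE$minus2logl, -1e-6)
  }
  # df bookkeeping: observations minus free parameters
  n_obs <- 2 * 600 + 20
  expect_equal(fits$ACE$df, n_obs - 4L)
  expect_equal(fits$AE$df, n_obs - 3L)
  expect_equal(fits$E$df, n_obs - 2L)
})

test_that("saturated per-zygosity fit reproduces double-entry correlations", {
  # with a single zygosity group the ACE covariance structure is saturated,
  # so the ML-implied within-pair correlation must equal the double-entry
  # Pearson correlation
  for (zyg in c("MZ", "DZ")) {
    df <- sim_ace_pairs(if (zyg == "MZ") 400 else 0,
                        if (zyg == "DZ") 400 else 0,
                        a2 = 0.55, c2 = 0.15, e2 = 0.30, seed = 18)
    zc <- zygosity_correlations(df, "y")
    r_sample <- if (zyg == "MZ") zc$r_mz else zc$r_dz
    fit <- fit_univariate(df, "y", "ACE", ci = FALSE)
    k <- if (zyg == "MZ") 1 else 0.5
    r_implied <- with(fit$components, (k * a2 + c2))
    expect_equal(r_implied, r_sample, tolerance = 1e-4)
  }
})

test_that("null covariance structure collapses to the E model", {
  df <- sim_ace_pairs(400, 400, a2 = 0, c2 = 0, e2 = 1, seed = 6)
  full <- fit_univariate(df, "y", "ACE", ci = FALSE)
  e_only <- fit_univariate(df, "y", "E", ci = FALSE)
  cmp <- compare_models(full, e_only)
  expect_lt(cmp$delta_minus2logl, 3.84 * 2)  # 2 df
  expect_lt(full$components$a2, 0.12)
})

test_that("model comparison arithmetic matches hand-checked chi-square values", {
  c1 <- model_comparison(0.069, 1)
  expect_equal(c1$p_value, 0.792, tolerance = 0.002)
  expect_equal(c1$aic, -1.931)
  c2 <- model_comparison(1.709, 1)
  expect_equal(c2$p_value, 0.191, tolerance = 0.002)
  expect_equal(c2$aic, -0.291)
  c3 <- model_comparison(0, 1)
  expect_equal(c3$p_value, 1)
  expect_equal(c3$aic, -2)
  expect_error(model_comparison(-0.5, 1), "negative")
  expect_error(model_comparison(1, 0), "delta_df")
})

test_that("compare_models enforces nesting", {
  df <- sim_ace_pairs(100, 100, a2 = 0.5, seed = 3)
  ae <- fit_univariate(df, "y", "AE", ci = FALSE)
  ce <- fit_univariate(df, "y", "CE", ci = FALSE)
  ace <- fit_univariate(df, "y", "ACE", ci = FALSE)
  expect_error(compare_models(ae, ce), "not nested")
  expect_error(compare_models(ae, ace), "not nested")
  cmp <- compare_models(ace, ae)
  expect_equal(cmp$delta_df, 1L)
})

test_that("mean heritability estimate rises with the generating a2", {
  means <- vapply(c(0.2, 0.4, 0.6, 0.8), function(a2_true) {
    est <- vapply(1:60, function(r) {
      df <- sim_ace_pairs(200, 200, a2 = a2_true, c2 = 0, seed = 1000 + r)
      fit_univariate(df, "y", "AE", ci = FALSE, restarts = 2)$components$a2
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(means, c(0.2, 0.4, 0.6, 0.8), tolerance = 0.15)
})

test_that("profile CIs bracket the estimate and widen for smaller samples", {
  df <- sim_ace_pairs(500, 500, a2 = 0.7, c2 = 0, seed = 77)
  fit <- fit_univariate(df, "y", "AE", ci = TRUE)
  ci <- fit$ci95["a2", ]
  expect_lt(ci[["lo"]], fit$components$a2)
  expect_gt(ci[["hi"]], fit$components$a2)
  small <- sim_ace_pairs(60, 60, a2 = 0.7, c2 = 0, seed = 78)
  fit_s <- fit_univariate(small, "y", "AE", ci = TRUE)
  expect_gt(diff(fit_s$ci95["a2", ]), diff(ci))
})

test_that("univariate_table assembles comparisons for each phenotype", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 120, n_dz_pairs = 120,
                                   n_singletons = 10, seed = 55))
  tab <- build_phenotypes(co, fit_pca(audiogram_matrix(co)))
  ut <- univariate_table(tab, phenotypes = c("pta", "pc1_minus_pc2"),
                         models = c("AE", "E"))
  expect_equal(nrow(ut), 6L)
  expect_true(all(ut$delta_minus2logl[ut$model != "ACE"] >= -1e-6))
  expect_true(all(is.na(ut$p_value[ut$model == "ACE"])))
  expect_true(all(ut$p_value[ut$model != "ACE"] >= 0 &
                    ut$p_value[ut$model != "ACE"] <= 1))
})
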