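test_that("better_ear applies the whole-ear rule with left-ear ties", {
  expect_equal(better_ear(rep(10, 7), rep(30, 7)), rep(10, 7))
  expect_equal(better_ear(rep(15, 7), rep(15, 7)), rep(15, 7))
  # right ear wins on the across-frequency mean even where left is better
  left <- c(5, 20, 20, 20, 20, 20, 35)   # mean 20
  right <- c(10, 20, 20, 20, 20, 20, 29.3)  # mean 19.9
  expect_equal(mean(right), 19.9)
  expect_equal(better_ear(left, right), right)
  # missing in one ear is filled from the other; both missing stays NA
  expect_equal(better_ear(c(NA, 10, 10), c(20, 20, 20))[1], 20)
  expect_true(is.na(better_ear(c(NA, 10), c(NA, 20))[1]))
})

test_that("log_transform matches direct evaluation and guards its domain", {
  expect_equal(log_transform(c(0, 75)), c(log10(25), 2))
  expect_equal(log_transform(c(2.718281828459045^2 - 1), offset = 1,
                             base = exp(1)), 2)
  expect_error(log_transform(-25), "non-positive")
  expect_equal(log_transform(10, offset = 0), 1)
})

test_that("scalar averages reproduce the arithmetic definitions", {
  freqs <- c(0.125, 0.25, 0.5, 1, 2, 4, 8)
  flat <- scalar_averages(rep(40, 7), freqs)
  expect_equal(flat$pta, 40)
  expect_equal(flat$behl, 40)
  s <- scalar_averages(c(10, 10, 10, 20, 30, 40, 50), freqs)
  expect_equal(s$pta, 170 / 7)
  expect_equal(s$behl, 25)
  expect_error(scalar_averages(numeric(), numeric()), "empty")
})

test_that("PCA recovers rank-1 and identity correlation structure", {
  set.seed(10)
  # one common factor plus tiny noise
  f <- rnorm(300)
  X <- outer(f, seq(1, 2, length.out = 5)) +
    matrix(rnorm(1500, sd = 0.01), 300, 5)
  am <- structure(list(subjects = as.character(1:300), freqs = 1:5,
                       values = X, raw = X,
                       transform_params = c(offset = 0, base = 10)),
                  class = "audiogram_matrix")
  p <- fit_pca(am)
  expect_gt(p$var_explained[1], 0.99)
  expect_true(all(p$loadings[, 1] > 0))
  # independent standardized columns: all eigenvalues near 1
  X2 <- matrix(rnorm(5000 * 6), 5000, 6)
  am2 <- structure(list(subjects = as.character(1:5000), freqs = 1:6,
                        values = X2, raw = X2,
                        transform_params = c(offset = 0, base = 10)),
                   class = "audiogram_matrix")
  p2 <- fit_pca(am2, n_components = 2)
  expect_true(all(abs(p2$eigenvalues - 1) < 0.15))
  # constant column is rejected
  X3 <- cbind(X2[, 1:3], 7)
  am3 <- am2; am3$values <- X3; am3$freqs <- 1:4
  expect_error(fit_pca(am3), "constant column")
})

test_that("two-factor audiograms give two components with the expected signs", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 400, n_dz_pairs = 400,
                                   n_singletons = 20, seed = 77))
  am <- audiogram_matrix(co)
  p <- fit_pca(am)
  expect_equal(sum(p$eigenvalues > 1), 2L)
  expect_true(all(p$loadings[, "PC1"] > 0))
  # PC2 sign flips between 0.5 and 4 kHz
  expect_gt(p$loadings["0.5", "PC2"], 0)
  expect_lt(p$loadings["4", "PC2"], 0)
  # brute-force eigen oracle: same eigenvalues as prcomp on scaled data
  pr <- prcomp(scale(am$values))
  expect_equal(p$eigenvalues, unname(pr$sdev^2), tolerance = 1e-8)
  # retained scores mutually uncorrelated on the fitting sample
  expect_lt(abs(cor(p$scores[, 1], p$scores[, 2])), 1e-10)
  # score variance equals the eigenvalue (correlation-PCA convention)
  expect_equal(stats::var(p$scores[, 1]), p$eigenvalues[1],
               tolerance = 1e-8)
})

test_that("phenotype table construction is consistent and centered", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 50, n_dz_pairs = 50,
                                   n_singletons = 5, seed = 31))
  am <- audiogram_matrix(co)
  p <- fit_pca(am)
  tab <- build_phenotypes(co, p, am = am)
  expect_equal(tab$pc1_minus_pc2, tab$pc1 - tab$pc2)
  expect_equal(mean(tab$pc1), 0, tolerance = 1e-12)
  expect_equal(mean(tab$pc2), 0, tolerance = 1e-12)
  # projecting the mean audiogram gives zero scores
  Z0 <- (p$center - p$center) / p$scale
  expect_equal(unname(drop(Z0 %*% p$loadings)), c(0, 0))
  # flat elevated vs flat normal: higher pc1, similar pc2
  mk <- function(level) log_transform(rep(level, 7))
  z_hi <- (mk(60) - p$center) / p$scale
  z_lo <- (mk(10) - p$center) / p$scale
  s_hi <- drop(z_hi %*% p$loadings)
  s_lo <- drop(z_lo %*% p$loadings)
  expect_gt(s_hi[1], s_lo[1])
  expect_lt(abs(s_hi[2] - s_lo[2]), abs(s_hi[1] - s_lo[1]) / 2)
  # frequency mismatch is an error
  p_bad <- p; p_bad$freqs <- p$freqs[-1]
  expect_error(build_phenotypes(co, p_bad, am = am), "mismatch")
})

test_that("ranking reproduces the published criterion arithmetic", {
  rk <- rank_from_criteria(
    c("pc1_minus_pc2", "pta", "pc1", "behl", "pc2"),
    r_age = c(0.61, 0.55, 0.53, 0.49, -0.29),
    r2_pc2 = c(0.26, 0.08, 0.12, 0.08, NA)
  )
  expect_equal(rk$phenotype[1], "pc1_minus_pc2")
  expect_equal(rk$overall_rank[1], 1L)
  expect_equal(rk$rank_age[rk$phenotype == "pc1_minus_pc2"], 1L)
  expect_equal(rk$rank_pc2[rk$phenotype == "pc1_minus_pc2"], 1L)
  # tie on the shape criterion: pta and behl share the minimum rank
  expect_equal(rk$rank_pc2[rk$phenotype == "pta"],
               rk$rank_pc2[rk$phenotype == "behl"])
  expect_equal(rk$rank_pc2[rk$phenotype == "pta"], 3L)
  expect_true(is.na(rk$overall_rank[rk$phenotype == "pc2"]))
})

test_that("ranking degenerate and noise cases behave", {
  rk <- rank_from_criteria(c("a", "b", "c"), r_age = c(0.5, 0.5, 0.5),
                           r2_pc2 = c(0.2, 0.2, 0.2))
  expect_true(all(rk$overall_rank == 1L))
  # a pure-noise phenotype ranks last on both criteria
  set.seed(5)
  co <- simulate_cohort(sim_config(n_mz_pairs = 150, n_dz_pairs = 150,
                                   n_singletons = 0, seed = 12))
  tab <- build_phenotypes(co, fit_pca(audiogram_matrix(co)))
  tab$noise <- rnorm(nrow(tab))
  rk2 <- rank_phenotypes(tab, phenotypes = c("pta", "pc1", "noise"),
                         seed = 1)
  expect_equal(rk2$phenotype[which.max(rk2$rank_sum)], "noise")
  # affine rescaling leaves the ranking invariant
  tab$pta_scaled <- -3.2 * tab$pta + 11
  rk3 <- rank_phenotypes(tab, phenotypes = c("pta_scaled", "pc1", "noise"),
                         seed = 1)
  expect_equal(rk3$rank_age[match("pta_scaled", rk3$phenotype)],
               rk2$rank_age[match("pta", rk2$phenotype)])
  expect_equal(rk3$rank_pc2[match("pta_scaled", rk3$phenotype)],
               rk2$rank_pc2[match("pta", rk2$phenotype)])
  # zero-variance phenotype excluded with a warning
  tab$flat <- 1
  expect_warning(rank_phenotypes(tab, phenotypes = c("pta", "pc1", "flat"),
                                 seed = 1), "zero-variance")
})

test_that("Kruskal-Wallis H matches the rank formula and the stats oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4)
  expect_equal(kw$df, 1L)
  # fully tied single-value groups
  expect_equal(kruskal_wallis(c(5, 5), c("a", "b"))$H, 0)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
  # dual-route check against stats::kruskal.test, with ties
  set.seed(33)
  for (i in 1:10) {
    v <- sample(1:8, 60, replace = TRUE)
    g <- sample(c("x", "y", "z"), 60, replace = TRUE)
    ours <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})
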