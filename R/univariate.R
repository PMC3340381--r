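#' @section Classical twin model:
#' Monozygotic (MZ) co-twins share all additive-genetic (A) factors and
#' dizygotic (DZ) co-twins half on average; common-environment (C) factors
#' are fully shared within pairs of either zygosity and unique-environment
#' (E) factors are unshared. The implied within-pair covariance of a
#' standardized trait is therefore `a2 + c2` in MZ and `a2/2 + c2` in DZ
#' pairs, with total variance `a2 + c2 + e2`.
#' @name ace-model
#' @keywords internal
NULL

# --- data plumbing ----------------------------------------------------------

# Split one phenotype column into complete MZ/DZ pair matrices plus a vector
# of unpaired observations (singletons and half-missing pairs).
pair_data <- function(data, column) {
  df <- if (inherits(data, "twin_cohort")) data$records else data
  for (nm in c("pair_id", "zygosity", column)) {
    if (!nm %in% names(df)) stop_config("column '%s' not found", nm)
  }
  x <- df[[column]]
  ok <- !is.na(x)
  df <- df[ok, , drop = FALSE]
  x <- x[ok]
  out <- list(mz = matrix(numeric(), 0, 2), dz = matrix(numeric(), 0, 2),
              singles = numeric())
  for (zyg in c("MZ", "DZ")) {
    sel <- df$zygosity == zyg
    sp <- split(x[sel], df$pair_id[sel])
    complete <- vapply(sp, length, integer(1)) == 2L
    if (any(complete)) {
      m <- t(vapply(sp[complete], identity, numeric(2)))
      out[[tolower(zyg)]] <- m
    }
    out$singles <- c(out$singles, unlist(sp[!complete], use.names = FALSE))
  }
  out$singles <- c(out$singles, x[df$zygosity == "singleton"])
  out
}

# Sufficient statistics: O(1) likelihood evaluations afterwards.
pair_suffstats <- function(pd) {
  ss <- function(m) {
    list(n = nrow(m), s1 = sum(m), s2 = sum(m^2),
         s12 = sum(m[, 1] * m[, 2]))
  }
  list(mz = ss(pd$mz), dz = ss(pd$dz),
       singles = list(n = length(pd$singles), s1 = sum(pd$singles),
                      s2 = sum(pd$singles^2)),
       n_obs = 2L * (nrow(pd$mz) + nrow(pd$dz)) + length(pd$singles))
}

# -2 log likelihood of the pair model from sufficient statistics.
# mu: common mean; v: total variance; cov_mz / cov_dz: within-pair covs.
m2ll_pairs <- function(st, mu, v, cov_mz, cov_dz) {
  if (!is.finite(v) || v <= 0) return(Inf)
  total <- 0
  for (g in list(c("mz", cov_mz), c("dz", cov_dz))) {
    s <- st[[g[[1]]]]
    if (s$n == 0L) next
    cv <- as.numeric(g[[2]])
    det <- v^2 - cv^2
    if (det <= 0 || abs(cv) >= v) return(Inf)
    sd2 <- s$s2 - 2 * mu * s$s1 + 2 * s$n * mu^2
    sd12 <- s$s12 - mu * s$s1 + s$n * mu^2
    total <- total + s$n * (2 * log(2 * pi) + log(det)) +
      (v * sd2 - 2 * cv * sd12) / det
  }
  s0 <- st$singles
  if (s0$n > 0L) {
    ssq <- s0$s2 - 2 * mu * s0$s1 + s0$n * mu^2
    total <- total + s0$n * (log(2 * pi) + log(v)) + ssq / v
  }
  total
}

model_paths <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"),
         AE = c("a", "e"),
         CE = c("c", "e"),
         E = "e",
         stop_config("unknown model '%s'", model))
}

# m2ll as a function of free parameters (mu + active components).
# nonneg: components are squared path coefficients; otherwise they are free
# real variances (saturated-covariance variant, A and C may go negative).
m2ll_theta <- function(theta, st, model, nonneg = TRUE) {
  mu <- theta[1]
  p <- c(a = 0, c = 0, e = 0)
  p[model_paths(model)] <- theta[-1]
  if (nonneg) {
    a2 <- p[["a"]]^2; c2 <- p[["c"]]^2; e2 <- p[["e"]]^2
  } else {
    a2 <- p[["a"]]; c2 <- p[["c"]]; e2 <- p[["e"]]
  }
  m2ll_pairs(st, mu, a2 + c2 + e2, a2 + c2, 0.5 * a2 + c2)
}

# --- descriptive twin statistics -------------------------------------------

#' Double-entry intraclass correlations by zygosity
#'
#' Pearson correlation on double-entered pairs (each pair contributes both
#' orderings), computed separately for MZ and DZ pairs.
#'
#' @param data a `twin_cohort` or phenotype table.
#' @param column phenotype column name.
#' @return List with `r_mz`, `r_dz`, `n_mz_pairs`, `n_dz_pairs`.
#' @export
zygosity_correlations <- function(data, column) {
  pd <- pair_data(data, column)
  de_cor <- function(m) {
    if (nrow(m) < 2L) return(NA_real_)
    x <- c(m[, 1], m[, 2]); y <- c(m[, 2], m[, 1])
    if (stats::sd(x) == 0) stop_config("phenotype constant within pairs")
    stats::cor(x, y)
  }
  list(r_mz = de_cor(pd$mz), r_dz = de_cor(pd$dz),
       n_mz_pairs = nrow(pd$mz), n_dz_pairs = nrow(pd$dz))
}

#' Closed-form (Falconer) variance-component estimates
#'
#' From MZ/DZ intraclass correlations: `a2 = 2 (r_mz - r_dz)` (twice the
#' MZ-DZ covariance difference), `c2 = 2 r_dz - r_mz` (DZ correlation minus
#' half the heritability) and `e2 = 1 - r_mz` (variation not shared within
#' MZ pairs). Serves as the independent closed-form oracle for the maximum
#' likelihood fit.
#'
#' @param corr a [zygosity_correlations()] result (or list with `r_mz`,
#'   `r_dz`).
#' @param clip clamp negative components to zero and renormalize to sum 1.
#' @return List with `a2`, `c2`, `e2`, `clipped`.
#' @export
falconer_estimates <- function(corr, clip = FALSE) {
  a2 <- 2 * (corr$r_mz - corr$r_dz)
  c2 <- 2 * corr$r_dz - corr$r_mz
  e2 <- 1 - corr$r_mz
  raw <- c(a2 = a2, c2 = c2, e2 = e2)
  clipped <- FALSE
  if (clip && any(raw < 0)) {
    raw <- pmax(raw, 0)
    raw <- raw / sum(raw)
    clipped <- TRUE
  }
  list(a2 = unname(raw["a2"]), c2 = unname(raw["c2"]),
       e2 = unname(raw["e2"]), clipped = clipped)
}

#' Age adjustment by linear regression
#'
#' Ordinary least-squares residuals of a phenotype on age (intercept plus
#' linear term), returned unstandardized and aligned with the input rows
#' (`NA` where the phenotype or age is missing).
#'
#' @param table data frame with an `age` column.
#' @param column phenotype column name.
#' @return Numeric vector of residuals.
#' @export
age_adjust <- function(table, column) {
  if (!"age" %in% names(table)) stop_config("no age column")
  if (stats::sd(table$age, na.rm = TRUE) == 0) stop_config("age is constant")
  y <- table[[column]]
  ok <- !is.na(y) & !is.na(table$age)
  res <- rep(NA_real_, length(y))
  fit <- stats::lm(y[ok] ~ table$age[ok])
  res[ok] <- stats::resid(fit)
  res
}

# --- maximum likelihood fit -------------------------------------------------

#' Fit a univariate variance-component twin model by maximum likelihood
#'
#' Maximizes the pairwise bivariate-normal likelihood with implied MZ
#' covariance `a2 + c2`, DZ covariance `a2/2 + c2`, a common mean and a
#' common total variance `a2 + c2 + e2` across zygosities. Singletons and
#' half-observed pairs contribute univariate-normal terms. Path-coefficient
#' parameterization (`a`, `c`, `e` estimated, variances are their squares)
#' keeps the components non-negative without constrained optimization.
#' Optimization runs from a moment-based start plus seeded random restarts;
#' the best solution is kept.
#'
#' 95% confidence intervals for the standardized shares are obtained by
#' profile likelihood: the interval bounds are the share values at which
#' the profiled -2 log L rises 3.84 above its minimum.
#'
#' @param data a `twin_cohort` or phenotype table with `pair_id` and
#'   `zygosity` columns.
#' @param column phenotype column.
#' @param model one of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param standardize `TRUE` (default) divides the phenotype by its overall
#'   sample SD; `"zygosity"` scales each zygosity group by its own SD,
#'   putting the fit in the same correlation metric the Falconer formulas
#'   use; `FALSE` fits on the raw scale. Shares are invariant to the
#'   overall scale either way.
#' @param restarts number of random restarts beyond the moment start.
#' @param seed seed for the restart draws.
#' @param ci compute profile-likelihood intervals (skip for speed in
#'   simulations).
#' @param nonneg constrain components non-negative via the path
#'   parameterization (default). `nonneg = FALSE` frees A and C as real
#'   variances (saturated-covariance variant), which makes the ACE ML
#'   solution agree with the closed-form Falconer estimates on balanced
#'   data; profile CIs are only available for the constrained fit.
#' @return Object of class `univariate_fit`: `model`, `components`
#'   (standardized `a2`, `c2`, `e2`), `ci95`, `minus2logl`, `df`,
#'   `n_params`, `mean`, `total_var`, `n_obs`, `boundary` flag.
#' @export
fit_univariate <- function(data, column, model = c("ACE", "AE", "CE", "E"),
                           standardize = TRUE, restarts = 5L, seed = 1L,
                           ci = TRUE, nonneg = TRUE) {
  model <- match.arg(model)
  pd <- pair_data(data, column)
  vals <- c(pd$mz, pd$dz, pd$singles)
  if (length(vals) < 4L) stop_config("too few observations")
  by_zyg <- identical(standardize, "zygosity")
  scale_factor <- if (isTRUE(standardize) || by_zyg) stats::sd(vals) else 1
  if (scale_factor == 0) stop_config("phenotype is constant")
  if (by_zyg) {
    sc <- function(m) if (length(m) > 3) m / stats::sd(m) else m / scale_factor
    pd$mz <- sc(pd$mz)
    pd$dz <- sc(pd$dz)
    pd$singles <- sc(pd$singles)
  } else {
    pd$mz <- pd$mz / scale_factor
    pd$dz <- pd$dz / scale_factor
    pd$singles <- pd$singles / scale_factor
  }
  st <- pair_suffstats(pd)

  mu0 <- mean(c(pd$mz, pd$dz, pd$singles))
  v0 <- stats::var(c(pd$mz, pd$dz, pd$singles))
  paths <- model_paths(model)
  start0 <- if (nonneg) {
    c(mu0, rep(sqrt(v0 / length(paths)), length(paths)))
  } else {
    c(mu0, rep(v0 / length(paths), length(paths)))
  }

  obj <- function(th) m2ll_theta(th, st, model, nonneg = nonneg)
  fits <- list(run_optim(obj, start0))
  extra <- with_seed(seed, {
    lapply(seq_len(restarts), function(i) {
      th <- start0 * stats::runif(length(start0), 0.4, 1.6) +
        c(stats::rnorm(1, 0, 0.1 * sqrt(v0)), numeric(length(paths)))
      run_optim(obj, th)
    })
  })
  fits <- c(fits, extra)
  vals_m2ll <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals_m2ll))) {
    stop_config("univariate fit failed to converge from any start")
  }
  best <- fits[[which.min(vals_m2ll)]]

  th <- best$par
  p <- c(a = 0, c = 0, e = 0)
  p[paths] <- th[-1]
  raw <- if (nonneg) p^2 else p
  total <- sum(raw)
  shares <- raw / total
  boundary <- nonneg && any(raw[paths] / total < 1e-6)

  ci95 <- NULL
  if (ci && nonneg) {
    ci95 <- profile_ci_univariate(st, model, best$value, shares)
  }
  structure(list(
    model = model,
    components = list(a2 = unname(shares["a"]), c2 = unname(shares["c"]),
                      e2 = unname(shares["e"])),
    ci95 = ci95,
    minus2logl = best$value,
    n_params = length(th),
    df = st$n_obs - length(th),
    mean = th[1] * scale_factor,
    total_var = total * scale_factor^2,
    n_obs = st$n_obs,
    boundary = boundary,
    column = column
  ), class = "univariate_fit")
}

run_optim <- function(obj, start) {
  out <- tryCatch(
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) list(par = start, value = Inf)
  )
  # polish with BFGS from the simplex solution
  polish <- tryCatch(
    stats::optim(out$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) out
  )
  if (is.finite(polish$value) && polish$value <= out$value) polish else out
}

# Profile -2logL over a fixed standardized share of one component.
# Remaining free parameters: mu, total variance, and (for ACE) the split of
# the complementary share between the other two components.
profiled_m2ll_share <- function(st, model, comp, s) {
  s <- min(max(s, 1e-8), 1 - 1e-8)  # keep the implied covariance non-singular
  paths <- model_paths(model)
  others <- setdiff(paths, comp)
  obj <- if (length(others) == 2L) {
    function(q) {
      mu <- q[1]; v <- exp(q[2]); t <- stats::plogis(q[3])
      sh <- c(a = 0, c = 0, e = 0)
      sh[comp] <- s
      sh[others[1]] <- (1 - s) * t
      sh[others[2]] <- (1 - s) * (1 - t)
      m2ll_pairs(st, mu, v, v * (sh[["a"]] + sh[["c"]]),
                 v * (0.5 * sh[["a"]] + sh[["c"]]))
    }
  } else {
    function(q) {
      mu <- q[1]; v <- exp(q[2])
      sh <- c(a = 0, c = 0, e = 0)
      sh[comp] <- s
      sh[others] <- 1 - s
      m2ll_pairs(st, mu, v, v * (sh[["a"]] + sh[["c"]]),
                 v * (0.5 * sh[["a"]] + sh[["c"]]))
    }
  }
  npar <- if (length(others) == 2L) 3L else 2L
  mu0 <- (st$mz$s1 + st$dz$s1 + st$singles$s1) / st$n_obs
  v0 <- (st$mz$s2 + st$dz$s2 + st$singles$s2) / st$n_obs - mu0^2
  start <- c(mu0, log(max(v0, 1e-8)), 0)[seq_len(npar)]
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  fit$value
}

profile_ci_univariate <- function(st, model, m2ll_min, shares,
                                  crit = 3.84) {
  paths <- model_paths(model)
  target <- m2ll_min + crit
  out <- matrix(NA_real_, nrow = 3, ncol = 2,
                dimnames = list(c("a2", "c2", "e2"), c("lo", "hi")))
  if (model == "E") {
    out["e2", ] <- c(1, 1)
    return(out)
  }
  for (comp in paths) {
    s_hat <- shares[comp]
    f <- function(s) profiled_m2ll_share(st, model, comp, s) - target
    lo <- if (f(0) <= 0) 0 else {
      tryCatch(stats::uniroot(f, c(0, s_hat), tol = 1e-5)$root,
               error = function(e) NA_real_)
    }
    hi <- if (f(1) <= 0) 1 else {
      tryCatch(stats::uniroot(f, c(s_hat, 1), tol = 1e-5)$root,
               error = function(e) NA_real_)
    }
    out[paste0(comp, "2"), ] <- c(lo, hi)
  }
  out
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("%s model fit for '%s' (-2logL = %.3f, df = %d)\n",
              x$model, x$column, x$minus2logl, x$df))
  comp <- unlist(x$components)
  for (nm in names(comp)) {
    line <- sprintf("  %s = %.3f", nm, comp[nm])
    if (!is.null(x$ci95) && !any(is.na(x$ci95[nm, ]))) {
      line <- sprintf("%s (95%% CI %.3f-%.3f)", line,
                      x$ci95[nm, 1], x$ci95[nm, 2])
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' Compares a reduced model (AE, CE or E) with the saturated ACE model (or E
#' with AE/CE): `delta = -2logL(nested) - (-2logL(full))` referred to an
#' upper-tail chi-square distribution with `delta_df` degrees of freedom.
#' The AIC column follows the relative convention `delta - 2 * delta_df`, so
#' a more negative value favours the reduced model.
#'
#' @param full,nested [fit_univariate()] results; `nested`'s free
#'   parameters must be a strict subset of `full`'s.
#' @return List with `delta_minus2logl`, `delta_df`, `p_value`, `aic`.
#' @export
compare_models <- function(full, nested) {
  stopifnot(inherits(full, "univariate_fit"),
            inherits(nested, "univariate_fit"))
  if (!all(model_paths(nested$model) %in% model_paths(full$model)) ||
      nested$n_params >= full$n_params) {
    stop_config("'%s' is not nested in '%s'", nested$model, full$model)
  }
  model_comparison(nested$minus2logl - full$minus2logl,
                   full$n_params - nested$n_params)
}

#' Nested-model comparison arithmetic
#'
#' The numeric core of [compare_models()], usable directly on published
#' likelihood differences: upper-tail chi-square p-value and relative AIC.
#'
#' @param delta_minus2logl difference in -2 log likelihood (nested minus
#'   full; must be >= 0 up to optimizer tolerance).
#' @param delta_df difference in free parameters (>= 1).
#' @return List with `delta_minus2logl`, `delta_df`, `p_value`, `aic`.
#' @export
model_comparison <- function(delta_minus2logl, delta_df) {
  if (delta_minus2logl < -1e-6) {
    stop_config("negative -2logL difference (%g): models not nested or not converged",
                delta_minus2logl)
  }
  if (delta_df < 1) stop_config("delta_df must be >= 1")
  delta <- max(delta_minus2logl, 0)
  list(delta_minus2logl = delta, delta_df = delta_df,
       p_value = stats::pchisq(delta, df = delta_df, lower.tail = FALSE),
       aic = delta - 2 * delta_df)
}

#' Univariate model table across phenotypes
#'
#' Fits the saturated ACE model and requested nested models for each
#' phenotype column and assembles a long results table (one row per
#' phenotype x model) with fit statistics, model comparisons against ACE
#' and standardized component estimates.
#'
#' @param table phenotype table (with `pair_id`, `zygosity`).
#' @param phenotypes columns to model.
#' @param models nested models to compare against ACE.
#' @param age_adjusted adjust each phenotype for age first.
#' @param ci compute profile-likelihood intervals.
#' @param seed optimizer restart seed.
#' @return Data frame with columns `phenotype`, `model`, `minus2logl`,
#'   `df`, `delta_minus2logl`, `delta_df`, `p_value`, `aic`, `a2`, `c2`,
#'   `e2` and CI bounds.
#' @export
univariate_table <- function(table,
                             phenotypes = c("pta", "pc1", "pc2",
                                            "pc1_minus_pc2", "behl"),
                             models = c("AE", "CE", "E"),
                             age_adjusted = TRUE, ci = FALSE, seed = 1L) {
  rows <- list()
  for (ph in phenotypes) {
    tab <- table
    col <- ph
    if (age_adjusted) {
      tab[[paste0(ph, "_adj")]] <- age_adjust(tab, ph)
      col <- paste0(ph, "_adj")
    }
    full <- fit_univariate(tab, col, "ACE", ci = ci, seed = seed)
    rows[[length(rows) + 1L]] <- fit_row(ph, full, NULL)
    for (m in models) {
      nested <- fit_univariate(tab, col, m, ci = ci, seed = seed)
      cmp <- compare_models(full, nested)
      rows[[length(rows) + 1L]] <- fit_row(ph, nested, cmp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_row <- function(ph, fit, cmp) {
  data.frame(
    phenotype = ph, model = fit$model,
    minus2logl = fit$minus2logl, df = fit$df,
    delta_minus2logl = if (is.null(cmp)) NA_real_ else cmp$delta_minus2logl,
    delta_df = if (is.null(cmp)) NA_integer_ else cmp$delta_df,
    p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
    aic = if (is.null(cmp)) NA_real_ else cmp$aic,
    a2 = fit$components$a2, c2 = fit$components$c2, e2 = fit$components$e2,
    a2_lo = ci_get(fit, "a2", 1), a2_hi = ci_get(fit, "a2", 2),
    c2_lo = ci_get(fit, "c2", 1), c2_hi = ci_get(fit, "c2", 2),
    e2_lo = ci_get(fit, "e2", 1), e2_hi = ci_get(fit, "e2", 2),
    stringsAsFactors = FALSE
  )
}

ci_get <- function(fit, comp, j) {
  if (is.null(fit$ci95)) NA_real_ else fit$ci95[comp, j]
}
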