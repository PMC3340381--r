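#' Normalizing cubic transform for SNR scores
#'
#' Centers at the median and applies a signed cube-root
#' (`sign(x - m) |x - m|^(1/3)`), which compresses the tails of skewed SNR
#' distributions toward normality. A literal-cube dialect
#' (`(x - m)^3`) is available via `method = "cube"`. The transform and
#' center are recorded as attributes.
#'
#' @param x numeric SNR values.
#' @param method `"cuberoot"` (default, normalizing) or `"cube"`.
#' @param center value to center at; defaults to the sample median.
#' @return Transformed vector with attributes `method` and `center`.
#' @export
cubic_transform <- function(x, method = c("cuberoot", "cube"),
                            center = stats::median(x, na.rm = TRUE)) {
  method <- match.arg(method)
  d <- x - center
  out <- switch(method,
                cuberoot = sign(d) * abs(d)^(1 / 3),
                cube = d^3)
  attr(out, "method") <- method
  attr(out, "center") <- center
  out
}

# --- data plumbing ----------------------------------------------------------

# Per-pair 4-vectors (x1, y1, x2, y2); singletons occupy member-1 slots.
bivariate_pairs <- function(data, x, y) {
  df <- if (inherits(data, "twin_cohort")) data$records else data
  for (nm in c("pair_id", "zygosity", x, y)) {
    if (!nm %in% names(df)) stop_config("column '%s' not found", nm)
  }
  keep <- !(is.na(df[[x]]) & is.na(df[[y]]))
  df <- df[keep, , drop = FALSE]
  rows <- list()
  for (zyg in c("MZ", "DZ")) {
    sel <- which(df$zygosity == zyg)
    if (!length(sel)) next
    sp <- split(sel, df$pair_id[sel])
    m <- t(vapply(sp, function(i) {
      if (length(i) == 2L) {
        c(df[[x]][i[1]], df[[y]][i[1]], df[[x]][i[2]], df[[y]][i[2]])
      } else {
        c(df[[x]][i], df[[y]][i], NA_real_, NA_real_)
      }
    }, numeric(4)))
    rows[[zyg]] <- m
  }
  sel <- which(df$zygosity == "singleton")
  if (length(sel)) {
    rows$singleton <- cbind(df[[x]][sel], df[[y]][sel],
                            NA_real_, NA_real_)
  }
  rows
}

# Group pair rows by missingness pattern; store sufficient statistics.
pattern_groups <- function(rows, complete_only = FALSE) {
  a_share <- c(MZ = 1, DZ = 0.5, singleton = 0)
  groups <- list()
  for (zyg in names(rows)) {
    m <- rows[[zyg]]
    if (complete_only && zyg != "singleton") {
      m <- m[stats::complete.cases(m), , drop = FALSE]
    }
    if (!nrow(m)) next
    mask_str <- apply(!is.na(m), 1, function(r) {
      paste(as.integer(r), collapse = "")
    })
    for (ms in unique(mask_str)) {
      mask <- strsplit(ms, "")[[1]] == "1"
      sub <- m[mask_str == ms, mask, drop = FALSE]
      if (!ncol(sub)) next
      groups[[length(groups) + 1L]] <- list(
        k = a_share[[zyg]], mask = which(mask), n = nrow(sub),
        s = colSums(sub), SXX = crossprod(sub)
      )
    }
  }
  groups
}

# Implied 4x4 covariance of (x1, y1, x2, y2) for the correlated-factors
# model. k is the additive-genetic sharing (1 MZ, 0.5 DZ).
cf_sigma <- function(par, k, model) {
  ax <- par[["ax"]]; ex <- par[["ex"]]; ay <- par[["ay"]]; ey <- par[["ey"]]
  ra <- par[["ra"]]; re <- par[["re"]]
  cx <- par[["cx"]] %||% 0; cy <- par[["cy"]] %||% 0; rc <- par[["rc"]] %||% 0
  if (model == "AE") { cx <- 0; cy <- 0; rc <- 0 }
  vx <- ax^2 + cx^2 + ex^2
  vy <- ay^2 + cy^2 + ey^2
  wxy <- ax * ay * ra + cx * cy * rc + ex * ey * re   # within person
  bxx <- k * ax^2 + cx^2                              # cross twin, trait x
  byy <- k * ay^2 + cy^2
  bxy <- k * ax * ay * ra + cx * cy * rc              # cross twin cross trait
  matrix(c(vx, wxy, bxx, bxy,
           wxy, vy, bxy, byy,
           bxx, bxy, vx, wxy,
           bxy, byy, wxy, vy), 4, 4)
}

m2ll_bivariate <- function(theta, groups, model) {
  nm <- if (model == "AE") {
    c("mux", "muy", "ax", "ex", "ay", "ey", "zra", "zre")
  } else {
    c("mux", "muy", "ax", "cx", "ex", "ay", "cy", "ey", "zra", "zrc", "zre")
  }
  names(theta) <- nm
  par <- list(ax = theta[["ax"]], ex = theta[["ex"]],
              ay = theta[["ay"]], ey = theta[["ey"]],
              ra = tanh(theta[["zra"]]), re = tanh(theta[["zre"]]))
  if (model == "ACE") {
    par$cx <- theta[["cx"]]; par$cy <- theta[["cy"]]
    par$rc <- tanh(theta[["zrc"]])
  }
  mu4 <- c(theta[["mux"]], theta[["muy"]], theta[["mux"]], theta[["muy"]])
  total <- 0
  for (g in groups) {
    S <- cf_sigma(par, g$k, model)[g$mask, g$mask, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    mu <- mu4[g$mask]
    M <- g$SXX - tcrossprod(g$s, mu) - tcrossprod(mu, g$s) +
      g$n * tcrossprod(mu)
    Sinv <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    total <- total + g$n * (length(mu) * log(2 * pi) + logdet) +
      sum(Sinv * M)
  }
  total
}

#' Fit the bivariate correlated-factors twin model
#'
#' Maximum-likelihood fit of the two-trait AE (default) or ACE
#' correlated-factors model to MZ/DZ pair data. Each trait has its own
#' latent factor paths; the genetic factors of the two traits correlate
#' `r_a` and the unique-environment factors `r_e`. Implied covariances:
#' same-trait cross-twin `k a_t^2` (k = 1 for MZ, 0.5 for DZ), cross-trait
#' within-person `a_x a_y r_a + e_x e_y r_e`, cross-trait cross-twin
#' `k a_x a_y r_a`. Pairs with one missing trait value contribute their
#' observed subvector's marginal likelihood (`complete_cases = TRUE` for
#' listwise deletion); singletons contribute their within-person block.
#'
#' Reported paths are standardized per trait (`a_x^2 + e_x^2 = 1`), so
#' `a_x^2` is trait X's heritability under the bivariate model and the
#' implied phenotypic correlation is `r_p = a_x a_y r_a + e_x e_y r_e`.
#'
#' @param data `twin_cohort` or phenotype table with `pair_id`, `zygosity`.
#' @param x,y trait column names (age-adjust and transform beforehand).
#' @param model `"AE"` (default) or `"ACE"`.
#' @param standardize scale each trait by its sample SD before fitting.
#' @param complete_cases drop pairs with any missing value.
#' @param restarts random restarts beyond the moment-based start.
#' @param seed restart seed.
#' @return Object of class `bivariate_fit` with standardized `a_x`, `e_x`,
#'   `a_y`, `e_y` (and `c_x`, `c_y` for ACE), `r_a`, `r_e`, `r_p`,
#'   `prop_genetic`, `minus2logl`, `df`, `n_params`, `n_obs`.
#' @export
fit_bivariate <- function(data, x, y, model = c("AE", "ACE"),
                          standardize = TRUE, complete_cases = FALSE,
                          restarts = 2L, seed = 1L) {
  model <- match.arg(model)
  rows <- bivariate_pairs(data, x, y)
  if (!length(rows)) stop_config("no usable pairs")
  n_pairs <- sum(vapply(rows[intersect(names(rows), c("MZ", "DZ"))], nrow,
                        integer(1)))
  if (n_pairs < 10L) stop_config("too few twin pairs for a bivariate fit")
  allm <- do.call(rbind, rows)
  sx <- if (standardize) stats::sd(c(allm[, 1], allm[, 3]), na.rm = TRUE) else 1
  sy <- if (standardize) stats::sd(c(allm[, 2], allm[, 4]), na.rm = TRUE) else 1
  if (sx == 0 || sy == 0) stop_config("constant trait")
  rows <- lapply(rows, function(m) sweep(m, 2, c(sx, sy, sx, sy), "/"))
  groups <- pattern_groups(rows, complete_only = complete_cases)
  n_obs <- sum(vapply(groups, function(g) g$n * length(g$mask), numeric(1)))

  allm <- do.call(rbind, rows)
  mux0 <- mean(c(allm[, 1], allm[, 3]), na.rm = TRUE)
  muy0 <- mean(c(allm[, 2], allm[, 4]), na.rm = TRUE)
  rxy <- stats::cor(c(allm[, 1], allm[, 3]), c(allm[, 2], allm[, 4]),
                    use = "pairwise.complete.obs")
  rxy <- max(min(rxy, 0.9, na.rm = TRUE), -0.9)
  z0 <- atanh(rxy)
  start0 <- if (model == "AE") {
    c(mux0, muy0, sqrt(0.5), sqrt(0.5), sqrt(0.5), sqrt(0.5), z0, z0)
  } else {
    c(mux0, muy0, sqrt(0.4), sqrt(0.2), sqrt(0.4),
      sqrt(0.4), sqrt(0.2), sqrt(0.4), z0, z0, z0)
  }
  obj <- function(th) m2ll_bivariate(th, groups, model)
  fits <- list(run_optim(obj, start0))
  fits <- c(fits, with_seed(seed, {
    lapply(seq_len(restarts), function(i) {
      th <- start0 + stats::rnorm(length(start0), 0, 0.2)
      run_optim(obj, th)
    })
  }))
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  if (!is.finite(best$value)) {
    stop_config("bivariate fit failed to converge from any start")
  }
  th <- best$par
  nm <- if (model == "AE") {
    c("mux", "muy", "ax", "ex", "ay", "ey", "zra", "zre")
  } else {
    c("mux", "muy", "ax", "cx", "ex", "ay", "cy", "ey", "zra", "zrc", "zre")
  }
  names(th) <- nm
  ax <- th[["ax"]]; ex <- th[["ex"]]; ay <- th[["ay"]]; ey <- th[["ey"]]
  cx <- if (model == "ACE") th[["cx"]] else 0
  cy <- if (model == "ACE") th[["cy"]] else 0
  ra <- tanh(th[["zra"]]); re <- tanh(th[["zre"]])
  rc <- if (model == "ACE") tanh(th[["zrc"]]) else NA_real_
  # resolve path-sign ambiguity: paths positive, signs absorbed into the
  # factor correlations
  ra <- ra * sign(ax) * sign(ay)
  re <- re * sign(ex) * sign(ey)
  if (model == "ACE") rc <- rc * sign(cx) * sign(cy)
  ax <- abs(ax); ex <- abs(ex); ay <- abs(ay); ey <- abs(ey)
  cx <- abs(cx); cy <- abs(cy)
  vx <- ax^2 + cx^2 + ex^2
  vy <- ay^2 + cy^2 + ey^2
  axs <- ax / sqrt(vx); exs <- ex / sqrt(vx); cxs <- cx / sqrt(vx)
  ays <- ay / sqrt(vy); eys <- ey / sqrt(vy); cys <- cy / sqrt(vy)
  r_p <- axs * ays * ra + exs * eys * re +
    (if (model == "ACE") cxs * cys * rc else 0)
  structure(list(
    model = model,
    a_x = axs, e_x = exs, a_y = ays, e_y = eys,
    c_x = if (model == "ACE") cxs else NA_real_,
    c_y = if (model == "ACE") cys else NA_real_,
    r_a = ra, r_e = re, r_c = rc,
    r_p = r_p,
    prop_genetic = if (abs(r_p) > 0) axs * ays * ra / r_p else NA_real_,
    minus2logl = best$value,
    n_params = length(th),
    df = n_obs - length(th),
    n_obs = n_obs,
    bound_hit = abs(ra) > 0.999,
    traits = c(x = x, y = y),
    scale = c(x = sx, y = sy)
  ), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate %s correlated-factors fit: %s vs %s\n",
              x$model, x$traits[["x"]], x$traits[["y"]]))
  cat(sprintf("  a2: %.3f / %.3f   e2: %.3f / %.3f\n",
              x$a_x^2, x$a_y^2, x$e_x^2, x$e_y^2))
  cat(sprintf("  r_a = %.3f, r_e = %.3f, implied r_p = %.3f\n",
              x$r_a, x$r_e, x$r_p))
  if (!is.na(x$prop_genetic)) {
    cat(sprintf("  share of phenotypic correlation due to genetics: %.1f%%\n",
                100 * x$prop_genetic))
  }
  invisible(x)
}

#' Share of the phenotypic correlation due to genetic factors
#'
#' `a_x a_y r_a / r_p`, expressed as a percentage.
#'
#' @param fit a [fit_bivariate()] result.
#' @return Percentage (may exceed 100 when genetic and environmental
#'   contributions have opposite signs).
#' @export
genetic_share <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (!is.finite(fit$r_p) || fit$r_p == 0) {
    stop_config("phenotypic correlation is zero; genetic share undefined")
  }
  100 * fit$a_x * fit$a_y * fit$r_a / fit$r_p
}
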