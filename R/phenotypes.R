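#' Better-ear selection
#'
#' Chooses, per subject, the ear with the lower mean threshold across all
#' frequencies (the "better ear") and returns that ear's full threshold
#' vector. Ties go to the left ear. Selection is whole-ear, not
#' per-frequency: a single ear represents the subject even if the other ear
#' is better at isolated frequencies. A frequency missing in the chosen ear
#' is filled from the other ear; a frequency missing in both ears yields
#' `NA` (cohort-level callers drop such subjects with a message).
#'
#' @param left,right numeric threshold vectors (dB HL), same frequency
#'   order.
#' @return Numeric vector of better-ear thresholds.
#' @export
better_ear <- function(left, right) {
  stopifnot(length(left) == length(right))
  ml <- mean(left, na.rm = TRUE)
  mr <- mean(right, na.rm = TRUE)
  if (is.nan(ml) && is.nan(mr)) return(rep(NA_real_, length(left)))
  pick_left <- is.nan(mr) || (!is.nan(ml) && ml <= mr)
  chosen <- if (pick_left) left else right
  other <- if (pick_left) right else left
  ifelse(is.na(chosen), other, chosen)
}

#' Shifted log transform of thresholds
#'
#' `log_base(threshold + offset)`. Audiometric thresholds in dB HL can be
#' negative (down to -10), so a positive offset (default 25 dB) guarantees a
#' positive argument.
#'
#' @param x thresholds in dB HL.
#' @param offset shift in dB added before taking logs.
#' @param base logarithm base.
#' @return Transformed values.
#' @export
log_transform <- function(x, offset = 25, base = 10) {
  shifted <- x + offset
  bad <- which(is.finite(shifted) & shifted <= 0)
  if (length(bad)) {
    stop_config("non-positive shifted threshold at position(s) %s (value + offset <= 0)",
                paste(bad, collapse = ", "))
  }
  log(shifted, base = base)
}

#' Pure-tone average and better-ear hearing level
#'
#' `pta` is the unweighted mean of the better-ear thresholds over all
#' configured frequencies; `behl` is the unweighted mean over 0.5, 1, 2 and
#' 4 kHz. Both are computed on raw (untransformed) dB.
#'
#' @param thresholds better-ear thresholds (dB HL).
#' @param freqs frequencies in kHz matching `thresholds`.
#' @param behl_freqs frequencies included in the BEHL average.
#' @return List with elements `pta` and `behl`.
#' @export
scalar_averages <- function(thresholds, freqs,
                            behl_freqs = c(0.5, 1, 2, 4)) {
  if (length(freqs) == 0L) stop_config("empty frequency configuration")
  stopifnot(length(thresholds) == length(freqs))
  sel <- freqs %in% behl_freqs
  if (!any(sel)) stop_config("no configured frequency lies in the BEHL band")
  list(pta = mean(thresholds), behl = mean(thresholds[sel]))
}

#' Better-ear log-transformed audiogram matrix for a cohort
#'
#' Applies [better_ear()] per subject, drops subjects with a frequency
#' missing in both ears (reported via `message`), and log-transforms the
#' result.
#'
#' @param cohort a `twin_cohort`.
#' @param offset,base see [log_transform()].
#' @return Object of class `audiogram_matrix`: list with `subjects`,
#'   `freqs`, `values` (subjects x freqs, transformed), `raw` (better-ear
#'   dB HL) and `transform_params`.
#' @export
audiogram_matrix <- function(cohort, offset = 25, base = 10) {
  stopifnot(inherits(cohort, "twin_cohort"))
  freqs <- cohort_freqs(cohort)
  L <- as.matrix(cohort$records[paste0("thr_L_", freqs)])
  R <- as.matrix(cohort$records[paste0("thr_R_", freqs)])
  raw <- t(vapply(seq_len(nrow(L)),
                  function(i) better_ear(L[i, ], R[i, ]),
                  numeric(length(freqs))))
  keep <- stats::complete.cases(raw)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped: threshold missing in both ears")
  }
  values <- log_transform(raw[keep, , drop = FALSE], offset, base)
  colnames(values) <- colnames(raw) <- freqs
  structure(list(subjects = cohort$records$subject_id[keep],
                 freqs = freqs, values = values,
                 raw = raw[keep, , drop = FALSE],
                 transform_params = c(offset = offset, base = base)),
            class = "audiogram_matrix")
}

#' Principal components of the audiogram
#'
#' PCA of the correlation matrix of log-transformed better-ear thresholds
#' (covariance PCA available via `use = "covariance"`). Components with
#' eigenvalue > 1 are retained by default. Signs are fixed so that PC1
#' loadings are all positive (overall level) and PC2's lowest-frequency
#' loading is positive, making PC2 decrease from low to high frequencies
#' (the audiogram-shape component).
#'
#' @param am an [audiogram_matrix()].
#' @param n_components number of components to retain, or `NULL` for the
#'   eigenvalue > 1 rule.
#' @param use `"correlation"` (default) or `"covariance"`.
#' @return Object of class `audiogram_pca`: `loadings` (freqs x retained),
#'   `eigenvalues` (all), `scores` (subjects x retained, variance equal to
#'   the eigenvalue), `var_explained`, `center`, `scale`, `freqs`,
#'   `sign_convention`.
#' @export
fit_pca <- function(am, n_components = NULL, use = c("correlation", "covariance")) {
  stopifnot(inherits(am, "audiogram_matrix"))
  use <- match.arg(use)
  X <- am$values
  if (nrow(X) < 2L || ncol(X) < 2L) {
    stop_config("PCA needs at least 2 subjects and 2 frequencies")
  }
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_config("constant column (zero-variance frequency): %s kHz",
                paste(am$freqs[sds == 0], collapse = ", "))
  }
  scl <- if (use == "correlation") sds else rep(1, ncol(X))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  S <- stats::cov(Z)
  eig <- eigen(S, symmetric = TRUE)
  k <- if (is.null(n_components)) max(1L, sum(eig$values > 1)) else n_components
  k <- min(k, ncol(X))
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  # sign conventions: PC1 uniformly positive, PC2 positive at low frequencies
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  if (k >= 2L) {
    lowf <- seq_len(ceiling(nrow(V) / 2))
    if (sum(V[lowf, 2]) < 0) V[, 2] <- -V[, 2]
  }
  scores <- Z %*% V
  rownames(V) <- am$freqs
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = V, eigenvalues = eig$values,
                 scores = scores,
                 var_explained = eig$values[seq_len(k)] / sum(eig$values),
                 center = ctr, scale = scl, freqs = am$freqs, use = use,
                 transform_params = am$transform_params,
                 sign_convention = "PC1 loadings positive; PC2 positive at low frequencies"),
            class = "audiogram_pca")
}

#' @export
print.audiogram_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  cat("Audiogram PCA (", x$use, " matrix): ", k, " component(s) retained, ",
      round(100 * sum(x$var_explained), 1), "% of variance\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Build the per-subject phenotype table
#'
#' Combines the scalar averages (PTA, BEHL; raw dB) with principal-component
#' scores (PC1, PC2 and their difference PC1 - PC2, on log-transformed
#' thresholds) and carries age, zygosity and SNR through. Scores are
#' computed by projecting each subject's standardized transformed audiogram
#' onto the fitted loadings, so subjects outside the fitting sample can be
#' scored with a frozen PCA.
#'
#' @param cohort a `twin_cohort`.
#' @param pca an [fit_pca()] result (must carry at least 2 components).
#' @param am optional precomputed [audiogram_matrix()] consistent with
#'   `pca`; computed from the cohort when omitted.
#' @return Data frame of class `phenotype_table` with columns `subject_id`,
#'   `pair_id`, `zygosity`, `age`, `sex`, `pta`, `behl`, `pc1`, `pc2`,
#'   `pc1_minus_pc2`, `snr`.
#' @export
build_phenotypes <- function(cohort, pca, am = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"), inherits(pca, "audiogram_pca"))
  if (is.null(am)) {
    am <- audiogram_matrix(cohort,
                           offset = pca_offset(pca), base = pca_base(pca))
  }
  if (!identical(am$freqs, pca$freqs)) {
    stop_config("frequency mismatch between cohort (%s) and PCA loadings (%s)",
                paste(am$freqs, collapse = "/"),
                paste(pca$freqs, collapse = "/"))
  }
  if (ncol(pca$loadings) < 2L) {
    stop_config("phenotype construction needs at least 2 retained components")
  }
  Z <- sweep(sweep(am$values, 2, pca$center), 2, pca$scale, "/")
  scores <- Z %*% pca$loadings
  avg <- t(apply(am$raw, 1, function(v) {
    unlist(scalar_averages(v, am$freqs))
  }))
  rec <- cohort$records[match(am$subjects, cohort$records$subject_id), ]
  out <- data.frame(
    subject_id = am$subjects,
    pair_id = rec$pair_id, zygosity = rec$zygosity,
    age = rec$age, sex = rec$sex,
    pta = avg[, "pta"], behl = avg[, "behl"],
    pc1 = scores[, 1], pc2 = scores[, 2],
    pc1_minus_pc2 = scores[, 1] - scores[, 2],
    snr = rec$snr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

pca_offset <- function(pca) unname(pca$transform_params["offset"] %||% 25)
pca_base <- function(pca) unname(pca$transform_params["base"] %||% 10)

#' Rank candidate hearing phenotypes
#'
#' Ranks phenotypes by two criteria: (i) magnitude of the Pearson
#' correlation with age and (ii) capture of audiogram shape, measured as the
#' semi-partial variance in PC2 explained beyond age. To respect twin
#' relatedness, the shared-variance regressions use one randomly selected
#' twin per pair (fixed seed); singletons are always included. PC2 itself is
#' excluded from the shape criterion (self-comparison). Ties share the
#' minimum rank; the overall order is by the sum of the two ranks.
#'
#' @param table a [build_phenotypes()] table.
#' @param phenotypes columns to rank.
#' @param seed seed for the one-twin-per-pair subsample.
#' @return Data frame of class `phenotype_ranking` with columns `phenotype`,
#'   `r_age`, `rank_age`, `r2_pc2`, `rank_pc2`, `rank_sum`, `overall_rank`.
#' @export
rank_phenotypes <- function(table,
                            phenotypes = c("pc1_minus_pc2", "pta", "pc1",
                                           "behl", "pc2"),
                            seed = 2012L) {
  stopifnot(inherits(table, "data.frame"), "age" %in% names(table))
  if (length(phenotypes) < 2L) stop_config("need at least 2 phenotypes to rank")
  keep <- vapply(phenotypes,
                 function(p) stats::sd(table[[p]], na.rm = TRUE) > 0,
                 logical(1))
  if (any(!keep)) {
    warning("zero-variance phenotype(s) excluded: ",
            paste(phenotypes[!keep], collapse = ", "))
    phenotypes <- phenotypes[keep]
  }
  r_age <- vapply(phenotypes, function(p) {
    stats::cor(table[[p]], table$age, use = "complete.obs")
  }, numeric(1))

  # one twin per pair for the relatedness-adjusted shape regressions
  sub <- with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(table)), table$pair_id),
                         function(i) if (length(i) > 1L) sample(i, 1L) else i))
    table[sort(idx), ]
  })
  r2_pc2 <- vapply(phenotypes, function(p) {
    if (p == "pc2") return(NA_real_)
    dat <- sub[stats::complete.cases(sub[c("pc2", "age", p)]), ]
    base_fit <- stats::lm(pc2 ~ age, data = dat)
    full_fit <- stats::lm(stats::reformulate(c("age", p), "pc2"), data = dat)
    summary(full_fit)$r.squared - summary(base_fit)$r.squared
  }, numeric(1))
  rank_from_criteria(phenotypes, r_age, r2_pc2)
}

#' Rank phenotypes from precomputed criterion values
#'
#' The ranking arithmetic of [rank_phenotypes()], usable directly on
#' published criterion values. Ranks are descending in `|r_age|` and in
#' `r2_pc2`, ties share the minimum rank, and a phenotype with `NA`
#' `r2_pc2` (the shape criterion's own reference) is excluded from the
#' overall ordering.
#'
#' @param phenotypes character names.
#' @param r_age correlations with age.
#' @param r2_pc2 shared-variance criterion values (`NA` to exclude).
#' @return A `phenotype_ranking` data frame.
#' @export
rank_from_criteria <- function(phenotypes, r_age, r2_pc2) {
  min_rank_desc <- function(x) {
    r <- rep(NA_integer_, length(x))
    ok <- !is.na(x)
    # min-rank convention: ties share the smallest rank of the block
    r[ok] <- rank(-x[ok], ties.method = "min")
    r
  }
  rank_age <- min_rank_desc(abs(r_age))
  rank_pc2 <- min_rank_desc(r2_pc2)
  rank_sum <- rank_age + rank_pc2
  overall <- rep(NA_integer_, length(rank_sum))
  ok <- !is.na(rank_sum)
  overall[ok] <- rank(rank_sum[ok], ties.method = "min")
  out <- data.frame(phenotype = phenotypes, r_age = r_age,
                    rank_age = rank_age, r2_pc2 = r2_pc2,
                    rank_pc2 = rank_pc2, rank_sum = rank_sum,
                    overall_rank = overall, stringsAsFactors = FALSE)
  out <- out[order(is.na(out$overall_rank), out$overall_rank), ]
  rownames(out) <- NULL
  class(out) <- c("phenotype_ranking", "data.frame")
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on `k - 1` degrees of freedom. Used to compare phenotype distributions
#' across MZ twins, DZ twins and singletons.
#'
#' @param values numeric observations.
#' @param groups group labels, at least two non-empty groups.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop_config("Kruskal-Wallis needs at least 2 groups")
  if (any(tabulate(groups) == 0L)) stop_config("empty group")
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  denom <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (denom > 0) H / denom else 0
  list(H = H, df = k - 1L,
       p_value = stats::pchisq(H, df = k - 1L, lower.tail = FALSE), n = n)
}

#' Zygosity-group comparison of phenotypes
#'
#' Kruskal-Wallis comparison of each phenotype across MZ, DZ and singleton
#' groups.
#'
#' @param table a phenotype table with a `zygosity` column.
#' @param phenotypes columns to compare.
#' @return Data frame with `phenotype`, `H`, `p_value`.
#' @export
compare_zygosity_groups <- function(table,
                                    phenotypes = c("pta", "pc1", "pc2",
                                                   "pc1_minus_pc2", "behl")) {
  res <- lapply(phenotypes, function(p) {
    kw <- kruskal_wallis(table[[p]], table$zygosity)
    data.frame(phenotype = p, H = kw$H, p_value = kw$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
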