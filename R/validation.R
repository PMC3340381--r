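#' Binary hearing-impairment reference labels
#'
#' Labels a subject impaired (1) when the reference phenotype strictly
#' exceeds the rule threshold. Two rules mirror the audiometric references:
#' `pta_gt` (moderate impairment, pure-tone average above a dB cutoff,
#' conventionally 40 dB) and `pc_diff_gt` (PC1 - PC2 composite score above a
#' cutoff).
#'
#' @param table phenotype table.
#' @param rule single-element named list: `list(pta_gt = 40)` or
#'   `list(pc_diff_gt = 3.4)`.
#' @return Integer 0/1 labels (`NA` where the reference is missing).
#' @export
binary_reference <- function(table, rule) {
  if (length(rule) != 1L || is.null(names(rule))) {
    stop_config("rule must be a single named threshold")
  }
  col <- switch(names(rule),
                pta_gt = "pta",
                pc_diff_gt = "pc1_minus_pc2",
                stop_config("unknown rule '%s'", names(rule)))
  if (!col %in% names(table)) stop_config("column '%s' not found", col)
  labels <- as.integer(table[[col]] > rule[[1]])
  if (all(labels == 0L, na.rm = TRUE)) {
    warning("no positive reference labels under rule ",
            names(rule), " = ", rule[[1]])
  }
  labels
}

#' ROC curve of the SNR screening test
#'
#' Sweeps all distinct score values as cutoffs; a subject is test-positive
#' when their SNR score strictly exceeds the cutoff (higher SNR = more
#' favourable speech-to-noise ratio required = worse hearing). Sensitivity
#' and specificity come from direct 2x2 counting; the AUC is the trapezoid
#' area over (1 - specificity, sensitivity).
#'
#' @param scores numeric test scores (dB SNR).
#' @param labels 0/1 reference labels (1 = impaired).
#' @param reference_rule free-text description carried into the result.
#' @param direction `"greater"` (default): test-positive when
#'   `score > cutoff`, the convention for a speech-reception threshold
#'   where worse listeners need a higher SNR. `"less"` reverses the rule
#'   for worlds in which impairment lowers the score (e.g. a synthetic
#'   cohort generated with negative audiogram-SNR factor correlations).
#' @return Object of class `roc_curve`: data frame `points` (cutoff,
#'   sensitivity, specificity), `auc`, `reference_rule`.
#' @export
roc_curve <- function(scores, labels, reference_rule = "",
                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (direction == "less") {
    rc <- roc_curve(-scores, labels, reference_rule, direction = "greater")
    rc$points$cutoff <- -rc$points$cutoff
    rc$direction <- "less"
    return(rc)
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_config("both classes must be present (pos = %d, neg = %d)",
                n_pos, n_neg)
  }
  # cutoffs: below all scores, each distinct score; positive = score > cutoff
  cutoffs <- c(min(scores) - 1, sort(unique(scores)))
  sens <- vapply(cutoffs, function(ct) sum(scores > ct & labels == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(cutoffs, function(ct) sum(scores <= ct & labels == 0L) / n_neg,
                 numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(list(points = data.frame(cutoff = cutoffs, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 reference_rule = reference_rule, direction = "greater"),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC = %.3f over %d cutoffs (%d impaired / %d normal)\n",
              x$reference_rule, x$auc, nrow(x$points), x$n_pos, x$n_neg))
  invisible(x)
}

#' Operating point maximizing Youden's J
#'
#' Selects the cutoff with maximal `J = sensitivity + specificity - 1`;
#' ties are broken toward higher sensitivity.
#'
#' @param curve a [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
best_operating_point <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  j <- p$sensitivity + p$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(p$sensitivity[best])]
  list(cutoff = p$cutoff[best], sensitivity = p$sensitivity[best],
       specificity = p$specificity[best], youden_j = j[best])
}

#' Operating point at a fixed cutoff
#'
#' Sensitivity/specificity of the rule "positive when score > cutoff",
#' for reporting performance at a pre-chosen SNR threshold.
#'
#' @param scores,labels,direction as in [roc_curve()].
#' @param cutoff dB SNR cutoff.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
operating_point_at <- function(scores, labels, cutoff,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  pos <- if (direction == "greater") scores > cutoff else scores < cutoff
  sens <- sum(pos & labels == 1L) / sum(labels == 1L)
  spec <- sum(!pos & labels == 0L) / sum(labels == 0L)
  list(cutoff = cutoff, sensitivity = sens, specificity = spec,
       youden_j = sens + spec - 1)
}

#' Bland-Altman repeatability analysis with Pitman's test
#'
#' For paired first/second measurements: mean difference with its t-based
#' 95% CI, 95% limits of agreement (`mean +/- 1.96 SD` of the differences),
#' and Pitman's test of equal variances, implemented classically as the
#' t-test on the correlation between sums and differences (n - 2 degrees of
#' freedom). Degenerate inputs (zero-variance sums or differences) are
#' flagged and reported with `p = 1`.
#'
#' @param first,second paired measurements (same length, `NA` pairs
#'   dropped).
#' @return Object of class `bland_altman`: `n`, `mean_diff`,
#'   `ci95_mean_diff`, `loa95`, `sd_diff`, `pitman_r`, `pitman_stat`,
#'   `pitman_p`, `degenerate`.
#' @export
bland_altman <- function(first, second) {
  stopifnot(length(first) == length(second))
  ok <- !is.na(first) & !is.na(second)
  first <- first[ok]; second <- second[ok]
  n <- length(first)
  if (n < 3L) stop_config("Bland-Altman needs at least 3 complete pairs")
  d <- first - second
  s <- first + second
  md <- mean(d)
  sdd <- stats::sd(d)
  se <- sdd / sqrt(n)
  tcrit <- stats::qt(0.975, df = n - 1)
  degenerate <- sdd == 0 || stats::sd(s) == 0
  if (degenerate) {
    r <- NA_real_; tstat <- NA_real_; p <- 1
  } else {
    r <- stats::cor(s, d)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(list(n = n, mean_diff = md,
                 ci95_mean_diff = c(md - tcrit * se, md + tcrit * se),
                 loa95 = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 sd_diff = sdd,
                 pitman_r = r, pitman_stat = tstat, pitman_p = p,
                 degenerate = degenerate),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.3f (95%% CI %.3f to %.3f)\n",
              x$n, x$mean_diff, x$ci95_mean_diff[1], x$ci95_mean_diff[2]))
  cat(sprintf("  limits of agreement %.3f to %.3f; Pitman p = %.3f\n",
              x$loa95[1], x$loa95[2], x$pitman_p))
  invisible(x)
}

#' Correlation of the SNR test with audiogram phenotypes
#'
#' Pairwise Pearson correlations between the SNR score and each audiogram
#' phenotype, with listwise-deletion counts.
#'
#' @param table phenotype table containing `snr`.
#' @param phenotypes columns to correlate with `snr`.
#' @return Data frame with `phenotype`, `r`, `n`.
#' @export
correlate_tests <- function(table,
                            phenotypes = c("pta", "behl", "pc1", "pc2",
                                           "pc1_minus_pc2")) {
  if (sum(!is.na(table$snr)) < 3L) stop_config("fewer than 3 SNR values")
  rows <- lapply(phenotypes, function(p) {
    v <- table[[p]]
    ok <- !is.na(v) & !is.na(table$snr)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0) {
      warning("phenotype '", p, "' excluded (missing or constant)")
      return(NULL)
    }
    data.frame(phenotype = p, r = stats::cor(v[ok], table$snr[ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_config("no usable phenotype columns")
  out
}
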