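# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Tiny hand-built cohort records frame (2 MZ pairs, 1 DZ pair, 1 singleton)
# with flat audiograms at given levels.
tiny_records <- function(levels = c(10, 20, 30, 40, 50, 60, 70),
                         freqs = c(0.125, 0.25, 0.5, 1, 2, 4, 8)) {
  n <- length(levels)
  zyg <- c("MZ", "MZ", "MZ", "MZ", "DZ", "DZ", "singleton")[seq_len(n)]
  pid <- c("p1", "p1", "p2", "p2", "p3", "p3", "p4")[seq_len(n)]
  rec <- data.frame(
    subject_id = sprintf("T%02d", seq_len(n)),
    pair_id = pid, zygosity = zyg,
    age = c(50, 50, 60, 60, 70, 70, 55)[seq_len(n)],
    sex = "F", stringsAsFactors = FALSE
  )
  for (f in freqs) {
    rec[[paste0("thr_L_", f)]] <- levels
    rec[[paste0("thr_R_", f)]] <- levels
  }
  rec$snr <- NA_real_
  rec
}

# Direct pair-level generator for one standardized ACE trait: the
# closed-form oracle generator used by the univariate tests, independent of
# simulate_cohort().
sim_ace_pairs <- function(n_mz, n_dz, a2, c2 = 0, e2 = 1 - a2 - c2,
                          mu = 0, sd_total = 1, seed = NULL,
                          n_singletons = 0) {
  draw <- function(n, share) {
    if (share == 1) {
      z <- rnorm(n); cbind(z, z)
    } else if (share == 0) {
      matrix(rnorm(2 * n), n, 2)
    } else {
      sqrt(share) * rnorm(n) + sqrt(1 - share) * matrix(rnorm(2 * n), n, 2)
    }
  }
  gen <- function(n, a_share) {
    sqrt(a2) * draw(n, a_share) + sqrt(c2) * draw(n, 1) +
      sqrt(e2) * draw(n, 0)
  }
  audiotwin:::with_seed(seed, {
    mz <- mu + sd_total * gen(n_mz, 1)
    dz <- mu + sd_total * gen(n_dz, 0.5)
    sing <- mu + sd_total * rnorm(n_singletons)
    df <- data.frame(
      pair_id = c(rep(sprintf("mz%04d", seq_len(n_mz)), each = 2),
                  rep(sprintf("dz%04d", seq_len(n_dz)), each = 2),
                  if (n_singletons) sprintf("s%04d", seq_len(n_singletons))),
      zygosity = c(rep("MZ", 2 * n_mz), rep("DZ", 2 * n_dz),
                   rep("singleton", n_singletons)),
      y = c(t(mz), t(dz), sing),
      stringsAsFactors = FALSE
    )
    df$subject_id <- sprintf("U%05d", seq_len(nrow(df)))
    df
  })
}

# Degenerate audiogram simulation where the pure-tone average is an exact
# affine function of the latent size factor (no slope factor, no ear noise,
# no age trend, no rounding): used for bivariate recovery tests.
sim_affine_cohort <- function(n_mz, n_dz, seed, r_a = -0.67, r_e = -0.2,
                              a2 = 0.7, h2 = 0.7) {
  simulate_cohort(sim_config(
    n_mz_pairs = n_mz, n_dz_pairs = n_dz, n_singletons = 1,
    slope_loadings = rep(0, 7), size_loadings = rep(6, 7),
    age_slope = rep(0, 7), ear_noise_sd = 0, round_to_5db = FALSE,
    var_components = list(size = c(a2 = a2, c2 = 0, e2 = 1 - a2),
                          slope = c(a2 = 0.7, c2 = 0, e2 = 0.3)),
    srt_params = list(mean = -10.2, sd = 2.2, r_a = r_a, r_e = r_e, h2 = h2),
    seed = seed
  ))
}

# Pair/zygosity table with x = PTA (raw mean over frequencies), y = snr.
affine_xy_table <- function(cohort) {
  fr <- cohort_freqs(cohort)
  data.frame(
    pair_id = cohort$records$pair_id,
    zygosity = cohort$records$zygosity,
    x = rowMeans(cohort$records[paste0("thr_L_", fr)]),
    y = cohort$records$snr,
    stringsAsFactors = FALSE
  )
}

# Exhaustive concordance-probability AUC oracle: P(score_pos > score_neg)
# + 0.5 P(tie) over all positive/negative pairs.
auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
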