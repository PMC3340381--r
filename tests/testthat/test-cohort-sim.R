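test_that("configuration errors are rejected", {
  expect_error(sim_config(n_mz_pairs = 0), "positive")
  expect_error(sim_config(n_dz_pairs = -1), "positive")
  expect_error(sim_config(var_components = list(
    size = c(a2 = 0.5, c2 = 0.4, e2 = 0.3),
    slope = c(a2 = 0.7, c2 = 0, e2 = 0.3))), "summing to 1")
  expect_error(sim_config(var_components = list(
    size = c(a2 = 1.2, c2 = -0.2, e2 = 0),
    slope = c(a2 = 0.7, c2 = 0, e2 = 0.3))), "non-negative")
  expect_error(sim_config(srt_params = list(mean = -10, sd = 2, r_a = 1.2,
                                            r_e = 0, h2 = 0.7)), "r_a")
  expect_error(sim_config(freqs = c(1, 1, 2)), "strictly increasing")
  expect_error(sim_config(mean_profile = 1:3), "length 7")
})

test_that("full genetic sharing makes MZ co-twins identical", {
  cfg <- sim_config(
    n_mz_pairs = 30, n_dz_pairs = 5, n_singletons = 0,
    var_components = list(size = c(a2 = 1, c2 = 0, e2 = 0),
                          slope = c(a2 = 1, c2 = 0, e2 = 0)),
    ear_noise_sd = 0, round_to_5db = FALSE, seed = 11
  )
  co <- simulate_cohort(cfg)
  mz <- co$records[co$records$zygosity == "MZ", ]
  thr <- grep("^thr_", names(mz), value = TRUE)
  for (pid in unique(mz$pair_id)) {
    pr <- mz[mz$pair_id == pid, thr]
    expect_equal(unname(unlist(pr[1, ])), unname(unlist(pr[2, ])))
  }
})

test_that("cohort shape and pair bookkeeping are exact", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 2, n_dz_pairs = 1,
                                   n_singletons = 1, seed = 3))
  expect_equal(nrow(co$records), 7L)  # 2x2 + 1x2 + 1
  counts <- table(co$records$pair_id)
  expect_equal(sum(counts == 2L), 3L)
  expect_equal(sum(counts == 1L), 1L)
  expect_false(anyDuplicated(co$records$subject_id) > 0)
  # pair members share pair-level attributes
  by_pair <- split(co$records, co$records$pair_id)
  for (pr in by_pair) {
    expect_length(unique(pr$age), 1L)
    expect_length(unique(pr$zygosity), 1L)
  }
})

test_that("identical seed gives a bit-identical cohort; rounding works", {
  cfg <- sim_config(n_mz_pairs = 15, n_dz_pairs = 15, n_singletons = 3,
                    seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$latent, b$latent)
  thr <- as.matrix(a$records[grep("^thr_", names(a$records))])
  expect_true(all(thr %% 5 == 0))
  # latent truth is kept out of the observed records
  expect_false(any(c("size", "slope", "srt_true") %in% names(a$records)))
})

test_that("latent twin correlations match the generating ACE structure", {
  cfg <- sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000, n_singletons = 1,
                    seed = 99)
  co <- simulate_cohort(cfg)
  lat <- merge(co$latent, co$records[c("subject_id", "pair_id", "zygosity")],
               by = "subject_id")
  icc <- function(zyg, col) {
    m <- do.call(rbind, lapply(split(lat[[col]][lat$zygosity == zyg],
                                     lat$pair_id[lat$zygosity == zyg]),
                               identity))
    stats::cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
  }
  # generating truth a2 = 0.7, c2 = 0 for both latent traits
  expect_equal(icc("MZ", "size"), 0.70, tolerance = 0.03)
  expect_equal(icc("DZ", "size"), 0.35, tolerance = 0.03)
  expect_equal(icc("MZ", "slope"), 0.70, tolerance = 0.03)
  expect_equal(icc("DZ", "slope"), 0.35, tolerance = 0.03)
  # componentwise recovery through the closed-form estimates
  fal <- falconer_estimates(list(r_mz = icc("MZ", "size"),
                                 r_dz = icc("DZ", "size")))
  expect_equal(fal$a2, 0.7, tolerance = 0.03)
  expect_equal(abs(fal$c2), 0, tolerance = 0.03)
  expect_equal(fal$e2, 0.3, tolerance = 0.03)

  # cross-twin cross-trait: MZ covariance of twin-1 audiogram factor with
  # twin-2 SRT is ~2x the DZ value when c2 = 0
  xcov <- function(zyg) {
    sub <- lat[lat$zygosity == zyg, ]
    sp <- split(sub, sub$pair_id)
    s1 <- vapply(sp, function(d) d$size[1], numeric(1))
    srt2 <- vapply(sp, function(d) d$srt_true[2], numeric(1))
    s2 <- vapply(sp, function(d) d$size[2], numeric(1))
    srt1 <- vapply(sp, function(d) d$srt_true[1], numeric(1))
    stats::cov(c(s1, s2), c(srt2, srt1))
  }
  expect_equal(xcov("MZ") / xcov("DZ"), 2, tolerance = 0.2)
})

test_that("repeat_measurement behaves as a true-score-plus-noise retest", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 10, n_dz_pairs = 10,
                                   n_singletons = 0, seed = 5))
  r0 <- repeat_measurement(co, noise_sd = 0, seed = 1)
  expect_equal(r0$second, r0$first)

  big <- simulate_cohort(sim_config(n_mz_pairs = 2500, n_dz_pairs = 2500,
                                    n_singletons = 0, seed = 6))
  r1 <- repeat_measurement(big, noise_sd = 1, seed = 2)
  expect_equal(mean(r1$first - r1$second), 0, tolerance = 0.05)

  blank <- simulate_cohort(sim_config(n_mz_pairs = 2, n_dz_pairs = 2,
                                      n_singletons = 0, observe_snr = FALSE,
                                      seed = 7))
  expect_warning(r2 <- repeat_measurement(blank, noise_sd = 1, seed = 3),
                 "no subjects")
  expect_equal(nrow(r2), 0L)
})

test_that("cohort CSV round trip is exact and malformed files are rejected", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 8, n_dz_pairs = 8,
                                   n_singletons = 2, seed = 21))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$records, co$records)
  expect_s3_class(back$config, "sim_config")
  expect_equal(back$config$seed, 21L)

  # triple-occurring pair id
  bad <- co$records
  bad$pair_id[bad$zygosity == "singleton"][1] <- bad$pair_id[1]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE, na = "")
  expect_error(read_cohort(p2), "cardinality")

  # zygosity outside the allowed set
  bad2 <- co$records
  bad2$zygosity[1] <- "XX"
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad2, p3, row.names = FALSE, na = "")
  expect_error(read_cohort(p3), "zygosity")

  # empty file
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(co$records[0, ], p4, row.names = FALSE)
  expect_error(read_cohort(p4), "no records")
})
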