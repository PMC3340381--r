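#' Simulation configuration for a synthetic twin cohort
#'
#' Describes the generating model for a female twin cohort with pure-tone
#' audiograms and a genetically correlated speech-reception threshold (SRT).
#' Each subject carries two latent audiogram factors: an overall-level
#' ("size") factor that raises thresholds at all frequencies, and a
#' high-frequency-downslope ("slope") factor whose loadings change sign from
#' low to high frequencies. Each latent factor decomposes into
#' additive-genetic (A), common-environment (C) and unique-environment (E)
#' parts: A correlates 1 within MZ pairs and 0.5 within DZ pairs, C is fully
#' shared within pairs, E is independent. The SRT trait is built from the
#' size factor's A and E components so that its latent genetic and
#' environmental correlations with the overall-level factor equal `r_a` and
#' `r_e` exactly in expectation.
#'
#' Default numbers of pairs and singletons, the age range and the SRT
#' mean/SD mirror a middle-aged female volunteer twin cohort; the
#' per-frequency baseline profile and age slopes are illustrative values for
#' age-related high-frequency hearing loss, not estimates from any specific
#' data set.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of monozygotic / dizygotic pairs
#'   (both must be positive).
#' @param n_singletons number of unpaired subjects (may be 0).
#' @param age_range ascending pair of ages in years; pair ages are uniform
#'   on this range and shared within pairs.
#' @param freqs strictly increasing test frequencies in kHz.
#' @param mean_profile per-frequency baseline threshold (dB HL) at the
#'   anchor age of 60 years.
#' @param age_slope per-frequency threshold increase in dB per year of age.
#' @param size_loadings per-frequency loading (dB per SD) of the latent
#'   overall-level factor.
#' @param slope_loadings per-frequency loading (dB per SD) of the latent
#'   downslope factor; negative at low and positive at high frequencies.
#' @param var_components list with elements `size` and `slope`, each a named
#'   `(a2, c2, e2)` triple of non-negative variance shares summing to 1.
#' @param srt_params list with `mean` (dB SNR), `sd` (dB), `r_a`, `r_e`
#'   (latent genetic/environmental correlations with the overall-level
#'   factor, in `[-1, 1]`) and `h2` (the SRT trait's own additive-genetic
#'   share; the remainder is unique environment).
#' @param ear_noise_sd SD (dB) of independent per-ear measurement noise.
#' @param round_to_5db round thresholds to the nearest 5 dB (audiometric
#'   convention).
#' @param observe_snr if `TRUE` the `snr` column is filled with the true
#'   SRT; if `FALSE` it is left missing (e.g. to be filled by
#'   [administer_snr_test()]).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_mz_pairs = 232L,
                       n_dz_pairs = 264L,
                       n_singletons = 41L,
                       age_range = c(41, 86),
                       freqs = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                       mean_profile = c(14, 13, 13, 15, 19, 28, 42),
                       age_slope = c(0.20, 0.20, 0.25, 0.35, 0.55, 0.85, 1.10),
                       size_loadings = rep(6, 7),
                       slope_loadings = c(-5, -4, -2.5, 0.5, 3, 6, 9),
                       var_components = list(
                         size = c(a2 = 0.7, c2 = 0, e2 = 0.3),
                         slope = c(a2 = 0.7, c2 = 0, e2 = 0.3)
                       ),
                       srt_params = list(mean = -10.2, sd = 2.2,
                                         r_a = -0.67, r_e = -0.20, h2 = 0.7),
                       ear_noise_sd = 5.5,
                       round_to_5db = TRUE,
                       observe_snr = TRUE,
                       seed = NULL) {
  if (n_mz_pairs < 1 || n_dz_pairs < 1) {
    stop_config("n_mz_pairs and n_dz_pairs must be positive")
  }
  if (n_singletons < 0) stop_config("n_singletons must be >= 0")
  if (length(age_range) != 2L || diff(age_range) < 0) {
    stop_config("age_range must be an ascending (lo, hi) pair")
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop_config("freqs must be strictly increasing")
  }
  nf <- length(freqs)
  for (nm in c("mean_profile", "age_slope", "size_loadings", "slope_loadings")) {
    v <- get(nm)
    if (length(v) != nf || any(!is.finite(v))) {
      stop_config("%s must be finite and of length %d (one per frequency)", nm, nf)
    }
  }
  var_components <- lapply(var_components, unlist)
  check_simplex(var_components$size, "var_components$size")
  check_simplex(var_components$slope, "var_components$slope")
  srt_params <- as.list(unlist(srt_params))
  sp <- srt_params
  if (abs(sp$r_a) > 1 || abs(sp$r_e) > 1) {
    stop_config("|r_a| and |r_e| must be <= 1")
  }
  if (sp$h2 < 0 || sp$h2 > 1) stop_config("srt h2 must be in [0, 1]")
  if (sp$sd <= 0) stop_config("srt sd must be positive")
  structure(
    list(
      n_mz_pairs = as.integer(n_mz_pairs),
      n_dz_pairs = as.integer(n_dz_pairs),
      n_singletons = as.integer(n_singletons),
      age_range = as.numeric(age_range), freqs = as.numeric(freqs),
      mean_profile = as.numeric(mean_profile),
      age_slope = as.numeric(age_slope),
      size_loadings = as.numeric(size_loadings),
      slope_loadings = as.numeric(slope_loadings),
      var_components = lapply(var_components, as.numeric),
      srt_params = sp,
      ear_noise_sd = as.numeric(ear_noise_sd),
      round_to_5db = isTRUE(round_to_5db),
      observe_snr = isTRUE(observe_snr),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Draw one standard-normal latent component for n families.
# share: within-pair correlation of the component (1 shared, 0.5 DZ additive
# genetics, 0 independent). Returns an n x members matrix.
draw_component <- function(n, members, share) {
  if (members == 1L) {
    return(matrix(stats::rnorm(n), n, 1L))
  }
  if (share == 1) {
    z <- stats::rnorm(n)
    cbind(z, z)
  } else if (share == 0) {
    matrix(stats::rnorm(2L * n), n, 2L)
  } else {
    z0 <- stats::rnorm(n)
    sqrt(share) * z0 + sqrt(1 - share) * matrix(stats::rnorm(2L * n), n, 2L)
  }
}

# A/C/E components and composite value of one latent trait for a block of
# families with a given zygosity structure.
draw_latent_trait <- function(n, members, a_share, vc) {
  A <- draw_component(n, members, a_share)
  C <- draw_component(n, members, 1)
  E <- draw_component(n, members, 0)
  list(A = A, C = C, E = E,
       value = sqrt(vc[1]) * A + sqrt(vc[2]) * C + sqrt(vc[3]) * E)
}

#' Simulate a twin cohort with known variance-component structure
#'
#' Generates MZ pairs, DZ pairs and singletons under the generating model
#' described in [sim_config()]. The observed record for each subject holds
#' per-frequency left/right-ear thresholds (dB HL) and, optionally, the SRT.
#' The generated latent factor values are retained in the `latent` element
#' for parameter-recovery tests only; estimators in this package accept only
#' the observed `records` columns.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `twin_cohort`: a list with elements `records`
#'   (data frame of observed columns), `latent` (data frame of generating
#'   factor values, one row per subject), `config` and `provenance`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_mz_pairs = 20, n_dz_pairs = 20,
#'                                      n_singletons = 2, seed = 1))
#' head(cohort$records)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_config("config must be created by sim_config()")
  }
  with_seed(config$seed, {
    blocks <- list(
      MZ = list(n = config$n_mz_pairs, members = 2L, a_share = 1),
      DZ = list(n = config$n_dz_pairs, members = 2L, a_share = 0.5),
      singleton = list(n = config$n_singletons, members = 1L, a_share = 0)
    )
    sp <- config$srt_params
    rec_list <- list()
    lat_list <- list()
    next_id <- 1L
    for (zyg in names(blocks)) {
      b <- blocks[[zyg]]
      if (b$n == 0L) next
      size <- draw_latent_trait(b$n, b$members, b$a_share,
                                config$var_components$size)
      slope <- draw_latent_trait(b$n, b$members, b$a_share,
                                 config$var_components$slope)
      # SRT latent: genetic part correlated r_a with the size factor's A,
      # environmental part correlated r_e with the size factor's E.
      A_extra <- draw_component(b$n, b$members, b$a_share)
      E_extra <- draw_component(b$n, b$members, 0)
      A_snr <- sp$r_a * size$A + sqrt(1 - sp$r_a^2) * A_extra
      E_snr <- sp$r_e * size$E + sqrt(1 - sp$r_e^2) * E_extra
      srt_true <- sp$mean +
        sp$sd * (sqrt(sp$h2) * A_snr + sqrt(1 - sp$h2) * E_snr)

      age_pair <- stats::runif(b$n, config$age_range[1], config$age_range[2])
      pair_ids <- sprintf("%s_%04d", tolower(substr(zyg, 1, 4)), seq_len(b$n))

      # flatten families to subjects (member-major within family)
      fam <- rep(seq_len(b$n), each = b$members)
      member <- rep(seq_len(b$members), times = b$n)
      idx <- cbind(fam, member)
      n_sub <- length(fam)
      S <- size$value[idx]
      D <- slope$value[idx]
      age <- age_pair[fam]

      nf <- length(config$freqs)
      common <- matrix(config$mean_profile, n_sub, nf, byrow = TRUE) +
        outer(age - 60, config$age_slope) +
        outer(S, config$size_loadings) +
        outer(D, config$slope_loadings)
      thr_L <- common + stats::rnorm(n_sub * nf, sd = config$ear_noise_sd)
      thr_R <- common + stats::rnorm(n_sub * nf, sd = config$ear_noise_sd)
      # audiometers do not report below -10 dB HL
      thr_L <- pmax(thr_L, -10)
      thr_R <- pmax(thr_R, -10)
      if (config$round_to_5db) {
        thr_L <- round(thr_L / 5) * 5
        thr_R <- round(thr_R / 5) * 5
      }
      colnames(thr_L) <- paste0("thr_L_", config$freqs)
      colnames(thr_R) <- paste0("thr_R_", config$freqs)

      sid <- sprintf("S%05d", next_id - 1L + seq_len(n_sub))
      next_id <- next_id + n_sub
      rec <- data.frame(
        subject_id = sid, pair_id = pair_ids[fam], zygosity = zyg,
        age = age, sex = "F", stringsAsFactors = FALSE
      )
      rec <- cbind(rec, as.data.frame(thr_L), as.data.frame(thr_R))
      rec$snr <- if (config$observe_snr) srt_true[idx] else NA_real_
      lat <- data.frame(
        subject_id = sid,
        A_size = size$A[idx], C_size = size$C[idx], E_size = size$E[idx],
        size = S,
        A_slope = slope$A[idx], C_slope = slope$C[idx], E_slope = slope$E[idx],
        slope = D,
        A_snr = A_snr[idx], E_snr = E_snr[idx], srt_true = srt_true[idx],
        stringsAsFactors = FALSE
      )
      rec_list[[zyg]] <- rec
      lat_list[[zyg]] <- lat
    }
    records <- do.call(rbind, rec_list)
    rownames(records) <- NULL
    latent <- do.call(rbind, lat_list)
    rownames(latent) <- NULL
    new_twin_cohort(records, config = config, latent = latent,
                    provenance = "simulate_cohort")
  })
}

new_twin_cohort <- function(records, config, latent = NULL,
                            provenance = "unknown") {
  validate_cohort_records(records)
  structure(list(records = records, latent = latent, config = config,
                 provenance = provenance),
            class = "twin_cohort")
}

validate_cohort_records <- function(records) {
  needed <- c("subject_id", "pair_id", "zygosity", "age", "sex")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_config("cohort is missing mandatory columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) stop_config("no records")
  bad_zyg <- setdiff(unique(records$zygosity), c("MZ", "DZ", "singleton"))
  if (length(bad_zyg)) {
    stop_config("zygosity values outside {MZ, DZ, singleton}: %s",
                paste(bad_zyg, collapse = ", "))
  }
  if (anyDuplicated(records$subject_id)) {
    stop_config("duplicated subject_id: %s",
                paste(unique(records$subject_id[duplicated(records$subject_id)]),
                      collapse = ", "))
  }
  counts <- table(records$pair_id)
  zyg_by_pair <- tapply(records$zygosity, records$pair_id,
                        function(z) z[1])
  n_by_pair <- tapply(records$zygosity, records$pair_id, length)
  expected <- ifelse(zyg_by_pair == "singleton", 1L, 2L)
  bad <- names(n_by_pair)[n_by_pair != expected]
  if (length(bad)) {
    stop_config("pair cardinality violation for pair_id: %s",
                paste(bad, collapse = ", "))
  }
  # members of a pair must agree on zygosity and age
  zyg_n <- tapply(records$zygosity, records$pair_id,
                  function(z) length(unique(z)))
  age_n <- tapply(records$age, records$pair_id,
                  function(a) length(unique(a)))
  bad2 <- names(zyg_n)[zyg_n > 1 | age_n > 1]
  if (length(bad2)) {
    stop_config("pair members disagree on zygosity or age: %s",
                paste(bad2, collapse = ", "))
  }
  invisible(records)
}

#' @export
print.twin_cohort <- function(x, ...) {
  z <- table(factor(x$records$zygosity, c("MZ", "DZ", "singleton")))
  cat("Twin cohort:", nrow(x$records), "subjects (",
      z[["MZ"]] / 2, "MZ pairs,", z[["DZ"]] / 2, "DZ pairs,",
      z[["singleton"]], "singletons )\n")
  cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Cohort frequency list
#'
#' Frequencies (kHz) carried by a cohort's threshold columns.
#' @param cohort a `twin_cohort`.
#' @return Numeric vector of frequencies in kHz.
#' @export
cohort_freqs <- function(cohort) {
  nm <- grep("^thr_L_", names(cohort$records), value = TRUE)
  sort(as.numeric(sub("^thr_L_", "", nm)))
}

#' Simulate a repeat administration of the SNR test
#'
#' Returns paired (first, second) SNR scores for every subject with an
#' observed SNR, where the second score is the subject's true SRT plus
#' independent normal noise. Intended as input for repeatability analyses
#' ([bland_altman()]).
#'
#' @param cohort a simulated `twin_cohort` (latent truth must be present).
#' @param noise_sd SD (dB) of the re-test measurement noise.
#' @param seed integer seed or `NULL`.
#' @return Data frame with columns `subject_id`, `first`, `second`.
#' @export
repeat_measurement <- function(cohort, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (is.null(cohort$latent)) {
    stop_config("repeat_measurement needs a simulated cohort with latent truth")
  }
  has_snr <- !is.na(cohort$records$snr)
  if (!any(has_snr)) {
    warning("no subjects with observed SNR; returning empty table")
    return(data.frame(subject_id = character(), first = numeric(),
                      second = numeric(), stringsAsFactors = FALSE))
  }
  if (any(!has_snr)) {
    warning(sum(!has_snr), " subject(s) without SNR skipped")
  }
  rec <- cohort$records[has_snr, ]
  lat <- cohort$latent[match(rec$subject_id, cohort$latent$subject_id), ]
  with_seed(seed, {
    data.frame(
      subject_id = rec$subject_id,
      first = rec$snr,
      second = lat$srt_true + stats::rnorm(nrow(rec), sd = noise_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read a twin cohort as CSV
#'
#' The CSV dialect has columns `subject_id, pair_id, zygosity, age, sex,
#' thr_L_<freq>..., thr_R_<freq>..., snr` with one threshold column per kHz
#' value (dot decimal mark) and empty cells for missing values. For simulated
#' cohorts `write_cohort()` stores the generating configuration (including
#' the seed) in a YAML sidecar `<path>.yaml`; latent truth is never written.
#'
#' @param cohort a `twin_cohort`.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `twin_cohort` whose `config` is the sidecar configuration
#'   when present and `"observed"` otherwise.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  out <- cohort$records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      # %.17g guarantees an exact double round trip
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- ""
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  if (inherits(cohort$config, "sim_config")) {
    cfg <- unclass(cohort$config)
    yaml::write_yaml(cfg, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  # read everything as character ("F" sexes would otherwise parse as FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             check.names = FALSE, colClasses = "character")
  if (nrow(records) == 0L) stop_config("no records in %s", path)
  thr_cols <- grep("^thr_[LR]_", names(records), value = TRUE)
  for (cl in c("age", "snr", thr_cols)) {
    if (cl %in% names(records)) {
      v <- records[[cl]]
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop_config("malformed numeric value in column %s at data line(s) %s",
                    cl, paste(bad + 1L, collapse = ", "))
      }
      records[[cl]] <- num
    }
  }
  cfg_path <- paste0(path, ".yaml")
  config <- if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    do.call(sim_config, cfg[setdiff(names(cfg), character())])
  } else {
    "observed"
  }
  new_twin_cohort(records, config = config, provenance = paste("read from", path))
}
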