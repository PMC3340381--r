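#' Pipeline configuration
#'
#' Bundles the simulation, phenotype, modelling and validation options for
#' [run_pipeline()]. A single global seed is fanned out to per-stage
#' substreams, so stages are independently reproducible.
#'
#' @param sim a [sim_config()]; its own seed is overridden by the
#'   stage substream derived from `seed`.
#' @param offset,log_base audiogram log-transform settings.
#' @param snr_mode `"direct"` (SNR column = true SRT, as simulated) or
#'   `"staircase"` (SNR column from per-subject adaptive staircases).
#' @param models nested univariate models compared against ACE.
#' @param ci compute profile-likelihood intervals in the univariate table.
#' @param pta_rule_db reference PTA cutoff (dB) for impairment labels.
#' @param pc_rule composite-score cutoff; `NULL` derives it from the
#'   cohort as the mean composite score of subjects within 2 dB of the PTA
#'   cutoff (threshold correspondence), falling back to the empirical
#'   quantile matching the PTA rule prevalence.
#' @param repeat_n,repeat_noise_sd size and noise SD of the repeatability
#'   subsample.
#' @param stages stages to run, a subset of
#'   `c("simulate", "phenotype", "rank", "univariate", "bivariate",
#'   "validate")`.
#' @param seed global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            offset = 25, log_base = 10,
                            snr_mode = c("direct", "staircase"),
                            models = c("AE", "CE", "E"),
                            ci = FALSE,
                            pta_rule_db = 40,
                            pc_rule = NULL,
                            repeat_n = 17L, repeat_noise_sd = 1,
                            stages = c("simulate", "phenotype", "rank",
                                       "univariate", "bivariate", "validate"),
                            seed = 1L) {
  snr_mode <- match.arg(snr_mode)
  known <- c("simulate", "phenotype", "rank", "univariate", "bivariate",
             "validate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(sim = sim, offset = offset, log_base = log_base,
                 snr_mode = snr_mode, models = models, ci = ci,
                 pta_rule_db = pta_rule_db, pc_rule = pc_rule,
                 repeat_n = as.integer(repeat_n),
                 repeat_noise_sd = repeat_noise_sd,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipe_log <- function(level, fmt, ..., verbose = TRUE) {
  if (verbose) {
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

run_stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  pipe_log("INFO", "stage %-10s done in %.2fs", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")),
           verbose = verbose)
  out
}

#' Run the full twin-analysis pipeline
#'
#' Simulate (or accept) a cohort, construct audiogram phenotypes, rank
#' them, fit univariate ACE and nested models, fit bivariate
#' correlated-factors models of the audiogram phenotypes against the SNR
#' trait, and validate the SNR screening test. Skipped stages are marked in
#' the returned bundle with a reason; stages depending on a skipped stage
#' are skipped in turn.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `twin_cohort`; replaces the simulate
#'   stage.
#' @param verbose log stage progress via `message`.
#' @return Object of class `report_bundle`: named list of stage outputs
#'   (`cohort`, `cohort_summary`, `pca`, `phenotypes`, `group_comparison`,
#'   `ranking`, `univariate`, `bivariate`, `validation`) plus `meta`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  skipped <- function(reason) structure(list(reason = reason),
                                        class = "skipped_stage")
  bundle <- list()
  on <- function(stage) stage %in% config$stages

  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "twin_cohort"))
  } else if (on("simulate")) {
    sim <- config$sim
    sim$seed <- child_seed(config$seed, "simulate")
    cohort <- run_stage("simulate", verbose, simulate_cohort(sim))
    if (config$snr_mode == "staircase") {
      cohort <- run_stage("staircase", verbose, administer_snr_test(
        cohort, seed = child_seed(config$seed, "staircase")))
    }
  } else {
    bundle$cohort <- skipped("simulate stage disabled and no cohort supplied")
  }
  if (!is.null(cohort)) bundle$cohort <- cohort

  phen <- NULL
  if (!is.null(cohort) && on("phenotype")) {
    res <- run_stage("phenotype", verbose, {
      am <- audiogram_matrix(cohort, offset = config$offset,
                             base = config$log_base)
      pca <- fit_pca(am)
      tab <- build_phenotypes(cohort, pca, am = am)
      list(pca = pca, phenotypes = tab,
           cohort_summary = cohort_summary(tab),
           group_comparison = compare_zygosity_groups(tab))
    })
    bundle$pca <- res$pca
    bundle$phenotypes <- phen <- res$phenotypes
    bundle$cohort_summary <- res$cohort_summary
    bundle$group_comparison <- res$group_comparison
  } else if (on("phenotype")) {
    bundle$phenotypes <- skipped("no cohort")
  } else {
    bundle$phenotypes <- skipped("phenotype stage disabled")
  }

  bundle$ranking <- if (!is.null(phen) && on("rank")) {
    run_stage("rank", verbose,
              rank_phenotypes(phen, seed = child_seed(config$seed, "rank")))
  } else {
    skipped(if (on("rank")) "phenotype stage unavailable" else "rank stage disabled")
  }

  bundle$univariate <- if (!is.null(phen) && on("univariate")) {
    run_stage("univariate", verbose,
              univariate_table(phen, models = config$models, ci = config$ci,
                               seed = child_seed(config$seed, "univariate")))
  } else {
    skipped(if (on("univariate")) "phenotype stage unavailable"
            else "univariate stage disabled")
  }

  have_snr <- !is.null(phen) && any(!is.na(phen$snr))
  bundle$bivariate <- if (on("bivariate") && have_snr) {
    run_stage("bivariate", verbose, {
      tab <- phen
      tab$snr_t <- cubic_transform(tab$snr)
      tab$snr_adj <- age_adjust(tab, "snr_t")
      tab$pta_adj <- age_adjust(tab, "pta")
      tab$pcdiff_adj <- age_adjust(tab, "pc1_minus_pc2")
      list(
        pta_snr = fit_bivariate(tab, "pta_adj", "snr_adj"),
        pcdiff_snr = fit_bivariate(tab, "pcdiff_adj", "snr_adj")
      )
    })
  } else {
    skipped(if (!on("bivariate")) "bivariate stage disabled"
            else "no SNR data")
  }

  bundle$validation <- if (on("validate") && have_snr) {
    run_stage("validate", verbose, {
      labels_pta <- binary_reference(phen, list(pta_gt = config$pta_rule_db))
      pc_rule <- config$pc_rule %||% derive_pc_rule(phen, config$pta_rule_db)
      labels_pc <- binary_reference(phen, list(pc_diff_gt = pc_rule))
      # test-positive direction from the observed score-reference
      # association: a generator with negative audiogram-SNR correlations
      # puts impaired listeners at low SNR scores
      dir <- if (stats::cor(phen$snr, phen$pta,
                            use = "complete.obs") >= 0) "greater" else "less"
      pipe_log("INFO", "screening direction: SNR %s cutoff = impaired",
               if (dir == "greater") ">" else "<", verbose = verbose)
      roc_pta <- roc_curve(phen$snr, labels_pta,
                           sprintf("PTA > %g dB", config$pta_rule_db),
                           direction = dir)
      roc_pc <- roc_curve(phen$snr, labels_pc,
                          sprintf("PC1-PC2 > %g", pc_rule),
                          direction = dir)
      rep_tab <- repeat_subsample(bundle$cohort, config$repeat_n,
                                  config$repeat_noise_sd,
                                  child_seed(config$seed, "repeat"))
      list(
        roc_pta = roc_pta, op_pta = best_operating_point(roc_pta),
        roc_pc = roc_pc, op_pc = best_operating_point(roc_pc),
        pc_rule = pc_rule,
        bland_altman = bland_altman(rep_tab$first, rep_tab$second),
        correlations = correlate_tests(phen)
      )
    })
  } else {
    skipped(if (!on("validate")) "validate stage disabled" else "no SNR data")
  }

  bundle$meta <- list(seed = config$seed, stages = config$stages,
                      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      package_version = as.character(utils::packageVersion("audiotwin")))
  class(bundle) <- "report_bundle"
  bundle
}

# Composite-score threshold corresponding to the PTA rule: mean composite
# score of subjects whose PTA lies within 2 dB of the cutoff; falls back to
# prevalence matching when that window is empty.
derive_pc_rule <- function(phen, pta_db) {
  near <- abs(phen$pta - pta_db) <= 2
  if (sum(near, na.rm = TRUE) >= 5) {
    mean(phen$pc1_minus_pc2[near], na.rm = TRUE)
  } else {
    prev <- mean(phen$pta > pta_db, na.rm = TRUE)
    stats::quantile(phen$pc1_minus_pc2, 1 - prev, na.rm = TRUE, names = FALSE)
  }
}

repeat_subsample <- function(cohort, n, noise_sd, seed) {
  with_snr <- cohort$records$subject_id[!is.na(cohort$records$snr)]
  n <- min(n, length(with_snr))
  keep_ids <- with_seed(seed, sample(with_snr, n))
  sub <- cohort
  sub$records <- cohort$records[cohort$records$subject_id %in% keep_ids, ]
  # repeat_measurement only needs snr + latent truth; relax pair structure
  tab <- with_seed(child_seed(seed, "noise"), {
    lat <- cohort$latent[match(sub$records$subject_id,
                               cohort$latent$subject_id), ]
    data.frame(subject_id = sub$records$subject_id,
               first = sub$records$snr,
               second = lat$srt_true + stats::rnorm(nrow(sub$records),
                                                    sd = noise_sd))
  })
  tab
}

#' Cohort demographic and phenotype summary
#'
#' Per-zygosity (and total) sample size, age range, and mean (SD) of age
#' and each phenotype.
#'
#' @param phen phenotype table.
#' @return Data frame, one row per zygosity group plus a total row.
#' @export
cohort_summary <- function(phen) {
  groups <- split(phen, factor(phen$zygosity, c("MZ", "DZ", "singleton")))
  groups$total <- phen
  msd <- function(v) sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
                             stats::sd(v, na.rm = TRUE))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(zygosity = g, n = nrow(d),
               age_range = sprintf("%.0f-%.0f", min(d$age), max(d$age)),
               mean_age = msd(d$age), mean_pta = msd(d$pta),
               mean_pc1 = msd(d$pc1), mean_pc2 = msd(d$pc2),
               mean_pc1_minus_pc2 = msd(d$pc1_minus_pc2),
               mean_behl = msd(d$behl), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' Writes every populated section as CSV (tables) or JSON (model fits,
#' operating points, metadata) under `dir`; skipped stages are recorded in
#' `skipped.json`.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, force = TRUE)
  wc <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                        row.names = FALSE)
  skipped <- list()
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (inherits(x, "skipped_stage")) {
      skipped[[nm]] <- x$reason
    }
  }
  if (inherits(bundle$cohort, "twin_cohort")) {
    write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  }
  if (is.data.frame(bundle$cohort_summary)) {
    wc(bundle$cohort_summary, "cohort_summary.csv")
  }
  if (inherits(bundle$pca, "audiogram_pca")) {
    ld <- data.frame(freq_khz = bundle$pca$freqs, bundle$pca$loadings)
    wc(ld, "pca_loadings.csv")
  }
  if (is.data.frame(bundle$phenotypes)) wc(bundle$phenotypes, "phenotypes.csv")
  if (is.data.frame(bundle$group_comparison)) {
    wc(bundle$group_comparison, "group_comparison.csv")
  }
  if (is.data.frame(bundle$ranking)) wc(bundle$ranking, "ranking.csv")
  if (is.data.frame(bundle$univariate)) wc(bundle$univariate, "univariate.csv")
  if (!inherits(bundle$bivariate, "skipped_stage") &&
      !is.null(bundle$bivariate)) {
    wj(lapply(bundle$bivariate, unclass), "bivariate.json")
  }
  if (!inherits(bundle$validation, "skipped_stage") &&
      !is.null(bundle$validation)) {
    v <- bundle$validation
    wc(v$roc_pta$points, "roc_pta.csv")
    wc(v$roc_pc$points, "roc_pc.csv")
    wj(list(pta = v$op_pta, pc = v$op_pc, pc_rule = v$pc_rule),
       "operating_points.json")
    wj(unclass(v$bland_altman), "bland_altman.json")
    wc(v$correlations, "snr_correlations.csv")
  }
  wj(bundle$meta, "meta.json")
  if (length(skipped)) wj(skipped, "skipped.json")
  invisible(dir)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `phenotype`, `rank`, `heritability`,
#' `bivariate`, `validate`, `run-all`. Common flags: `--seed`, `--out`,
#' `--cohort` (input CSV for stages downstream of simulation),
#' `--log-level`. `run-all` executes the full pipeline and writes a report
#' directory.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the result object of the subcommand.
#' @export
audiotwin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: audiotwin <simulate|phenotype|rank|heritability|bivariate|validate|run-all> [options]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = "audiotwin_out"),
      optparse::make_option("--cohort", type = "character", default = NULL),
      optparse::make_option("--log-level", type = "character",
                            default = "info", dest = "log_level")
    )),
    args = args[-1]
  )
  verbose <- tolower(opts$log_level) %in% c("info", "debug")
  stage_map <- list(
    simulate = "simulate",
    phenotype = c("simulate", "phenotype"),
    rank = c("simulate", "phenotype", "rank"),
    heritability = c("simulate", "phenotype", "univariate"),
    bivariate = c("simulate", "phenotype", "bivariate"),
    validate = c("simulate", "phenotype", "validate"),
    `run-all` = c("simulate", "phenotype", "rank", "univariate",
                  "bivariate", "validate")
  )
  if (!cmd %in% names(stage_map)) {
    stop_config("unknown subcommand '%s'", cmd)
  }
  cohort <- if (!is.null(opts$cohort)) read_cohort(opts$cohort) else NULL
  cfg <- pipeline_config(stages = stage_map[[cmd]], seed = opts$seed)
  bundle <- run_pipeline(cfg, cohort = cohort, verbose = verbose)
  write_report(bundle, opts$out)
  pipe_log("INFO", "report written to %s", opts$out, verbose = verbose)
  invisible(bundle)
}
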