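#' Virtual listener for the digit-triplet speech-in-noise test
#'
#' A listener is summarised by a psychometric function for triplet
#' recognition: `srt_true` is the speech-to-noise ratio at which half of the
#' triplets are understood (the speech-reception threshold), `slope` the
#' logistic steepness in probability per dB, and `lapse_rate` a stimulus-
#' independent error probability (splits symmetrically between floor and
#' ceiling).
#'
#' @param srt_true SRT in dB SNR.
#' @param slope logistic steepness (> 0), per dB; `Inf` gives a step
#'   function.
#' @param lapse_rate lapse probability in `[0, 0.5)`.
#' @return An object of class `listener_profile`.
#' @export
listener_profile <- function(srt_true, slope = 1, lapse_rate = 0) {
  if (!(slope > 0)) stop_config("slope must be > 0")
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    stop_config("lapse_rate must be in [0, 0.5)")
  }
  structure(list(srt_true = srt_true, slope = slope,
                 lapse_rate = lapse_rate),
            class = "listener_profile")
}

#' Probability of recognising a triplet at a given SNR
#'
#' `p = lapse/2 + (1 - lapse) / (1 + exp(-slope * (snr - srt_true)))`;
#' strictly increasing in SNR, equal to 0.5 at the SRT when `lapse = 0`.
#'
#' @param snr presented SNR in dB (vectorised).
#' @param listener a [listener_profile()].
#' @return Recognition probabilities.
#' @export
psychometric <- function(snr, listener) {
  stopifnot(inherits(listener, "listener_profile"), all(is.finite(snr)))
  core <- if (is.infinite(listener$slope)) {
    as.numeric(snr >= listener$srt_true)
  } else {
    1 / (1 + exp(-listener$slope * (snr - listener$srt_true)))
  }
  listener$lapse_rate / 2 + (1 - listener$lapse_rate) * core
}

#' Run one adaptive 1-down/1-up staircase
#'
#' Speech is presented at constant intensity against variable background
#' noise: after a correctly repeated triplet the SNR decreases by `step` dB
#' (harder), after an error it increases by `step` dB. The equal-step
#' 1-down/1-up rule converges on the 50% point, i.e. the SRT. The estimate
#' is the mean of the levels presented on trials `burn_in + 1 .. n_trials`
#' together with the virtual next level implied by the final response.
#'
#' @param listener a [listener_profile()].
#' @param start_snr first presentation level (dB SNR).
#' @param step step size in dB (> 0); the deployed test used 2 dB.
#' @param n_trials number of triplets presented (>= 8).
#' @param burn_in leading trials excluded from the estimate.
#' @param seed integer seed or `NULL`.
#' @return Object of class `staircase_trace`: list with `levels`, `correct`,
#'   `step`, `n_trials`, `snr_estimate`.
#' @export
run_staircase <- function(listener, start_snr, step = 2, n_trials = 24L,
                          burn_in = 4L, seed = NULL) {
  stopifnot(inherits(listener, "listener_profile"))
  if (!(step > 0)) stop_config("step must be > 0")
  if (n_trials < 8L) stop_config("n_trials must be >= 8")
  if (burn_in < 0L || burn_in >= n_trials) {
    stop_config("burn_in must be in [0, n_trials)")
  }
  with_seed(seed, {
    levels <- numeric(n_trials)
    correct <- logical(n_trials)
    lvl <- start_snr
    for (i in seq_len(n_trials)) {
      levels[i] <- lvl
      correct[i] <- stats::runif(1) < psychometric(lvl, listener)
      lvl <- lvl + if (correct[i]) -step else step
    }
    used <- c(levels[(burn_in + 1L):n_trials], lvl)
    structure(list(levels = levels, correct = correct, step = step,
                   n_trials = as.integer(n_trials),
                   snr_estimate = mean(used)),
              class = "staircase_trace")
  })
}

#' @export
print.staircase_trace <- function(x, ...) {
  cat("Staircase:", x$n_trials, "trials, step", x$step, "dB; SRT estimate",
      round(x$snr_estimate, 2), "dB SNR\n")
  invisible(x)
}

#' Administer the SNR staircase test to every subject of a cohort
#'
#' Runs an independent staircase per subject using the subject's true SRT
#' (from the simulation latent truth) and writes the estimate into the
#' cohort's `snr` column. The starting level is `srt_true + 10` dB plus a
#' uniform jitter of +/- 2 dB, emulating the user-adapted start of the web
#' test.
#'
#' @param cohort a simulated `twin_cohort`.
#' @param slope,lapse_rate psychometric parameters shared by all virtual
#'   listeners.
#' @param step,n_trials,burn_in staircase protocol, see [run_staircase()].
#' @param seed integer seed; the same seed reproduces the `snr` column
#'   exactly.
#' @param keep_traces if `TRUE`, attach the per-subject traces as attribute
#'   `"traces"` of the returned cohort.
#' @return The cohort with `records$snr` replaced by staircase estimates.
#' @export
administer_snr_test <- function(cohort, slope = 1, lapse_rate = 0,
                                step = 2, n_trials = 24L, burn_in = 4L,
                                seed = NULL, keep_traces = FALSE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (nrow(cohort$records) == 0L) {
    warning("empty cohort; nothing to administer")
    return(cohort)
  }
  if (is.null(cohort$latent) || is.null(cohort$latent$srt_true)) {
    stop_config("cohort has no true SRT values (not a simulated cohort?)")
  }
  lat <- cohort$latent[match(cohort$records$subject_id,
                             cohort$latent$subject_id), ]
  missing_srt <- is.na(lat$srt_true)
  if (any(missing_srt)) {
    warning(sum(missing_srt), " subject(s) without true SRT left missing")
  }
  with_seed(seed, {
    traces <- vector("list", nrow(cohort$records))
    est <- rep(NA_real_, nrow(cohort$records))
    for (i in seq_len(nrow(cohort$records))) {
      if (missing_srt[i]) next
      lp <- listener_profile(lat$srt_true[i], slope, lapse_rate)
      start <- lat$srt_true[i] + 10 + stats::runif(1, -2, 2)
      tr <- run_staircase(lp, start_snr = start, step = step,
                          n_trials = n_trials, burn_in = burn_in)
      est[i] <- tr$snr_estimate
      if (keep_traces) traces[[i]] <- tr
    }
    cohort$records$snr <- est
    if (keep_traces) {
      names(traces) <- cohort$records$subject_id
      attr(cohort, "traces") <- traces
    }
    cohort
  })
}

#' Tidy export of staircase traces
#'
#' @param traces named list of `staircase_trace` objects (e.g. the
#'   `"traces"` attribute set by [administer_snr_test()]).
#' @return Data frame with columns `subject_id`, `trial`, `level_db`,
#'   `correct`.
#' @export
traces_to_frame <- function(traces) {
  traces <- traces[!vapply(traces, is.null, logical(1))]
  out <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(subject_id = id, trial = seq_len(tr$n_trials),
               level_db = tr$levels, correct = tr$correct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||% data.frame(subject_id = character(),
                                      trial = integer(),
                                      level_db = numeric(),
                                      correct = logical())
}
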