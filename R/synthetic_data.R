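#' Population specification for simulated cohorts
#'
#' Per-parameter uniform sampling ranges for the true cochlear and masking
#' parameters of simulated subjects. The defaults bracket the spread of
#' published estimates for normal-hearing adults at 2 kHz: maximum gain
#' 13-36 dB, compression exponent 0.05-0.65, compressive-range center
#' 37-53 dB SPL, signal-to-masker ratio 0.69-3.0, masker decay rate
#' 0.12-0.97 dB/ms, passive attenuation 11-35 dB, and elicitor-induced gain
#' reduction -1 to 22 dB. The observer noise parameter (dB) is the slope of
#' the simulated observer's psychometric function and sets the trial-to-trial
#' variability of the adaptive tracks; 0 gives a noiseless observer whose
#' thresholds equal the model predictions exactly.
#'
#' @param g_max,c,bp_ctr,k,mu,p,delta_g Two-element ranges (min, max).
#' @param quiet_threshold_db Range of the signal quiet threshold in dB SPL;
#'   the signal is presented at 10 dB above it.
#' @param noise_sd Observer noise in dB (single value).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(g_max = base::c(13, 36), c = base::c(0.05, 0.65),
                            bp_ctr = base::c(37, 53), k = base::c(0.69, 3.0),
                            mu = base::c(0.12, 0.97), p = base::c(11, 35),
                            delta_g = base::c(-1, 22),
                            quiet_threshold_db = base::c(18, 28),
                            noise_sd = 2) {
  ranges <- list(g_max = g_max, c = c, bp_ctr = bp_ctr, k = k, mu = mu,
                 p = p, delta_g = delta_g,
                 quiet_threshold_db = quiet_threshold_db)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[2] < r[1])
      stop("invalid range for ", nm)
  }
  bounds <- tmc_fit_bounds()
  for (nm in c("g_max", "c", "bp_ctr", "k", "mu", "p")) {
    if (ranges[[nm]][1] < bounds$lower[[nm]] ||
        ranges[[nm]][2] > bounds$upper[[nm]])
      stop("range for ", nm, " exceeds the fitting bounds")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(c(ranges, list(noise_sd = noise_sd)),
            class = "population_spec")
}

#' Draw one subject's true parameters
#'
#' Uniform draws within the ranges of a [population_spec()]. Uses the current
#' RNG state; seed at the caller for reproducibility.
#'
#' @param spec A [population_spec()].
#' @param subject_id Identifier stored with the record.
#' @return A list with `subject_id`, `params` ([cochlear_io_params()]),
#'   `ctx` ([masking_context()]), `delta_g`, `quiet_threshold_db` and
#'   `noise_sd`.
#' @export
sample_subject <- function(spec, subject_id = "S1") {
  stopifnot(inherits(spec, "population_spec"))
  draw <- function(r) stats::runif(1, r[1], r[2])
  # The TMC method presents the signal at a low sensation level so that its
  # response receives the full gain, i.e. the signal level lies below the
  # lower break point of the tip IO function. Joint draws violating this are
  # rejected, which induces the negative gain-compression correlation seen
  # in fitted cohorts (large gain with strong compression keeps the
  # compressive range narrow and its lower edge above the signal).
  for (i in 1:10000) {
    params <- cochlear_io_params(draw(spec$g_max), draw(spec$c),
                                 bp_ctr = draw(spec$bp_ctr), p = draw(spec$p))
    quiet <- draw(spec$quiet_threshold_db)
    if (params$bp1 >= quiet + 10) break
    params <- NULL
  }
  if (is.null(params))
    stop("could not draw a subject with the signal below the compressive ",
         "range; check the population ranges")
  ctx <- masking_context(l_s = quiet + 10, k = draw(spec$k),
                         mu = draw(spec$mu))
  list(subject_id = subject_id, params = params, ctx = ctx,
       delta_g = draw(spec$delta_g), quiet_threshold_db = quiet,
       noise_sd = spec$noise_sd)
}

#' Draw a cohort of subjects
#'
#' @param spec A [population_spec()].
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return A list of subject records (see [sample_subject()]).
#' @export
sample_cohort <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) sample_subject(spec, sprintf("S%d", i)))
}

#' True-parameter table for a cohort
#'
#' @param cohort A list of subject records.
#' @return A data frame in the fitted-parameter-table layout, one row per
#'   subject, with the true values.
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id, G_max = s$params$g_max,
               c = s$params$c, BP_ctr = s$params$bp_ctr, k = s$ctx$k,
               mu = s$ctx$mu, P = s$params$p, dG = s$delta_g,
               c_tilde = elicitor_effect(s$delta_g, s$params)$c_tilde,
               quiet_threshold_db = s$quiet_threshold_db)
  }))
}

#' Adaptive-track configuration
#'
#' The three-interval, three-alternative forced-choice transformed up-down
#' procedure: masker tracks follow a two-up one-down rule (signal tracks the
#' mirrored two-down one-up rule), both converging on 70.7 % correct. Step
#' size is 10 dB up to the first reversal, 5 dB up to the second, and 2.5 dB
#' for the remaining ten; a track ends after 12 reversals and the threshold
#' estimate is the mean of the last 10 reversal levels. Six estimates are
#' acquired per condition and the subset of three or more with minimum
#' standard error is averaged.
#'
#' @param rule `"two_up_one_down"` (masker level adaptive) or
#'   `"two_down_one_up"` (signal level adaptive).
#' @param step_schedule Step sizes in dB keyed to the reversal count.
#' @param n_reversals Total reversals per track.
#' @param average_last Number of final reversal levels averaged.
#' @param n_estimates Estimates acquired per condition.
#' @param min_subset Smallest subset size considered by [select_estimate()].
#' @param start_offset_db Track start level relative to the true threshold.
#' @return An object of class `track_config`.
#' @export
track_config <- function(rule = c("two_up_one_down", "two_down_one_up"),
                         step_schedule = c(10, 5, 2.5), n_reversals = 12,
                         average_last = 10, n_estimates = 6, min_subset = 3,
                         start_offset_db = 20) {
  rule <- match.arg(rule)
  if (average_last >= n_reversals + 1)
    stop("average_last must be at most n_reversals")
  if (min_subset > n_estimates)
    stop("min_subset must not exceed n_estimates")
  structure(list(rule = rule, step_schedule = step_schedule,
                 n_reversals = n_reversals, average_last = average_last,
                 n_estimates = n_estimates, min_subset = min_subset,
                 start_offset_db = start_offset_db),
            class = "track_config")
}

# 3-AFC probability of a correct response. `ease` is the stimulus's distance
# from the true threshold in the direction that makes the task easier
# (masker below threshold / signal above threshold). Logistic in dB with
# chance 1/3 and midpoint at the true threshold. Slope 0 is the idealized
# deterministic observer: always right above threshold, always wrong below
# (no guessing), so the staircase becomes fully deterministic.
psychometric_3afc <- function(ease, slope_db) {
  if (slope_db <= 0)
    return(as.numeric(ease > 0) + 0.5 * (ease == 0))
  1 / 3 + 2 / 3 * stats::plogis(ease / slope_db)
}

#' Simulate one adaptive threshold track
#'
#' Runs the transformed up-down staircase against a simulated observer whose
#' probability of a correct response follows a 3-AFC logistic psychometric
#' function centered on the true threshold. Uses the current RNG state.
#'
#' @param true_threshold_db True threshold in dB (masker level for the
#'   two-up one-down rule, signal level for two-down one-up).
#' @param config A [track_config()].
#' @param observer_slope_db Psychometric slope in dB; larger is noisier,
#'   0 is a deterministic step observer.
#' @return The threshold estimate in dB (mean of the last `average_last`
#'   reversal levels), with the reversal levels as attribute `"reversals"`.
#' @export
simulate_track <- function(true_threshold_db, config = track_config(),
                           observer_slope_db = 2) {
  stopifnot(inherits(config, "track_config"), observer_slope_db >= 0)
  harder <- if (config$rule == "two_up_one_down") +1 else -1
  level <- true_threshold_db + config$start_offset_db
  streak <- 0L
  last_move <- 0L
  reversals <- numeric(0)
  while (length(reversals) < config$n_reversals) {
    ease <- harder * (true_threshold_db - level)
    p <- psychometric_3afc(ease, observer_slope_db)
    correct <- stats::runif(1) < p
    move <- 0L
    if (correct) {
      streak <- streak + 1L
      if (streak == 2L) {
        move <- harder      # two correct: make the task harder
        streak <- 0L
      }
    } else {
      move <- -harder       # one wrong: make it easier
      streak <- 0L
    }
    if (move != 0L) {
      if (last_move != 0L && move != last_move)
        reversals <- c(reversals, level)
      step_idx <- min(length(reversals) + 1, length(config$step_schedule))
      level <- level + move * config$step_schedule[step_idx]
      last_move <- move
    }
  }
  est <- mean(utils::tail(reversals, config$average_last))
  attr(est, "reversals") <- reversals
  est
}

#' Select the final threshold from repeated estimates
#'
#' Over all subsets of size `min_subset` to `length(estimates)`, picks the
#' subset with the minimum standard error of the mean and returns its mean.
#' Ties are broken toward the larger subset, then by lexicographic order of
#' the member indices.
#'
#' @param estimates Numeric vector of threshold estimates.
#' @param min_subset Smallest admissible subset size.
#' @return The mean of the selected subset.
#' @export
select_estimate <- function(estimates, min_subset = 3) {
  n <- length(estimates)
  if (n < min_subset) stop("need at least ", min_subset, " estimates")
  best_sem <- Inf
  best_mean <- NA_real_
  for (size in seq(n, min_subset)) {     # larger subsets first (tie-break)
    idx_sets <- utils::combn(n, size, simplify = FALSE)
    for (idx in idx_sets) {              # combn is lexicographic
      sem <- stats::sd(estimates[idx]) / sqrt(size)
      if (sem < best_sem - 1e-12) {
        best_sem <- sem
        best_mean <- mean(estimates[idx])
      }
    }
  }
  best_mean
}

#' Generate a TMC threshold table for one simulated subject
#'
#' For every cell of the design (gap by masker by elicitor condition) the
#' true threshold follows from [predict_threshold()] under the subject's true
#' parameters; with a noisy observer, `n_estimates` adaptive tracks are
#' simulated and reduced by [select_estimate()]. With `noise_sd = 0` the
#' table equals the model predictions exactly. The `"full"` design crosses
#' both masker frequencies with both elicitor conditions; the `"reduced"`
#' design omits the with-elicitor off-frequency cell.
#'
#' @param subject A subject record from [sample_subject()].
#' @param gaps Masker-signal gaps in ms.
#' @param design `"full"` or `"reduced"`.
#' @param config A [track_config()].
#' @return A [tmc_dataset()].
#' @export
generate_tmc_dataset <- function(subject, gaps = seq(5, 30, by = 5),
                                 design = c("full", "reduced"),
                                 config = track_config()) {
  design <- match.arg(design)
  cells <- expand.grid(masker = c("on", "off"),
                       elicitor = c("without", "with"),
                       stringsAsFactors = FALSE)
  if (design == "reduced")
    cells <- cells[!(cells$masker == "off" & cells$elicitor == "with"), ]
  effect <- elicitor_effect(subject$delta_g, subject$params)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    masker <- cells$masker[i]
    eff <- if (cells$elicitor[i] == "with") effect else NULL
    truth <- predict_tmc(subject$params, subject$ctx, gaps, masker, eff)
    thr <- if (subject$noise_sd <= 0) truth else
      vapply(truth, function(tt) {
        ests <- vapply(seq_len(config$n_estimates),
                       function(j) as.numeric(
                         simulate_track(tt, config, subject$noise_sd)),
                       numeric(1))
        select_estimate(ests, config$min_subset)
      }, numeric(1))
    data.frame(subject_id = subject$subject_id, gap_ms = gaps,
               masker = masker, elicitor = cells$elicitor[i],
               threshold_db_spl = thr,
               signal_level_db_spl = subject$ctx$l_s)
  })
  tmc_dataset(do.call(rbind, rows))
}

#' Generate one CEOAE recording with two replicates
#'
#' The deterministic emission is a sum of decaying tone bursts whose
#' latencies fall inside the 6-16 ms analysis window (longer latencies for
#' lower frequencies, following the cochlear place-frequency map). Both
#' replicates share the emission scaled by `suppression_factor` (1 = no
#' elicitor effect) and differ by independent Gaussian microphone noise whose
#' standard deviation scales as `1 / sqrt(n_trials)`, emulating online
#' averaging. Optional artifact trials exceed the 5-mPa rejection threshold.
#'
#' @param suppression_factor Emission amplitude scale in (0, 1] for the
#'   with-elicitor condition.
#' @param n_trials Number of averaged trials per replicate.
#' @param trial_noise_sd_pa Per-trial microphone noise sd in Pa.
#' @param fs Sample rate in Hz.
#' @param duration_ms Buffer length in ms.
#' @param emission Data frame with columns `freq_hz`, `latency_ms`,
#'   `amp_pa` and `decay_ms` describing the tone bursts.
#' @param return_trials If `TRUE`, also return raw per-trial buffers (one
#'   column per trial) for artifact-rejection testing.
#' @param n_artifact_trials Number of trials contaminated with a 10-mPa
#'   spike inside the scoring window (only with `return_trials = TRUE`).
#' @return An object of class `ceoae_recording`: `replicate_a`,
#'   `replicate_b`, `fs`, `suppression_factor`, and optionally `trials`.
#' @export
generate_ceoae_recording <- function(suppression_factor = 1,
                                     n_trials = 2000,
                                     trial_noise_sd_pa = 0.001,
                                     fs = 30000, duration_ms = 20,
                                     emission = default_emission(),
                                     return_trials = FALSE,
                                     n_artifact_trials = 0) {
  if (!is.finite(suppression_factor) || suppression_factor <= 0 ||
      suppression_factor > 1)
    stop("suppression_factor must lie in (0, 1]")
  n <- round(duration_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  s <- numeric(n)
  for (i in seq_len(nrow(emission))) {
    dt <- t_ms - emission$latency_ms[i]
    env <- ifelse(dt >= 0, exp(-dt / emission$decay_ms[i]), 0)
    s <- s + emission$amp_pa[i] * env *
      sin(2 * pi * emission$freq_hz[i] * dt / 1000)
  }
  s <- s * suppression_factor
  rep_noise_sd <- trial_noise_sd_pa / sqrt(n_trials)
  rec <- list(replicate_a = s + stats::rnorm(n, 0, rep_noise_sd),
              replicate_b = s + stats::rnorm(n, 0, rep_noise_sd),
              fs = fs, suppression_factor = suppression_factor)
  if (return_trials) {
    trials <- s + matrix(stats::rnorm(n * n_trials, 0, trial_noise_sd_pa),
                         n, n_trials)
    if (n_artifact_trials > 0) {
      idx <- seq_len(min(n_artifact_trials, n_trials))
      spike_at <- which.min(abs(t_ms - 10))
      trials[spike_at, idx] <- trials[spike_at, idx] + 0.010
    }
    rec$trials <- trials
  }
  class(rec) <- "ceoae_recording"
  rec
}

#' Default synthetic CEOAE emission components
#'
#' Five tone bursts between 1 and 4 kHz with latencies inside the 6-16 ms
#' analysis window (low frequencies arrive later), amplitudes a fraction of
#' a millipascal, matching the scale of adult click-evoked emissions.
#'
#' @return A data frame with columns `freq_hz`, `latency_ms`, `amp_pa`,
#'   `decay_ms`.
#' @export
default_emission <- function() {
  data.frame(freq_hz = c(1000, 1500, 2000, 3000, 4000),
             latency_ms = c(13, 11.5, 10, 8.5, 7.5),
             amp_pa = c(1e-4, 1.25e-4, 1.5e-4, 1e-4, 0.75e-4),
             decay_ms = c(2.5, 2.2, 2.0, 1.6, 1.2))
}
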