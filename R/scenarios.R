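#' Specify a synthetic saccadic-choice scenario
#'
#' A scenario parameterises the two-process race model that stands in for a
#' group of observers. Each trial draws one latency from a shifted
#' ex-Gaussian; saccades triggered before the selective process comes online
#' (`selective_onset_ms`) land on the target side with the task-blind
#' probability `nonselective_correct_prob` (0.5 = unbiased; below 0.5 the
#' early process is pulled toward the distractor), later saccades with
#' `selective_correct_prob`. When a context-onset is set, congruent pairs
#' gain `context_delta` and incongruent pairs lose it from
#' `context_onset_ms` onward.
#'
#' @param condition_name label for the condition.
#' @param task one of `"animal"`, `"vehicle"`, `"natural"`, `"manmade"`.
#' @param latency list with `shift`, `mu`, `sigma`, `tau` (ms); see
#'   [rexgauss()].
#' @param selective_onset_ms earliest latency (ms) at which the selective
#'   process can drive the saccade; `Inf` gives a pure null scenario.
#' @param selective_correct_prob asymptotic accuracy of the selective
#'   process.
#' @param nonselective_correct_prob side-choice probability of the early,
#'   task-blind process.
#' @param context_onset_ms latency (ms) from which congruency modulates
#'   accuracy, or `NULL` for no context effect.
#' @param context_delta accuracy increment (congruent) / decrement
#'   (incongruent) applied from `context_onset_ms`.
#' @param context_assignment how scene contexts are assigned in object
#'   tasks: `"random"` draws target and distractor contexts independently
#'   (half natural / half manmade, so a quarter of pairs are fully congruent,
#'   a quarter fully incongruent, half mixed), `"paired"` makes every pair
#'   fully congruent or fully incongruent (50/50), `"none"` leaves contexts
#'   unset (scene tasks).
#' @param n_subjects,trials_per_subject design size; defaults mirror a
#'   12-observer session of 4 runs of 48 trials.
#' @param subject_mu_sd per-subject jitter (sd, ms) added to the Gaussian
#'   mean so that observers are exchangeable but not identical.
#' @param spoil_fraction fraction of trials deliberately emitted outside the
#'   80-800 ms validity window or without a saccade, to exercise
#'   [filter_trials()].
#' @param planted optional named list of the summary values the scenario was
#'   calibrated to reproduce (accuracy, median SRT, minimal SRT, ...);
#'   carried along for parameter-recovery checks.
#' @param seed integer seed; the whole trial list is a deterministic
#'   function of the spec including this seed.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(condition_name, task,
                          latency = list(shift = 80, mu = 80, sigma = 30, tau = 50),
                          selective_onset_ms, selective_correct_prob,
                          nonselective_correct_prob = 0.5,
                          context_onset_ms = NULL, context_delta = 0,
                          context_assignment = c("none", "random", "paired"),
                          n_subjects = 12, trials_per_subject = 192,
                          subject_mu_sd = 10, spoil_fraction = 0,
                          planted = list(), seed = 1L) {
  context_assignment <- match.arg(context_assignment)
  stopifnot(task %in% task_levels,
            is.list(latency),
            all(c("shift", "mu", "sigma", "tau") %in% names(latency)),
            n_subjects >= 1, trials_per_subject >= 1,
            spoil_fraction >= 0, spoil_fraction < 1)
  check_exgauss_params(latency$shift, latency$mu, latency$sigma, latency$tau)
  if (!is.infinite(selective_onset_ms) && selective_onset_ms < 80)
    stop("`selective_onset_ms` must be >= 80 ms (or Inf)", call. = FALSE)
  probs <- c(nonselective_correct_prob, selective_correct_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(context_onset_ms)) {
    if (context_assignment == "none")
      stop("a context onset requires context_assignment 'random' or 'paired'",
           call. = FALSE)
    shifted <- selective_correct_prob + c(context_delta, -context_delta)
    if (any(shifted < 0 | shifted > 1))
      stop("`selective_correct_prob` +/- `context_delta` leaves [0, 1]",
           call. = FALSE)
  }
  structure(list(condition_name = condition_name, task = task,
                 latency = latency,
                 selective_onset_ms = selective_onset_ms,
                 selective_correct_prob = selective_correct_prob,
                 nonselective_correct_prob = nonselective_correct_prob,
                 context_onset_ms = context_onset_ms,
                 context_delta = context_delta,
                 context_assignment = context_assignment,
                 n_subjects = n_subjects,
                 trials_per_subject = trials_per_subject,
                 subject_mu_sd = subject_mu_sd,
                 spoil_fraction = spoil_fraction,
                 planted = planted, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$condition_name, "(task:", x$task, ")\n")
  cat("  latency: shift", x$latency$shift, "+ exGauss(mu", x$latency$mu,
      ", sigma", x$latency$sigma, ", tau", x$latency$tau, ") ms\n")
  cat("  selective onset:", x$selective_onset_ms, "ms, p(correct)",
      x$nonselective_correct_prob, "->", x$selective_correct_prob, "\n")
  if (!is.null(x$context_onset_ms))
    cat("  context onset:", x$context_onset_ms, "ms, delta +/-",
        x$context_delta, "(", x$context_assignment, "pairs )\n")
  cat("  design:", x$n_subjects, "subjects x", x$trials_per_subject,
      "trials, seed", x$seed, "\n")
  invisible(x)
}

#' Packaged study scenarios
#'
#' The four task conditions plus the congruency condition, with latency and
#' accuracy parameters calibrated so that the pooled summaries (accuracy,
#' mean of subject median SRTs) and the onsets recovered by the full
#' filtering / binning / chi-square pipeline match the planted values stored
#' in each spec's `planted` field. The congruency scenario uses the blocked
#' pair design (`context_assignment = "paired"`) so that the congruent and
#' incongruent conditions have equal trial counts.
#'
#' @param seed integer; base seed stored in each spec.
#' @return named list of [scenario_spec()] objects.
#' @export
packaged_scenarios <- function(seed = 1L) {
  list(
    animal = scenario_spec(
      "animal", task = "animal",
      latency = list(shift = 80, mu = 58.84, sigma = 32, tau = 48),
      selective_onset_ms = 120, selective_correct_prob = 0.8370,
      planted = list(accuracy = 80.9, median_srt = 181, min_srt = 120),
      seed = seed),
    vehicle = scenario_spec(
      "vehicle", task = "vehicle",
      latency = list(shift = 80, mu = 67.64, sigma = 34, tau = 55),
      selective_onset_ms = 180, selective_correct_prob = 0.7881,
      nonselective_correct_prob = 0.40,
      planted = list(accuracy = 63.2, median_srt = 207, min_srt = 180),
      seed = seed),
    natural = scenario_spec(
      "natural", task = "natural",
      latency = list(shift = 80, mu = 89.09, sigma = 34, tau = 55),
      selective_onset_ms = 160, selective_correct_prob = 0.7554,
      planted = list(accuracy = 72.2, median_srt = 217, min_srt = 160),
      seed = seed),
    manmade = scenario_spec(
      "manmade", task = "manmade",
      latency = list(shift = 80, mu = 83.06, sigma = 34, tau = 55),
      selective_onset_ms = 160, selective_correct_prob = 0.7839,
      planted = list(accuracy = 73.8, median_srt = 212, min_srt = 160),
      seed = seed),
    animal_congruency = scenario_spec(
      "animal_congruency", task = "animal",
      latency = list(shift = 80, mu = 74.69, sigma = 24, tau = 32),
      selective_onset_ms = 120, selective_correct_prob = 0.8231,
      context_onset_ms = 160, context_delta = 0.0811,
      context_assignment = "paired",
      planted = list(accuracy_congruent = 87.5, accuracy_incongruent = 75.5,
                     context_onset = 160, min_srt = 120),
      seed = seed)
  )
}
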