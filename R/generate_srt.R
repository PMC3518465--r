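#' Generate synthetic saccadic-choice trials from a scenario
#'
#' Draws one latency per trial from the scenario's shifted ex-Gaussian (with
#' a per-subject jitter of the Gaussian mean, fixed by the seed) and decides
#' the saccade side by the two-process rule: before `selective_onset_ms` the
#' response is correct with `nonselective_correct_prob`, from that latency on
#' with `selective_correct_prob`, modulated by `context_delta` on fully
#' congruent / incongruent pairs once the latency reaches
#' `context_onset_ms`. Latencies are redrawn into the 80-800 ms validity
#' window so the emitted table passes [filter_trials()] by construction,
#' except for a `spoil_fraction` of trials deliberately spoiled (fast/slow
#' SRT or no saccade) for filter testing.
#'
#' The trial list is a deterministic function of the spec: identical specs
#' (including seed) give bit-identical tables.
#'
#' @param spec a [scenario_spec()].
#' @return a trial tibble (see [trial_table]).
#' @export
generate_srt_data <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(spec$seed, generate_srt_data_impl(spec))
}

draw_latencies <- function(n, lat, mu_s, window = c(80, 800)) {
  l <- rexgauss(n, lat$shift, mu_s, lat$sigma, lat$tau)
  bad <- which(l < window[1] | l > window[2])
  while (length(bad) > 0) {
    l[bad] <- rexgauss(length(bad), lat$shift, mu_s, lat$sigma, lat$tau)
    bad <- bad[l[bad] < window[1] | l[bad] > window[2]]
  }
  l
}

generate_srt_data_impl <- function(spec) {
  n_sub <- spec$n_subjects
  n_tr <- spec$trials_per_subject
  lat <- spec$latency
  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    mu_s <- lat$mu + stats::rnorm(1, 0, spec$subject_mu_sd)
    l <- draw_latencies(n_tr, lat, mu_s)
    target <- sample(c("left", "right"), n_tr, replace = TRUE)
    ctx <- assign_contexts(spec, n_tr)
    p <- ifelse(l < spec$selective_onset_ms,
                spec$nonselective_correct_prob,
                spec$selective_correct_prob)
    if (!is.null(spec$context_onset_ms)) {
      late <- l >= spec$context_onset_ms
      p <- p + spec$context_delta * late *
        (ctx$pair == "congruent") * (l >= spec$selective_onset_ms) -
        spec$context_delta * late *
        (ctx$pair == "incongruent") * (l >= spec$selective_onset_ms)
    }
    correct <- stats::runif(n_tr) < p
    response <- ifelse(correct, target,
                       ifelse(target == "left", "right", "left"))
    if (spec$spoil_fraction > 0) {
      n_spoil <- round(spec$spoil_fraction * n_tr)
      if (n_spoil > 0) {
        idx <- sample(n_tr, n_spoil)
        kind <- sample(c("fast", "slow", "none"), n_spoil, replace = TRUE)
        l[idx[kind == "fast"]] <- stats::runif(sum(kind == "fast"), 20, 79)
        l[idx[kind == "slow"]] <- stats::runif(sum(kind == "slow"), 801, 1200)
        response[idx[kind == "none"]] <- "none"
      }
    }
    subjects[[s]] <- tibble::tibble(
      subject_id = sprintf("S%02d", s), task = spec$task,
      target_side = target, response_side = response, srt_ms = l,
      target_context = ctx$target, distractor_context = ctx$distractor)
  }
  dplyr::bind_rows(subjects)
}

assign_contexts <- function(spec, n) {
  if (spec$context_assignment == "none" ||
      !(spec$task %in% c("animal", "vehicle")))
    return(list(target = rep("none", n), distractor = rep("none", n),
                pair = rep("not_applicable", n)))
  target_home <- if (spec$task == "animal") "natural" else "manmade"
  distractor_home <- if (spec$task == "animal") "manmade" else "natural"
  other <- function(x) ifelse(x == "natural", "manmade", "natural")
  if (spec$context_assignment == "paired") {
    cong <- stats::runif(n) < 0.5
    target <- ifelse(cong, target_home, other(target_home))
    distractor <- ifelse(cong, distractor_home, other(distractor_home))
  } else {
    target <- sample(c("natural", "manmade"), n, replace = TRUE)
    distractor <- sample(c("natural", "manmade"), n, replace = TRUE)
  }
  pair <- label_congruency(data.frame(task = spec$task,
                                      target_context = target,
                                      distractor_context = distractor))
  list(target = target, distractor = distractor, pair = pair)
}

#' Expected pooled accuracy of a scenario
#'
#' Closed-form mixture expectation
#' `P(L < t_sel) p_ns + P(L >= t_sel) p_sel` under the latency law truncated
#' to the 80-800 ms window, averaged over congruency conditions when a
#' context effect is planted. Used to cross-check the generator against an
#' integration oracle and to calibrate the packaged scenarios.
#'
#' @param spec a [scenario_spec()].
#' @param pair `"any"` for the marginal accuracy, or `"congruent"` /
#'   `"incongruent"` for one pair condition.
#' @return expected proportion correct (0-1).
#' @export
scenario_expected_accuracy <- function(spec, pair = "any") {
  lat <- spec$latency
  Fw <- function(q) pexgauss(q, lat$shift, lat$mu, lat$sigma, lat$tau)
  lo <- Fw(80); hi <- Fw(800)
  Ft <- function(q) (pmin(pmax(Fw(q), lo), hi) - lo) / (hi - lo)
  q_sel <- if (is.infinite(spec$selective_onset_ms)) 1 else Ft(spec$selective_onset_ms)
  base <- q_sel * spec$nonselective_correct_prob +
    (1 - q_sel) * spec$selective_correct_prob
  if (is.null(spec$context_onset_ms) || pair == "any") return(base)
  q_ctx <- Ft(max(spec$context_onset_ms, spec$selective_onset_ms))
  delta <- if (pair == "congruent") spec$context_delta else -spec$context_delta
  base + delta * (1 - q_ctx)
}
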