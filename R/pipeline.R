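#' Full single-condition analysis
#'
#' Filters a trial table (or generates one from a scenario), bins the SRTs,
#' estimates the minimal SRT and computes the condition summary — the whole
#' behavioural pipeline for one condition.
#'
#' @param x a trial table or a [scenario_spec()].
#' @param n_resamples bootstrap resamples for the summary CIs.
#' @param ... passed to [min_srt()].
#' @return list with `filter_report`, `distribution`, `min_srt`, `summary`,
#'   and the filtered `trials`.
#' @export
run_scenario_analysis <- function(x, n_resamples = 2000, ...) {
  trials <- if (inherits(x, "scenario_spec")) generate_srt_data(x) else x
  filtered <- filter_trials(trials)
  list(filter_report = filtered$report,
       distribution = dist <- bin_srt_distribution(filtered$trials),
       min_srt = min_srt(dist, ...),
       summary = group_summary(filtered$trials, n_resamples = n_resamples),
       trials = filtered$trials)
}

respec_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

#' Minimal-SRT recovery over seeded replicates
#'
#' Regenerates a scenario under `n_replicates` derived seeds and estimates
#' the minimal SRT on each pooled distribution; used for parameter-recovery
#' checks (the planted selective onset should be the modal estimate).
#'
#' @param spec a [scenario_spec()].
#' @param n_replicates number of regenerated datasets.
#' @param seed base seed; replicate r runs under `seed * 1000 + r`.
#' @return numeric vector of onsets (ms; `NA` where undefined).
#' @export
replicate_min_srt <- function(spec, n_replicates = 50, seed = 1L) {
  vapply(seq_len(n_replicates), function(r) {
    trials <- generate_srt_data(respec_seed(spec, seed * 1000 + r))
    dist <- bin_srt_distribution(filter_trials(trials)$trials)
    min_srt(dist)$onset_ms
  }, numeric(1))
}

#' Congruency-onset recovery over seeded replicates
#'
#' As [replicate_min_srt()], but running the full congruency pipeline
#' (pair labelling, mixed-pair exclusion, hits-minus-FA differencing,
#' per-bin chi-square with the consecutive-bin rule).
#'
#' @inheritParams replicate_min_srt
#' @param ... passed to [congruency_onset()].
#' @return numeric vector of detected onsets (ms; `NA` where undefined).
#' @export
replicate_congruency_onset <- function(spec, n_replicates = 200, seed = 1L,
                                       ...) {
  vapply(seq_len(n_replicates), function(r) {
    trials <- filter_trials(
      generate_srt_data(respec_seed(spec, seed * 1000 + r)))$trials
    lab <- label_congruency(trials)
    congruency_onset(
      bin_srt_distribution(trials[lab == "congruent", , drop = FALSE]),
      bin_srt_distribution(trials[lab == "incongruent", , drop = FALSE]),
      ...)$onset_ms
  }, numeric(1))
}

#' Group-summary recovery over seeded replicates
#'
#' @inheritParams replicate_min_srt
#' @param n_resamples bootstrap resamples per replicate (the point
#'   estimates, not the CIs, are what recovery uses; keep this small).
#' @return tibble with one row per replicate: pooled accuracy (%) and mean
#'   of subject median SRTs (ms).
#' @export
replicate_group_summary <- function(spec, n_replicates = 20, seed = 1L,
                                    n_resamples = 50) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    trials <- filter_trials(
      generate_srt_data(respec_seed(spec, seed * 1000 + r)))$trials
    gs <- group_summary(trials, n_resamples = n_resamples)
    tibble::tibble(replicate = r, accuracy = gs$accuracy$estimate,
                   median_srt = gs$median_srt$estimate)
  })
  dplyr::bind_rows(rows)
}

#' Modal value of a vector of detected onsets
#'
#' @param x numeric vector (NA = not detected).
#' @return the most frequent finite value, ties broken toward the earliest;
#'   `NA` if nothing was detected.
#' @export
modal_onset <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
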