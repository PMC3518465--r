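#' Bin saccadic reaction times into a correct/error histogram
#'
#' Pools filtered trials of a single condition into contiguous half-open
#' 10-ms bins `[80, 90), [90, 100), ...` and counts correct and error
#' saccades per bin. The binned object is the input to [min_srt()] and the
#' congruency analysis.
#'
#' @param trials filtered trial table (one condition).
#' @param bin_width_ms bin width, ms.
#' @param min_ms,max_ms range covered by the grid.
#' @return an object of class `srt_distribution`: list with `bins` (tibble
#'   `bin_lower`, `n_correct`, `n_error`), `bin_width_ms` and `n_total`.
#' @export
bin_srt_distribution <- function(trials, bin_width_ms = 10,
                                 min_ms = 80, max_ms = 800) {
  validate_trials(trials)
  correct <- trial_correct(trials)
  if (any(is.na(correct)))
    stop("trials contain no-saccade responses; run filter_trials() first",
         call. = FALSE)
  if (nrow(trials) > 0 &&
      (min(trials$srt_ms) < min_ms || max(trials$srt_ms) > max_ms))
    stop("SRTs outside [", min_ms, ", ", max_ms,
         "] ms; run filter_trials() first", call. = FALSE)
  edges <- seq(min_ms, max_ms, by = bin_width_ms)
  # half-open [lower, lower + w); the top edge (= max_ms exactly) joins the
  # last bin so that the inclusive validity window loses no trial
  idx <- pmin(floor((trials$srt_ms - min_ms) / bin_width_ms) + 1L,
              length(edges) - 1L)
  n_bins <- length(edges) - 1L
  n_correct <- tabulate(idx[correct], nbins = n_bins)
  n_error <- tabulate(idx[!correct], nbins = n_bins)
  structure(list(bins = tibble::tibble(bin_lower = edges[-length(edges)],
                                       n_correct = n_correct,
                                       n_error = n_error),
                 bin_width_ms = bin_width_ms, n_total = nrow(trials)),
            class = "srt_distribution")
}

#' @export
print.srt_distribution <- function(x, ...) {
  nz <- x$bins[x$bins$n_correct + x$bins$n_error > 0, ]
  cat("<srt_distribution>", x$n_total, "trials,", x$bin_width_ms,
      "ms bins,", nrow(nz), "occupied bins",
      if (nrow(nz) > 0) paste0("(", min(nz$bin_lower), "-",
                               max(nz$bin_lower) + x$bin_width_ms, " ms)"),
      "\n")
  invisible(x)
}

#' Per-bin chi-square test of correct vs error counts
#'
#' Pearson goodness-of-fit of the pair `(n_correct, n_error)` against an
#' equal split (1 df, no continuity correction):
#' `X^2 = (n_correct - n_error)^2 / (n_correct + n_error)`. A bin counts as
#' significant only when `p < alpha`, correct responses outnumber errors
#' (the onset question is one-directional) and the bin holds at least
#' `min_total` responses (guards the sparse tails).
#'
#' @param n_correct,n_error nonnegative counts (vectorised).
#' @param alpha significance criterion.
#' @param min_total minimum per-bin total for a bin to qualify.
#' @return tibble with `chi2`, `p`, `significant`. Empty bins get `NA`
#'   statistics and a `FALSE` flag.
#' @export
chi2_correct_vs_error <- function(n_correct, n_error,
                                  alpha = 0.05, min_total = 5) {
  stopifnot(length(n_correct) == length(n_error),
            all(n_correct >= 0), all(n_error >= 0))
  total <- n_correct + n_error
  chi2 <- ifelse(total > 0, (n_correct - n_error)^2 / total, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  sig <- !is.na(p) & p < alpha & n_correct > n_error & total >= min_total
  tibble::tibble(chi2 = chi2, p = p, significant = sig)
}

first_sustained_run <- function(flags, consecutive) {
  if (length(flags) < consecutive) return(NA_integer_)
  run <- stats::filter(as.numeric(flags), rep(1, consecutive),
                       sides = 1)
  hit <- which(!is.na(run) & run == consecutive)
  if (length(hit) == 0) return(NA_integer_)
  hit[1] - consecutive + 1L
}

#' Minimal SRT: onset of reliably selective saccades
#'
#' The minimal SRT is the lower edge of the first 10-ms bin in which correct
#' responses significantly outnumber errors (per-bin chi-square, p < .05,
#' see [chi2_correct_vs_error()]) with the four immediately following bins
#' also reaching the criterion. Undefined (`NA`) when no such run of five
#' bins exists.
#'
#' @param dist an [bin_srt_distribution()] result.
#' @param alpha per-bin significance criterion.
#' @param consecutive length of the qualifying run (the significant bin plus
#'   its followers).
#' @param min_total minimum per-bin total (see [chi2_correct_vs_error()]).
#' @return object of class `min_srt_result`: `onset_ms` (ms or `NA`),
#'   `per_bin` trace, and the rule parameters.
#' @export
min_srt <- function(dist, alpha = 0.05, consecutive = 5, min_total = 5) {
  stopifnot(inherits(dist, "srt_distribution"))
  if (dist$n_total == 0)
    stop("empty SRT distribution: no trials to test", call. = FALSE)
  test <- chi2_correct_vs_error(dist$bins$n_correct, dist$bins$n_error,
                                alpha = alpha, min_total = min_total)
  i <- first_sustained_run(test$significant, consecutive)
  onset <- if (is.na(i)) NA_real_ else dist$bins$bin_lower[i]
  structure(list(onset_ms = onset,
                 per_bin = dplyr::bind_cols(dist$bins, test),
                 alpha = alpha, consecutive_required = consecutive,
                 min_total = min_total),
            class = "min_srt_result")
}

#' @export
print.min_srt_result <- function(x, ...) {
  cat("<min_srt_result> onset:",
      if (is.na(x$onset_ms)) "undefined" else paste0(x$onset_ms, " ms"),
      sprintf("(p < %g in %d consecutive bins)\n", x$alpha,
              x$consecutive_required))
  invisible(x)
}

percentile_ci <- function(stats, level = 0.95) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  stats::quantile(stats, probs, names = FALSE, na.rm = TRUE)
}

bootstrap_ci <- function(estimate, resamples, level, statistic_name) {
  ci <- percentile_ci(resamples, level)
  list(estimate = estimate, lower = ci[1], upper = ci[2], level = level,
       n_resamples = length(resamples), statistic_name = statistic_name)
}

#' Percentile-bootstrap confidence interval for the median of one sample
#'
#' Resamples the observations with replacement, recomputes the sample
#' median, and takes the 2.5 and 97.5 percentiles of the resampled medians
#' (at the default level). Medians of even-length samples use midpoint
#' interpolation.
#'
#' @param x numeric sample.
#' @param n_resamples number of bootstrap resamples.
#' @param level nominal coverage.
#' @return list with `estimate`, `lower`, `upper`, `level`, `n_resamples`,
#'   `statistic_name`.
#' @export
bootstrap_median_ci <- function(x, n_resamples = 2000, level = 0.95) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  m <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
  # median of each resample via two order statistics (midpoint rule)
  k <- if (n %% 2 == 1) c((n + 1) / 2, (n + 1) / 2) else c(n / 2, n / 2 + 1)
  meds <- apply(m, 2, function(idx) {
    v <- sort.int(x[idx], partial = unique(k))
    (v[k[1]] + v[k[2]]) / 2
  })
  bootstrap_ci(stats::median(x), meds, level, "median")
}

#' Condition summary: pooled accuracy and mean of subject medians
#'
#' Accuracy is the pooled proportion of correct saccades; the latency
#' summary is the unweighted mean over subjects of each subject's median
#' correct-trial SRT. 95% confidence intervals come from a percentile
#' bootstrap that resamples subjects with replacement (2000 resamples).
#' Subjects without a single correct trial have no median and are dropped
#' from the latency mean with a warning.
#'
#' @param trials filtered trial table of one condition.
#' @param n_resamples bootstrap resamples.
#' @param level nominal CI level.
#' @return object of class `group_summary`: `accuracy` and `median_srt`
#'   bootstrap-CI lists (percent and ms), `subject_medians`, `n_trials`,
#'   `n_subjects`.
#' @export
group_summary <- function(trials, n_resamples = 2000, level = 0.95) {
  validate_trials(trials)
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  correct <- trial_correct(trials)
  if (any(is.na(correct)))
    stop("trials contain no-saccade responses; run filter_trials() first",
         call. = FALSE)
  per_subj <- tibble::tibble(subject_id = trials$subject_id,
                             srt_ms = trials$srt_ms, correct = correct) |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(correct),
                     median_srt = ifelse(sum(correct) > 0,
                                         stats::median(srt_ms[correct]),
                                         NA_real_),
                     .groups = "drop")
  if (any(is.na(per_subj$median_srt)))
    warning(sum(is.na(per_subj$median_srt)),
            " subject(s) without correct trials dropped from the median summary")
  acc <- 100 * sum(per_subj$n_correct) / sum(per_subj$n)
  med <- mean(per_subj$median_srt, na.rm = TRUE)
  n_subj <- nrow(per_subj)
  boot <- vapply(seq_len(n_resamples), function(i) {
    pick <- per_subj[sample.int(n_subj, n_subj, replace = TRUE), ]
    c(100 * sum(pick$n_correct) / sum(pick$n),
      mean(pick$median_srt, na.rm = TRUE))
  }, numeric(2))
  structure(list(accuracy = bootstrap_ci(acc, boot[1, ], level, "accuracy"),
                 median_srt = bootstrap_ci(med, boot[2, ], level,
                                           "mean_of_subject_medians"),
                 subject_medians = per_subj, n_trials = nrow(trials),
                 n_subjects = n_subj),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d subjects, %d trials\n", x$n_subjects,
              x$n_trials))
  cat(sprintf("  accuracy: %.1f%% [%.1f, %.1f]\n", x$accuracy$estimate,
              x$accuracy$lower, x$accuracy$upper))
  cat(sprintf("  mean of subject median SRTs: %.0f ms [%.0f, %.0f]\n",
              x$median_srt$estimate, x$median_srt$lower, x$median_srt$upper))
  invisible(x)
}

#' Monte-Carlo permutation test between two conditions
#'
#' Pools the per-subject summary values of the two conditions, reshuffles
#' them into fake samples of the original sizes, and recomputes the
#' difference of group means each time. The two-sided p-value counts null
#' differences at least as extreme as the observed one, with the +1/(n+1)
#' correction so that p = 0 is impossible; the raw exceedance count and a
#' normal-approximation p (from the null mean/sd) are also reported.
#'
#' @param a,b numeric vectors of per-subject summaries (one value per
#'   subject per condition).
#' @param n_permutations number of random reshuffles.
#' @param statistic_name label stored in the result.
#' @return object of class `permutation_result`.
#' @export
permutation_test <- function(a, b, n_permutations = 2000,
                             statistic_name = "mean") {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per condition", call. = FALSE)
  pooled <- c(a, b)
  na <- length(a)
  observed <- mean(a) - mean(b)
  null_diff <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  count <- sum(abs(null_diff) >= abs(observed))
  p <- (count + 1) / (n_permutations + 1)
  p_normal <- 2 * stats::pnorm(-abs(observed - mean(null_diff)) /
                                 stats::sd(null_diff))
  structure(list(observed_diff = observed, n_permutations = n_permutations,
                 p_value = p, exceedance_count = count,
                 p_normal_approx = p_normal,
                 null_mean = mean(null_diff), null_sd = stats::sd(null_diff),
                 statistic_name = statistic_name),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  floor_p <- 1 / (x$n_permutations + 1)
  cat(sprintf("<permutation_result> %s: observed diff %.4g, p %s\n",
              x$statistic_name, x$observed_diff,
              if (x$exceedance_count == 0)
                sprintf("< %.2g (floor)", floor_p)
              else sprintf("= %.4g", x$p_value)))
  invisible(x)
}
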