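#' Hits-minus-false-alarms differenced distribution
#'
#' Collapses a binned correct/error distribution into a single signed
#' per-bin count, hits minus false alarms. The raw difference can be
#' negative (early bins of a condition with an error bias).
#'
#' @param dist an [bin_srt_distribution()] result.
#' @return tibble with `bin_lower` and `diff`.
#' @export
hits_minus_fa <- function(dist) {
  stopifnot(inherits(dist, "srt_distribution"))
  if (dist$n_total == 0) stop("empty SRT distribution", call. = FALSE)
  tibble::tibble(bin_lower = dist$bins$bin_lower,
                 diff = dist$bins$n_correct - dist$bins$n_error)
}

#' Onset of the congruency effect between two differenced distributions
#'
#' Compares the congruent and incongruent hits-minus-FA distributions bin by
#' bin with the same chi-square / consecutive-bin procedure as [min_srt()].
#' The exact per-bin contingency the original procedure used on differenced
#' counts is under-determined (differences can be negative), so this is a
#' reconstruction: differenced counts are rescaled to equal condition
#' totals, negatives are clipped to zero, and each bin's clipped pair
#' `(a, b)` is tested against an equal split (2-cell Pearson, 1 df). The
#' onset is the lower edge of the first bin with `p < alpha`, `a > b`,
#' `a + b >= min_total`, and four consecutive successors also qualifying.
#' `method = "raw2x2"` offers the alternative reading: a 2x2 Pearson test of
#' the raw hit/false-alarm counts by condition per bin, with the same
#' direction and run rules on the rescaled differences.
#'
#' @param dist_congruent,dist_incongruent [bin_srt_distribution()] results
#'   on the same bin grid.
#' @param alpha,consecutive,min_total decision rule, as in [min_srt()].
#' @param method `"diff_clip"` (default, clipped differenced counts) or
#'   `"raw2x2"`.
#' @return object of class `congruency_onset_result`: `onset_ms`,
#'   per-bin trace (raw and clipped differences, chi2, p, flag), and the
#'   rule parameters.
#' @export
congruency_onset <- function(dist_congruent, dist_incongruent,
                             alpha = 0.05, consecutive = 5, min_total = 5,
                             method = c("diff_clip", "raw2x2")) {
  method <- match.arg(method)
  stopifnot(inherits(dist_congruent, "srt_distribution"),
            inherits(dist_incongruent, "srt_distribution"))
  if (!identical(dist_congruent$bins$bin_lower,
                 dist_incongruent$bins$bin_lower) ||
      dist_congruent$bin_width_ms != dist_incongruent$bin_width_ms)
    stop("the two distributions are binned on different grids", call. = FALSE)
  if (dist_congruent$n_total == 0 || dist_incongruent$n_total == 0)
    stop("empty SRT distribution", call. = FALSE)

  d_c <- hits_minus_fa(dist_congruent)$diff
  d_i <- hits_minus_fa(dist_incongruent)$diff
  # rescale both conditions to the mean total so unequal designs compare
  n_ref <- mean(c(dist_congruent$n_total, dist_incongruent$n_total))
  s_c <- d_c * n_ref / dist_congruent$n_total
  s_i <- d_i * n_ref / dist_incongruent$n_total
  a <- pmax(s_c, 0)
  b <- pmax(s_i, 0)

  if (method == "diff_clip") {
    test <- chi2_correct_vs_error(a, b, alpha = alpha, min_total = min_total)
  } else {
    # 2x2 on raw per-bin hit/FA counts by condition; direction still taken
    # from the rescaled differences
    hc <- dist_congruent$bins$n_correct; fc <- dist_congruent$bins$n_error
    hi <- dist_incongruent$bins$n_correct; fi <- dist_incongruent$bins$n_error
    n <- hc + fc + hi + fi
    chi2 <- ifelse(n > 0 & (hc + hi) > 0 & (fc + fi) > 0 &
                     (hc + fc) > 0 & (hi + fi) > 0,
                   n * (hc * fi - fc * hi)^2 /
                     ((hc + fc) * (hi + fi) * (hc + hi) * (fc + fi)),
                   NA_real_)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    sig <- !is.na(p) & p < alpha & a > b & (a + b) >= min_total
    test <- tibble::tibble(chi2 = chi2, p = p, significant = sig)
  }
  i <- first_sustained_run(test$significant, consecutive)
  onset <- if (is.na(i)) NA_real_ else dist_congruent$bins$bin_lower[i]
  structure(list(onset_ms = onset,
                 per_bin = tibble::tibble(
                   bin_lower = dist_congruent$bins$bin_lower,
                   diff_congruent = d_c, diff_incongruent = d_i,
                   clipped_congruent = a, clipped_incongruent = b,
                   chi2 = test$chi2, p = test$p,
                   significant = test$significant),
                 alpha = alpha, consecutive_required = consecutive,
                 min_total = min_total, method = method),
            class = "congruency_onset_result")
}

#' @export
print.congruency_onset_result <- function(x, ...) {
  cat("<congruency_onset_result> onset:",
      if (is.na(x$onset_ms)) "undefined" else paste0(x$onset_ms, " ms"),
      sprintf("(%s, p < %g over %d consecutive bins)\n", x$method, x$alpha,
              x$consecutive_required))
  invisible(x)
}

#' Congruency analysis of an object-task trial table
#'
#' Labels each pair, keeps fully congruent / fully incongruent trials (mixed
#' pairs are dropped, matching the trial selection of the behavioural
#' analysis), bins the two conditions and runs [congruency_onset()], plus a
#' [group_summary()] per condition.
#'
#' @param trials filtered object-task trial table.
#' @param ... passed to [congruency_onset()].
#' @return list with `onset` (a `congruency_onset_result`),
#'   `summary_congruent`, `summary_incongruent`, and the per-condition trial
#'   counts.
#' @export
run_congruency_analysis <- function(trials, ...) {
  validate_trials(trials)
  lab <- label_congruency(trials)
  if (all(lab == "not_applicable"))
    stop("congruency analysis needs object-task trials with contexts",
         call. = FALSE)
  cong <- trials[lab == "congruent", , drop = FALSE]
  incong <- trials[lab == "incongruent", , drop = FALSE]
  onset <- congruency_onset(bin_srt_distribution(cong),
                            bin_srt_distribution(incong), ...)
  list(onset = onset,
       summary_congruent = group_summary(cong),
       summary_incongruent = group_summary(incong),
       n_congruent = nrow(cong), n_incongruent = nrow(incong),
       n_mixed = sum(lab == "mixed"))
}
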