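#!/usr/bin/env Rscript

# Stage 2: behavioural analysis of the four task conditions.
# Filters each trial table, bins the SRTs, estimates the minimal SRT
# (per-bin chi-square + 4 consecutive qualifying bins), summarises accuracy
# and the mean of subject median SRTs with subject-level bootstrap CIs, and
# runs the six pairwise Monte-Carlo permutation tests on both summaries.

library(sacchoice)

in_dir <- "results/trials"
out_dir <- "results/srt"
fig_dir <- "results/figures"
for (d in c(out_dir, fig_dir)) dir.create(d, recursive = TRUE,
                                          showWarnings = FALSE)
conditions <- c("animal", "vehicle", "natural", "manmade")

analyses <- lapply(conditions, function(nm) {
  trials <- read_trial_table(file.path(in_dir, paste0(nm, ".tsv")))
  res <- run_scenario_analysis(trials)
  message(sprintf(
    "%-8s kept %4d/%4d trials | accuracy %.1f%% [%.1f, %.1f] | median %3.0f ms [%3.0f, %3.0f] | minSRT %s",
    nm, sum(res$filter_report$n_kept), sum(res$filter_report$n_total),
    res$summary$accuracy$estimate, res$summary$accuracy$lower,
    res$summary$accuracy$upper, res$summary$median_srt$estimate,
    res$summary$median_srt$lower, res$summary$median_srt$upper,
    ifelse(is.na(res$min_srt$onset_ms), "undefined",
           paste0(res$min_srt$onset_ms, " ms"))))
  ggplot2::ggsave(file.path(fig_dir, paste0("srt_", nm, ".png")),
                  plot_srt_distribution(res$distribution,
                                        res$min_srt$onset_ms, title = nm),
                  width = 6, height = 4, dpi = 150)
  res
})
names(analyses) <- conditions

# six pairwise permutation tests per summary statistic
set.seed(2L)
pairs <- utils::combn(conditions, 2, simplify = FALSE)
perm <- lapply(pairs, function(pr) {
  s1 <- analyses[[pr[1]]]$summary$subject_medians
  s2 <- analyses[[pr[2]]]$summary$subject_medians
  acc <- permutation_test(100 * s1$n_correct / s1$n,
                          100 * s2$n_correct / s2$n,
                          statistic_name = "accuracy")
  med <- permutation_test(s1$median_srt, s2$median_srt,
                          statistic_name = "median_srt")
  message(sprintf("%-8s vs %-8s accuracy diff %+6.1f%% (p %.4g) | median diff %+6.1f ms (p %.4g)",
                  pr[1], pr[2], acc$observed_diff, acc$p_value,
                  med$observed_diff, med$p_value))
  list(pair = pr, accuracy = unclass(acc), median_srt = unclass(med))
})

bundle <- list(
  conditions = lapply(analyses, function(r) list(
    accuracy = r$summary$accuracy, median_srt = r$summary$median_srt,
    min_srt_ms = r$min_srt$onset_ms,
    per_bin = r$min_srt$per_bin,
    exclusions = r$filter_report)),
  permutation_tests = perm)
jsonlite::write_json(bundle, file.path(out_dir, "srt_analysis.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
message("wrote ", file.path(out_dir, "srt_analysis.json"))
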