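# hand-buildable trial rows for unit tests
make_trials <- function(srt, correct = TRUE, subject = "S01", task = "animal",
                        target_context = "natural",
                        distractor_context = "manmade") {
  n <- length(srt)
  correct <- rep_len(correct, n)
  target <- rep_len("left", n)
  tibble::tibble(
    subject_id = rep_len(subject, n), task = rep_len(task, n),
    target_side = target,
    response_side = ifelse(correct, target, "right"),
    srt_ms = srt,
    target_context = rep_len(target_context, n),
    distractor_context = rep_len(distractor_context, n))
}

# build an srt_distribution directly from per-bin counts (grid from 80 ms)
make_distribution <- function(n_correct, n_error, bin_width = 10) {
  srt <- c(rep(80 + bin_width * (seq_along(n_correct) - 1) + 1,
               times = n_correct),
           rep(80 + bin_width * (seq_along(n_error) - 1) + 1,
               times = n_error))
  correct <- c(rep(TRUE, sum(n_correct)), rep(FALSE, sum(n_error)))
  bin_srt_distribution(make_trials(srt, correct), bin_width_ms = bin_width)
}

quiet_summary <- function(...) suppressWarnings(group_summary(...))
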