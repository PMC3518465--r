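test_that("SRT validity window keeps only 80-800 ms trials with a saccade", {
  trials <- make_trials(c(75, 120, 850))
  out <- filter_trials(trials)
  expect_equal(out$trials$srt_ms, 120)

  # boundary values are inside the inclusive window
  out <- filter_trials(make_trials(c(80, 800, 79.9, 800.1)))
  expect_equal(out$trials$srt_ms, c(80, 800))

  # all-in-range input passes unchanged
  trials <- make_trials(c(100, 200, 300))
  expect_identical(filter_trials(trials)$trials, trials)
})

test_that("exclusion report matches an exhaustive hand count", {
  trials <- make_trials(c(79, runif(97, 100, 700), 500, 600))
  trials$response_side[99:100] <- "none"
  out <- filter_trials(trials)
  # brute-force count over the rows
  expected_excluded <- sum(trials$response_side == "none" |
                             trials$srt_ms < 80 | trials$srt_ms > 800)
  expect_equal(out$report$n_total, 100)
  expect_equal(out$report$n_no_saccade, 2)
  expect_equal(out$report$n_out_of_range, 1)
  expect_equal(out$report$pct_excluded, 100 * expected_excluded / 100)
  expect_equal(nrow(out$trials), 100 - expected_excluded)
})

test_that("filtering is idempotent and empty input is not an error", {
  trials <- make_trials(c(75, 120, 850, 400))
  once <- filter_trials(trials)$trials
  expect_identical(filter_trials(once)$trials, once)
  empty <- filter_trials(trials[0, ])
  expect_equal(nrow(empty$trials), 0)
  expect_equal(nrow(empty$report), 0)
})

test_that("congruency labels follow the full truth table", {
  # independent oracle: the definition written out case by case
  oracle <- function(task, tc, dc) {
    if (!(task %in% c("animal", "vehicle")) || tc == "none" || dc == "none")
      return("not_applicable")
    t_ok <- (task == "animal" && tc == "natural") ||
      (task == "vehicle" && tc == "manmade")
    d_ok <- (task == "animal" && dc == "manmade") ||
      (task == "vehicle" && dc == "natural")
    if (t_ok && d_ok) "congruent"
    else if (!t_ok && !d_ok) "incongruent"
    else "mixed"
  }
  grid <- expand.grid(task = c("animal", "vehicle", "natural", "manmade"),
                      tc = c("natural", "manmade", "none"),
                      dc = c("natural", "manmade", "none"),
                      stringsAsFactors = FALSE)
  got <- label_congruency(data.frame(task = grid$task,
                                     target_context = grid$tc,
                                     distractor_context = grid$dc))
  want <- mapply(oracle, grid$task, grid$tc, grid$dc)
  expect_equal(got, unname(want))
  # the spot checks from the definition
  expect_equal(label_congruency(data.frame(
    task = "animal", target_context = "natural",
    distractor_context = "manmade")), "congruent")
  expect_equal(label_congruency(data.frame(
    task = "animal", target_context = "manmade",
    distractor_context = "natural")), "incongruent")
  expect_equal(label_congruency(data.frame(
    task = "animal", target_context = "natural",
    distractor_context = "natural")), "mixed")
})

test_that("trial tables round-trip through disk losslessly", {
  withr::with_seed(7, {
    spec <- packaged_scenarios()$animal
    spec$n_subjects <- 2
    spec$trials_per_subject <- 25
    trials <- generate_srt_data(spec)
  })
  trials$extra_note <- paste0("n", seq_len(nrow(trials)))  # unknown column
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(trials, path)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(trials))
})

test_that("reader handles delimiters, case, and malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  # comma-delimited with upper-case header
  writeLines(c("Subject_ID,Task,Target_Side,Response_Side,SRT_MS,Target_Context,Distractor_Context",
               "S01,animal,left,left,150,natural,manmade"), path)
  tbl <- read_trial_table(path)
  expect_equal(tbl$srt_ms, 150)

  # header only -> empty table
  writeLines(paste(c("subject_id", "task", "target_side", "response_side",
                     "srt_ms", "target_context", "distractor_context"),
                   collapse = "\t"), path)
  expect_equal(nrow(read_trial_table(path)), 0)

  # missing mandatory column is named
  writeLines(c("subject_id,task,target_side,response_side,target_context,distractor_context",
               "S01,animal,left,left,natural,manmade"), path)
  expect_error(read_trial_table(path), "srt_ms")

  # unparsable SRT cites the line
  writeLines(c("subject_id,task,target_side,response_side,srt_ms,target_context,distractor_context",
               "S01,animal,left,left,150,natural,manmade",
               "S01,animal,left,left,abc,natural,manmade"), path)
  expect_error(read_trial_table(path), "line 3")
})
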