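#' Trial tables
#'
#' A trial table is a tibble with one row per saccadic response and the
#' columns `subject_id`, `task` (animal / vehicle / natural / manmade),
#' `target_side` (left / right), `response_side` (left / right / none),
#' `srt_ms` (saccadic reaction time, ms), `target_context` and
#' `distractor_context` (natural / manmade / none). Scene tasks (natural,
#' manmade) carry `"none"` in both context columns: the scene is the target,
#' there is no foreground object.
#'
#' @name trial_table
NULL

trial_cols <- c("subject_id", "task", "target_side", "response_side",
                "srt_ms", "target_context", "distractor_context")
task_levels <- c("animal", "vehicle", "natural", "manmade")
side_levels <- c("left", "right", "none")
context_levels <- c("natural", "manmade", "none")

validate_trials <- function(trials) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing) > 0)
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(trials$srt_ms))
    stop("`srt_ms` must be numeric", call. = FALSE)
  bad <- setdiff(unique(trials$task), task_levels)
  if (length(bad) > 0)
    stop("unknown task value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(trials)
}

#' Was the saccade correct?
#'
#' A trial is correct iff the saccade landed on the target side. Trials with
#' no saccade (`response_side == "none"`) are `NA` and must be removed by
#' [filter_trials()] before analysis.
#'
#' @param trials a trial table.
#' @return logical vector, one element per trial.
#' @export
trial_correct <- function(trials) {
  ifelse(trials$response_side == "none", NA,
         trials$response_side == trials$target_side)
}

#' Apply the SRT validity window and drop trials without a saccade
#'
#' Keeps trials with a saccade and a reaction time inside the inclusive
#' 80-800 ms window; anything faster is treated as an anticipation, anything
#' slower as a lapse, and no-saccade trials are discarded at the same stage.
#'
#' @param trials a trial table.
#' @param window inclusive SRT validity window in ms.
#' @return a list with `trials` (the retained rows) and `report`, a tibble of
#'   per-task counts: trials seen, trials with no saccade, trials outside the
#'   window, and the percentage excluded.
#' @export
filter_trials <- function(trials, window = c(80, 800)) {
  validate_trials(trials)
  if (nrow(trials) == 0) {
    report <- tibble::tibble(task = character(), n_total = integer(),
                             n_no_saccade = integer(), n_out_of_range = integer(),
                             n_kept = integer(), pct_excluded = numeric())
    return(list(trials = trials, report = report))
  }
  no_sacc <- trials$response_side == "none"
  out_rng <- !no_sacc & (trials$srt_ms < window[1] | trials$srt_ms > window[2])
  keep <- !no_sacc & !out_rng
  report <- tibble::tibble(task = trials$task, no_sacc = no_sacc,
                           out_rng = out_rng, keep = keep) |>
    dplyr::group_by(task) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_no_saccade = sum(no_sacc),
                     n_out_of_range = sum(out_rng),
                     n_kept = sum(keep),
                     pct_excluded = 100 * (1 - sum(keep) / dplyr::n()),
                     .groups = "drop")
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Label object/context congruency of a trial pair
#'
#' An animal is congruent in a natural context, a vehicle in a man-made one.
#' In the object tasks the distractor carries the opposite object category,
#' so a pair is `congruent` only when both the target and the distractor
#' scene match their object (animal target in natural with vehicle distractor
#' in manmade, or the vehicle-task mirror), `incongruent` when both violate
#' it, and `mixed` otherwise. Scene tasks have no object and return
#' `not_applicable`.
#'
#' @param trials a trial table (or any data frame with `task`,
#'   `target_context`, `distractor_context`).
#' @return character vector with values `congruent`, `incongruent`, `mixed`,
#'   `not_applicable`.
#' @export
label_congruency <- function(trials) {
  task <- trials$task
  tc <- trials$target_context
  dc <- trials$distractor_context
  # context in which each object category is congruent
  target_home <- ifelse(task == "animal", "natural", "manmade")
  distractor_home <- ifelse(task == "animal", "manmade", "natural")
  t_match <- tc == target_home
  d_match <- dc == distractor_home
  out <- ifelse(t_match & d_match, "congruent",
         ifelse(!t_match & !d_match, "incongruent", "mixed"))
  out[!(task %in% c("animal", "vehicle")) | tc == "none" | dc == "none"] <-
    "not_applicable"
  out
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read / write a trial table
#'
#' Delimited UTF-8 text with a header; tab or comma is auto-detected on read
#' and columns are matched case-insensitively. Unknown columns are preserved,
#' so a read-write round trip is lossless. Writing uses canonical lower-case
#' column names and tab separation.
#'
#' @param path file path.
#' @param trials a trial table.
#' @return `read_trial_table` returns a trial tibble; `write_trial_table`
#'   returns `trials` invisibly.
#' @export
read_trial_table <- function(path) {
  delim <- detect_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(trimws(names(tbl)))
  missing <- setdiff(trial_cols, names(tbl))
  if (length(missing) > 0)
    stop("trial table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(tbl$srt_ms)) {
    parsed <- suppressWarnings(as.numeric(tbl$srt_ms))
    bad <- which(is.na(parsed) & !is.na(tbl$srt_ms))
    if (length(bad) > 0)
      stop("unparsable srt_ms value ", dQuote(tbl$srt_ms[bad[1]]),
           " at data line ", bad[1] + 1L, " of ", path, call. = FALSE)
    tbl$srt_ms <- parsed
  }
  for (col in c("subject_id", "task", "target_side", "response_side",
                "target_context", "distractor_context"))
    tbl[[col]] <- as.character(tbl[[col]])
  validate_trials(tbl)
  tbl
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  validate_trials(trials)
  ordered <- trials[, c(trial_cols, setdiff(names(trials), trial_cols))]
  readr::write_delim(ordered, path, delim = "\t", progress = FALSE)
  invisible(trials)
}
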