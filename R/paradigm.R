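#' Build a block-design stimulus paradigm
#'
#' Constructs the alternating rest/task block structure of a motor-task
#' session: a lead-in rest, then `n_trials` cycles of a task block (up
#' to 5 minutes each) followed by a rest block.
#'
#' @param n_trials Number of task trials (>= 1).
#' @param task_s Task block duration in seconds (<= 300).
#' @param rest_s Rest duration between trials in seconds (default 60).
#' @param lead_in_s Rest before the first trial, seconds (default 30).
#' @return A tibble of blocks with columns `onset` (s), `duration` (s)
#'   and `condition` (`"task"` or `"rest"`), sorted by onset, carrying
#'   attributes `n_trials` and `session_duration` (s). Class
#'   `stim_paradigm`.
#' @export
#' @examples
#' build_paradigm(n_trials = 5, task_s = 300, rest_s = 60)
build_paradigm <- function(n_trials, task_s = 300, rest_s = 60, lead_in_s = 30) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1 ||
      n_trials != round(n_trials)) {
    abort("`n_trials` must be a positive integer.")
  }
  if (task_s <= 0 || rest_s <= 0 || lead_in_s < 0) {
    abort("Block durations must be positive (lead-in may be zero).")
  }
  if (task_s > 300) {
    abort("Task blocks are capped at 300 s (5 minutes).")
  }
  onset <- lead_in_s
  rows <- vector("list", 2L * n_trials + (lead_in_s > 0))
  k <- 1L
  if (lead_in_s > 0) {
    rows[[k]] <- list(onset = 0, duration = lead_in_s, condition = "rest")
    k <- k + 1L
  }
  for (i in seq_len(n_trials)) {
    rows[[k]] <- list(onset = onset, duration = task_s, condition = "task")
    k <- k + 1L
    onset <- onset + task_s
    rows[[k]] <- list(onset = onset, duration = rest_s, condition = "rest")
    k <- k + 1L
    onset <- onset + rest_s
  }
  out <- dplyr::bind_rows(rows)
  out <- tibble::new_tibble(out, class = "stim_paradigm")
  attr(out, "n_trials") <- as.integer(n_trials)
  attr(out, "session_duration") <- onset
  out
}

#' Session duration of a paradigm
#' @param paradigm A `stim_paradigm`.
#' @return Duration in seconds.
#' @export
session_duration <- function(paradigm) {
  attr(paradigm, "session_duration") %||%
    max(paradigm$onset + paradigm$duration)
}

#' Task boxcar on a sampling grid
#'
#' @param paradigm A `stim_paradigm`.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector, 1 during task blocks, 0 elsewhere.
#' @export
task_boxcar <- function(paradigm, fs) {
  n <- round(session_duration(paradigm) * fs)
  t <- (seq_len(n) - 1) / fs
  box <- numeric(n)
  tasks <- paradigm[paradigm$condition == "task", ]
  for (i in seq_len(nrow(tasks))) {
    box[t >= tasks$onset[i] & t < tasks$onset[i] + tasks$duration[i]] <- 1
  }
  box
}

task_onsets <- function(paradigm) {
  paradigm$onset[paradigm$condition == "task"]
}
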