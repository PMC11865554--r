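# Tabular trial schema
#
# One row per trial:
#   subject_id      character/integer
#   trial_index     integer
#   start           "row,col" (0-based)
#   sender_goal     "row,col"
#   receiver_goal   "row,col"
#   trajectory      "row,col|row,col|..." ordered states incl. start
#   receiver_choice "row,col" (the Receiver's chosen state)
#   success         logical: receiver_choice equals receiver_goal

.format_state <- function(s) sprintf("%d,%d", s[1L], s[2L])
.parse_state <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
.format_trajectory <- function(states)
  paste(sprintf("%d,%d", states[, 1L], states[, 2L]), collapse = "|")
.parse_trajectory <- function(x) {
  parts <- strsplit(strsplit(x, "|", fixed = TRUE)[[1L]], ",", fixed = TRUE)
  matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
}

TRIAL_COLUMNS <- c("subject_id", "trial_index", "start", "sender_goal",
                   "receiver_goal", "trajectory", "receiver_choice",
                   "success")

.as_trial_table <- function(trials) {
  if (is.list(trials) && !is.data.frame(trials) && !is.null(trials$trials))
    trials <- trials$trials
  if (!is.data.frame(trials))
    stop("expected a trial table data frame")
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  trials
}

#' Read a trial table from CSV
#'
#' Validates the documented schema: every state within the board and every
#' trajectory starting at `start` with 4-adjacent consecutive states.
#'
#' @param path CSV file path.
#' @param board A [tcg_board()] used for bounds/adjacency validation.
#' @return Trial table data frame.
#' @export
read_tcg_trials <- function(path, board = tcg_board()) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(success = "logical"))
  trials <- .as_trial_table(trials)
  for (i in seq_len(nrow(trials))) {
    states <- .parse_trajectory(trials$trajectory[i])
    start <- .parse_state(trials$start[i])
    if (!all(states[1L, ] == start))
      stop(sprintf("row %d: trajectory does not start at start state", i))
    tcg_message(states, board)  # validates bounds and adjacency
    .check_state(board, .parse_state(trials$sender_goal[i]), "sender_goal")
    .check_state(board, .parse_state(trials$receiver_goal[i]),
                 "receiver_goal")
    .check_state(board, .parse_state(trials$receiver_choice[i]),
                 "receiver_choice")
  }
  trials
}

#' Write a trial table to CSV
#'
#' @param trials Trial table data frame (see [read_tcg_trials()]).
#' @param path Output CSV path.
#' @export
write_tcg_trials <- function(trials, path) {
  trials <- .as_trial_table(trials)
  utils::write.csv(trials, path, row.names = FALSE)  # states contain commas
  invisible(path)
}

# split a trial table into per-subject lists of configs + trajectory index
# vectors for the C++ likelihood
.subject_data <- function(trials, board = tcg_board()) {
  trials <- .as_trial_table(trials)
  lapply(split(trials, trials$subject_id), function(tt) {
    goals <- t(vapply(seq_len(nrow(tt)), function(i)
      c(.state_index(board, .parse_state(tt$sender_goal[i])),
        .state_index(board, .parse_state(tt$receiver_goal[i]))),
      integer(2)))
    trajs <- lapply(tt$trajectory, function(x) {
      st <- .parse_trajectory(x)
      as.integer(st[, 1L] * board$n_cols + st[, 2L])
    })
    list(goals = goals, trajs = trajs, n = nrow(tt))
  })
}
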