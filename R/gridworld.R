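#' Game board for the Tacit Communication Game
#'
#' The TCG is played on a rectangular grid (4 x 4 in the original task) on
#' which tokens move in the four compass directions only.  States are
#' addressed as 0-based `(row, col)` pairs, row-major.
#'
#' @param n_rows,n_cols Board dimensions (positive integers; default 4 x 4).
#' @return An object of class `tcg_board`.
#' @examples
#' b <- tcg_board()
#' neighbors(b, c(0, 0))
#' @export
tcg_board <- function(n_rows = 4L, n_cols = 4L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("board dimensions must be positive integers")
  structure(list(n_rows = n_rows, n_cols = n_cols), class = "tcg_board")
}

#' @export
print.tcg_board <- function(x, ...) {
  cat(sprintf("TCG board: %d x %d grid, 4-connected\n", x$n_rows, x$n_cols))
  invisible(x)
}

# Absolute compass directions, clockwise. "N" decreases the row index.
DIRECTIONS <- c("N", "E", "S", "W")
.DIR_DROW <- c(N = -1L, E = 0L, S = 1L, W = 0L)
.DIR_DCOL <- c(N = 0L, E = 1L, S = 0L, W = -1L)

.check_state <- function(board, s, what = "state") {
  s <- as.integer(s)
  if (length(s) != 2L || anyNA(s))
    stop(sprintf("%s must be an integer (row, col) pair", what))
  if (s[1L] < 0L || s[1L] >= board$n_rows || s[2L] < 0L || s[2L] >= board$n_cols)
    stop(sprintf("%s (%d, %d) is off the %d x %d board",
                 what, s[1L], s[2L], board$n_rows, board$n_cols))
  s
}

# row-major 0-based linear index, used at the C++ boundary
.state_index <- function(board, s) s[1L] * board$n_cols + s[2L]
.index_state <- function(board, i) c(i %/% board$n_cols, i %% board$n_cols)

#' Feasible moves from a state
#'
#' @param board A [tcg_board()].
#' @param s State as 0-based `(row, col)`.
#' @return Named list mapping each feasible absolute direction (`"N"`, `"E"`,
#'   `"S"`, `"W"`) to the target state.  Corners have 2 entries, edges 3,
#'   interior states 4.
#' @export
neighbors <- function(board, s) {
  s <- .check_state(board, s)
  out <- list()
  for (d in DIRECTIONS) {
    t <- c(s[1L] + .DIR_DROW[[d]], s[2L] + .DIR_DCOL[[d]])
    if (t[1L] >= 0L && t[1L] < board$n_rows && t[2L] >= 0L && t[2L] < board$n_cols)
      out[[d]] <- t
  }
  out
}

#' Direction of a move relative to the current heading
#'
#' The heading is the absolute direction of the preceding move; the first
#' move of a trajectory has no heading (`NA`) and maps to `"first"`.  `"L"`
#' is fixed as the counter-clockwise rotation of the heading (so heading
#' `"E"`, move `"N"` is a left turn); priors are L/R symmetric, so the
#' convention only matters for message profiles.
#'
#' @param heading Absolute direction of the last move, or `NA` before the
#'   first move.
#' @param move Absolute direction of the move to classify.
#' @return One of `"F"`, `"L"`, `"R"`, `"B"`, `"first"`.
#' @export
relative_direction <- function(heading, move) {
  if (!move %in% DIRECTIONS) stop("unknown direction: ", move)
  if (is.na(heading) || identical(heading, "undefined")) return("first")
  if (!heading %in% DIRECTIONS) stop("unknown heading: ", heading)
  diff <- (match(move, DIRECTIONS) - match(heading, DIRECTIONS)) %% 4L
  c("F", "R", "B", "L")[diff + 1L]
}

#' Shortest path length between two states
#'
#' On an obstacle-free 4-connected grid this is the Manhattan distance.
#'
#' @inheritParams neighbors
#' @param a,b States as 0-based `(row, col)`.
#' @export
shortest_path_length <- function(board, a, b) {
  a <- .check_state(board, a); b <- .check_state(board, b)
  abs(a[1L] - b[1L]) + abs(a[2L] - b[2L])
}

#' Goal configuration of a TCG trial
#'
#' @param start,sender_goal,receiver_goal States as 0-based `(row, col)`.
#'   Both goals must differ from the start.
#' @param board A [tcg_board()]; defaults to the 4 x 4 task board.
#' @return An object of class `tcg_config`.
#' @export
tcg_config <- function(start, sender_goal, receiver_goal, board = tcg_board()) {
  start <- .check_state(board, start, "start")
  sender_goal <- .check_state(board, sender_goal, "sender_goal")
  receiver_goal <- .check_state(board, receiver_goal, "receiver_goal")
  if (all(sender_goal == start)) stop("sender_goal must differ from start")
  if (all(receiver_goal == start)) stop("receiver_goal must differ from start")
  structure(list(start = start, sender_goal = sender_goal,
                 receiver_goal = receiver_goal, board = board),
            class = "tcg_config")
}

#' @export
print.tcg_config <- function(x, ...) {
  fmt <- function(s) sprintf("(%d,%d)", s[1L], s[2L])
  cat(sprintf("TCG goal configuration on %d x %d board: start %s, sender goal %s, receiver goal %s [%s]\n",
              x$board$n_rows, x$board$n_cols, fmt(x$start), fmt(x$sender_goal),
              fmt(x$receiver_goal), classify_trial(x)))
  invisible(x)
}

#' Classify a goal configuration as direct or indirect
#'
#' A trial is *direct* when the Receiver's goal lies on at least one shortest
#' path from the start to the Sender's goal, i.e. when
#' `d(start, rg) + d(rg, sg) == d(start, sg)` with `d` the Manhattan
#' distance; otherwise it is *indirect* and the Sender must leave the direct
#' route to mark the Receiver's goal.
#'
#' @param config A [tcg_config()].
#' @return `"direct"` or `"indirect"`.
#' @export
classify_trial <- function(config) {
  stopifnot(inherits(config, "tcg_config"))
  b <- config$board
  d1 <- shortest_path_length(b, config$start, config$receiver_goal)
  d2 <- shortest_path_length(b, config$receiver_goal, config$sender_goal)
  d0 <- shortest_path_length(b, config$start, config$sender_goal)
  if (d1 + d2 == d0) "direct" else "indirect"
}

#' Points remaining after the best continuation
#'
#' The Sender starts each trial with an endowment of ten points and pays one
#' point per step.  The reward of being in `s_next` after `steps_taken`
#' moves is the number of points that would remain after continuing on the
#' shortest route through the Receiver's goal (if not yet visited) to the
#' Sender's goal.  Values are deliberately not clamped at zero: negative
#' rewards preserve the urgency gradient on long trajectories.
#'
#' @param config A [tcg_config()].
#' @param s_next State reached by the move under evaluation.
#' @param steps_taken Number of moves taken including the move into `s_next`.
#' @param receiver_goal_visited Has the trajectory already visited the
#'   Receiver's goal (before this move)?
#' @return Remaining points (may be negative).
#' @export
remaining_reward <- function(config, s_next, steps_taken,
                             receiver_goal_visited = FALSE) {
  stopifnot(inherits(config, "tcg_config"), steps_taken >= 1)
  b <- config$board
  s_next <- .check_state(b, s_next, "s_next")
  rg <- config$receiver_goal; sg <- config$sender_goal
  visited <- receiver_goal_visited || all(s_next == rg)
  remaining <- if (visited) shortest_path_length(b, s_next, sg)
  else shortest_path_length(b, s_next, rg) + shortest_path_length(b, rg, sg)
  10 - steps_taken - remaining
}

#' Construct a message (Sender trajectory)
#'
#' @param states Matrix with one 0-based `(row, col)` state per row, starting
#'   at the trial's start state; consecutive states must be 4-adjacent.
#' @param board A [tcg_board()].
#' @param step_surprise Optional per-move Shannon surprise values (bits).
#' @return An object of class `tcg_message` with absolute moves (`actions`)
#'   and heading-relative moves (`relative_actions`, first move `"first"`).
#' @export
tcg_message <- function(states, board = tcg_board(), step_surprise = NULL) {
  states <- matrix(as.integer(states), ncol = 2L)
  if (nrow(states) < 2L) stop("a message needs at least one move")
  for (i in seq_len(nrow(states))) .check_state(board, states[i, ])
  dr <- diff(states[, 1L]); dc <- diff(states[, 2L])
  if (any(abs(dr) + abs(dc) != 1L))
    stop("consecutive states must be 4-adjacent")
  actions <- character(length(dr))
  for (i in seq_along(dr)) {
    actions[i] <- names(which(.DIR_DROW == dr[i] & .DIR_DCOL == dc[i]))
  }
  relative <- character(length(actions))
  heading <- NA_character_
  for (i in seq_along(actions)) {
    relative[i] <- relative_direction(heading, actions[i])
    heading <- actions[i]
  }
  if (!is.null(step_surprise) && length(step_surprise) != length(actions))
    stop("step_surprise must have one value per move")
  structure(list(states = states, actions = actions,
                 relative_actions = relative, step_surprise = step_surprise,
                 board = board),
            class = "tcg_message")
}

#' @export
print.tcg_message <- function(x, ...) {
  path <- paste(sprintf("(%d,%d)", x$states[, 1L], x$states[, 2L]),
                collapse = " -> ")
  cat(sprintf("TCG message, %d moves: %s\n", length(x$actions), path))
  cat(" relative:", paste(x$relative_actions, collapse = " "), "\n")
  if (!is.null(x$step_surprise))
    cat(" surprise (bits):",
        paste(formatC(x$step_surprise, digits = 3, format = "f"),
              collapse = " "), "\n")
  invisible(x)
}

# all 8 symmetries of a rectangular board as state maps (used by tests and
# the symmetry invariance checks); only square boards admit the rotations.
.board_symmetries <- function(board) {
  n <- board$n_rows
  if (board$n_cols != n) {
    return(list(identity = function(s) s,
                flip_r = function(s) c(board$n_rows - 1L - s[1L], s[2L]),
                flip_c = function(s) c(s[1L], board$n_cols - 1L - s[2L]),
                flip_rc = function(s) c(board$n_rows - 1L - s[1L],
                                        board$n_cols - 1L - s[2L])))
  }
  list(
    identity  = function(s) s,
    rot90     = function(s) c(s[2L], n - 1L - s[1L]),
    rot180    = function(s) c(n - 1L - s[1L], n - 1L - s[2L]),
    rot270    = function(s) c(n - 1L - s[2L], s[1L]),
    flip_r    = function(s) c(n - 1L - s[1L], s[2L]),
    flip_c    = function(s) c(s[1L], n - 1L - s[2L]),
    transpose = function(s) c(s[2L], s[1L]),
    anti      = function(s) c(n - 1L - s[2L], n - 1L - s[1L])
  )
}
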