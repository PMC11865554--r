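#' Movement prior over heading-relative moves
#'
#' Movement-kinetic expectations: an object in motion is expected to keep
#' moving straight, so forward is most likely, left and right turns equally
#' less likely, and a backward move least likely.  Two parameters govern the
#' four probabilities: `lambda` is the backward probability p(b), and
#' `gamma` the odds of forward versus any turn, p(f) / (p(l) + p(r)).  The
#' remaining mass is split as
#' p(f) = (gamma / (gamma + 1)) (1 - lambda) and
#' p(l) = p(r) = (1/2) (1 - gamma / (gamma + 1)) (1 - lambda),
#' so p(f) > p(l) = p(r) > p(b) throughout the admissible box.
#'
#' @param lambda Backward-move probability, in `[0.001, 0.3]` when fitting
#'   (`lambda = 0` is allowed for demonstrations, where backward moves get
#'   infinite surprise).
#' @param gamma Forward-vs-turn odds, in `[2, 10]`.
#' @param strict Enforce the fitting box (default `TRUE`).
#' @return Named numeric vector `c(F = , L = , R = , B = )` summing to 1.
#' @examples
#' movement_prior(lambda = 0, gamma = 2, strict = FALSE)  # 2/3, 1/6, 1/6, 0
#' @export
movement_prior <- function(lambda, gamma, strict = TRUE) {
  if (strict) {
    if (lambda < 0.001 || lambda > 0.3)
      stop("lambda must be in [0.001, 0.3]")
    if (gamma < 2 || gamma > 10)
      stop("gamma must be in [2, 10]")
  } else {
    if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
    if (gamma <= 0) stop("gamma must be positive")
  }
  p_b <- lambda
  p_f <- gamma / (gamma + 1) * (1 - lambda)
  p_lr <- 0.5 * (1 - gamma / (gamma + 1)) * (1 - lambda)
  c(F = p_f, L = p_lr, R = p_lr, B = p_b)
}

#' State prior field toward the Sender's goal
#'
#' Goal-orientation expectations: the prior has value 1 at the Sender's goal
#' and decays with grid distance `d` by the inverse power rule
#' `p(s) = alpha^(-d)`.  Distance is Manhattan distance, the metric induced
#' by the legal 4-connected moves (the "concentric circles" of the decay are
#' diamonds on the grid).  The field is static within a trial.
#'
#' @param board A [tcg_board()].
#' @param sender_goal Goal state as 0-based `(row, col)`.
#' @param alpha Decay slope, constrained `> 1` so the prior strictly
#'   decreases with distance.
#' @return Numeric matrix (`n_rows` x `n_cols`) of prior values in `(0, 1]`.
#' @export
state_prior <- function(board, sender_goal, alpha) {
  sender_goal <- .check_state(board, sender_goal, "sender_goal")
  if (alpha <= 1) stop("alpha must be > 1")
  d <- outer(abs(seq_len(board$n_rows) - 1L - sender_goal[1L]),
             abs(seq_len(board$n_cols) - 1L - sender_goal[2L]), `+`)
  alpha^(-d)
}

#' Combined movement-state action prior at a state
#'
#' For each feasible move `m` from `s`, the movement prior evaluated at the
#' heading-relative direction of `m` is multiplied by the state-prior value
#' of the target state, and the products are renormalized over the feasible
#' moves (a normalization, not a softmax).  Infeasible (off-board) moves get
#' no mass and are never scored for surprise.  Before the first move there
#' is no heading and the movement factor is uniform over feasible moves; the
#' state-prior factor still applies.
#'
#' @param mv Movement prior from [movement_prior()] (ignored when
#'   `heading` handling leaves it uniform and `field` carries all
#'   structure).
#' @param heading Absolute direction of the previous move, or `NA` at the
#'   trajectory start.
#' @param field State-prior matrix from [state_prior()], or `NULL` for a
#'   flat field (movement prior only).
#' @param s Current state, 0-based `(row, col)`.
#' @param board A [tcg_board()].
#' @return Named probability vector over feasible absolute moves.
#' @export
combined_action_prior <- function(mv, heading, field, s, board = tcg_board()) {
  nb <- neighbors(board, s)
  w <- vapply(names(nb), function(m) {
    rel <- relative_direction(heading, m)
    mvw <- if (rel == "first") 1 else mv[[rel]]
    fw <- if (is.null(field)) 1 else field[nb[[m]][1L] + 1L, nb[[m]][2L] + 1L]
    mvw * fw
  }, numeric(1))
  tot <- sum(w)
  if (tot <= 0) stop("zero total prior mass over feasible moves")
  w / tot
}

#' Shannon surprise of an action
#'
#' `h(a | s) = -log2 p(a | s)`: how strongly the chosen action deviates from
#' what an observer holding the combined priors expects.  This surprise is
#' the signalling currency of the model: the Sender deliberately picks
#' improbable actions to draw the Receiver's attention.
#'
#' @param dist Named probability vector over feasible moves (see
#'   [combined_action_prior()]).
#' @param a Absolute move, one of the names of `dist`.
#' @return Surprise in bits (non-negative).
#' @export
surprise <- function(dist, a) {
  if (!a %in% names(dist)) stop("action '", a, "' not in the support")
  -log2(dist[[a]])
}
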