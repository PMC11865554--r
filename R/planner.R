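VARIANTS <- c("surprise", "state", "movement")

# parameter names used by each model variant, in canonical order
.variant_parnames <- function(variant) {
  switch(variant,
         surprise = c("lambda", "gamma", "alpha", "epsilon", "tau"),
         state    = c("alpha", "epsilon", "tau"),
         movement = c("lambda", "gamma", "epsilon", "tau"),
         stop("unknown variant: ", variant))
}

# box constraints on the natural scale (open intervals handled by the
# unconstrained transforms during fitting)
.param_box <- list(lambda  = c(0.001, 0.3),
                   gamma   = c(2, 10),
                   epsilon = c(0, 1),
                   tau     = c(0, Inf),
                   alpha   = c(1, Inf))

#' Model parameters for a planner variant
#'
#' The full (surprise) model has five parameters: `lambda` (backward-move
#' probability) and `gamma` (forward-vs-turn odds) shape the movement
#' prior; `alpha` (> 1) is the decay slope of the state prior; `epsilon`
#' in (0, 1) discounts rewards per planning depth; `tau` (> 0) is the
#' softmax choice stochasticity.  The *state* variant drops the movement
#' prior (no `lambda`, `gamma`) and never uses surprise; the *movement*
#' variant drops the state prior (no `alpha`) and uses surprise in both
#' phases.
#'
#' @param variant One of `"surprise"`, `"state"`, `"movement"`.
#' @param lambda,gamma,alpha,epsilon,tau Parameter values; only those used
#'   by the variant may be supplied.
#' @param strict Enforce the fitting boxes `lambda` in `[0.001, 0.3]`,
#'   `gamma` in `[2, 10]` (default `TRUE`).
#' @return An object of class `tcg_params`.
#' @export
tcg_params <- function(variant = "surprise", lambda = NULL, gamma = NULL,
                       alpha = NULL, epsilon = NULL, tau = NULL,
                       strict = TRUE) {
  variant <- match.arg(variant, VARIANTS)
  given <- list(lambda = lambda, gamma = gamma, alpha = alpha,
                epsilon = epsilon, tau = tau)
  need <- .variant_parnames(variant)
  extra <- setdiff(names(Filter(Negate(is.null), given)), need)
  if (length(extra))
    stop(sprintf("variant '%s' does not use parameter(s): %s",
                 variant, paste(extra, collapse = ", ")))
  missing <- need[vapply(given[need], is.null, logical(1))]
  if (length(missing))
    stop(sprintf("variant '%s' requires parameter(s): %s",
                 variant, paste(missing, collapse = ", ")))
  p <- unlist(given[need])
  if (p[["epsilon"]] <= 0 || p[["epsilon"]] >= 1)
    stop("epsilon must be in (0, 1)")
  if (p[["tau"]] <= 0) stop("tau must be > 0")
  if ("alpha" %in% need && p[["alpha"]] <= 1) stop("alpha must be > 1")
  if (strict && "lambda" %in% need &&
      (p[["lambda"]] < 0.001 || p[["lambda"]] > 0.3))
    stop("lambda must be in [0.001, 0.3]")
  if (strict && "gamma" %in% need &&
      (p[["gamma"]] < 2 || p[["gamma"]] > 10))
    stop("gamma must be in [2, 10]")
  structure(list(variant = variant, values = p), class = "tcg_params")
}

#' @export
print.tcg_params <- function(x, ...) {
  cat(sprintf("TCG %s-model parameters:\n", x$variant))
  print(round(x$values, 4))
  invisible(x)
}

#' Reference group-level parameter estimates
#'
#' Group posterior means for the three planner variants as estimated on the
#' original behavioral sample; used as the package's default generating
#' parameters for synthetic cohorts and demonstrations.  Note the movement
#' variant's `gamma` estimate sits below the fitting box and is therefore
#' constructed with `strict = FALSE`.
#'
#' @param variant One of `"surprise"`, `"state"`, `"movement"`.
#' @return A [tcg_params()] object.
#' @export
default_group_params <- function(variant = "surprise") {
  variant <- match.arg(variant, VARIANTS)
  switch(variant,
         surprise = tcg_params("surprise", lambda = 0.10, gamma = 2.14,
                               alpha = 1.84, epsilon = 0.39, tau = 6.93),
         state = tcg_params("state", alpha = 1.11, epsilon = 0.39,
                            tau = 2.90),
         movement = tcg_params("movement", lambda = 0.15, gamma = 1.50,
                               epsilon = 0.62, tau = 1.92, strict = FALSE))
}

#' Planner settings
#'
#' @param horizon Lookahead depth of the policy tree (>= 1; default 3,
#'   which reproduces the qualitative message patterns at negligible cost
#'   on a 4 x 4 board).
#' @param aggregate How expected values of tree branches sharing a first
#'   move are reduced: `"max"` (best continuation; default), `"sum"`, or
#'   `"mean"`.
#' @param guard Maximum number of moves before generation aborts
#'   (default 20).
#' @return An object of class `tcg_planner`.
#' @export
tcg_planner <- function(horizon = 3L, aggregate = c("max", "sum", "mean"),
                        guard = 20L) {
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be >= 1")
  aggregate <- match.arg(aggregate)
  structure(list(horizon = horizon, aggregate = aggregate,
                 guard = as.integer(guard)),
            class = "tcg_planner")
}

.variant_code <- function(variant) match(variant, VARIANTS) - 1L
.agg_code <- function(aggregate) match(aggregate, c("max", "sum", "mean")) - 1L

# fill unused parameters with inert values at the C++ boundary
.cpp_args <- function(params) {
  v <- params$values
  list(variant = .variant_code(params$variant),
       lambda = if ("lambda" %in% names(v)) v[["lambda"]] else 0.1,
       gamma = if ("gamma" %in% names(v)) v[["gamma"]] else 2,
       alpha = if ("alpha" %in% names(v)) v[["alpha"]] else 2,
       eps = v[["epsilon"]], tau = v[["tau"]])
}

#' Expected values of the immediately available moves
#'
#' Enumerates the policy tree of move sequences up to the planning horizon.
#' Each tree edge at depth `i` (0 at the immediate move) contributes the
#' variant's step value -- for the surprise model in phase 1 the Shannon
#' surprise of the move under the combined movement-state prior times the
#' discounted remaining reward `epsilon^i * r`; in phase 2 (after the
#' Receiver's goal is reached) the state-prior action probability replaces
#' the surprise.  Branch sums are reduced to one value per first move by
#' the planner's aggregation rule.  The phase is evaluated per tree node,
#' and branches stop at the Sender's goal.
#'
#' @param config A [tcg_config()].
#' @param s Current state, 0-based `(row, col)`.
#' @param heading Absolute direction of the previous move, or `NA` at the
#'   trajectory start.
#' @param steps_taken Moves already taken in the trajectory.
#' @param params A [tcg_params()].
#' @param planner A [tcg_planner()].
#' @param receiver_goal_visited Has the trajectory already visited the
#'   Receiver's goal?
#' @return Named numeric vector of expected values over feasible moves.
#' @export
expected_values <- function(config, s, heading = NA, steps_taken = 0L,
                            params = default_group_params(),
                            planner = tcg_planner(),
                            receiver_goal_visited = FALSE) {
  stopifnot(inherits(config, "tcg_config"), inherits(params, "tcg_params"))
  b <- config$board
  s <- .check_state(b, s)
  h <- if (is.na(heading)) -1L else match(heading, DIRECTIONS) - 1L
  a <- .cpp_args(params)
  res <- cpp_plan_step(b$n_rows, b$n_cols,
                       .state_index(b, config$sender_goal),
                       .state_index(b, config$receiver_goal),
                       .state_index(b, s), h, as.integer(steps_taken),
                       receiver_goal_visited, a$variant, a$lambda, a$gamma,
                       a$alpha, a$eps, a$tau, planner$horizon,
                       .agg_code(planner$aggregate))
  ev <- res$ev
  names(ev) <- DIRECTIONS
  ev[!is.na(ev)]
}

#' Softmax action policy
#'
#' `Pr(a) = exp(tau * EV(a)) / sum_a' exp(tau * EV(a'))`, computed with
#' max-subtraction for overflow safety.  As `tau` shrinks to 0 the policy
#' becomes uniform; large `tau` concentrates on the argmax move.
#'
#' @param ev Named numeric vector of expected values.
#' @param tau Temperature (> 0).
#' @return Named probability vector.
#' @export
softmax_policy <- function(ev, tau) {
  if (!length(ev)) stop("empty move set")
  if (tau <= 0) stop("tau must be > 0")
  w <- exp(tau * (ev - max(ev)))
  w / sum(w)
}

.parse_plan <- function(config, traj_idx, aborted, params, planner) {
  b <- config$board
  states <- t(vapply(traj_idx, function(i) .index_state(b, i), integer(2)))
  a <- .cpp_args(params)
  info <- cpp_step_info(as.integer(traj_idx), b$n_rows, b$n_cols,
                        .state_index(b, config$sender_goal),
                        .state_index(b, config$receiver_goal),
                        a$variant, a$lambda, a$gamma, a$alpha, a$eps, a$tau,
                        planner$horizon, .agg_code(planner$aggregate))
  msg <- tcg_message(states, board = b, step_surprise = info$surprise)
  records <- data.frame(step = seq_len(nrow(info)),
                        action = DIRECTIONS[info$move + 1L],
                        relative = msg$relative_actions,
                        phase = info$phase,
                        surprise = info$surprise,
                        prior_p = info$prior_p,
                        policy_p = info$policy_p,
                        ev = info$ev)
  structure(list(message = msg, records = records, config = config,
                 variant = params$variant,
                 points = 10L - length(msg$actions), aborted = aborted),
            class = "tcg_plan")
}

#' @export
print.tcg_plan <- function(x, ...) {
  cat(sprintf("TCG %s-model message plan (%s)\n", x$variant,
              if (x$aborted) "aborted at length guard" else
                sprintf("%d points remaining", x$points)))
  print(x$message)
  invisible(x)
}

#' Generate a message by sampling the planner policy
#'
#' Samples moves step by step from the softmax policy over expected values,
#' switching from the signalling phase to the goal-directed phase at the
#' first arrival at the Receiver's goal, and stopping at the first arrival
#' at the Sender's goal.  Generation uses R's RNG stream, so results are
#' reproducible under `set.seed()`.  Trajectories exceeding the planner's
#' length guard are flagged `aborted`.
#'
#' @inheritParams expected_values
#' @return A `tcg_plan` with the [tcg_message()] (including per-step
#'   surprise in bits), a per-step record table (phase, prior and policy
#'   probabilities, expected value), points remaining, and the aborted
#'   flag.
#' @export
generate_message <- function(config, params = default_group_params(),
                             planner = tcg_planner()) {
  stopifnot(inherits(config, "tcg_config"), inherits(params, "tcg_params"))
  b <- config$board
  a <- .cpp_args(params)
  res <- cpp_generate(b$n_rows, b$n_cols, .state_index(b, config$start),
                      .state_index(b, config$sender_goal),
                      .state_index(b, config$receiver_goal),
                      a$variant, a$lambda, a$gamma, a$alpha, a$eps, a$tau,
                      planner$horizon, .agg_code(planner$aggregate),
                      planner$guard, stats::runif(planner$guard))
  .parse_plan(config, res$traj, res$aborted, params, planner)
}

#' Log-likelihood of an observed message
#'
#' Sum over moves of the log softmax-policy probability of the observed
#' move, with the planning phase inferred from the first arrival at the
#' Receiver's goal.
#'
#' @param message A [tcg_message()] or a `tcg_plan`.
#' @inheritParams expected_values
#' @return Log-likelihood (natural log).
#' @export
sequence_loglik <- function(message, config,
                            params = default_group_params(),
                            planner = tcg_planner()) {
  if (inherits(message, "tcg_plan")) message <- message$message
  stopifnot(inherits(message, "tcg_message"), inherits(config, "tcg_config"))
  if (!all(message$states[1L, ] == config$start))
    stop("message does not start at the configuration's start state")
  b <- config$board
  traj <- apply(message$states, 1L, function(s) .state_index(b, s))
  a <- .cpp_args(params)
  cpp_sequence_loglik(as.integer(traj), b$n_rows, b$n_cols,
                      .state_index(b, config$sender_goal),
                      .state_index(b, config$receiver_goal),
                      a$variant, a$lambda, a$gamma, a$alpha, a$eps, a$tau,
                      planner$horizon, .agg_code(planner$aggregate))
}
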