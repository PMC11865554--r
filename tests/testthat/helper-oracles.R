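# Independent reference implementations used as oracles.  They are written
# against the exported prior/reward primitives (or from first principles)
# and never call the compiled planner path they check.

# enumerate all shortest paths a -> b on an obstacle-free grid (recursive,
# moves that reduce Manhattan distance only)
all_shortest_paths <- function(board, a, b) {
  if (all(a == b)) return(list(matrix(a, ncol = 2)))
  out <- list()
  for (nb in neighbors(board, a)) {
    if (shortest_path_length(board, nb, b) <
        shortest_path_length(board, a, b)) {
      for (tail in all_shortest_paths(board, nb, b))
        out[[length(out) + 1L]] <- rbind(a, tail)
    }
  }
  out
}

# trial type by explicit path enumeration: direct iff the receiver goal
# appears on some shortest start -> sender_goal path
oracle_trial_type <- function(config) {
  paths <- all_shortest_paths(config$board, config$start, config$sender_goal)
  hit <- any(vapply(paths, function(p)
    any(p[, 1] == config$receiver_goal[1] & p[, 2] == config$receiver_goal[2]),
    logical(1)))
  if (hit) "direct" else "indirect"
}

# variant's per-move value and prior at a node, from the exported
# primitives (phase 1 = receiver goal not yet visited)
oracle_step_values <- function(config, s, heading, steps, rgvis, params,
                               depth_i) {
  board <- config$board
  v <- params$values
  nb <- neighbors(board, s)
  field <- if ("alpha" %in% names(v))
    state_prior(board, config$sender_goal, v[["alpha"]]) else NULL
  mv <- if ("lambda" %in% names(v))
    movement_prior(v[["lambda"]], v[["gamma"]], strict = FALSE) else NULL
  dist <- switch(params$variant,
    surprise = if (!rgvis)
      combined_action_prior(mv, heading, field, s, board)
    else combined_action_prior(NULL, NA, field, s, board),
    state = combined_action_prior(NULL, NA, field, s, board),
    movement = combined_action_prior(mv, heading, NULL, s, board))
  use_surprise <- params$variant == "movement" ||
    (params$variant == "surprise" && !rgvis)
  vapply(names(nb), function(m) {
    r <- remaining_reward(config, nb[[m]], steps + 1, rgvis)
    w <- if (use_surprise) surprise(dist, m) else dist[[m]]
    w * v[["epsilon"]]^depth_i * r
  }, numeric(1))
}

# exhaustive policy-tree enumeration: aggregate (default max) over the
# branch sums of all move sequences up to the horizon, stopping at the
# sender goal
oracle_expected_values <- function(config, s, heading = NA, steps = 0,
                                   rgvis = FALSE, params, horizon,
                                   aggregate = "max") {
  cont <- function(s, heading, steps, rgvis, i) {
    if (i >= horizon || all(s == config$sender_goal)) return(0)
    vals <- oracle_step_values(config, s, heading, steps, rgvis, params, i)
    nb <- neighbors(config$board, s)
    branch <- vapply(names(nb), function(m) {
      nxt <- nb[[m]]
      vals[[m]] + cont(nxt, m, steps + 1,
                       rgvis || all(nxt == config$receiver_goal), i + 1)
    }, numeric(1))
    switch(aggregate, max = max(branch), sum = sum(branch),
           mean = mean(branch))
  }
  vals <- oracle_step_values(config, s, heading, steps, rgvis, params, 0)
  nb <- neighbors(config$board, s)
  vapply(names(nb), function(m) {
    nxt <- nb[[m]]
    vals[[m]] + cont(nxt, m, steps + 1,
                     rgvis || all(nxt == config$receiver_goal), 1)
  }, numeric(1))
}

# fine-grid quadrature for the two-sample JZS Bayes factor (trapezoid on a
# log-spaced g grid), independent of stats::integrate
oracle_jzs_bf10 <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  g <- exp(seq(log(1e-8), log(1e8), length.out = 40000))
  dens <- (0.5)^0.5 / gamma(0.5) * g^(-1.5) * exp(-0.5 / g)
  num <- (1 + N * g * rscale^2)^(-0.5) *
    (1 + t^2 / ((1 + N * g * rscale^2) * nu))^(-(nu + 1) / 2)
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  f <- num / den * dens
  sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
}

# build a tcg_message from a compact direction string like "NNEW"
msg_from_moves <- function(start, moves, board = tcg_board()) {
  dr <- c(N = -1, E = 0, S = 1, W = 0)
  dc <- c(N = 0, E = 1, S = 0, W = -1)
  states <- matrix(start, ncol = 2)
  for (m in strsplit(moves, "")[[1]]) {
    states <- rbind(states, states[nrow(states), ] + c(dr[[m]], dc[[m]]))
  }
  tcg_message(states, board)
}

# map a trial-type label onto its symmetric image
apply_symmetry_config <- function(config, f) {
  tcg_config(f(config$start), f(config$sender_goal),
             f(config$receiver_goal), config$board)
}
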