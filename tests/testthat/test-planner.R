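ref_params <- default_group_params("surprise")

test_that("horizon 1 reduces expected values to single-step values", {
  cfg <- tcg_config(c(1, 1), c(3, 3), c(0, 2))
  for (heading in c(NA, "N", "E")) {
    ev <- expected_values(cfg, c(1, 2), heading, steps_taken = 1,
                          params = ref_params,
                          planner = tcg_planner(horizon = 1))
    ref <- oracle_step_values(cfg, c(1, 2), heading, 1, FALSE, ref_params, 0)
    expect_equal(ev[names(ref)], ref, tolerance = 1e-12)
  }
})

test_that("policy-tree EVs match exhaustive enumeration on small boards", {
  cases <- list(
    list(board = tcg_board(2, 2), start = c(0, 0), sg = c(1, 1),
         rg = c(0, 1)),
    list(board = tcg_board(2, 3), start = c(0, 0), sg = c(1, 2),
         rg = c(1, 0)),
    list(board = tcg_board(2, 3), start = c(1, 1), sg = c(0, 2),
         rg = c(0, 0)))
  variants <- list(ref_params,
                   tcg_params("state", alpha = 1.5, epsilon = 0.5, tau = 2),
                   tcg_params("movement", lambda = 0.2, gamma = 3,
                              epsilon = 0.7, tau = 1))
  for (cs in cases) {
    cfg <- tcg_config(cs$start, cs$sg, cs$rg, cs$board)
    for (params in variants) {
      for (hz in 1:2) {
        for (agg in c("max", "sum", "mean")) {
          ev <- expected_values(cfg, cs$start, NA, 0, params,
                                tcg_planner(horizon = hz, aggregate = agg))
          ref <- oracle_expected_values(cfg, cs$start, NA, 0, FALSE,
                                        params, hz, agg)
          expect_equal(ev[names(ref)], ref, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("EVs and deeper horizons agree with the oracle on the 4x4 board", {
  cfg <- tcg_config(c(2, 1), c(0, 3), c(3, 3))
  for (hz in c(2, 3)) {
    ev <- expected_values(cfg, c(2, 1), "S", 2, ref_params,
                          tcg_planner(horizon = hz))
    ref <- oracle_expected_values(cfg, c(2, 1), "S", 2, FALSE, ref_params,
                                  hz, "max")
    expect_equal(ev[names(ref)], ref, tolerance = 1e-10)
  }
  # phase 2: receiver goal already visited
  ev2 <- expected_values(cfg, c(3, 3), "S", 5, ref_params,
                         tcg_planner(horizon = 3),
                         receiver_goal_visited = TRUE)
  ref2 <- oracle_expected_values(cfg, c(3, 3), "S", 5, TRUE, ref_params,
                                 3, "max")
  expect_equal(ev2[names(ref2)], ref2, tolerance = 1e-10)
})

test_that("EVs are invariant under joint board symmetries", {
  cfg <- tcg_config(c(1, 1), c(3, 2), c(0, 2))
  ev <- expected_values(cfg, cfg$start, NA, 0, ref_params)
  syms <- tcgsurprise:::.board_symmetries(cfg$board)
  dirmap <- function(f) {
    # image of each absolute direction under the symmetry
    vapply(c(N = "N", E = "E", S = "S", W = "W"), function(d) {
      delta <- f(c(1, 1) + switch(d, N = c(-1, 0), E = c(0, 1),
                                  S = c(1, 0), W = c(0, -1))) - f(c(1, 1))
      names(which(vapply(list(N = c(-1, 0), E = c(0, 1), S = c(1, 0),
                              W = c(0, -1)),
                         function(x) all(x == delta), logical(1))))
    }, character(1))
  }
  for (f in syms) {
    cfg2 <- apply_symmetry_config(cfg, f)
    ev2 <- expected_values(cfg2, cfg2$start, NA, 0, ref_params)
    dm <- dirmap(f)
    expect_equal(unname(ev2[dm[names(ev)]]), unname(ev), tolerance = 1e-10)
  }
})

test_that("softmax policy normalizes, saturates and sharpens with tau", {
  expect_equal(unname(softmax_policy(c(a = 2, b = 2, c = 2), 5)),
               rep(1 / 3, 3))
  p <- softmax_policy(c(a = 1, b = 0), 6.93)
  expect_equal(unname(p), c(0.99903, 0.00097), tolerance = 1e-4)
  # tau -> 0 approaches uniform
  expect_equal(unname(softmax_policy(c(a = 3, b = -1), 1e-9)),
               c(0.5, 0.5), tolerance = 1e-6)
  # increasing tau strictly increases the argmax probability
  ev <- c(a = 0.8, b = 0.5, c = 0.1)
  pmax_tau <- vapply(c(0.5, 1, 2, 4, 8, 16), function(tau)
    softmax_policy(ev, tau)[["a"]], numeric(1))
  expect_true(all(diff(pmax_tau) > 0))
  # overflow-safe for large EV scales
  expect_equal(sum(softmax_policy(c(a = 5000, b = 4999), 10)), 1)
  expect_error(softmax_policy(numeric(0), 1), "empty")
})

test_that("generated messages replay deterministically under a seed", {
  cfg <- tcg_config(c(2, 2), c(0, 0), c(3, 0))
  set.seed(99)
  p1 <- generate_message(cfg, ref_params)
  set.seed(99)
  p2 <- generate_message(cfg, ref_params)
  expect_identical(p1$message$states, p2$message$states)
  expect_identical(p1$records, p2$records)
})

test_that("message plans end at the sender goal with one phase switch", {
  set.seed(123)
  for (i in 1:25) {
    cfg <- sample_goal_configuration()
    plan <- generate_message(cfg, ref_params)
    if (plan$aborted) next
    st <- plan$message$states
    expect_equal(unname(st[nrow(st), ]), unname(cfg$sender_goal))
    ph <- plan$records$phase
    expect_true(all(diff(ph) >= 0))  # 1 -> 2 at most once, never back
    expect_equal(plan$points, 10 - nrow(st) + 1)
    # per-step surprise agrees with the recorded prior probability
    expect_equal(plan$records$surprise, -log2(plan$records$prior_p))
  }
})

test_that("rewarded surprise planning visits the receiver goal first", {
  set.seed(2024)
  n <- 300; hits <- logical(n)
  for (i in seq_len(n)) {
    cfg <- sample_goal_configuration()
    plan <- generate_message(cfg, ref_params)
    st <- plan$message$states
    at <- function(s) which(st[, 1] == s[1] & st[, 2] == s[2])
    rg_i <- at(cfg$receiver_goal); sg_i <- at(cfg$sender_goal)
    hits[i] <- !plan$aborted && length(rg_i) > 0 &&
      min(rg_i) < max(sg_i)
  }
  expect_gte(mean(hits), 0.98)
})

test_that("sequence likelihood matches the uniform limit and is finite", {
  cfg <- tcg_config(c(1, 1), c(3, 3), c(0, 2))
  msg <- msg_from_moves(c(1, 1), "ENESSS")
  ll <- sequence_loglik(msg, cfg, ref_params)
  expect_true(is.finite(ll) && ll < 0)
  # tau -> 0: every step uniform over feasible moves
  tiny <- tcg_params("surprise", lambda = 0.1, gamma = 2.14, alpha = 1.84,
                     epsilon = 0.39, tau = 1e-10)
  k <- vapply(seq_len(nrow(msg$states) - 1), function(i)
    length(neighbors(cfg$board, msg$states[i, ])), numeric(1))
  expect_equal(sequence_loglik(msg, cfg, tiny), -sum(log(k)),
               tolerance = 1e-6)
  # a forced single move has probability one (1 x 2 board)
  b12 <- tcg_board(1, 2)
  cfg12 <- tcg_config(c(0, 0), c(0, 1), c(0, 1), board = b12)
  m12 <- tcg_message(rbind(c(0, 0), c(0, 1)), b12)
  expect_equal(sequence_loglik(m12, cfg12, ref_params), 0)
  expect_error(sequence_loglik(msg_from_moves(c(0, 0), "E"), cfg,
                               ref_params), "start")
})

test_that("likelihood is higher at generating than at perturbed parameters", {
  set.seed(7)
  perturbed <- tcg_params("surprise", lambda = 0.1, gamma = 2.14,
                          alpha = 1.84, epsilon = 0.39, tau = 6.93 * 1.5)
  # subject-level gaps (120 trials each) between the generating and the
  # tau-inflated parameterization
  gaps <- replicate(25, {
    sum(replicate(120, {
      cfg <- sample_goal_configuration()
      plan <- generate_message(cfg, ref_params)
      sequence_loglik(plan$message, cfg, ref_params) -
        sequence_loglik(plan$message, cfg, perturbed)
    }))
  })
  expect_gt(mean(gaps), 0)
})
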