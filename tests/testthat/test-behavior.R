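test_that("message profiles count relative directions after the first move", {
  expect_equal(message_profile(msg_from_moves(c(3, 0), "NNN")),
               c(F = 2L, L = 0L, R = 0L, B = 0L))
  # N,N,E,W: forward, then a right turn, then an immediate reversal
  expect_equal(message_profile(msg_from_moves(c(3, 0), "NNEW")),
               c(F = 1L, L = 0L, R = 1L, B = 1L))
  # an enter-exit style walk with 4 forward, 2 left/right, 1 backward
  m <- msg_from_moves(c(0, 0), "SSSEEWNN")
  expect_equal(sum(message_profile(m)), length(m$actions) - 1L)
  expect_equal(message_profile(m), c(F = 4L, L = 1L, R = 1L, B = 1L))
  expect_warning(p <- message_profile(msg_from_moves(c(0, 0), "E")),
                 "single-move")
  expect_equal(unname(p), rep(0L, 4))
})

test_that("message types follow the reversal-count rules", {
  cfg <- tcg_config(c(1, 0), c(1, 3), c(1, 1))
  # straight path through rg: no reversal
  ty <- classify_message(msg_from_moves(c(1, 0), "EEE"), cfg)
  expect_equal(as.character(ty), "pass_by")
  expect_true(attr(ty, "communicative"))
  # enter rg, step back out, continue: exactly one reversal
  cfg2 <- tcg_config(c(1, 0), c(3, 1), c(0, 1))
  ty2 <- classify_message(msg_from_moves(c(1, 0), "ENSSS"), cfg2)
  expect_equal(as.character(ty2), "enter_exit")
  # oscillation between rg and an adjacent cell: wiggly
  ty3 <- classify_message(msg_from_moves(c(1, 0), "ENSNSSS"), cfg2)
  expect_equal(as.character(ty3), "wiggly")
  # two reversals at different cell pairs: residual category
  ty4 <- classify_message(msg_from_moves(c(1, 0), "EWEENSSS"), cfg2)
  expect_equal(as.character(ty4), "other")
  # message that never visits rg is flagged non-communicative
  ty5 <- classify_message(msg_from_moves(c(1, 0), "SSE"), cfg2)
  expect_false(attr(ty5, "communicative"))
  # rule table is overridable
  loose <- tcg_type_rules(wiggly_same_pair = FALSE)
  expect_equal(as.character(classify_message(
    msg_from_moves(c(1, 0), "EWEENSSS"), cfg2, rules = loose)), "wiggly")
})

test_that("classification is invariant under board symmetries", {
  cfg <- tcg_config(c(1, 0), c(3, 1), c(0, 1))
  msgs <- list(msg_from_moves(c(1, 0), "ENSSS"),
               msg_from_moves(c(1, 0), "ENSNSSS"),
               msg_from_moves(c(1, 0), "EEESS"))
  syms <- tcgsurprise:::.board_symmetries(cfg$board)
  for (m in msgs) {
    base <- as.character(classify_message(m, cfg))
    for (f in syms) {
      st2 <- t(apply(m$states, 1, f))
      m2 <- tcg_message(st2, cfg$board)
      expect_equal(as.character(classify_message(m2,
        apply_symmetry_config(cfg, f))), base)
    }
  }
})

test_that("every message gets exactly one label", {
  set.seed(31)
  for (i in 1:40) {
    cfg <- sample_goal_configuration()
    plan <- generate_message(cfg)
    lab <- as.character(classify_message(plan))
    expect_true(lab %in% c("enter_exit", "wiggly", "pass_by", "other"))
    expect_length(lab, 1)
  }
})

test_that("index summary reproduces a hand-labelled fixture exactly", {
  b <- tcg_board()
  mk <- function(subject, idx, start, sg, rg, moves, choice) {
    msg <- msg_from_moves(start, moves)
    data.frame(subject_id = subject, trial_index = idx,
               start = sprintf("%d,%d", start[1], start[2]),
               sender_goal = sprintf("%d,%d", sg[1], sg[2]),
               receiver_goal = sprintf("%d,%d", rg[1], rg[2]),
               trajectory = paste(sprintf("%d,%d", msg$states[, 1],
                                          msg$states[, 2]), collapse = "|"),
               receiver_choice = sprintf("%d,%d", choice[1], choice[2]),
               success = all(choice == rg))
  }
  # subject A: 2 pass-by (1 correct), 1 enter-exit (correct)
  # subject B: 2 wiggly (0 correct), 1 other (correct)
  trials <- rbind(
    mk("A", 1, c(1, 0), c(1, 3), c(1, 1), "EEE", c(1, 1)),      # pass_by, direct
    mk("A", 2, c(1, 0), c(1, 3), c(1, 2), "EEE", c(1, 1)),      # pass_by, direct
    mk("A", 3, c(1, 0), c(3, 1), c(0, 1), "ENSSS", c(0, 1)),   # enter_exit, indirect
    mk("B", 1, c(1, 0), c(3, 1), c(0, 1), "ENSNSSS", c(1, 1)),  # wiggly, indirect
    mk("B", 2, c(1, 0), c(3, 1), c(0, 1), "ENSNSSS", c(2, 1)),  # wiggly, indirect
    mk("B", 3, c(1, 0), c(3, 1), c(0, 1), "EWEENSSS", c(0, 1))) # other, indirect
  idx <- summarize_indices(trials, b)
  ps <- idx$per_subject
  a <- ps[ps$subject_id == "A", ]; bb <- ps[ps$subject_id == "B", ]
  expect_equal(a$freq_pass_by, 2 / 3)
  expect_equal(a$freq_enter_exit, 1 / 3)
  expect_equal(a$freq_enter_exit_indirect, 1)
  expect_equal(a$freq_pass_by_direct, 1)
  expect_equal(a$accuracy, 2 / 3)
  expect_equal(a$accuracy_pass_by, 1 / 2)
  expect_equal(bb$freq_wiggly, 2 / 3)
  expect_equal(bb$freq_other, 1 / 3)
  expect_equal(bb$accuracy, 1 / 3)
  # frequencies sum to one per subject (including other)
  freq_cols <- paste0("freq_", c("enter_exit", "wiggly", "pass_by", "other"))
  expect_equal(unname(rowSums(ps[freq_cols])), c(1, 1))
  # group table carries mean and SE
  g <- idx$group
  expect_equal(g$mean[g$index == "accuracy"], mean(c(2 / 3, 1 / 3)))
  expect_equal(g$se[g$index == "accuracy"],
               sd(c(2 / 3, 1 / 3)) / sqrt(2))
})

test_that("degenerate summaries behave sensibly", {
  trials <- data.frame(
    subject_id = "S", trial_index = 1:2, start = "1,0",
    sender_goal = "1,3", receiver_goal = "1,1",
    trajectory = "1,0|1,1|1,2|1,3", receiver_choice = "1,1",
    success = TRUE)
  idx <- summarize_indices(trials)
  expect_equal(idx$per_subject$freq_pass_by, 1)
  expect_equal(idx$group$se[idx$group$index == "freq_pass_by"], 0)
  expect_equal(idx$per_subject$accuracy, 1)
  expect_error(summarize_indices(trials[0, ]), "empty")
})
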