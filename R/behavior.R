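#' Classification rules for message types
#'
#' The three named message types are formalized through the number of
#' immediate reversals (heading-relative `"B"` moves, i.e. returns to the
#' immediately preceding cell): no reversal is a Pass-By, exactly one an
#' Enter-Exit, and two or more reversals that all shuttle between the same
#' pair of adjacent cells a Wiggly.  Anything else falls into the residual
#' `other` category rather than being force-binned.  The rule table is
#' exposed so alternative codings can be compared on real data.
#'
#' @param enter_exit_reversals Reversal count defining Enter-Exit
#'   (default 1).
#' @param wiggly_min_reversals Minimum reversal count for Wiggly
#'   (default 2).
#' @param wiggly_same_pair Require all Wiggly reversals to oscillate
#'   between one pair of adjacent cells (default `TRUE`).
#' @return A list of class `tcg_type_rules`.
#' @export
tcg_type_rules <- function(enter_exit_reversals = 1L,
                           wiggly_min_reversals = 2L,
                           wiggly_same_pair = TRUE) {
  structure(list(enter_exit_reversals = as.integer(enter_exit_reversals),
                 wiggly_min_reversals = as.integer(wiggly_min_reversals),
                 wiggly_same_pair = isTRUE(wiggly_same_pair)),
            class = "tcg_type_rules")
}

MESSAGE_TYPES <- c("enter_exit", "wiggly", "pass_by", "other")

#' Message profile: relative-direction counts
#'
#' Counts the heading-relative directions of moves 2..n of a message.  The
#' first move is excluded: originating from the start it has no preceding
#' movement to be oriented against.
#'
#' @param message A [tcg_message()] or `tcg_plan`.
#' @return Named integer vector `c(F = , L = , R = , B = )` summing to
#'   `moves - 1`.  A single-move message yields an all-zero profile with a
#'   warning.
#' @export
message_profile <- function(message) {
  if (inherits(message, "tcg_plan")) message <- message$message
  stopifnot(inherits(message, "tcg_message"))
  rel <- message$relative_actions[-1L]
  if (!length(rel)) {
    warning("single-move message has an empty profile")
    return(c(F = 0L, L = 0L, R = 0L, B = 0L))
  }
  vapply(c(F = "F", L = "L", R = "R", B = "B"),
         function(d) sum(rel == d), integer(1))
}

#' Classify a message as Enter-Exit, Wiggly, Pass-By or other
#'
#' See [tcg_type_rules()] for the reversal-count formalization.  The label
#' is a pure function of the relative-action sequence; whether the message
#' actually visits the Receiver's goal is reported separately through the
#' `communicative` attribute (non-visiting messages remain classifiable
#' but cannot signal the goal).
#'
#' @param message A [tcg_message()] or `tcg_plan`.
#' @param config A [tcg_config()] (used only for the communicative flag).
#' @param rules A [tcg_type_rules()].
#' @return Character label (one of `"enter_exit"`, `"wiggly"`,
#'   `"pass_by"`, `"other"`) with logical attribute `communicative`.
#' @export
classify_message <- function(message, config = NULL,
                             rules = tcg_type_rules()) {
  if (inherits(message, "tcg_plan")) {
    if (is.null(config)) config <- message$config
    message <- message$message
  }
  stopifnot(inherits(message, "tcg_message"))
  rel <- message$relative_actions
  rev_idx <- which(rel == "B")
  n_rev <- length(rev_idx)
  label <- if (n_rev == 0L) "pass_by"
  else if (n_rev == rules$enter_exit_reversals) "enter_exit"
  else if (n_rev >= rules$wiggly_min_reversals) {
    if (rules$wiggly_same_pair) {
      # each reversal shuttles between states[i] and states[i+1]; Wiggly
      # requires one common pair of adjacent cells
      pairs <- lapply(rev_idx, function(i)
        sort(c(.state_index(message$board, message$states[i, ]),
               .state_index(message$board, message$states[i + 1L, ]))))
      if (length(unique(pairs)) == 1L) "wiggly" else "other"
    } else "wiggly"
  } else "other"
  if (!is.null(config)) {
    visited <- any(message$states[, 1L] == config$receiver_goal[1L] &
                   message$states[, 2L] == config$receiver_goal[2L])
    attr(label, "communicative") <- visited
  }
  label
}

# per-trial derived quantities for a trial table (internal)
.trial_features <- function(trials, board, rules = tcg_type_rules()) {
  msgs <- lapply(trials$trajectory, .parse_trajectory)
  feats <- lapply(seq_len(nrow(trials)), function(i) {
    cfg <- tcg_config(.parse_state(trials$start[i]),
                      .parse_state(trials$sender_goal[i]),
                      .parse_state(trials$receiver_goal[i]), board)
    msg <- tcg_message(msgs[[i]], board)
    type <- classify_message(msg, cfg, rules)
    prof <- suppressWarnings(message_profile(msg))  # 1-move messages are fine here
    choice <- .parse_state(trials$receiver_choice[i])
    list(type = as.character(type),
         trial_type = classify_trial(cfg),
         communicative = attr(type, "communicative"),
         prof = prof,
         correct = all(choice == cfg$receiver_goal))
  })
  data.frame(subject_id = trials$subject_id,
             type = vapply(feats, `[[`, character(1), "type"),
             trial_type = vapply(feats, `[[`, character(1), "trial_type"),
             communicative = vapply(feats, `[[`, logical(1), "communicative"),
             correct = vapply(feats, `[[`, logical(1), "correct"),
             t(vapply(feats, `[[`, numeric(4), "prof")))
}

#' Model-free behavioral indices of a trial set
#'
#' Computes, per subject, the frequencies of the four message types
#' (overall and stratified by direct/indirect trial type), the mean message
#' profile (relative-direction counts), and communication accuracy (the
#' fraction of trials on which the Receiver chose the true goal), then
#' summarizes across subjects as mean and standard error.
#'
#' @param trials Trial table in the package's tabular schema (see
#'   [read_tcg_trials()]), or the `$trials` element of a simulated cohort.
#' @param board A [tcg_board()].
#' @param rules A [tcg_type_rules()].
#' @return An object of class `tcg_indices` with elements `per_trial`,
#'   `per_subject` (one row per subject) and `group` (mean and SE of each
#'   index).
#' @export
summarize_indices <- function(trials, board = tcg_board(),
                              rules = tcg_type_rules()) {
  trials <- .as_trial_table(trials)
  if ("aborted" %in% names(trials) && any(trials$aborted)) {
    message(sum(trials$aborted), " aborted trial(s) excluded from indices")
    trials <- trials[!trials$aborted, , drop = FALSE]
  }
  if (!nrow(trials)) stop("empty trial set")
  feats <- .trial_features(trials, board, rules)
  subjects <- unique(feats$subject_id)
  rows <- lapply(subjects, function(sid) {
    f <- feats[feats$subject_id == sid, ]
    freq <- vapply(MESSAGE_TYPES, function(ty) mean(f$type == ty), numeric(1))
    names(freq) <- paste0("freq_", MESSAGE_TYPES)
    strat <- unlist(lapply(c("direct", "indirect"), function(tt) {
      g <- f[f$trial_type == tt, ]
      v <- if (nrow(g)) vapply(MESSAGE_TYPES, function(ty)
        mean(g$type == ty), numeric(1)) else rep(NA_real_, 4L)
      names(v) <- paste0("freq_", MESSAGE_TYPES, "_", tt)
      v
    }))
    prof <- colMeans(f[, c("F", "L", "R", "B")])
    names(prof) <- paste0("prof_", names(prof))
    acc_type <- vapply(MESSAGE_TYPES, function(ty) {
      g <- f[f$type == ty, ]
      if (nrow(g)) mean(g$correct) else NA_real_
    }, numeric(1))
    names(acc_type) <- paste0("accuracy_", MESSAGE_TYPES)
    c(n_trials = nrow(f), freq, strat, prof,
      accuracy = mean(f$correct), acc_type)
  })
  per_subject <- data.frame(subject_id = subjects, do.call(rbind, rows))
  num <- per_subject[, -1L, drop = FALSE]
  group <- data.frame(
    index = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    se = vapply(num, function(x) {
      x <- x[!is.na(x)]
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }, numeric(1)),
    row.names = NULL)
  structure(list(per_trial = feats, per_subject = per_subject,
                 group = group),
            class = "tcg_indices")
}

#' @export
print.tcg_indices <- function(x, digits = 3, ...) {
  n <- nrow(x$per_subject)
  cat(sprintf("TCG behavioral indices: %d subjects, %d trials\n",
              n, nrow(x$per_trial)))
  show <- x$group[x$group$index %in%
                    c(paste0("freq_", MESSAGE_TYPES), "accuracy"), ]
  show$mean <- round(show$mean, digits); show$se <- round(show$se, digits)
  print(show, row.names = FALSE)
  invisible(x)
}
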