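#' Sample a goal configuration
#'
#' Emulates the task's trial construction on the 4 x 4 board: the start is
#' drawn uniformly from the four central cells, and the two goals uniformly
#' from the remaining cells (distinct from the start and from each other),
#' rejection-sampled until the requested trial type is met.  Uses R's RNG
#' stream.
#'
#' @param board A [tcg_board()] (the default protocol assumes 4 x 4).
#' @param trial_type `"direct"`, `"indirect"`, or `NULL` for no constraint.
#' @param max_tries Rejection bound before erroring.
#' @return A [tcg_config()] with `classify_trial()` equal to the request.
#' @export
sample_goal_configuration <- function(board = tcg_board(),
                                      trial_type = NULL,
                                      max_tries = 1000L) {
  if (!is.null(trial_type))
    trial_type <- match.arg(trial_type, c("direct", "indirect"))
  rmid <- unique(c((board$n_rows - 1L) %/% 2L, board$n_rows %/% 2L))
  cmid <- unique(c((board$n_cols - 1L) %/% 2L, board$n_cols %/% 2L))
  centers <- as.matrix(expand.grid(row = rmid, col = cmid))
  all_states <- as.matrix(expand.grid(row = 0:(board$n_rows - 1L),
                                      col = 0:(board$n_cols - 1L)))
  for (i in seq_len(max_tries)) {
    start <- centers[sample.int(nrow(centers), 1L), ]
    others <- all_states[!(all_states[, 1L] == start[1L] &
                           all_states[, 2L] == start[2L]), , drop = FALSE]
    pick <- sample.int(nrow(others), 2L)
    cfg <- tcg_config(start, others[pick[1L], ], others[pick[2L], ], board)
    if (is.null(trial_type) || classify_trial(cfg) == trial_type)
      return(cfg)
  }
  stop("could not sample a '", trial_type, "' configuration in ",
       max_tries, " tries")
}

#' Heuristic Receiver: decode the goal from surprise
#'
#' The Receiver knows the start and the Sender's goal but not his own.
#' This fixture Receiver scores every state the message visits by the
#' maximal Shannon surprise of the arrival steps into it, evaluated under
#' the Receiver's own combined movement-state priors (state prior centred
#' on the Sender's goal, the only goal he knows), and chooses through a
#' softmax over these scores.  `temperature = 0` is the deterministic
#' argmax with earliest-arrival tie-breaking.  The start and the Sender's
#' goal are excluded from the candidate set.  This is a plausible decoding
#' heuristic used to close the synthetic loop, not a fitted model of real
#' Receivers.
#'
#' @param message A [tcg_message()] or `tcg_plan`.
#' @param config A [tcg_config()].
#' @param params Receiver priors (a `"surprise"`-variant [tcg_params()]).
#' @param temperature Softmax temperature on the surprise scores (bits).
#' @return The chosen state as 0-based `(row, col)`.
#' @export
simulate_receiver <- function(message, config,
                              params = default_group_params(),
                              temperature = 0.5) {
  if (inherits(message, "tcg_plan")) message <- message$message
  stopifnot(inherits(message, "tcg_message"), inherits(config, "tcg_config"))
  b <- config$board
  a <- .cpp_args(params)
  traj <- apply(message$states, 1L, function(s) .state_index(b, s))
  info <- cpp_step_info(as.integer(traj), b$n_rows, b$n_cols,
                        .state_index(b, config$sender_goal),
                        .state_index(b, config$receiver_goal),
                        0L, a$lambda, a$gamma, a$alpha, a$eps, a$tau,
                        3L, 0L)
  arrived <- traj[-1L]
  keep <- arrived != .state_index(b, config$sender_goal) &
    arrived != .state_index(b, config$start)
  if (!any(keep)) {
    cand <- setdiff(seq_len(b$n_rows * b$n_cols) - 1L,
                    c(.state_index(b, config$start),
                      .state_index(b, config$sender_goal)))
    return(.index_state(b, sample(cand, 1L)))
  }
  score <- tapply(info$surprise[keep], arrived[keep], max)
  first_seen <- tapply(which(keep), arrived[keep], min)
  states <- as.integer(names(score))
  if (temperature <= 0) {
    best <- which(score == max(score))
    pick <- best[which.min(first_seen[best])]
  } else {
    p <- exp((score - max(score)) / temperature)
    pick <- sample.int(length(states), 1L, prob = p / sum(p))
  }
  .index_state(b, states[pick])
}

#' Specification of a synthetic TCG cohort
#'
#' The defaults emulate the original study conditions: 29 Sender-Receiver
#' pairs, 120 trials each with a 66% direct / 34% indirect mix, Sender
#' messages generated from the surprise variant at the reference group
#' parameters with between-subject variability on the unconstrained
#' parameter scale, a surprise-decoding Receiver, and physiological epochs
#' linearly coupled to step surprise.
#'
#' @param n_subjects Number of simulated Sender-Receiver pairs.
#' @param trials_per_subject Trials per pair.
#' @param direct_fraction Fraction of direct-configuration trials.
#' @param variant Generating planner variant.
#' @param group_params Group-mean parameters (a [tcg_params()]).
#' @param group_sd Between-subject SD on the unconstrained scale (scalar or
#'   per-parameter).
#' @param receiver_temperature Softmax temperature of the fixture Receiver.
#' @param pdr_slope,pdr_slope_sd,pdr_intercept_sd,pdr_noise_sd Pupil
#'   coupling: fixed slope (units per bit), random-effect SDs, residual SD.
#' @param planner A [tcg_planner()].
#' @return A list of class `tcg_synthetic_spec`.
#' @export
tcg_synthetic_spec <- function(n_subjects = 29L, trials_per_subject = 120L,
                               direct_fraction = 0.66,
                               variant = "surprise",
                               group_params = default_group_params(variant),
                               group_sd = 0.5,
                               receiver_temperature = 0.5,
                               pdr_slope = 0.02, pdr_slope_sd = 0.01,
                               pdr_intercept_sd = 0.1, pdr_noise_sd = 0.05,
                               planner = tcg_planner()) {
  stopifnot(direct_fraction >= 0, direct_fraction <= 1, group_sd >= 0,
            pdr_slope_sd >= 0, pdr_intercept_sd >= 0, pdr_noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 direct_fraction = direct_fraction, variant = variant,
                 group_params = group_params, group_sd = group_sd,
                 receiver_temperature = receiver_temperature,
                 pdr_slope = pdr_slope, pdr_slope_sd = pdr_slope_sd,
                 pdr_intercept_sd = pdr_intercept_sd,
                 pdr_noise_sd = pdr_noise_sd, planner = planner),
            class = "tcg_synthetic_spec")
}

# draw one subject's parameters around the group mean on the
# unconstrained scale
.draw_subject_params <- function(variant, group_params, group_sd) {
  tr <- param_transform(variant)
  mu <- tr$to_unconstrained(group_params$values)
  theta <- mu + stats::rnorm(length(mu), sd = rep_len(group_sd, length(mu)))
  # keep draws inside the numerically exact range of the transforms
  theta <- pmin(pmax(theta, -15), 15)
  names(theta) <- tr$parnames
  .params_from_theta(variant, theta)
}

#' Simulate a synthetic cohort of Senders and Receivers
#'
#' Per subject, draws individual parameters from the group distribution,
#' generates one message per goal configuration with [generate_message()],
#' and lets the fixture Receiver choose a goal.  Fully determined by the
#' spec and R's RNG state (`set.seed()` before the call for exact
#' reproducibility).
#'
#' @param spec A [tcg_synthetic_spec()].
#' @param configs Optional list of per-subject configuration lists (each a
#'   list of [tcg_config()]); when supplied (e.g. for posterior predictive
#'   checks matching an observed cohort), the spec's trial counts and
#'   direct fraction are ignored.
#' @param board A [tcg_board()].
#' @return A list of class `tcg_cohort` with the trial table (`trials`,
#'   including per-trial `aborted` flags), a per-step table (`steps`:
#'   subject, trial, step, phase, surprise), and the generating
#'   subject-level parameters (`subject_params`).
#' @export
simulate_cohort <- function(spec = tcg_synthetic_spec(), configs = NULL,
                            board = tcg_board()) {
  stopifnot(inherits(spec, "tcg_synthetic_spec"))
  n_sub <- if (is.null(configs)) spec$n_subjects else length(configs)
  trial_rows <- list(); step_rows <- list(); subject_params <- list()
  for (s in seq_len(n_sub)) {
    sid <- sprintf("S%02d", s)
    pars <- .draw_subject_params(spec$variant, spec$group_params,
                                 spec$group_sd)
    subject_params[[sid]] <- pars$values
    cfgs <- if (!is.null(configs)) configs[[s]] else {
      n_direct <- round(spec$trials_per_subject * spec$direct_fraction)
      types <- sample(c(rep("direct", n_direct),
                        rep("indirect", spec$trials_per_subject - n_direct)))
      lapply(types, function(tt)
        sample_goal_configuration(board, tt))
    }
    for (i in seq_along(cfgs)) {
      cfg <- cfgs[[i]]
      plan <- generate_message(cfg, pars, spec$planner)
      choice <- simulate_receiver(plan$message, cfg, spec$group_params,
                                  spec$receiver_temperature)
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        subject_id = sid, trial_index = i,
        start = .format_state(cfg$start),
        sender_goal = .format_state(cfg$sender_goal),
        receiver_goal = .format_state(cfg$receiver_goal),
        trajectory = .format_trajectory(plan$message$states),
        receiver_choice = .format_state(choice),
        success = all(choice == cfg$receiver_goal),
        aborted = plan$aborted)
      step_rows[[length(step_rows) + 1L]] <- data.frame(
        subject_id = sid, trial_index = i,
        step = plan$records$step, phase = plan$records$phase,
        surprise = plan$records$surprise)
    }
  }
  empty_trials <- data.frame(subject_id = character(), trial_index = integer(),
                             start = character(), sender_goal = character(),
                             receiver_goal = character(),
                             trajectory = character(),
                             receiver_choice = character(),
                             success = logical(), aborted = logical())
  structure(list(trials = if (length(trial_rows)) do.call(rbind, trial_rows)
                 else empty_trials,
                 steps = do.call(rbind, step_rows),
                 subject_params = subject_params, spec = spec),
            class = "tcg_cohort")
}

#' @export
print.tcg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TCG cohort: %d subjects, %d trials (%s variant), %d aborted\n",
              length(x$subject_params), nrow(x$trials), x$spec$variant,
              sum(x$trials$aborted)))
  invisible(x)
}

#' Simulate pupil responses coupled to step surprise
#'
#' One mean pupil-dilation value per message step:
#' `PDR = (intercept + u0) + (slope + u1) * surprise + noise`, with
#' subject-level random effects `u0`, `u1` supplied by the caller and
#' Gaussian residual noise.
#'
#' @param step_surprise Non-negative surprise values (bits), one per step.
#' @param slope Fixed-effect slope (PDR units per bit).
#' @param subject_effects Length-2 numeric `c(u0, u1)`: the subject's
#'   intercept and slope deviations.
#' @param noise_sd Residual SD.
#' @param intercept Fixed-effect intercept.
#' @return Numeric vector of per-step PDR values.
#' @export
simulate_pdr <- function(step_surprise, slope = 0.02,
                         subject_effects = c(0, 0), noise_sd = 0.05,
                         intercept = 0) {
  stopifnot(all(step_surprise >= 0), length(subject_effects) == 2L)
  (intercept + subject_effects[1L]) +
    (slope + subject_effects[2L]) * step_surprise +
    stats::rnorm(length(step_surprise), sd = noise_sd)
}

#' Channel neighbor graph for synthetic epochs
#'
#' @param n_channels Number of channels.
#' @param type `"chain"` (channel i adjacent to i-1 and i+1) or `"grid"`
#'   (channels arranged on a near-square grid, 4-connected).
#' @return Symmetric logical adjacency matrix.
#' @export
channel_neighbors <- function(n_channels, type = c("chain", "grid")) {
  type <- match.arg(type)
  adj <- matrix(FALSE, n_channels, n_channels)
  if (type == "chain") {
    idx <- seq_len(n_channels - 1L)
    adj[cbind(idx, idx + 1L)] <- TRUE
  } else {
    ncol_g <- ceiling(sqrt(n_channels))
    for (i in seq_len(n_channels)) {
      r <- (i - 1L) %/% ncol_g; c <- (i - 1L) %% ncol_g
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        j <- (r + d[1L]) * ncol_g + (c + d[2L]) + 1L
        if (r + d[1L] >= 0L && c + d[2L] >= 0L && c + d[2L] < ncol_g &&
            j >= 1L && j <= n_channels) adj[i, j] <- TRUE
      }
    }
  }
  adj | t(adj)
}

#' Simulate step-locked EEG-like epochs coupled to surprise
#'
#' One epoch per message step on an abstract channels x time grid spanning
#' 0-1200 ms.  A deterministic signal `amplitude * surprise` is injected on
#' the patterned channels inside the time window; everywhere the epochs
#' carry Gaussian noise smoothed once across neighboring channels (spatial
#' correlation, as in real sensor arrays).
#'
#' @param step_surprise Surprise values (bits), one per epoch.
#' @param channel_pattern Integer indices of signal-carrying channels.
#' @param time_window `c(lo, hi)` ms of the injected effect.
#' @param amplitude Signal gain (signal units per bit).
#' @param noise_sd Noise SD before smoothing.
#' @param n_channels,n_timepoints Grid size; time points span 0-1200 ms.
#' @param neighbors Adjacency matrix used for noise smoothing (defaults to
#'   a chain).
#' @return List with `data` (epochs x channels x timepoints array) and
#'   `times` (ms).
#' @export
simulate_eeg <- function(step_surprise, channel_pattern = 1:4,
                         time_window = c(400, 800), amplitude = 1,
                         noise_sd = 1, n_channels = 16L,
                         n_timepoints = 61L,
                         neighbors = channel_neighbors(n_channels)) {
  times <- seq(0, 1200, length.out = n_timepoints)
  if (time_window[1L] < 0 || time_window[2L] > 1200)
    stop("time window must lie within the 0-1200 ms epoch")
  n_ep <- length(step_surprise)
  data <- array(0, c(n_ep, n_channels, n_timepoints))
  if (noise_sd > 0) {
    noise <- array(stats::rnorm(n_ep * n_channels * n_timepoints,
                                sd = noise_sd),
                   c(n_ep, n_channels, n_timepoints))
    # one smoothing pass across neighboring channels, rescaled so each
    # channel keeps marginal SD noise_sd (a single channels x channels
    # matrix product over the flattened epochs x time axis)
    W <- (diag(n_channels) + (neighbors * 1)) /
      sqrt(rowSums(neighbors) + 1)
    flat <- matrix(aperm(noise, c(1, 3, 2)), ncol = n_channels)
    sm <- flat %*% t(W)
    data <- aperm(array(sm, c(n_ep, n_timepoints, n_channels)),
                  c(1, 3, 2))
  }
  win <- times >= time_window[1L] & times <= time_window[2L]
  for (ch in channel_pattern)
    data[, ch, win] <- data[, ch, win] + amplitude * step_surprise
  list(data = data, times = times)
}
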