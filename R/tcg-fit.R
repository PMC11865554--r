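#' Fit the surprise model (and degenerate variants) to TCG trials
#'
#' The central model-fitting entry point: hierarchical empirical-Bayes
#' estimation of the planner parameters per subject and variant, Laplace
#' model evidences, and random-effects comparison of the variants (model
#' frequencies and protected exceedance probabilities).  Returns a classed
#' object with the usual modelling methods (`print`, `summary`, `coef`,
#' `logLik`, `simulate`, `predict`, `plot`).
#'
#' @param trials Trial table (see [read_tcg_trials()]) or a `tcg_cohort`.
#' @param variants Variant labels to fit and compare.
#' @param planner A [tcg_planner()].
#' @param board A [tcg_board()].
#' @param ... Passed to [hierarchical_fit()] (`max_iter`, `tol`,
#'   `n_starts`, ...).
#' @return An object of class `tcg_fit`.
#' @export
tcg_fit <- function(trials, variants = VARIANTS, planner = tcg_planner(),
                    board = tcg_board(), ...) {
  trials <- .as_trial_table(trials)
  if ("aborted" %in% names(trials)) trials <- trials[!trials$aborted, ]
  hfit <- hierarchical_fit(trials, variants, planner, board, ...)
  structure(list(hfit = hfit, trials = trials, board = board,
                 planner = planner, call = match.call()),
            class = "tcg_fit")
}

#' Best-supported variant of a fit
#' @param object A `tcg_fit`.
#' @return Variant label with the highest model frequency.
#' @export
best_variant <- function(object) {
  stopifnot(inherits(object, "tcg_fit"))
  names(which.max(object$hfit$comparison$model_frequency))
}

#' @export
print.tcg_fit <- function(x, ...) {
  cat("Surprise-model fit to TCG trials\n")
  print(x$hfit)
  invisible(x)
}

#' @export
summary.tcg_fit <- function(object, ...) {
  structure(list(table = comparison_table(object$hfit),
                 best = best_variant(object),
                 n_subjects = nrow(object$hfit$log_evidence),
                 n_trials = nrow(object$trials),
                 bor = object$hfit$comparison$bor,
                 converged = object$hfit$converged),
            class = "summary.tcg_fit")
}

#' @export
print.summary.tcg_fit <- function(x, ...) {
  cat(sprintf("TCG model comparison: %d subjects, %d trials\n",
              x$n_subjects, x$n_trials))
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Best-supported variant: %s (Bayes omnibus risk %.4f)\n",
              x$best, x$bor))
  if (!x$converged) cat("note: hierarchical fit did not fully converge\n")
  invisible(x)
}

#' @export
coef.tcg_fit <- function(object, variant = best_variant(object), ...) {
  object$hfit$group_params[[variant]]
}

#' @export
logLik.tcg_fit <- function(object, variant = best_variant(object), ...) {
  nll <- vapply(object$hfit$subject_fits[[variant]], `[[`, numeric(1),
                "nll")
  val <- -sum(nll)
  attr(val, "df") <- length(.variant_parnames(variant)) *
    length(nll)
  attr(val, "nobs") <- nrow(object$trials)
  class(val) <- "logLik"
  val
}

# configurations of the fitted trials, grouped by subject (used so
# simulated cohorts match the observed cohort's configuration lists)
.fitted_configs <- function(object) {
  trials <- object$trials
  lapply(split(trials, trials$subject_id), function(tt)
    lapply(seq_len(nrow(tt)), function(i)
      tcg_config(.parse_state(tt$start[i]),
                 .parse_state(tt$sender_goal[i]),
                 .parse_state(tt$receiver_goal[i]), object$board)))
}

#' Simulate posterior predictive cohorts from a fit
#'
#' Draws subject parameters from the fitted group distribution of the
#' chosen variant and regenerates one message per observed configuration,
#' so the simulated indices are directly comparable to the observed ones.
#'
#' @param object A `tcg_fit`.
#' @param nsim Number of cohorts.
#' @param seed Optional seed.
#' @param variant Variant to simulate from.
#' @param ... Unused.
#' @return A `tcg_cohort` (or list of them when `nsim > 1`).
#' @export
simulate.tcg_fit <- function(object, nsim = 1, seed = NULL,
                             variant = best_variant(object), ...) {
  if (!is.null(seed)) set.seed(seed)
  gp <- object$hfit$group_params[[variant]]
  gv <- object$hfit$group[[variant]]$v
  params <- do.call(tcg_params,
                    c(list(variant = variant, strict = FALSE), as.list(gp)))
  spec <- tcg_synthetic_spec(variant = variant, group_params = params,
                             group_sd = sqrt(gv),  # per-parameter spread
                             planner = object$planner)
  configs <- .fitted_configs(object)
  out <- lapply(seq_len(nsim), function(i)
    simulate_cohort(spec, configs = configs, board = object$board))
  if (nsim == 1L) out[[1L]] else out
}

#' Predict messages or policies for new goal configurations
#'
#' @param object A `tcg_fit`.
#' @param newdata List of [tcg_config()] objects.
#' @param type `"message"` samples a message plan per configuration at the
#'   group parameters; `"policy"` returns the first-step action
#'   probabilities.
#' @param variant Variant to use.
#' @param ... Unused.
#' @return List of `tcg_plan`s or of named policy vectors.
#' @export
predict.tcg_fit <- function(object, newdata,
                            type = c("message", "policy"),
                            variant = best_variant(object), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "tcg_config")) newdata <- list(newdata)
  gp <- object$hfit$group_params[[variant]]
  params <- do.call(tcg_params,
                    c(list(variant = variant, strict = FALSE), as.list(gp)))
  lapply(newdata, function(cfg) {
    if (type == "message") generate_message(cfg, params, object$planner)
    else softmax_policy(expected_values(cfg, cfg$start, NA, 0L, params,
                                        object$planner),
                        gp[["tau"]])
  })
}

#' Plot observed versus simulated message-type frequencies
#'
#' @param x A `tcg_fit`.
#' @param simulated Optional pre-computed `tcg_cohort`; simulated from the
#'   fit when omitted.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.tcg_fit <- function(x, simulated = NULL, ...) {
  obs <- summarize_indices(x$trials, x$board)
  if (is.null(simulated)) simulated <- simulate.tcg_fit(x)
  sim <- summarize_indices(simulated$trials, x$board)
  cols <- paste0("freq_", MESSAGE_TYPES)
  m <- rbind(observed = colMeans(obs$per_subject[cols]),
             simulated = colMeans(sim$per_subject[cols]))
  colnames(m) <- c("Enter-Exit", "Wiggly", "Pass-By", "Other")
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "frequency",
                    main = "Message types: observed vs simulated", ...)
  invisible(m)
}
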