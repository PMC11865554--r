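# Unconstrained parameterization used by the optimizer:
#   lambda  scaled logit on [0.001, 0.3]
#   gamma   scaled logit on [2, 10]
#   epsilon logit on (0, 1)
#   tau     log
#   alpha   log(alpha - 1)   (keeps the state prior strictly decreasing)

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

.to_unconstrained_one <- function(name, value) {
  switch(name,
         lambda  = .logit((value - 0.001) / (0.3 - 0.001)),
         gamma   = .logit((value - 2) / 8),
         epsilon = .logit(value),
         tau     = log(value),
         alpha   = log(value - 1))
}

.to_natural_one <- function(name, theta) {
  switch(name,
         lambda  = 0.001 + (0.3 - 0.001) * .inv_logit(theta),
         gamma   = 2 + 8 * .inv_logit(theta),
         epsilon = .inv_logit(theta),
         tau     = exp(theta),
         alpha   = 1 + exp(theta))
}

#' Map parameters between the constrained box and the real line
#'
#' Monotone bijections per parameter (scaled logits for the box-constrained
#' `lambda`, `gamma`, `epsilon`; `log` for `tau`; `log(alpha - 1)` for
#' `alpha`) let the optimizer search an unconstrained space while the
#' likelihood only ever sees admissible values.
#'
#' @param variant Model variant label.
#' @return List with functions `to_unconstrained(values)` and
#'   `to_natural(theta)`, both operating on named vectors in the variant's
#'   canonical parameter order.
#' @export
param_transform <- function(variant = "surprise") {
  variant <- match.arg(variant, VARIANTS)
  pn <- .variant_parnames(variant)
  list(
    parnames = pn,
    to_unconstrained = function(values) {
      vapply(pn, function(nm) .to_unconstrained_one(nm, values[[nm]]),
             numeric(1))
    },
    to_natural = function(theta) {
      vapply(pn, function(nm) .to_natural_one(nm, theta[[nm]]), numeric(1))
    })
}

.params_from_theta <- function(variant, theta) {
  tr <- param_transform(variant)
  vals <- tr$to_natural(theta)
  do.call(tcg_params, c(list(variant = variant), as.list(vals)))
}

#' Negative log-likelihood of a subject's trials
#'
#' @param trials Trial table rows of a single subject (see
#'   [read_tcg_trials()]).
#' @param params A [tcg_params()].
#' @param planner A [tcg_planner()].
#' @param board A [tcg_board()].
#' @return Summed negative log-likelihood over the subject's trials.
#' @export
negative_loglik <- function(trials, params, planner = tcg_planner(),
                            board = tcg_board()) {
  trials <- .as_trial_table(trials)
  if (length(unique(trials$subject_id)) > 1L)
    stop("negative_loglik expects trials of a single subject")
  sd <- .subject_data(trials, board)[[1L]]
  .nll_subdata(sd, params, planner, board)
}

.nll_subdata <- function(sd, params, planner, board) {
  a <- .cpp_args(params)
  cpp_nll_subject(sd$trajs, sd$goals, board$n_rows, board$n_cols,
                  a$variant, a$lambda, a$gamma, a$alpha, a$eps, a$tau,
                  planner$horizon, .agg_code(planner$aggregate))
}

# log joint (negated) on the unconstrained scale, incl. Gaussian group prior
.make_objective <- function(sd, variant, mu, v, planner, board) {
  pn <- .variant_parnames(variant)
  function(theta) {
    names(theta) <- pn
    params <- tryCatch(.params_from_theta(variant, theta),
                       error = function(e) NULL)
    if (is.null(params)) return(1e10)
    nll <- .nll_subdata(sd, params, planner, board)
    if (!is.finite(nll)) return(1e10)
    nll + sum(0.5 * (theta - mu)^2 / v + 0.5 * log(2 * pi * v))
  }
}

#' MAP fit of one subject with Laplace-approximated evidence
#'
#' Maximizes log-likelihood plus Gaussian group-prior density on the
#' unconstrained scale via multi-start BFGS; the log model evidence is the
#' Laplace approximation: penalized optimum plus `d/2 log(2 pi)` minus half
#' the log determinant of the local curvature (central-difference Hessian,
#' step 1e-4).
#'
#' @param trials Trial table rows of a single subject.
#' @param variant Model variant label.
#' @param group_prior List with unconstrained-scale mean `mu` and variance
#'   `v` (scalars or per-parameter vectors; default mean 0, variance 6.25).
#' @param planner A [tcg_planner()].
#' @param board A [tcg_board()].
#' @param n_starts Number of optimizer restarts (first from the prior mean,
#'   the rest drawn around it from the current RNG stream).
#' @param start Optional extra start (unconstrained scale, e.g. a previous
#'   fit for warm-starting).
#' @param maxit BFGS iteration cap per start.
#' @return An object of class `tcg_subject_fit` with MAP parameters on both
#'   scales, the negative log-likelihood at the MAP, the Laplace log
#'   evidence, and the curvature matrix.
#' @export
fit_subject_map <- function(trials, variant = "surprise",
                            group_prior = NULL, planner = tcg_planner(),
                            board = tcg_board(), n_starts = 10L,
                            start = NULL, maxit = 100L) {
  trials <- .as_trial_table(trials)
  if (nrow(trials) < 10L)
    warning("fewer than 10 trials: estimates will be prior-dominated")
  sd <- .subject_data(trials, board)[[1L]]
  .fit_subject_subdata(sd, variant, group_prior, planner, board,
                       n_starts, start, maxit)
}

.fit_subject_subdata <- function(sd, variant, group_prior, planner, board,
                                 n_starts = 10L, start = NULL,
                                 maxit = 100L) {
  pn <- .variant_parnames(variant)
  d <- length(pn)
  mu <- if (is.null(group_prior)) rep(0, d) else rep_len(group_prior$mu, d)
  v <- if (is.null(group_prior)) rep(6.25, d) else rep_len(group_prior$v, d)
  obj <- .make_objective(sd, variant, mu, v, planner, board)
  starts <- list(mu)
  if (!is.null(start)) starts <- c(starts, list(rep_len(start, d)))
  while (length(starts) < n_starts)
    starts <- c(starts, list(mu + stats::rnorm(d, sd = sqrt(v) / 2)))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, obj, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(variant = variant, flagged = TRUE),
                     class = "tcg_subject_fit"))
  theta <- best$par
  names(theta) <- pn
  H <- tryCatch(
    stats::optimHess(theta, obj, control = list(ndeps = rep(1e-4, d))),
    error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) H <- diag(1 / v, d)
  # regularize a non-PD curvature (flat directions) toward the prior
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) H <- H + diag(1e-8 - min(ev, 0) + 1e-8, d)
  logdet <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  log_evidence <- -best$value + 0.5 * d * log(2 * pi) - 0.5 * logdet
  params <- .params_from_theta(variant, theta)
  nll <- .nll_subdata(sd, params, planner, board)
  # the Gaussian prior bounds the posterior variance by v; a nearly flat
  # likelihood direction can make the numerical curvature miss that
  sigma2 <- pmin(diag(solve(H)), v)
  structure(list(variant = variant, theta = theta,
                 params = params$values, nll = nll,
                 log_evidence = log_evidence, hessian = H,
                 posterior_var = sigma2, flagged = FALSE),
            class = "tcg_subject_fit")
}

#' @export
print.tcg_subject_fit <- function(x, ...) {
  if (isTRUE(x$flagged)) {
    cat("TCG subject fit (", x$variant, "): all optimizer starts failed\n")
    return(invisible(x))
  }
  cat(sprintf("TCG subject fit (%s): NLL %.2f, Laplace log evidence %.2f\n",
              x$variant, x$nll, x$log_evidence))
  print(round(x$params, 4))
  invisible(x)
}

#' Hierarchical empirical-Bayes fit across subjects and variants
#'
#' Iterates (a) subject-level MAP fits given the current Gaussian group
#' prior of each variant, (b) group mean/variance updates from the Laplace
#' posteriors, weighted by (c) per-subject responsibilities over variants
#' derived from the Laplace evidences and the current variant frequencies.
#' Convergence is declared when no group mean moves more than `tol`
#' (default 1e-3) on the unconstrained scale, capped at `max_iter`
#' iterations (a non-converged fit returns the best iterate with a flag).
#'
#' @param trials Trial table of all subjects.
#' @param variants Character vector of variant labels to fit.
#' @param planner A [tcg_planner()].
#' @param board A [tcg_board()].
#' @param max_iter,tol Convergence controls.
#' @param n_starts Optimizer restarts for the first iteration (later
#'   iterations warm-start from the previous MAP).
#' @param var_floor Lower bound on group variances, preventing collapse of
#'   the prior onto a point.
#' @return An object of class `tcg_hfit`: per-variant group estimates
#'   (both scales), subject fits, the subjects x variants log-evidence
#'   matrix, responsibilities, and the random-effects model comparison.
#' @export
hierarchical_fit <- function(trials, variants = VARIANTS,
                             planner = tcg_planner(), board = tcg_board(),
                             max_iter = 50L, tol = 1e-3, n_starts = 5L,
                             var_floor = 0.01) {
  trials <- .as_trial_table(trials)
  variants <- match.arg(variants, VARIANTS, several.ok = TRUE)
  subdata <- .subject_data(trials, board)
  n <- length(subdata)
  if (n < 2L) stop("hierarchical_fit needs at least 2 subjects")
  K <- length(variants)
  group <- lapply(variants, function(vn) {
    d <- length(.variant_parnames(vn))
    list(mu = rep(0, d), v = rep(6.25, d))
  })
  names(group) <- variants
  fits <- vector("list", K)
  resp <- matrix(1 / K, n, K)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lme <- matrix(NA_real_, n, K,
                  dimnames = list(names(subdata), variants))
    for (k in seq_len(K)) {
      vn <- variants[k]
      fits[[k]] <- lapply(seq_len(n), function(i) {
        warm <- if (iter > 1L) fits[[k]][[i]]$theta else NULL
        .fit_subject_subdata(subdata[[i]], vn, group[[vn]], planner, board,
                             n_starts = if (iter == 1L) n_starts else 1L,
                             start = warm)
      })
      lme[, k] <- vapply(fits[[k]], function(f)
        if (isTRUE(f$flagged)) -1e10 else f$log_evidence, numeric(1))
    }
    # responsibilities: evidence weighted by current variant frequencies
    freq <- colMeans(resp)
    lw <- sweep(lme, 2L, log(freq), `+`)
    lw <- lw - apply(lw, 1L, max)
    resp <- exp(lw) / rowSums(exp(lw))
    # group updates
    max_shift <- 0
    for (k in seq_len(K)) {
      vn <- variants[k]
      th <- t(vapply(fits[[k]], `[[`, group[[vn]]$mu, "theta"))
      s2 <- t(vapply(fits[[k]], `[[`, group[[vn]]$v, "posterior_var"))
      if (sum(resp[, k]) < 1e-12) next  # variant carries no subjects
      w <- resp[, k] / sum(resp[, k])
      mu_new <- colSums(w * th)
      v_new <- pmax(colSums(w * (sweep(th, 2L, mu_new)^2 + s2)), var_floor)
      max_shift <- max(max_shift, abs(mu_new - group[[vn]]$mu))
      group[[vn]]$mu <- mu_new
      group[[vn]]$v <- v_new
    }
    if (max_shift < tol) { converged <- TRUE; break }
  }
  names(fits) <- variants
  comparison <- model_comparison(lme)
  group_params <- lapply(variants, function(vn)
    param_transform(vn)$to_natural(stats::setNames(group[[vn]]$mu,
                                                   .variant_parnames(vn))))
  names(group_params) <- variants
  structure(list(variants = variants, group = group,
                 group_params = group_params, subject_fits = fits,
                 log_evidence = lme, responsibilities = resp,
                 comparison = comparison, converged = converged,
                 iterations = iter, planner = planner, board = board),
            class = "tcg_hfit")
}

#' Summary table of a hierarchical fit
#'
#' One row per variant with the per-subject mean log-likelihood (at the
#' subject MAP estimates), summed log evidence, model frequency, protected
#' exceedance probability, and group parameter estimates on the natural
#' scale.
#'
#' @param hfit A `tcg_hfit` object.
#' @return Data frame, one row per variant.
#' @export
comparison_table <- function(hfit) {
  stopifnot(inherits(hfit, "tcg_hfit"))
  K <- length(hfit$variants)
  rows <- lapply(seq_len(K), function(k) {
    vn <- hfit$variants[k]
    nll <- vapply(hfit$subject_fits[[vn]], `[[`, numeric(1), "nll")
    gp <- hfit$group_params[[vn]]
    data.frame(model = vn,
               log_lik_mean = -mean(nll),
               log_lik_sum = -sum(nll),
               log_evidence = sum(hfit$log_evidence[, k]),
               model_frequency = hfit$comparison$model_frequency[k],
               pep = hfit$comparison$pep[k],
               tau = gp[["tau"]], epsilon = gp[["epsilon"]],
               lambda = if ("lambda" %in% names(gp)) gp[["lambda"]] else NA,
               gamma = if ("gamma" %in% names(gp)) gp[["gamma"]] else NA,
               alpha = if ("alpha" %in% names(gp)) gp[["alpha"]] else NA)
  })
  do.call(rbind, rows)
}

#' @export
print.tcg_hfit <- function(x, ...) {
  cat(sprintf("TCG hierarchical fit: %d subjects, variants %s (%s, %d iterations)\n",
              nrow(x$log_evidence), paste(x$variants, collapse = "/"),
              if (x$converged) "converged" else "not converged",
              x$iterations))
  tab <- comparison_table(x)
  tab[-1L] <- lapply(tab[-1L], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
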