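#' Default (JZS) Bayes factor for a two-sample comparison
#'
#' Computes the two-sample default Bayes factor with a Jeffreys-Zellner-Siow
#' prior (Cauchy prior of scale `rscale` on the standardized effect,
#' Jeffreys prior on the variance) by numerical integration of the
#' marginal likelihood over the Cauchy mixing variable.  `BF01 > 1` is
#' evidence for no group difference.
#'
#' @param x,y Numeric samples (each `n >= 2`, not jointly constant).
#' @param rscale Cauchy prior scale; default `sqrt(2)/2`, the conventional
#'   medium scale.
#' @return List of class `tcg_bf`: `bf01`, `bf10`, `t`, `df`, group means
#'   and sizes.
#' @export
bf01_ttest <- function(x, y, rscale = sqrt(2) / 2) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(c(x, y)) == 0)
    stop("degenerate zero-variance samples")
  n1 <- length(x); n2 <- length(y)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  t <- unname(tt$statistic)
  bf10 <- .jzs_bf10(t, n1, n2, rscale)
  structure(list(bf01 = 1 / bf10, bf10 = bf10, t = t, df = n1 + n2 - 2,
                 mean_x = mean(x), mean_y = mean(y), n1 = n1, n2 = n2,
                 rscale = rscale),
            class = "tcg_bf")
}

# two-sample JZS Bayes factor BF10 (Rouder et al. style): integrate the
# alternative's marginal over g ~ InverseGamma(1/2, rscale^2/2), with
# effective sample size N = n1 n2 / (n1 + n2) and df nu = n1 + n2 - 2.
.jzs_bf10 <- function(t, n1, n2, rscale) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    log_f <- -0.5 * log1p(N * g * rscale^2) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + N * g * rscale^2) * nu)) -
      log_h0 +
      stats::dgamma(1 / g, shape = 0.5, rate = 0.5, log = TRUE) -
      2 * log(g)  # inverse-gamma density via 1/g jacobian
    exp(log_f)
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' @export
print.tcg_bf <- function(x, ...) {
  cat(sprintf("JZS Bayes factor: BF01 = %.3f (t = %.3f, df = %d, means %.3f vs %.3f)\n",
              x$bf01, x$t, x$df, x$mean_x, x$mean_y))
  invisible(x)
}

# index columns compared in posterior predictive checks
.ppc_index_columns <- function() {
  c(paste0("freq_", c("enter_exit", "wiggly", "pass_by")),
    paste0("freq_", c("enter_exit", "wiggly", "pass_by"), "_direct"),
    paste0("freq_", c("enter_exit", "wiggly", "pass_by"), "_indirect"),
    paste0("prof_", c("F", "L", "R", "B")))
}

#' Posterior predictive check report
#'
#' One default Bayes factor per behavioral index, comparing the
#' per-subject index values of the observed cohort against those of a
#' model-simulated cohort.  `BF01 < 1` flags an index on which the model
#' fails to reproduce the data.
#'
#' @param observed,simulated [summarize_indices()] results with matching
#'   index sets.
#' @param indices Index columns to compare (defaults to the message-type
#'   frequencies overall and by trial type, and the profile components).
#' @param rscale JZS prior scale passed to [bf01_ttest()].
#' @return Data frame of class `tcg_ppc`: index, observed and simulated
#'   group means, t, BF01, and the mismatch flag.
#' @export
ppc_report <- function(observed, simulated,
                       indices = .ppc_index_columns(),
                       rscale = sqrt(2) / 2) {
  stopifnot(inherits(observed, "tcg_indices"),
            inherits(simulated, "tcg_indices"))
  missing <- setdiff(indices, intersect(names(observed$per_subject),
                                        names(simulated$per_subject)))
  if (length(missing))
    stop("index set mismatch: ", paste(missing, collapse = ", "))
  rows <- lapply(indices, function(ix) {
    xo <- observed$per_subject[[ix]]
    xs <- simulated$per_subject[[ix]]
    bf <- tryCatch(bf01_ttest(xo, xs, rscale), error = function(e) NULL)
    data.frame(index = ix,
               observed_mean = mean(xo, na.rm = TRUE),
               simulated_mean = mean(xs, na.rm = TRUE),
               t = if (is.null(bf)) NA_real_ else bf$t,
               bf01 = if (is.null(bf)) NA_real_ else bf$bf01,
               mismatch = if (is.null(bf)) NA else bf$bf01 < 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tcg_ppc", "data.frame")
  out
}

#' @export
print.tcg_ppc <- function(x, digits = 3, ...) {
  cat("Posterior predictive check (JZS BF01 per index; * = mismatch)\n")
  y <- as.data.frame(x)
  y$observed_mean <- round(y$observed_mean, digits)
  y$simulated_mean <- round(y$simulated_mean, digits)
  y$t <- round(y$t, 2); y$bf01 <- round(y$bf01, 2)
  y$mismatch <- ifelse(is.na(y$mismatch), "?", ifelse(y$mismatch, "*", ""))
  print(y, row.names = FALSE)
  invisible(x)
}
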