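#' Random-effects Bayesian model comparison
#'
#' Treats the variant generating each subject's data as a random effect
#' with population frequencies `r ~ Dirichlet(alpha0)` (`alpha0 = 1`
#' uniform).  A variational update yields the posterior Dirichlet
#' concentration `alpha`; model frequencies are its mean.  Exceedance
#' probabilities (EP, the probability that a variant is the most frequent)
#' are estimated by Monte-Carlo sampling from the Dirichlet posterior.
#' The Bayes omnibus risk (BOR) is the posterior probability of the null
#' model in which all variants are equally frequent, computed by comparing
#' the variational free energy of the random-effects model against the
#' equal-frequency marginal likelihood; protected exceedance probabilities
#' are `PEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param log_evidences Numeric matrix, subjects x variants, of log model
#'   evidences (e.g. `$log_evidence` of a [hierarchical_fit()]).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param alpha0 Prior Dirichlet concentration (scalar, default 1).
#' @return An object of class `tcg_bms` with elements `alpha`,
#'   `model_frequency`, `ep`, `bor`, `pep`, and the per-subject posterior
#'   assignment probabilities `g`.
#' @export
model_comparison <- function(log_evidences, n_samples = 1e6, alpha0 = 1) {
  lme <- as.matrix(log_evidences)
  if (any(!is.finite(lme))) stop("log evidence matrix must be finite")
  n <- nrow(lme); K <- ncol(lme)
  labels <- colnames(lme)
  if (is.null(labels)) labels <- paste0("m", seq_len(K))
  if (K == 1L) {
    return(structure(list(alpha = stats::setNames(alpha0 + n, labels),
                          model_frequency = stats::setNames(1, labels),
                          ep = stats::setNames(1, labels),
                          bor = 0, pep = stats::setNames(1, labels),
                          g = matrix(1, n, 1,
                                     dimnames = list(NULL, labels))),
                     class = "tcg_bms"))
  }
  alpha <- rep(alpha0, K)
  g <- matrix(1 / K, n, K)
  for (iter in 1:200) {
    lw <- sweep(lme, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1L, max)
    g <- exp(lw) / rowSums(exp(lw))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  freq <- alpha / sum(alpha)
  # exceedance probabilities by Dirichlet Monte Carlo
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha,
                                                           each = n_samples)),
                  n_samples, K)
  ep <- tabulate(max.col(draws), nbins = K) / n_samples
  bor <- .bayes_omnibus_risk(lme, alpha, rep(alpha0, K), g)
  pep <- ep * (1 - bor) + bor / K
  structure(list(alpha = stats::setNames(alpha, labels),
                 model_frequency = stats::setNames(freq, labels),
                 ep = stats::setNames(ep, labels), bor = bor,
                 pep = stats::setNames(pep, labels),
                 g = `dimnames<-`(g, list(rownames(lme), labels))),
            class = "tcg_bms")
}

# free energy of the random-effects model vs the equal-frequency null:
#   F1 = E_q[log p(y|m)] + E_q[log p(m|r)] - KL(q(r)||p(r)) + H[q(m)]
#   F0 = sum_n log( (1/K) sum_k exp(lme_nk) )
#   BOR = 1 / (1 + exp(F1 - F0))
.bayes_omnibus_risk <- function(lme, alpha, alpha0, g) {
  K <- ncol(lme)
  e_log_r <- digamma(alpha) - digamma(sum(alpha))
  f1 <- sum(g * lme) + sum(g %*% e_log_r) -
    .kl_dirichlet(alpha, alpha0) - sum(g[g > 0] * log(g[g > 0]))
  mx <- apply(lme, 1L, max)
  f0 <- sum(mx + log(rowMeans(exp(lme - mx))))
  1 / (1 + exp(f1 - f0))
}

.kl_dirichlet <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  lgamma(sa) - sum(lgamma(a)) - lgamma(sb) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sa)))
}

#' @export
print.tcg_bms <- function(x, ...) {
  cat("Random-effects model comparison\n")
  print(data.frame(model = names(x$model_frequency),
                   frequency = round(x$model_frequency, 3),
                   ep = round(x$ep, 3), pep = round(x$pep, 3),
                   row.names = NULL), row.names = FALSE)
  cat(sprintf("Bayes omnibus risk: %.4f\n", x$bor))
  invisible(x)
}
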