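test_that("parameter transforms round-trip on a grid over the box", {
  for (vn in c("surprise", "state", "movement")) {
    tr <- param_transform(vn)
    grids <- list(lambda = c(0.002, 0.05, 0.15, 0.29),
                  gamma = c(2.1, 4, 7, 9.9),
                  epsilon = c(0.05, 0.4, 0.9),
                  tau = c(0.1, 2, 20),
                  alpha = c(1.05, 1.8, 5))
    pn <- tr$parnames
    for (i in 1:8) {
      vals <- vapply(pn, function(nm)
        grids[[nm]][(i %% length(grids[[nm]])) + 1], numeric(1))
      theta <- tr$to_unconstrained(vals)
      back <- tr$to_natural(theta)
      expect_equal(back, vals, tolerance = 1e-10)
    }
  }
})

test_that("negative log-likelihood is additive and hits the uniform limit", {
  set.seed(17)
  spec <- tcg_synthetic_spec(n_subjects = 1, trials_per_subject = 12,
                             group_sd = 0)
  co <- simulate_cohort(spec)
  trials <- co$trials[!co$trials$aborted, ]
  params <- default_group_params()
  nll <- negative_loglik(trials, params)
  expect_true(is.finite(nll) && nll > 0)
  # equals the summed per-trial sequence likelihoods
  lls <- vapply(seq_len(nrow(trials)), function(i) {
    cfg <- tcg_config(
      tcgsurprise:::.parse_state(trials$start[i]),
      tcgsurprise:::.parse_state(trials$sender_goal[i]),
      tcgsurprise:::.parse_state(trials$receiver_goal[i]))
    msg <- tcg_message(tcgsurprise:::.parse_trajectory(trials$trajectory[i]))
    sequence_loglik(msg, cfg, params)
  }, numeric(1))
  expect_equal(nll, -sum(lls), tolerance = 1e-10)
  # duplicating the data doubles the NLL exactly
  dup <- rbind(trials, transform(trials, trial_index = trial_index + 100))
  expect_equal(negative_loglik(dup, params), 2 * nll, tolerance = 1e-10)
  # tau -> 0: sum of log feasible-move counts
  tiny <- tcg_params("surprise", lambda = 0.1, gamma = 2.14, alpha = 1.84,
                     epsilon = 0.39, tau = 1e-9)
  ks <- unlist(lapply(trials$trajectory, function(tr) {
    st <- tcgsurprise:::.parse_trajectory(tr)
    vapply(seq_len(nrow(st) - 1), function(i)
      length(neighbors(tcg_board(), st[i, ])), numeric(1))
  }))
  expect_equal(negative_loglik(trials, tiny), sum(log(ks)),
               tolerance = 1e-5)
})

test_that("subject MAP fits recover generating parameters and warn when starved", {
  set.seed(23)
  spec <- tcg_synthetic_spec(n_subjects = 1, trials_per_subject = 80,
                             group_sd = 0)
  co <- simulate_cohort(spec)
  set.seed(1)
  fit <- fit_subject_map(co$trials, "surprise", n_starts = 3)
  expect_false(fit$flagged)
  expect_true(is.finite(fit$log_evidence))
  truth <- co$subject_params$S01
  expect_equal(unname(fit$params[c("lambda", "gamma", "epsilon")]),
               unname(truth[c("lambda", "gamma", "epsilon")]),
               tolerance = 0.35)
  # Laplace evidence is below the unpenalized maximum of the log-likelihood
  expect_lt(fit$log_evidence, -fit$nll + 1e-6)
  expect_warning(fit_subject_map(co$trials[1:5, ], "surprise",
                                 n_starts = 1, maxit = 5),
                 "fewer than 10")
})

test_that("random-effects comparison behaves on constructed evidence", {
  # equal evidences: frequencies 1/K, PEP near 1/K
  lme <- matrix(-50, 12, 3, dimnames = list(NULL, VARIANTS))
  set.seed(4)
  cmp <- model_comparison(lme, n_samples = 2e5)
  expect_equal(unname(cmp$model_frequency), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(unname(cmp$pep), rep(1 / 3, 3), tolerance = 0.05)
  expect_equal(sum(cmp$model_frequency), 1, tolerance = 1e-12)
  # one variant dominating every subject by >= 10 nats
  lme2 <- lme; lme2[, 1] <- lme2[, 1] + 10
  cmp2 <- model_comparison(lme2, n_samples = 2e5)
  expect_gt(cmp2$pep[1], 0.99)
  expect_equal(names(which.max(cmp2$model_frequency)), "surprise")
  # PEP identity and ranges
  expect_equal(unname(cmp2$pep),
               unname(cmp2$ep * (1 - cmp2$bor) + cmp2$bor / 3),
               tolerance = 1e-12)
  expect_true(cmp2$bor >= 0 && cmp2$bor <= 1)
  # two identical variants split responsibilities evenly
  lme3 <- cbind(a = rnorm(8, -40), b = 0)
  lme3[, 2] <- lme3[, 1]
  cmp3 <- model_comparison(lme3, n_samples = 1e5)
  expect_equal(unname(cmp3$model_frequency), c(0.5, 0.5), tolerance = 1e-6)
  # degenerate single-variant input
  cmp1 <- model_comparison(lme[, 1, drop = FALSE])
  expect_equal(unname(cmp1$model_frequency), 1)
  expect_equal(unname(cmp1$pep), 1)
})

test_that("hierarchical fit runs on a small cohort and attributes variants", {
  set.seed(41)
  spec <- tcg_synthetic_spec(n_subjects = 4, trials_per_subject = 40)
  co <- simulate_cohort(spec)
  set.seed(2)
  hf <- hierarchical_fit(co$trials[!co$trials$aborted, ],
                         variants = c("surprise", "state"),
                         max_iter = 4, n_starts = 2)
  expect_s3_class(hf, "tcg_hfit")
  expect_equal(unname(rowSums(hf$responsibilities)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(is.finite(hf$log_evidence)))
  expect_true(all(hf$group$surprise$v > 0))
  tab <- comparison_table(hf)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$log_lik_mean)))
  # data came from the surprise variant
  expect_equal(names(which.max(hf$comparison$model_frequency)), "surprise")
  expect_error(hierarchical_fit(co$trials[co$trials$subject_id == "S01", ]),
               "2 subjects")
})
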