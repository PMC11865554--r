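test_that("simulation runs write reproducible artifacts with a manifest", {
  spec <- tcg_synthetic_spec(n_subjects = 2, trials_per_subject = 6)
  out1 <- tempfile(); out2 <- tempfile()
  run_simulate(spec, out1, seed = 11)
  run_simulate(spec, out2, seed = 11)
  for (f in c("trials.csv", "steps.csv", "manifest.json")) {
    expect_true(file.exists(file.path(out1, f)))
  }
  # byte-identical payload under the same seed
  expect_identical(readLines(file.path(out1, "trials.csv")),
                   readLines(file.path(out2, "trials.csv")))
  expect_identical(readLines(file.path(out1, "steps.csv")),
                   readLines(file.path(out2, "steps.csv")))
  trials <- read_tcg_trials(file.path(out1, "trials.csv"))
  expect_equal(nrow(trials), 2 * 6)
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_equal(man$command, "simulate")
})

test_that("spec files load from YAML/JSON and bad specs error", {
  spec_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_subjects = 2, trials_per_subject = 4,
                            direct_fraction = 0.5,
                            group_params = list(lambda = 0.1, gamma = 2.14,
                                                alpha = 1.84,
                                                epsilon = 0.39, tau = 6.93)),
                       spec_file, auto_unbox = TRUE)
  out <- tempfile()
  run_simulate(spec_file, out, seed = 3)
  expect_equal(nrow(read_tcg_trials(file.path(out, "trials.csv"))), 8)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_subjects = 2, direct_fraction = 2), bad,
                       auto_unbox = TRUE)
  expect_error(run_simulate(bad, tempfile()))
})

test_that("fit runs produce a comparison table in JSON", {
  set.seed(61)
  spec <- tcg_synthetic_spec(n_subjects = 3, trials_per_subject = 25)
  dir <- tempfile(); dir.create(dir)
  run_simulate(spec, dir, seed = 13)
  out <- tempfile()
  fit <- run_fit(file.path(dir, "trials.csv"), out,
                 variants = c("surprise", "state"), seed = 1,
                 max_iter = 2, n_starts = 2)
  expect_s3_class(fit, "tcg_fit")
  cmp <- jsonlite::read_json(file.path(out, "comparison.json"),
                             simplifyVector = TRUE)
  expect_equal(sort(cmp$comparison$model), c("state", "surprise"))
  expect_true(all(c("pep", "group_params", "bor") %in% names(cmp)))
  fits <- jsonlite::read_json(file.path(out, "fits.json"),
                              simplifyVector = FALSE)
  expect_length(fits$surprise, 3)
  expect_true(all(c("params", "theta", "nll", "log_evidence") %in%
                    names(fits$surprise[[1]])))
})

test_that("the model object carries the standard methods", {
  set.seed(71)
  spec <- tcg_synthetic_spec(n_subjects = 3, trials_per_subject = 25)
  co <- simulate_cohort(spec)
  fit <- tcg_fit(co$trials, variants = c("surprise", "state"),
                 max_iter = 2, n_starts = 2)
  expect_true(best_variant(fit) %in% c("surprise", "state"))
  expect_named(coef(fit, "surprise"),
               c("lambda", "gamma", "alpha", "epsilon", "tau"))
  ll <- logLik(fit)
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(attr(ll, "nobs"), nrow(fit$trials))
  sim <- simulate(fit, seed = 5, variant = "surprise")
  expect_s3_class(sim, "tcg_cohort")
  expect_equal(nrow(sim$trials), nrow(fit$trials))
  cfg <- tcg_config(c(1, 1), c(3, 3), c(0, 2))
  pol <- predict(fit, cfg, type = "policy", variant = "surprise")[[1]]
  expect_equal(sum(pol), 1, tolerance = 1e-12)
  msg <- predict(fit, cfg, type = "message", variant = "surprise")[[1]]
  expect_s3_class(msg, "tcg_plan")
  expect_output(print(summary(fit)), "model comparison")
  pdf(NULL)
  m <- plot(fit, simulated = sim)
  dev.off()
  expect_equal(dim(m), c(2L, 4L))
})

test_that("physio runs write cluster and slope reports", {
  set.seed(81)
  spec <- tcg_synthetic_spec(n_subjects = 5, trials_per_subject = 15)
  dir <- tempfile(); dir.create(dir)
  run_simulate(spec, dir, seed = 17)
  out <- tempfile()
  res <- run_physio(file.path(dir, "steps.csv"), out, seed = 2,
                    amplitude = 1, noise_sd = 1, n_channels = 8,
                    n_timepoints = 20, n_perm = 100)
  expect_true(file.exists(file.path(out, "clusters.csv")))
  slope <- jsonlite::read_json(file.path(out, "pdr_slope.json"),
                               simplifyVector = TRUE)
  expect_true(is.numeric(slope$slope))
  expect_s3_class(res$clusters, "tcg_clusters")
})
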