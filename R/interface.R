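# Workflow entry points: each writes plain-text outputs plus a manifest
# (inputs, seeds, package version) sufficient to regenerate them.  A thin
# command-line dispatcher over these functions ships in inst/exec/tcg.

.write_manifest <- function(out_dir, command, seed, inputs, outputs) {
  manifest <- list(command = command, seed = seed, inputs = inputs,
                   outputs = outputs,
                   package = as.character(utils::packageVersion("tcgsurprise")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.load_spec_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML specs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  gp <- raw$group_params
  args <- raw[intersect(names(raw),
                        c("n_subjects", "trials_per_subject",
                          "direct_fraction", "variant", "group_sd",
                          "receiver_temperature", "pdr_slope",
                          "pdr_slope_sd", "pdr_intercept_sd",
                          "pdr_noise_sd"))]
  if (!is.null(gp)) {
    variant <- if (is.null(raw$variant)) "surprise" else raw$variant
    args$group_params <- do.call(tcg_params,
                                 c(list(variant = variant), gp))
  }
  do.call(tcg_synthetic_spec, args)
}

#' Simulate a synthetic cohort to disk
#'
#' @param spec A [tcg_synthetic_spec()] or path to a YAML/JSON file with
#'   its fields.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(spec = tcg_synthetic_spec(), out_dir, seed = 1L) {
  input <- if (is.character(spec)) spec else "inline spec"
  if (is.character(spec)) spec <- .load_spec_file(spec)
  stopifnot(inherits(spec, "tcg_synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cohort <- simulate_cohort(spec)
  trials_path <- file.path(out_dir, "trials.csv")
  steps_path <- file.path(out_dir, "steps.csv")
  write_tcg_trials(cohort$trials, trials_path)
  utils::write.csv(cohort$steps, steps_path, row.names = FALSE,
                   quote = FALSE)
  .write_manifest(out_dir, "simulate", seed,
                  list(spec = input,
                       variant = spec$variant,
                       n_subjects = spec$n_subjects,
                       trials_per_subject = spec$trials_per_subject,
                       group_params = as.list(spec$group_params$values)),
                  list(trials = "trials.csv", steps = "steps.csv"))
  invisible(c(trials = trials_path, steps = steps_path))
}

#' Fit and compare the planner variants from a trial file
#'
#' @param trials_file CSV trial table path.
#' @param out_dir Output directory.
#' @param variants Variant labels to fit.
#' @param seed Integer seed (optimizer restarts).
#' @param ... Passed to [tcg_fit()].
#' @return Invisibly, the fitted `tcg_fit` object.
#' @export
run_fit <- function(trials_file, out_dir, variants = VARIANTS, seed = 1L,
                    ...) {
  trials <- read_tcg_trials(trials_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  fit <- tcg_fit(trials, variants, ...)
  per_subject <- lapply(fit$hfit$variants, function(vn) {
    lapply(fit$hfit$subject_fits[[vn]], function(f)
      list(params = as.list(f$params), theta = as.list(f$theta),
           nll = f$nll, log_evidence = f$log_evidence))
  })
  names(per_subject) <- fit$hfit$variants
  jsonlite::write_json(
    list(comparison = comparison_table(fit$hfit),
         group_params = fit$hfit$group_params,
         pep = as.list(fit$hfit$comparison$pep),
         bor = fit$hfit$comparison$bor),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(per_subject, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "fit", seed,
                  list(trials = trials_file,
                       variants = as.list(variants)),
                  list(comparison = "comparison.json",
                       fits = "fits.json"))
  invisible(fit)
}

#' Posterior predictive check from a trial file and fitted parameters
#'
#' @param trials_file CSV trial table (the observed cohort).
#' @param out_dir Output directory.
#' @param fit A `tcg_fit` (e.g. from [run_fit()]); refitted from the
#'   trials when omitted.
#' @param variant Variant to simulate from.
#' @param seed Integer seed.
#' @return Invisibly, the [ppc_report()] table.
#' @export
run_ppc <- function(trials_file, out_dir, fit = NULL, variant = NULL,
                    seed = 1L) {
  trials <- read_tcg_trials(trials_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (is.null(fit)) fit <- tcg_fit(trials)
  if (is.null(variant)) variant <- best_variant(fit)
  sim <- simulate.tcg_fit(fit, variant = variant)
  report <- ppc_report(summarize_indices(trials),
                       summarize_indices(sim$trials))
  utils::write.csv(as.data.frame(report),
                   file.path(out_dir, "ppc.csv"), row.names = FALSE)
  .write_manifest(out_dir, "ppc", seed,
                  list(trials = trials_file, variant = variant),
                  list(ppc = "ppc.csv"))
  invisible(report)
}

#' Model-informed physiological analysis of synthetic epochs
#'
#' Generates a surprise-coupled synthetic physiological data set from a
#' cohort's step surprises (EEG-like epochs and per-step pupil values),
#' then runs the cluster-based permutation test and the two-stage pupil
#' slope test, writing both reports.
#'
#' @param steps_file CSV of per-step surprise values (from
#'   [run_simulate()]).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param amplitude,noise_sd EEG injection gain and noise level.
#' @param n_channels,n_timepoints Epoch grid.
#' @param n_perm Permutations for the cluster test.
#' @return Invisibly, list with the cluster result and the pupil test.
#' @export
run_physio <- function(steps_file, out_dir, seed = 1L, amplitude = 0.5,
                       noise_sd = 1, n_channels = 16L, n_timepoints = 61L,
                       n_perm = 1000L) {
  steps <- utils::read.csv(steps_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  subjects <- unique(steps$subject_id)
  n_ep <- min(table(steps$subject_id))
  nb <- channel_neighbors(n_channels)
  dat <- array(0, c(length(subjects), n_ep, n_channels, n_timepoints))
  sur <- matrix(0, length(subjects), n_ep)
  pdr <- list()
  for (i in seq_along(subjects)) {
    ss <- steps$surprise[steps$subject_id == subjects[i]][seq_len(n_ep)]
    sur[i, ] <- ss
    eeg <- simulate_eeg(ss, amplitude = amplitude, noise_sd = noise_sd,
                        n_channels = n_channels,
                        n_timepoints = n_timepoints, neighbors = nb)
    dat[i, , , ] <- eeg$data
    pdr[[i]] <- data.frame(
      subject = subjects[i], surprise = ss,
      pdr = simulate_pdr(ss, subject_effects = c(stats::rnorm(1, 0, 0.1),
                                                 stats::rnorm(1, 0, 0.01))))
  }
  epochs <- tcg_epochs(dat, sur, nb, seq(0, 1200,
                                         length.out = n_timepoints))
  epochs <- baseline_correct(epochs)
  betas <- epoch_regression(epochs)
  clusters <- cluster_permutation_test(betas, nb, n_perm = n_perm)
  pdr <- do.call(rbind, pdr)
  slope <- pdr_slope_test(pdr$pdr, pdr$surprise, pdr$subject)
  utils::write.csv(clusters$clusters, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(slope = slope$slope, ci = slope$ci, t = slope$statistic,
         df = slope$df, p = slope$p_value),
    file.path(out_dir, "pdr_slope.json"), auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "physio", seed,
                  list(steps = steps_file, amplitude = amplitude,
                       noise_sd = noise_sd, n_perm = n_perm),
                  list(clusters = "clusters.csv",
                       pdr = "pdr_slope.json"))
  invisible(list(clusters = clusters, pdr = slope))
}

#' Recompute published-style group statistics from a deposited trial table
#'
#' Thin adapter for full-data reproduction: expects the deposited
#' behavioral data converted to the package's CSV trial schema (see
#' [read_tcg_trials()]), then recomputes the model-free indices, the
#' hierarchical model comparison, and the posterior predictive Bayes
#' factors.  Point the option `tcgsurprise.deposited_dir` at a directory
#' containing `trials.csv` to enable it.
#'
#' @param dir Directory containing `trials.csv`.
#' @param fit Also run the (slow) hierarchical fit and PPC (default
#'   `TRUE`).
#' @param seed Integer seed.
#' @return List with `indices`, and when `fit` is `TRUE` the `comparison`
#'   table and `ppc` report.
#' @export
reproduce_dataset <- function(dir, fit = TRUE, seed = 1L) {
  trials <- read_tcg_trials(file.path(dir, "trials.csv"))
  out <- list(indices = summarize_indices(trials))
  if (fit) {
    set.seed(seed)
    f <- tcg_fit(trials)
    out$comparison <- comparison_table(f$hfit)
    sim <- simulate.tcg_fit(f)
    out$ppc <- ppc_report(out$indices, summarize_indices(sim$trials))
  }
  out
}
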